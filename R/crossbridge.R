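#' Bell-type load dependence of a transition rate
#'
#' Exponential load law `k(F) = k0 * exp(-F * d / kT)`: a resisting load
#' (positive `F`) slows the transition, an assisting load accelerates it; `d`
#' is the distance to the transition state along the pulling coordinate.
#'
#' @param k0 rate at zero load (s^-1 or mM^-1 s^-1).
#' @param d Bell distance parameter (nm, >= 0).
#' @param cond a [conditions()] object supplying `load` (pN) and `kT` (pN nm).
#' @return The loaded rate, same units as `k0`.
#' @export
#' @examples
#' load_rate(19.4, 1.8, conditions(atp = 2, load = 2))
load_rate <- function(k0, d, cond) {
  if (!(is.numeric(k0) && all(k0 > 0))) stop("k0 must be > 0", call. = FALSE)
  if (d < 0) stop("d must be >= 0", call. = FALSE)
  if (!(cond$kT > 0)) stop("kT must be > 0", call. = FALSE)
  k0 * exp(-cond$load * d / cond$kT)
}

# loaded exit rates of the two attached states
k1_loaded <- function(rates, cond) load_rate(rates$k1_0, rates$d1, cond)
k2_loaded <- function(rates, cond) load_rate(rates$k2_0, rates$d2, cond)

#' Mean actin-attached time of the cycle
#'
#' The attached phase is sequential: an ADP-bound post-stroke state left at
#' `k1(F)` followed by a rigor state left by ATP binding at `k2(F) * [ATP]`,
#' so `t_on = 1/k1(F) + 1/(k2(F) * atp)`.
#'
#' @param rates a [cycle_rates()] object.
#' @param cond a [conditions()] object; `atp` must be > 0 unless
#'   `zero_atp = "Inf"`.
#' @param zero_atp what to do at `atp == 0`: `"error"` (default) or `"Inf"`.
#' @return Mean attached time (s).
#' @export
#' @examples
#' mean_attached_time(cycle_rates(19.4, 55), conditions(atp = 0.1))
mean_attached_time <- function(rates, cond, zero_atp = c("error", "Inf")) {
  zero_atp <- match.arg(zero_atp)
  if (cond$atp == 0) {
    if (zero_atp == "Inf") return(Inf)
    stop("atp must be > 0 (rigor state never exits)", call. = FALSE)
  }
  1 / k1_loaded(rates, cond) + 1 / (k2_loaded(rates, cond) * cond$atp)
}

#' Apparent duty ratio
#'
#' Fraction of the full cycle spent attached to actin,
#' `t_on / (t_on + t_off)` with `t_off = 1/k_att`.
#'
#' @inheritParams mean_attached_time
#' @return Duty ratio in (0, 1).
#' @export
apparent_duty_ratio <- function(rates, cond) {
  t_on <- mean_attached_time(rates, cond)
  t_on / (t_on + 1 / rates$k_att)
}

#' Predicted actin-gliding velocity
#'
#' Single-attached-head limit `v = ws_total / t_on`.  The absolute number is
#' an upper bound on measured gliding speed; the ratio between variants is the
#' quantitative prediction.
#'
#' @param mech a [mech_params()] object.
#' @inheritParams mean_attached_time
#' @return Velocity (nm s^-1).
#' @export
predicted_gliding_velocity <- function(mech, rates, cond) {
  if (mech$ws_total == 0) return(0)
  mech$ws_total / mean_attached_time(rates, cond)
}

#' Stall force of a single motor head
#'
#' The maximum force a head can hold equals the working stroke times the
#' crossbridge stiffness of the selected attached state,
#' `F_stall = ws_total * kappa(state)`.
#'
#' @param mech a [mech_params()] object.
#' @param state `"rigor"` (default) or `"pre"` (ADP-bound, pre-rigor).
#' @return Stall force (pN).
#' @export
#' @examples
#' stall_force(mech_params(18, kappa_rigor = 0.25))  # 4.5 pN
stall_force <- function(mech, state = c("rigor", "pre")) {
  state <- match.arg(state)
  kappa <- switch(state, rigor = mech$kappa_rigor, pre = mech$kappa_pre)
  mech$ws_total * kappa
}

#' Occupancy of the nucleotide-free rigor state
#'
#' Fraction of the attached time spent in rigor,
#' `(1/(k2(F) atp)) / t_on(F, atp)`.  Because `d2 > d1` for MYO6, resisting
#' load shifts attached time into rigor, which becomes the dominant attached
#' state near stall.
#'
#' @inheritParams mean_attached_time
#' @return Fraction in (0, 1).
#' @export
rigor_occupancy <- function(rates, cond) {
  t_rigor <- 1 / (k2_loaded(rates, cond) * cond$atp)
  t_rigor / mean_attached_time(rates, cond)
}

#' Closed-form cycle summary for one variant
#'
#' Evaluates the cycle model at given conditions: mean attached time, duty
#' ratio, predicted gliding velocity, rigor occupancy and stall forces.
#'
#' @param variant variant name passed to [myo6_variant()], or a list with
#'   `rates` and `mech` components.
#' @param cond a [conditions()] object.
#' @return A one-row `data.frame`.
#' @export
#' @examples
#' cycle_summary("S267E", conditions(atp = 2))
cycle_summary <- function(variant, cond) {
  v <- if (is.character(variant)) myo6_variant(variant) else variant
  data.frame(
    variant = if (is.character(variant)) variant else v$variant %||% "custom",
    atp_mM = cond$atp, load_pN = cond$load,
    t_on_s = mean_attached_time(v$rates, cond),
    duty_ratio = apparent_duty_ratio(v$rates, cond),
    velocity_nm_s = predicted_gliding_velocity(v$mech, v$rates, cond),
    rigor_occupancy = rigor_occupancy(v$rates, cond),
    stall_pre_pN = stall_force(v$mech, "pre"),
    stall_rigor_pN = stall_force(v$mech, "rigor"),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
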