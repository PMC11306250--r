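# Load-resolved kinetics: bin events by mean crossbridge load, estimate
# per-bin rates, fit the Bell relation k = k0 exp(-F d / kT).

#' Bin events by mean crossbridge load
#'
#' @param events a data.frame with a `mean_load` column (pN).
#' @param bin_edges numeric vector of bin boundaries (pN).
#' @param min_events bins with fewer events are dropped with a warning
#'   (default 10).
#' @return Named list of event subsets; names are bin centres, each element
#'   carries attribute `mean_load` (the within-bin mean).
#' @export
bin_events_by_load <- function(events, bin_edges, min_events = 10) {
  if (nrow(events) == 0) stop("no events to bin", call. = FALSE)
  if (is.null(events$mean_load)) stop("events carry no mean_load", call. = FALSE)
  grp <- cut(events$mean_load, breaks = bin_edges, include.lowest = TRUE)
  out <- split(as.data.frame(events), grp, drop = FALSE)
  small <- vapply(out, nrow, integer(1)) < min_events
  if (all(small)) stop("all load bins underpopulated", call. = FALSE)
  if (any(small))
    warning(sum(small), " underpopulated load bin(s) dropped", call. = FALSE)
  out <- out[!small]
  for (i in seq_along(out))
    attr(out[[i]], "mean_load") <- mean(out[[i]]$mean_load)
  out
}

#' Fit the Bell load law to per-bin rates
#'
#' Weighted least squares of `log k` against `F`: `log k = log k0 - F d/kT`,
#' giving the zero-load rate `k0` and distance parameter `d` (resisting load
#' positive).  Weights are `(k/sigma_k)^2` (delta method on log k) when rate
#' uncertainties are supplied.
#'
#' @param force per-bin mean loads (pN), >= 3 values.
#' @param rate per-bin rates (s^-1 or mM^-1 s^-1), > 0.
#' @param rate_se optional per-bin rate standard errors.
#' @param kT thermal energy (pN nm, default 4.07); fixed, not fitted.
#' @return An object of class `bell_fit`: `k0`, `d` (nm), `stderr`, `n_bins`,
#'   `bins` (the (F, k, se) table).
#' @export
#' @examples
#' F <- c(-1, 0, 1, 2)
#' fit_bell(F, 19.4 * exp(-F * 1.8 / 4.07))
fit_bell <- function(force, rate, rate_se = NULL, kT = 4.07) {
  if (length(force) < 3) stop("need >= 3 (F, k) points", call. = FALSE)
  if (any(rate <= 0)) stop("non-positive rates", call. = FALSE)
  w <- if (is.null(rate_se)) rep(1, length(rate)) else (rate / rate_se)^2
  fit <- stats::lm(log(rate) ~ force, weights = w)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  d <- -cf[[2]] * kT
  structure(list(
    k0 = exp(cf[[1]]), d = d,
    stderr = c(k0 = exp(cf[[1]]) * se[[1]], d = se[[2]] * kT),
    n_bins = length(force),
    bins = data.frame(force = force, rate = rate,
                      rate_se = rate_se %||% NA_real_)),
    class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf("<bell_fit> k0 = %.3g +/- %.2g, d = %.3g +/- %.2g nm (%d bins)\n",
              x$k0, x$stderr[["k0"]], x$d, x$stderr[["d"]], x$n_bins))
  invisible(x)
}

#' Load-resolved rates from binned dwell fits
#'
#' Runs [cumulative_dwell_fit()] in every load bin and extracts the ADP
#' (faster, ATP-independent) and ATP (slower at the assay's sub-saturating
#' ATP) branch rates, then fits the Bell relation to each branch.
#'
#' @param bins result of [bin_events_by_load()].
#' @param atp ATP concentration (mM) used to convert the ATP-branch rate to
#'   mM^-1 s^-1.
#' @param kT thermal energy (pN nm).
#' @param branch_order how to assign the two fitted rates to branches:
#'   `"k1_faster"` (default; valid when `k1 > k2_obs*atp` across the sweep)
#'   labels the faster component as the ADP branch.
#' @return List with `bell_k1` and `bell_k2` ([fit_bell()] objects; `bell_k2`
#'   rates in mM^-1 s^-1) and the per-bin rate table.
#' @export
load_resolved_bell <- function(bins, atp, kT = 4.07,
                               branch_order = "k1_faster") {
  tab <- lapply(bins, function(ev) {
    f <- cumulative_dwell_fit(ev$dwell)
    data.frame(force = attr(ev, "mean_load"),
               k_fast = f$k2_obs, k_fast_se = f$stderr[["k2_obs"]],
               k_slow = f$k1, k_slow_se = f$stderr[["k1"]],
               n = f$n_events)
  })
  tab <- do.call(rbind, tab)
  bell_k1 <- fit_bell(tab$force, tab$k_fast, tab$k_fast_se, kT)
  bell_k2 <- fit_bell(tab$force, tab$k_slow / atp, tab$k_slow_se / atp, kT)
  list(bell_k1 = bell_k1, bell_k2 = bell_k2, rates = tab)
}
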