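#' Kinetic constants of one motor variant
#'
#' Zero-load rate constants and Bell distance parameters of the three-state
#' actomyosin cycle used throughout the package: detached -> post-stroke-1
#' (ADP-bound) -> rigor (nucleotide free) -> detached.  The attached phase is
#' left via ADP release (`k1_0`) followed by second-order ATP binding
#' (`k2_0 * [ATP]`); both rates carry Bell-type load sensitivity with distance
#' parameters `d1` and `d2`.
#'
#' @param k1_0 ADP-release rate at zero load (s^-1).
#' @param k2_0 second-order ATP-binding constant at zero load (mM^-1 s^-1).
#' @param d1,d2 Bell distance parameters for `k1` and `k2` (nm, >= 0).
#' @param k_att attachment rate from the detached state (s^-1). The assay does
#'   not fix this number; the default 0.5 s^-1 gives the ~2 s detached periods
#'   that make duty ratios "apparent".
#' @return An object of class `cycle_rates`.
#' @export
#' @examples
#' cycle_rates(19.4, 55, d1 = 1.8, d2 = 2.8)
cycle_rates <- function(k1_0, k2_0, d1 = 0, d2 = 0, k_att = 0.5) {
  stopifnot(is.numeric(k1_0), is.numeric(k2_0))
  if (!(k1_0 > 0 && k2_0 > 0 && k_att > 0))
    stop("all rates must be > 0", call. = FALSE)
  if (d1 < 0 || d2 < 0)
    stop("Bell distances d1, d2 must be >= 0", call. = FALSE)
  structure(list(k1_0 = k1_0, k2_0 = k2_0, d1 = d1, d2 = d2, k_att = k_att),
            class = "cycle_rates")
}

#' Mechanical parameters of the three-bead dumbbell assay
#'
#' Working-stroke amplitudes and the elastic/viscous constants of the linear
#' network formed by two trapped beads, the actin dumbbell and the attached
#' crossbridge.  Units: nm, pN, pN nm^-1, s.
#'
#' @param ws_total total working stroke (nm).
#' @param ws1,ws2 substep amplitudes (nm); must sum to `ws_total`. Default
#'   splits `ws_total` into a large first substep and a 3-nm second substep
#'   completed on ADP release.
#' @param kappa_pre crossbridge stiffness before rigor (ADP state, pN nm^-1).
#' @param kappa_rigor crossbridge stiffness in the nucleotide-free state.
#' @param kappa_trap single-trap stiffness (pN nm^-1, default 0.02).
#' @param kappa_link actin-to-bead connection stiffness (pN nm^-1, >= 1).
#' @param bead_radius bead radius (nm, default 500).
#' @param viscosity solvent viscosity (pN s nm^-2; default water at 22 C).
#' @param gamma_rod drag coefficient assigned to the rigid actin-rod
#'   coordinate (pN s nm^-1); small compared to the bead drag.
#' @return An object of class `mech_params`.
#' @export
#' @examples
#' mech_params(18.2, kappa_pre = 0.25, kappa_rigor = 0.35)
mech_params <- function(ws_total, ws1 = ws_total - 3, ws2 = ws_total - ws1,
                        kappa_pre = 0.25, kappa_rigor = 0.25,
                        kappa_trap = 0.02, kappa_link = 1.0,
                        bead_radius = 500, viscosity = 9.544e-10,
                        gamma_rod = 1e-6) {
  if (abs(ws1 + ws2 - ws_total) > 1e-9)
    stop("ws1 + ws2 must equal ws_total", call. = FALSE)
  for (nm in c("kappa_pre", "kappa_rigor", "kappa_trap", "kappa_link",
               "bead_radius", "viscosity", "gamma_rod")) {
    v <- get(nm)
    if (!(is.numeric(v) && v > 0)) stop(nm, " must be > 0", call. = FALSE)
  }
  if (kappa_link < 1.0)
    stop("kappa_link must be >= 1.0 pN/nm (dumbbell pre-tensioned)",
         call. = FALSE)
  structure(list(ws_total = ws_total, ws1 = ws1, ws2 = ws2,
                 kappa_pre = kappa_pre, kappa_rigor = kappa_rigor,
                 kappa_trap = kappa_trap, kappa_link = kappa_link,
                 bead_radius = bead_radius, viscosity = viscosity,
                 gamma_rod = gamma_rod),
            class = "mech_params")
}

#' Drag coefficient of a trapped bead
#'
#' Stokes drag `6 pi eta r` in pN s nm^-1.
#' @param mech a [mech_params()] object.
#' @export
bead_drag <- function(mech) 6 * pi * mech$viscosity * mech$bead_radius

#' Experimental conditions
#'
#' @param atp ATP concentration (mM, >= 0).
#' @param load signed force on the crossbridge (pN); resisting load positive,
#'   assisting negative.
#' @param kT thermal energy (pN nm); default 4.07 pN nm (22 C assay
#'   temperature).
#' @return An object of class `trap_conditions`.
#' @export
conditions <- function(atp, load = 0, kT = 4.07) {
  if (!is.numeric(atp) || atp < 0) stop("atp must be >= 0", call. = FALSE)
  if (!(kT > 0)) stop("kT must be > 0", call. = FALSE)
  structure(list(atp = atp, load = load, kT = kT), class = "trap_conditions")
}

#' MYO6 variant parameter sets
#'
#' Kinetic and mechanical parameters for the wild-type and the S267
#' phospho-mutant motors, as measured in single-molecule trap assays (rates,
#' working stroke, stiffness, Bell distances) and in stopped-flow solution
#' kinetics (`sf`: ADP-release rate at 2 mM ATP chase, and second-order
#' ATP-induced dissociation constant).  Shipped as a JSON table under
#' `inst/extdata/variants.json`.
#'
#' @param name one of `"WT"`, `"S267A"`, `"S267E"`.
#' @return A list with elements `rates` ([cycle_rates()]), `mech`
#'   ([mech_params()]) and `sf` (list with `k_adp` s^-1 and `k2` mM^-1 s^-1).
#' @export
#' @examples
#' myo6_variant("S267E")$rates$k1_0
myo6_variant <- function(name = c("WT", "S267A", "S267E")) {
  name <- match.arg(name)
  tab <- myo6_variant_table()
  v <- tab[[name]]
  list(
    variant = name,
    rates = cycle_rates(v$k1_0, v$k2_0, d1 = v$d1, d2 = v$d2,
                        k_att = v$k_att),
    mech = mech_params(v$ws_total, kappa_pre = v$kappa_pre,
                       kappa_rigor = v$kappa_rigor),
    sf = v$sf
  )
}

#' @rdname myo6_variant
#' @export
myo6_variant_table <- function() {
  path <- system.file("extdata", "variants.json", package = "myotrap",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' @export
print.cycle_rates <- function(x, ...) {
  cat(sprintf(
    "<cycle_rates> k1_0 = %.3g /s  k2_0 = %.3g /mM/s  d1 = %.2g nm  d2 = %.2g nm  k_att = %.3g /s\n",
    x$k1_0, x$k2_0, x$d1, x$d2, x$k_att))
  invisible(x)
}

#' @export
print.mech_params <- function(x, ...) {
  cat(sprintf(
    "<mech_params> W/S %.3g nm (%.3g + %.3g)  kappa pre/rigor %.3g/%.3g  trap %.3g  link %.3g pN/nm\n",
    x$ws_total, x$ws1, x$ws2, x$kappa_pre, x$kappa_rigor, x$kappa_trap,
    x$kappa_link))
  invisible(x)
}
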