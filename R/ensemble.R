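# Start/end-synchronised ensemble averaging of displacement and of
# demodulated crossbridge stiffness through the attached period.

#' Start/end-synchronised ensemble average of event displacement
#'
#' Events are placed on a common grid (one point per sample) synchronised at
#' the chosen edge.  Events shorter than the grid are extended: for start
#' alignment, by the mean of their last 20 samples (the level reached at the
#' end of the event); for end alignment, by the mean of their first 20
#' samples prepended at the beginning.  After extension every grid point
#' averages the same number of events.
#'
#' @param trace a `trap_trace` (forcing-free protocol for displacement).
#' @param events a [detect_events()] table (>= 20 events; events shorter than
#'   20 samples are excluded with a warning).
#' @param alignment `"start"` or `"end"`.
#' @param grid_quantile event-length quantile defining the grid length
#'   (default 0.9; longer events are truncated at the grid).
#' @param baseline subtract each event's flanking detached baseline
#'   (default TRUE): the average then reads displacement in nm.
#' @return An object of class `ensemble_average`: list with `time` (s,
#'   relative to the alignment edge), `mean` (nm), `n_contrib`, `n_events`,
#'   `alignment`.
#' @export
align_and_average <- function(trace, events, alignment = c("start", "end"),
                              grid_quantile = 0.9, baseline = TRUE) {
  alignment <- match.arg(alignment)
  fs <- trace$sample_rate
  if (nrow(events) < 20) stop("need >= 20 events", call. = FALSE)
  len <- round(events$dwell * fs)
  short <- len < 20
  if (any(short)) {
    warning(sum(short), " events shorter than 20 samples excluded",
            call. = FALSE)
    events <- events[!short, , drop = FALSE]
    len <- len[!short]
  }
  n_grid <- max(20L, round(stats::quantile(len, grid_quantile)))
  x <- trace$x_passive
  acc <- numeric(n_grid)
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$t_start[i] * fs) + 1L
    i1 <- min(i0 + len[i] - 1L, length(x))
    seg <- x[i0:i1]
    # per-event detached baseline recovered from the detection record:
    # displacement = mean(event) - baseline
    if (baseline) seg <- seg - (mean(seg) - events$displacement[i])
    if (alignment == "start") {
      pad <- mean(seg[max(1L, length(seg) - 19L):length(seg)])
      v <- c(seg, rep(pad, max(0L, n_grid - length(seg))))[seq_len(n_grid)]
    } else {
      pad <- mean(seg[seq_len(min(20L, length(seg)))])
      v <- c(rep(pad, max(0L, n_grid - length(seg))), seg)
      v <- v[seq.int(length(v) - n_grid + 1L, length(v))]
    }
    acc <- acc + v
  }
  avg <- acc / nrow(events)
  tgrid <- if (alignment == "start") (seq_len(n_grid) - 1) / fs else
    -rev(seq_len(n_grid) - 1) / fs
  structure(list(time = tgrid, mean = avg, n_contrib = rep(nrow(events), n_grid),
                 n_events = nrow(events), alignment = alignment),
            class = "ensemble_average")
}

#' Single-exponential fit of an ensemble-averaged time course
#'
#' Fits `f(t) = A exp(-k t) + y0` by least squares; for end-aligned
#' ensembles time runs backwards from the alignment point.
#'
#' @param avg an [align_and_average()] / [ensemble_stiffness()] time course,
#'   or a list with `time` and `mean` (>= 30 grid points).
#' @return List with `A`, `k` (s^-1, > 0), `y0` and `stderr`.
#' @export
fit_single_exponential <- function(avg) {
  t <- avg$time; y <- avg$mean
  if (avg$alignment %||% "start" == "end") t <- -t
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 30) stop("need >= 30 grid points", call. = FALSE)
  o <- order(t); t <- t[o]; y <- y[o]
  span <- max(t) - min(t)
  y_inf <- mean(y[t > max(t) - span / 5])
  y_0 <- mean(y[t < min(t) + span / 20])
  k0 <- 3 / span
  # crude rate guess from the 1/e crossing
  ycross <- y_inf + (y_0 - y_inf) / exp(1)
  icross <- which(if (y_0 < y_inf) y >= ycross else y <= ycross)[1]
  if (!is.na(icross) && t[icross] > 0) k0 <- 1 / t[icross]
  fit <- NULL; last_err <- NULL
  for (kf in c(1, 3, 1 / 3, 10)) {
    cand <- tryCatch(suppressWarnings(stats::nls(
      y ~ A * exp(-k * t) + y0, data = data.frame(t = t, y = y),
      start = list(A = y_0 - y_inf, k = k0 * kf, y0 = y_inf),
      lower = c(-Inf, 1e-9, -Inf), algorithm = "port",
      control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
      error = function(e) { last_err <<- e; NULL })
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit)))
      fit <- cand
  }
  if (is.null(fit))
    stop("exponential fit did not converge: ", conditionMessage(last_err),
         call. = FALSE)
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  list(A = cf[["A"]], k = cf[["k"]], y0 = cf[["y0"]],
       stderr = c(A = se[["A"]], k = se[["k"]], y0 = se[["y0"]]))
}

#' Demodulate crossbridge stiffness over one event
#'
#' Synchronous detection at the forcing frequency, one estimate per forcing
#' cycle: the applied force phasor `F = kappa_trap (C1 - X1 - X2)` (drive
#' minus both bead responses) and the crossbridge extension phasor from the
#' passive bead, `Ext = X2 (kappa_link + kappa_trap)/kappa_link`, give
#' `kappa = |F| / |Ext|`.  Detached segments give the noise floor near 0.
#'
#' @param trace a `trap_trace` simulated with forcing.
#' @param t_start,t_end event boundaries (s); vectors accepted via
#'   [event_stiffness_series()].
#' @return A `data.frame` with one row per complete forcing cycle inside the
#'   event: `time` (cycle centre, s), `kappa` (pN/nm), and the complex
#'   phasors `F` and `Ext`.
#' @export
demodulate_stiffness <- function(trace, t_start, t_end) {
  cfg <- trace$metadata$sim_config
  if (is.null(cfg) || (cfg$forcing_amp %||% 0) == 0)
    stop("forcing absent from trace metadata", call. = FALSE)
  fs <- trace$sample_rate
  n_c <- round(fs / cfg$forcing_freq)
  w <- 2 * pi * cfg$forcing_freq
  kt <- trace$metadata$mech$kappa_trap
  kl <- trace$metadata$mech$kappa_link
  drive <- drive_signal(trace) - (cfg$static_offset %||% 0)
  # complete cycles on the global cycle grid inside [t_start, t_end]
  c0 <- ceiling((t_start * fs) / n_c) + 1
  c1 <- floor((t_end * fs) / n_c)
  if (c1 <= c0) return(data.frame(time = numeric(0), kappa = numeric(0)))
  cyc <- seq.int(c0, c1 - 1)
  ph <- function(y, idx) {
    tt <- trace$time[idx]
    e <- exp(-1i * w * tt)
    (2 / n_c) * sum(y[idx] * e)
  }
  rows <- lapply(cyc, function(k) {
    idx <- seq.int((k - 1) * n_c + 1, k * n_c)
    Fph <- kt * (ph(drive, idx) - ph(trace$x_driven, idx) -
                   ph(trace$x_passive, idx))
    Ext <- ph(trace$x_passive, idx) * (kl + kt) / kl
    data.frame(time = mean(trace$time[idx]), kappa = Mod(Fph) / Mod(Ext),
               F_re = Re(Fph), F_im = Im(Fph),
               Ext_re = Re(Ext), Ext_im = Im(Ext))
  })
  do.call(rbind, rows)
}

#' Ensemble-averaged stiffness time course
#'
#' Start- and end-aligned ensemble averages of the per-cycle force and
#' extension phasors across events (complex averaging, so the common drive
#' phase cancels event-to-event noise), giving the stiffness of the
#' acto-myosin complex through the attached period.  Plateau levels are the
#' medians of the first/last quartile of the start-/end-aligned course, and
#' single-exponential fits of the two courses give the stiffness-transition
#' rates: `k1_stiff` (s^-1, start-aligned rise, ADP release) and `k2_stiff`
#' (mM^-1 s^-1, end-aligned decay scaled by ATP).
#'
#' @param trace a forcing-protocol `trap_trace`.
#' @param events a [detect_events()] table (>= 30 events with forcing).
#' @param atp ATP concentration (mM) used to scale `k2_stiff`; defaults to
#'   trace metadata.
#' @param grid_quantile event-length quantile defining the grid (default 0.9).
#' @return An object of class `stiffness_timecourse`: `time` (s), `kappa`
#'   (start-aligned), `kappa_end` (end-aligned, time negative), `plateau_pre`,
#'   `plateau_rigor`, `k1_stiff`, `k2_stiff`, `single_plateau` flag, `n_events`.
#' @export
ensemble_stiffness <- function(trace, events, atp = NULL,
                               grid_quantile = 0.9) {
  if (nrow(events) < 30) stop("need >= 30 events with forcing", call. = FALSE)
  atp <- atp %||% trace$metadata$atp
  per_event <- lapply(seq_len(nrow(events)), function(i)
    demodulate_stiffness(trace, events$t_start[i], events$t_end[i]))
  n_cyc <- vapply(per_event, nrow, integer(1))
  keep <- n_cyc >= 2
  if (sum(keep) < 20)
    stop("too few events with >= 2 complete forcing cycles", call. = FALSE)
  per_event <- per_event[keep]
  n_cyc <- n_cyc[keep]
  n_grid <- max(3L, round(stats::quantile(n_cyc, grid_quantile)))
  pad_avg <- function(z, n_last = 2) {
    # complex series padded with the mean of its last n_last values
    if (length(z) >= n_grid) return(z[seq_len(n_grid)])
    pad <- mean(z[seq.int(max(1, length(z) - n_last + 1), length(z))])
    c(z, rep(pad, n_grid - length(z)))
  }
  pad_avg_front <- function(z, n_first = 2) {
    if (length(z) >= n_grid)
      return(z[seq.int(length(z) - n_grid + 1, length(z))])
    pad <- mean(z[seq_len(min(n_first, length(z)))])
    c(rep(pad, n_grid - length(z)), z)
  }
  Fz <- lapply(per_event, function(d) complex(real = d$F_re, imaginary = d$F_im))
  Ez <- lapply(per_event, function(d) complex(real = d$Ext_re, imaginary = d$Ext_im))
  Fs <- Reduce(`+`, lapply(Fz, pad_avg)) / length(Fz)
  Es <- Reduce(`+`, lapply(Ez, pad_avg)) / length(Ez)
  Fe <- Reduce(`+`, lapply(Fz, pad_avg_front)) / length(Fz)
  Ee <- Reduce(`+`, lapply(Ez, pad_avg_front)) / length(Ez)
  kappa_start <- Mod(Fs) / Mod(Es)
  kappa_end <- Mod(Fe) / Mod(Ee)
  cyc_t <- 1 / trace$metadata$sim_config$forcing_freq
  tgrid <- (seq_len(n_grid) - 0.5) * cyc_t
  q1 <- seq_len(max(1L, n_grid %/% 4))
  q4 <- seq.int(n_grid - max(1L, n_grid %/% 4) + 1L, n_grid)
  plateau_pre <- stats::median(kappa_start[q1])
  plateau_rigor <- stats::median(kappa_start[q4])
  # transition present?  two-sample comparison of the earliest cycles (most
  # pre-rigor-like; the ADP state is short relative to the grid quartiles)
  # against the final quartile
  e1 <- seq_len(max(2L, n_grid %/% 8))
  early <- stats::median(kappa_start[e1])
  noise <- stats::mad(diff(kappa_start)) / sqrt(2)
  se_diff <- 1.2533 * noise * sqrt(1 / length(e1) + 1 / length(q4))
  single_plateau <- abs(plateau_rigor - early) < max(0.01, 3 * se_diff)
  k1s <- k2s <- NULL
  if (!single_plateau) {
    f1 <- tryCatch(fit_single_exponential(
      list(time = tgrid, mean = kappa_start, alignment = "start")),
      error = function(e) NULL)
    # kappa_end[j]: j = n_grid is the detachment cycle; express as decay in
    # s = time before detachment
    f2 <- tryCatch(fit_single_exponential(
      list(time = rev(tgrid), mean = kappa_end, alignment = "start")),
      error = function(e) NULL)
    k1s <- f1; k2s <- f2
    if (!is.null(f1)) {
      # fit-based plateau levels: the pre-rigor state is short-lived
      # relative to the grid quartiles, so the asymptotes of the
      # exponential are the unbiased level estimates
      plateau_rigor <- f1$y0
      plateau_pre <- f1$y0 + f1$A
    }
  } else {
    plateau_pre <- plateau_rigor <- stats::median(kappa_start)
  }
  structure(list(
    time = tgrid, kappa = kappa_start, kappa_end = kappa_end,
    plateau_pre = plateau_pre, plateau_rigor = plateau_rigor,
    k1_stiff = if (!is.null(k1s)) k1s$k else NA_real_,
    k1_stiff_se = if (!is.null(k1s)) k1s$stderr[["k"]] else NA_real_,
    k2_stiff = if (!is.null(k2s)) k2s$k / atp else NA_real_,
    k2_stiff_se = if (!is.null(k2s)) k2s$stderr[["k"]] / atp else NA_real_,
    single_plateau = single_plateau, n_events = length(Fz)),
    class = "stiffness_timecourse")
}

#' @export
print.stiffness_timecourse <- function(x, ...) {
  cat(sprintf(
    "<stiffness_timecourse> plateaus %.3f -> %.3f pN/nm (%s), k1 = %.3g /s, k2 = %.3g /mM/s, n = %d\n",
    x$plateau_pre, x$plateau_rigor,
    if (x$single_plateau) "single plateau" else "transition",
    x$k1_stiff, x$k2_stiff, x$n_events))
  invisible(x)
}
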