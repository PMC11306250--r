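#' Detection configuration
#'
#' @param window rolling-variance window (ms, default 20).
#' @param threshold_mode `"auto"` (two-population split of the log-variance
#'   histogram) or `"manual"` (supply `thresholds`).
#' @param thresholds manual `c(attach, detach)` thresholds on the log
#'   rolling variance (attach < detach), used when `threshold_mode = "manual"`.
#' @param hysteresis_frac fraction of the mode separation placed between the
#'   attach and detach thresholds (default 0.2).
#' @param min_duration minimum event duration (ms, default 10).
#' @param baseline_span flanking detached time used for the displacement
#'   baseline (s, default 0.5).
#' @param channel channel carrying the thermal-motion variance; the passive
#'   bead by default (the driven bead carries the forcing).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(window = 20, threshold_mode = c("auto", "manual"),
                             thresholds = NULL, hysteresis_frac = 0.2,
                             min_duration = 10, baseline_span = 0.5,
                             channel = c("x_passive", "x_driven")) {
  threshold_mode <- match.arg(threshold_mode)
  channel <- match.arg(channel)
  if (!(hysteresis_frac > 0 && hysteresis_frac < 1))
    stop("hysteresis_frac must be in (0,1)", call. = FALSE)
  if (threshold_mode == "manual" &&
      (is.null(thresholds) || length(thresholds) != 2))
    stop("manual mode needs thresholds = c(attach, detach)", call. = FALSE)
  structure(list(window = window, threshold_mode = threshold_mode,
                 thresholds = thresholds, hysteresis_frac = hysteresis_frac,
                 min_duration = min_duration, baseline_span = baseline_span,
                 channel = channel),
            class = "detection_config")
}

# Remove the synchronous forcing component: per forcing cycle, least-squares
# fit of (1, sin, cos) at the forcing frequency, subtracting the oscillatory
# part only (levels are kept for displacement measurement).
remove_forcing <- function(x, time, forcing_freq, sample_rate) {
  n_c <- round(sample_rate / forcing_freq)
  n <- length(x)
  n_full <- floor(n / n_c)
  w <- 2 * pi * forcing_freq
  if (n_full == 0) return(x)
  idx <- seq_len(n_full * n_c)
  S <- sin(w * time[idx]); C <- cos(w * time[idx])
  xm <- matrix(x[idx], n_c, n_full)
  Sm <- matrix(S, n_c, n_full); Cm <- matrix(C, n_c, n_full)
  # per-cycle projections; sin/cos are orthogonal over a full cycle
  bs <- colSums(xm * Sm) / colSums(Sm * Sm)
  bc <- colSums(xm * Cm) / colSums(Cm * Cm)
  fit <- sweep(Sm, 2, bs, `*`) + sweep(Cm, 2, bc, `*`)
  x[idx] <- x[idx] - as.vector(fit)
  x
}

#' Rolling variance of a bead-position channel
#'
#' Centered rolling variance after removal of the sinusoidal forcing
#' component (per-cycle synchronous subtraction).  Edges are padded with the
#' nearest interior value.
#'
#' @param trace a [simulate_trap_trace()] / [read_trace()] object, or a
#'   numeric vector (then `sample_rate` must be given and no forcing removal
#'   is attempted).
#' @param window window length (ms).
#' @param sample_rate sampling rate (Hz), taken from the trace if omitted.
#' @param channel channel name for trace input.
#' @return Numeric vector of variances (nm^2), same length as the channel.
#' @export
rolling_variance <- function(trace, window = 20, sample_rate = NULL,
                             channel = "x_passive") {
  if (inherits(trace, "trap_trace")) {
    sample_rate <- trace$sample_rate
    x <- trace[[channel]]
    cfg <- trace$metadata$sim_config
    if (!is.null(cfg) && (cfg$forcing_amp %||% 0) > 0)
      x <- remove_forcing(x, trace$time, cfg$forcing_freq, sample_rate)
  } else {
    if (is.null(sample_rate)) stop("sample_rate required", call. = FALSE)
    x <- as.numeric(trace)
  }
  w <- max(5L, round(window * 1e-3 * sample_rate))
  if (w >= length(x)) stop("window longer than trace", call. = FALSE)
  # O(n) via cumulative sums; centre first so a constant channel gives
  # exact zeros and cancellation error stays negligible
  x <- x - mean(x)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - 1L - (w %/% 2L))
  hi <- pmin(n, seq_len(n) + (w - w %/% 2L) - 1L)
  cnt <- hi - lo
  m <- (cs[hi + 1L] - cs[lo + 1L]) / cnt
  v <- (cs2[hi + 1L] - cs2[lo + 1L]) / cnt - m^2
  pmax(v, 0)
}

# Two-population split of log-variance values -> c(attach, detach, mid, sep).
auto_thresholds <- function(logv, hysteresis_frac) {
  sub <- logv[seq(1, length(logv), by = max(1L, length(logv) %/% 20000L))]
  if (diff(range(sub)) < 1e-12)
    stop("no attached population: variance histogram is unimodal",
         call. = FALSE)
  km <- suppressWarnings(stats::kmeans(sub, centers = range(sub), iter.max = 50))
  cen <- sort(km$centers[, 1])
  sdw <- sqrt(mean(km$withinss / km$size))
  sep <- cen[2] - cen[1]
  if (sep < 2 * sdw || sep < 0.5)
    stop("no attached population: variance histogram is unimodal",
         call. = FALSE)
  mid <- unname(mean(cen)); sep <- unname(sep)
  c(attach = mid - hysteresis_frac * sep / 2,
    detach = mid + hysteresis_frac * sep / 2)
}

#' Detect actin-binding events in a trap trace
#'
#' Dual-threshold hysteresis on the log rolling variance of the passive-bead
#' channel: the motor is scored attached while the variance stays below the
#' attach threshold and until it exceeds the detach threshold.  Events
#' shorter than `min_duration` or touching the trace boundaries are
#' discarded.  Displacement is measured against the flanking detached
#' baseline; `displacement` is the whole-event mean, `displacement_ws` the
#' 20-sample mean ending half a window before the detected end (the rigor
#' level, used for working-stroke estimation).  `mean_load` is the
#' trap-derived force averaged over the event (resisting positive).
#'
#' @param trace a `trap_trace`, at least 10 s long.
#' @param cfg a [detection_config()].
#' @return A `data.frame` of class `binding_events` with one row per event;
#'   attributes `total_time`, `detached_time`, `n_events`.
#' @export
detect_events <- function(trace, cfg = detection_config()) {
  fs <- trace$sample_rate
  if (length(trace$time) < 10 * fs)
    stop("trace must be >= 10 s", call. = FALSE)
  scfg <- trace$metadata$sim_config
  forcing <- !is.null(scfg) && (scfg$forcing_amp %||% 0) > 0
  chans <- list(x_driven = trace$x_driven, x_passive = trace$x_passive)
  if (forcing) {
    chans <- lapply(chans, remove_forcing, time = trace$time,
                    forcing_freq = scfg$forcing_freq, sample_rate = fs)
  }
  v <- rolling_variance(chans[[cfg$channel]], window = cfg$window,
                        sample_rate = fs)
  logv <- log(pmax(v, .Machine$double.eps))
  thr <- if (cfg$threshold_mode == "auto")
    auto_thresholds(logv, cfg$hysteresis_frac) else
    c(attach = cfg$thresholds[1], detach = cfg$thresholds[2])

  att <- hysteresis_state(logv, thr["attach"], thr["detach"])
  r <- rle(att)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- which(r$values)
  n <- length(logv)
  # refine edges to the mid-threshold crossing: the hysteresis trigger fires
  # deep inside the event, contracting both edges by ~window/2
  mid <- mean(thr)
  for (j in ev) {
    i0 <- starts[j]
    while (i0 > 1L && logv[i0 - 1L] < mid) i0 <- i0 - 1L
    i1 <- ends[j]
    while (i1 < n && logv[i1 + 1L] < mid) i1 <- i1 + 1L
    starts[j] <- i0; ends[j] <- i1
  }
  # debias: the centred window crosses the geometric-mean threshold where a
  # fraction f* = (v_det - sqrt(v_att v_det)) / (v_det - v_att) of it is
  # attached, i.e. (f* - 1/2) * window inside the true edge; shift outward
  wsamp <- round(cfg$window * 1e-3 * fs)
  v_att <- stats::median(v[att]); v_det <- stats::median(v[!att])
  fstar <- (v_det - sqrt(v_att * v_det)) / (v_det - v_att)
  shift <- max(0L, round((fstar - 0.5) * wsamp))
  if (shift > 0 && length(ev)) {
    s_new <- pmax(1L, starts[ev] - shift)
    e_new <- pmin(n, ends[ev] + shift)
    # never cross into a neighbouring event
    if (length(ev) > 1) {
      gap_lo <- c(1L, ends[ev][-length(ev)] + 1L)
      gap_hi <- c(starts[ev][-1] - 1L, n)
      s_new <- pmax(s_new, gap_lo)
      e_new <- pmin(e_new, gap_hi)
    }
    starts[ev] <- s_new; ends[ev] <- e_new
  }
  for (j in ev) att[starts[j]:ends[j]] <- TRUE
  r$lengths[ev] <- ends[ev] - starts[ev] + 1L
  min_samp <- round(cfg$min_duration * 1e-3 * fs)
  keep <- r$lengths[ev] >= min_samp & starts[ev] > 1L & ends[ev] < n
  ev <- ev[keep]
  kt <- trace$metadata$mech$kappa_trap
  off <- scfg$static_offset %||% 0
  bspan <- round(cfg$baseline_span * fs)
  wsamp <- round(cfg$window * 1e-3 * fs)
  # guard band: detected edges contract inward by up to window/2, so samples
  # within one window of an event may still be attached; exclude them from
  # the detached baseline
  guard <- att
  for (j in which(r$values)) {
    g0 <- max(1L, starts[j] - wsamp); g1 <- min(n, ends[j] + wsamp)
    guard[g0:g1] <- TRUE
  }
  x2 <- chans$x_passive; x1 <- chans$x_driven
  rows <- lapply(ev, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    bl_idx <- c(seq(max(1L, i0 - bspan - wsamp), max(1L, i0 - 1L)),
                seq(min(n, i1 + 1L), min(n, i1 + bspan + wsamp)))
    bl_idx <- bl_idx[!guard[bl_idx]]
    baseline <- mean(x2[bl_idx])
    # rigor-level window: 20 samples ending ~window/3 before the refined
    # end, inside the attached period even under edge jitter
    back <- wsamp %/% 3L
    iw <- max(i0, i1 - back - 19L):max(i0, i1 - back)
    data.frame(
      t_start = trace$time[i0], t_end = trace$time[i1],
      dwell = (i1 - i0 + 1L) / fs,
      displacement = mean(x2[i0:i1]) - baseline,
      displacement_ws = mean(x2[iw]) - baseline,
      mean_load = kt * ((mean(x1[i0:i1]) - off) + (mean(x2[i0:i1]) - off)),
      var_attached = mean(v[i0:i1]),
      var_detached = mean(v[bl_idx]))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_start = numeric(0), t_end = numeric(0), dwell = numeric(0),
               displacement = numeric(0), displacement_ws = numeric(0),
               mean_load = numeric(0), var_attached = numeric(0),
               var_detached = numeric(0))
  class(out) <- c("binding_events", class(out))
  attr(out, "total_time") <- n / fs
  attr(out, "detached_time") <- sum(!att) / fs
  attr(out, "thresholds") <- thr
  attr(out, "compliance_rigor") <- trace$metadata$compliance_rigor
  out
}

# attached = TRUE while logv < attach threshold, released when > detach.
hysteresis_state <- function(logv, thr_attach, thr_detach) {
  code <- integer(length(logv))
  code[logv < thr_attach] <- 1L
  code[logv > thr_detach] <- -1L
  idx <- which(code != 0L)
  if (!length(idx)) return(rep(FALSE, length(logv)))
  pos <- findInterval(seq_along(logv), idx)
  c(-1L, code[idx])[pos + 1L] == 1L
}

#' Serialize binding events to a plain table
#'
#' @param events a [detect_events()] result.
#' @return A plain `data.frame` (lossless; attributes moved to columns of a
#'   comment line on write).
#' @export
event_table <- function(events) {
  out <- as.data.frame(events)
  class(out) <- "data.frame"
  out
}
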