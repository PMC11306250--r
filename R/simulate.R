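#' Simulation configuration for trap traces
#'
#' @param duration trace length (s).
#' @param sample_rate output sampling rate (Hz, default 5000).
#' @param internal_step internal integration step (s, default 2e-5); must
#'   divide the sampling interval, and satisfy
#'   `internal_step <= 1/(2 sample_rate)`.
#' @param forcing_freq frequency of the sinusoidal forcing applied to the
#'   driven trap (Hz, default 100).
#' @param forcing_amp peak-to-peak amplitude of the forcing (nm, default 100);
#'   set 0 for no forcing (ensemble-displacement protocol).
#' @param static_offset common static displacement of both trap centres (nm),
#'   imposing a net load on the attached crossbridge.
#' @param seed integer seed recorded in trace metadata.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration, sample_rate = 5000, internal_step = 2e-5,
                       forcing_freq = 100, forcing_amp = 100,
                       static_offset = 0, seed = 1L) {
  if (!(duration > 0)) stop("duration must be > 0", call. = FALSE)
  if (internal_step > 1 / (2 * sample_rate))
    stop("internal_step must be <= 1/(2*sample_rate)", call. = FALSE)
  navg <- 1 / (sample_rate * internal_step)
  if (abs(navg - round(navg)) > 1e-8)
    stop("internal_step must divide the sampling interval", call. = FALSE)
  if (forcing_amp < 0) stop("forcing_amp must be >= 0", call. = FALSE)
  structure(list(duration = duration, sample_rate = sample_rate,
                 internal_step = internal_step, forcing_freq = forcing_freq,
                 forcing_amp = forcing_amp, static_offset = static_offset,
                 seed = as.integer(seed), navg = as.integer(round(navg))),
            class = "sim_config")
}

#' Simulate a Markov state sequence of the attachment cycle
#'
#' Draws exponential waiting times through the cycle detached -> post-stroke-1
#' (ADP) -> rigor -> detached.  Exit rates are `k_att`, `k1(F)` and
#' `k2(F) * atp`, with the Bell load `F` taken from the static-offset
#' contribution of the mechanical configuration (stroke-induced self-load
#' excluded) evaluated at state entry, or from `cond$load` when no mechanics
#' are supplied.
#'
#' @param rates a [cycle_rates()] object.
#' @param cond a [conditions()] object (`atp` > 0).
#' @param duration total simulated time (s).
#' @param seed integer seed; the function uses its own RNG stream.
#' @param mech optional [mech_params()] used with `static_offset` to compute
#'   per-state entry loads.
#' @param static_offset trap-centre offset (nm), used when `mech` is given.
#' @return A `data.frame` of class `state_trajectory` with columns `state`,
#'   `t_start`, `t_end`, `load_at_entry`.
#' @export
#' @examples
#' traj <- simulate_state_sequence(cycle_rates(19.4, 55), conditions(0.1), 50, seed = 1)
#' table(traj$state)
simulate_state_sequence <- function(rates, cond, duration, seed = 1L,
                                    mech = NULL, static_offset = 0) {
  if (!(duration > 0)) stop("duration must be > 0", call. = FALSE)
  if (cond$atp <= 0) stop("atp must be > 0", call. = FALSE)
  set.seed(seed)
  state_load <- function(state) {
    if (is.null(mech)) {
      if (state == "detached") 0 else cond$load
    } else {
      offset_load(mech, state, static_offset)
    }
  }
  exit_rate <- function(state, F) {
    cnd <- conditions(cond$atp, load = F, kT = cond$kT)
    switch(state,
           detached = rates$k_att,
           post1_ADP = k1_loaded(rates, cnd),
           rigor = k2_loaded(rates, cnd) * cond$atp)
  }
  # preallocate generously: expected number of intervals + slack
  n_guess <- max(64L, ceiling(duration * 3 *
    (1 / (1 / rates$k_att + mean_attached_time(rates, cond)))) + 64L)
  st <- character(n_guess); t0 <- numeric(n_guess)
  t1 <- numeric(n_guess); ld <- numeric(n_guess)
  t <- 0; i <- 0L; state <- "detached"
  while (t < duration) {
    F <- state_load(state)
    dwell <- stats::rexp(1L, exit_rate(state, F))
    i <- i + 1L
    if (i > length(st)) {  # grow if the guess was short
      st <- c(st, character(n_guess)); t0 <- c(t0, numeric(n_guess))
      t1 <- c(t1, numeric(n_guess)); ld <- c(ld, numeric(n_guess))
    }
    st[i] <- state; t0[i] <- t; t1[i] <- min(t + dwell, duration); ld[i] <- F
    t <- t + dwell
    state <- switch(state, detached = "post1_ADP", post1_ADP = "rigor",
                    rigor = "detached")
  }
  out <- data.frame(state = st[seq_len(i)], t_start = t0[seq_len(i)],
                    t_end = t1[seq_len(i)], load_at_entry = ld[seq_len(i)],
                    stringsAsFactors = FALSE)
  class(out) <- c("state_trajectory", class(out))
  attr(out, "atp") <- cond$atp
  attr(out, "seed") <- seed
  out
}

#' Attached dwell times of a state trajectory
#'
#' Collapses consecutive post-stroke/rigor intervals into full attachment
#' events and returns their durations, excluding events truncated by the
#' trace boundaries.
#'
#' @param traj a [simulate_state_sequence()] result.
#' @return List with `dwells` (s), `t_start`, `t_end`, `load` (time-averaged
#'   entry load per event) and `detached` (complete detached dwells, s).
#' @export
attached_events <- function(traj) {
  att <- traj$state != "detached"
  r <- rle(att)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- r$values  # attached runs
  t_start <- traj$t_start[idx_start[keep]]
  t_end <- traj$t_end[idx_end[keep]]
  load <- vapply(which(keep), function(j) {
    rows <- idx_start[j]:idx_end[j]
    w <- traj$t_end[rows] - traj$t_start[rows]
    sum(w * traj$load_at_entry[rows]) / sum(w)
  }, numeric(1))
  # drop boundary-censored events
  dur <- max(traj$t_end)
  ok <- t_start > 0 & t_end < dur
  det <- !r$values
  d_start <- traj$t_start[idx_start[det]]
  d_end <- traj$t_end[idx_end[det]]
  dok <- d_start > 0 & d_end < dur
  list(dwells = (t_end - t_start)[ok], t_start = t_start[ok],
       t_end = t_end[ok], load = load[ok],
       detached = (d_end - d_start)[dok])
}

#' Simulate a two-bead trap trace over a state trajectory
#'
#' Propagates the 3-coordinate linear network (driven bead, passive bead,
#' actin rod) through the attachment cycle using the exact Gaussian one-step
#' propagator of the overdamped linear SDE (no time-discretisation error; the
#' only approximation is rounding state-transition times to the internal
#' step).  The driven trap centre carries the sinusoidal forcing; output is
#' block-averaged to `sample_rate`.  Output timestamps are block mid-times.
#'
#' @param traj a [simulate_state_sequence()] trajectory covering
#'   `cfg$duration`.
#' @param mech a [mech_params()] object.
#' @param cfg a [sim_config()] object.
#' @param cond a [conditions()] object (supplies `kT`; ATP recorded).
#' @return An object of class `trap_trace`: list with `time`, `x_driven`,
#'   `x_passive`, `sample_rate`, `metadata` (config, parameters, compliance
#'   factors, expected displacement) and `truth` (the trajectory).
#' @export
simulate_trap_trace <- function(traj, mech, cfg, cond = conditions(0.1)) {
  if (max(traj$t_end) < cfg$duration - 1e-9)
    stop("trajectory does not cover cfg$duration", call. = FALSE)
  dt <- cfg$internal_step
  navg <- cfg$navg
  n_out <- round(cfg$duration * cfg$sample_rate)
  n_int <- n_out * navg
  # rounding of transition times to internal steps, then run-length encoding
  steps_end <- pmin(round(traj$t_end / dt), n_int)
  steps_start <- c(0, steps_end[-length(steps_end)])
  seg_len <- steps_end - steps_start
  keep <- seg_len > 0
  seg_len <- seg_len[keep]
  state_idx <- match(traj$state[keep], motor_states) - 1L
  if (sum(seg_len) != n_int) {  # pad with final state
    seg_len[length(seg_len)] <- seg_len[length(seg_len)] +
      (n_int - sum(seg_len))
  }
  omega <- if (cfg$forcing_amp > 0) 2 * pi * cfg$forcing_freq else 0
  terms <- lapply(motor_states, function(s)
    ou_state_terms(mech, s, dt, cond$kT, cfg$static_offset,
                   cfg$forcing_freq, cfg$forcing_amp))
  set.seed(cfg$seed)
  x0 <- terms[[state_idx[1] + 1]]$xc +
    drop(t(chol(terms[[state_idx[1] + 1]]$Sigma)) %*% stats::rnorm(3))
  out <- ou_propagate_cpp(
    state_idx, as.numeric(seg_len),
    lapply(terms, `[[`, "Phi"), lapply(terms, `[[`, "cholQ"),
    lapply(terms, `[[`, "xc"), lapply(terms, `[[`, "Xr"),
    lapply(terms, `[[`, "Xi"),
    dt, omega, navg, n_out, x0)
  # block mid-times: mean of the navg internal sample times in each block
  tout <- (seq_len(n_out) - 1) / cfg$sample_rate + (navg + 1) * dt / 2
  comp_rigor <- series_compliance_factor(mech, "rigor")
  metadata <- list(
    sim_config = unclass(cfg), mech = unclass(mech),
    kT = cond$kT, atp = cond$atp,
    compliance_rigor = comp_rigor,
    compliance_pre = series_compliance_factor(mech, "post1_ADP"),
    expected_displacement = mech$ws_total * comp_rigor,
    seed = cfg$seed,
    package = as.character(utils::packageVersion("myotrap")))
  structure(list(time = tout, x_driven = out[, 1], x_passive = out[, 2],
                 sample_rate = cfg$sample_rate, metadata = metadata,
                 truth = traj),
            class = "trap_trace")
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("<trap_trace> %.3g s at %g Hz (%d samples)%s%s\n",
              length(x$time) / x$sample_rate, x$sample_rate, length(x$time),
              if (!is.null(x$truth)) ", with ground truth" else "",
              if ((x$metadata$sim_config$forcing_amp %||% 0) > 0)
                sprintf(", %g Hz forcing", x$metadata$sim_config$forcing_freq)
              else ""))
  invisible(x)
}

#' Reconstruct the (block-averaged) driven-trap drive
#'
#' The sinusoidal component of the driven trap centre, filtered exactly as the
#' simulator's block averaging filters the bead channels, so that
#' demodulation of drive and response uses consistent phases.
#'
#' @param trace a [simulate_trap_trace()] trace.
#' @return Numeric vector, nm (static offset included).
#' @export
drive_signal <- function(trace) {
  cfg <- trace$metadata$sim_config
  if ((cfg$forcing_amp %||% 0) == 0)
    return(rep(cfg$static_offset %||% 0, length(trace$time)))
  gain <- block_average_gain(cfg$forcing_freq, cfg$internal_step, cfg$navg)
  (cfg$static_offset %||% 0) +
    (cfg$forcing_amp / 2) * gain * sin(2 * pi * cfg$forcing_freq * trace$time)
}

#' Simulate a stopped-flow fluorescence transient
#'
#' Single-exponential approach `y(t) = y0 + amplitude (1 - exp(-k_obs t))`
#' plus Gaussian noise.  A negative amplitude models a fluorescence decrease.
#'
#' @param k_obs observed rate (s^-1, > 0).
#' @param amplitude signal amplitude (a.u., signed).
#' @param y0 starting level (a.u.).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param duration record length (s); must be >= 5/k_obs.
#' @param n_points number of samples (>= 50).
#' @param seed integer seed.
#' @return A `data.frame` of class `sf_transient` with columns `time`,
#'   `signal`; the ground-truth rate is stored in attribute `truth_rate`.
#' @export
simulate_stopped_flow <- function(k_obs, amplitude = 1, y0 = 0,
                                  noise_sd = 0.05, duration = 5 / k_obs,
                                  n_points = 500, seed = 1L) {
  if (!(k_obs > 0)) stop("k_obs must be > 0", call. = FALSE)
  if (duration < 5 / k_obs)
    stop("duration must be >= 5/k_obs", call. = FALSE)
  if (n_points < 50) stop("need >= 50 points", call. = FALSE)
  set.seed(seed)
  t <- seq(0, duration, length.out = n_points)
  y <- y0 + amplitude * (1 - exp(-k_obs * t)) +
    stats::rnorm(n_points, sd = noise_sd)
  out <- data.frame(time = t, signal = y)
  class(out) <- c("sf_transient", class(out))
  attr(out, "truth_rate") <- k_obs
  out
}

#' Euler-Maruyama reference integrator
#'
#' Brute-force first-order integration of the same linear network SDE, used
#' as an independent cross-check of the exact propagator.  Refuses steps that
#' violate the explicit-scheme stability margin
#' `kappa_max * dt / gamma_min >= 0.1`.
#'
#' @inheritParams simulate_trap_trace
#' @param state motor state held fixed over the integration.
#' @param dt time step (s).
#' @param duration integration time (s).
#' @param noise logical; FALSE integrates the deterministic part only.
#' @param seed integer seed.
#' @return Matrix with columns `x1`, `x2`, `xa` at times `dt * (1:n)`.
#' @export
em_integrate <- function(mech, cfg, state = "detached", dt = 1e-6,
                         duration = 0.05, kT = 4.07, noise = TRUE, seed = 1L) {
  K <- network_stiffness(mech, state)
  g <- diag(network_drag(mech))
  kmax <- max(abs(diag(K)))
  if (kmax * dt / min(g) >= 0.1)
    stop(sprintf(
      "unstable step: kappa_max*dt/gamma = %.3g >= 0.1; reduce dt",
      kmax * dt / min(g)), call. = FALSE)
  n <- round(duration / dt)
  amp <- cfg$forcing_amp / 2
  w <- 2 * pi * cfg$forcing_freq
  b0 <- network_drive(mech, state, cfg$static_offset)
  set.seed(seed)
  x <- drop(solve(K, b0))
  sd_noise <- sqrt(2 * kT * dt / g)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("x1", "x2", "xa")))
  for (i in seq_len(n)) {
    b <- b0
    b[1] <- b[1] + mech$kappa_trap * amp * sin(w * (i - 1) * dt)
    drift <- (b - drop(K %*% x)) / g
    x <- x + drift * dt + if (noise) sd_noise * stats::rnorm(3) else 0
    out[i, ] <- x
  }
  out
}
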