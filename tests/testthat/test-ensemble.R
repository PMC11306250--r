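# Ensemble averaging of displacement and demodulated stiffness.

# hand-built noiseless trace: staircase events on a flat baseline
staircase_trace <- function(n_events = 25, level1 = 10, level2 = 16,
                            fs = 5000) {
  ev_len <- 0.4; gap <- 0.6
  dur <- n_events * (ev_len + gap) + 1
  n <- round(dur * fs)
  x <- numeric(n)
  t_start <- t_end <- numeric(n_events)
  for (i in seq_len(n_events)) {
    t0 <- 0.5 + (i - 1) * (ev_len + gap)
    i0 <- round(t0 * fs) + 1
    i1 <- i0 + round(ev_len * fs) - 1
    half <- round((i0 + i1) / 2)
    x[i0:half] <- level1
    x[(half + 1):i1] <- level2
    t_start[i] <- t0; t_end[i] <- i1 / fs
  }
  trace <- structure(list(
    time = (seq_len(n) - 0.5) / fs, x_driven = x, x_passive = x,
    sample_rate = fs,
    metadata = list(sim_config = list(forcing_amp = 0), mech = list(kappa_trap = 0.02)),
    truth = NULL), class = "trap_trace")
  ev <- data.frame(t_start = t_start, t_end = t_end,
                   dwell = t_end - t_start,
                   displacement = (level1 + level2) / 2)
  class(ev) <- c("binding_events", class(ev))
  list(trace = trace, events = ev)
}

test_that("identical noiseless staircases average to the staircase", {
  s <- staircase_trace()
  avg <- align_and_average(s$trace, s$events, "start")
  expect_equal(avg$n_events, 25L)
  expect_equal(avg$mean[5], 10, tolerance = 1e-9)
  expect_equal(avg$mean[length(avg$mean) - 5], 16, tolerance = 1e-9)
  # extension never changes the value at the alignment point
  avg2 <- align_and_average(s$trace, s$events, "end")
  expect_equal(avg2$mean[length(avg2$mean)], 16, tolerance = 1e-9)
  expect_equal(avg$mean[1], 10, tolerance = 1e-9)
})

test_that("ensemble averaging commutes with event subsampling", {
  s <- sim_variant_trace(n_events = 60, seed = 301)
  ev <- detect_events(s$trace)
  avg <- align_and_average(s$trace, ev, "start", grid_quantile = 0.5)
  h1 <- align_and_average(s$trace, ev[seq(1, nrow(ev), 2), ], "start",
                          grid_quantile = 0.5)
  h2 <- align_and_average(s$trace, ev[seq(2, nrow(ev), 2), ], "start",
                          grid_quantile = 0.5)
  m <- min(length(avg$mean), length(h1$mean), length(h2$mean))
  pooled <- (h1$mean[1:m] * h1$n_events + h2$mean[1:m] * h2$n_events) /
    (h1$n_events + h2$n_events)
  expect_lt(stats::sd(pooled - avg$mean[1:m]), 0.4)
})

test_that("start/end-aligned displacement ensembles recover the two rates", {
  v <- fix_s267e()
  s <- sim_variant_trace(n_events = 150, seed = 302)
  ev <- detect_events(s$trace)
  f_start <- fit_single_exponential(align_and_average(s$trace, ev, "start"))
  expect_lt(abs(f_start$k / v$rates$k1_0 - 1), 0.35)
  f_end <- fit_single_exponential(align_and_average(s$trace, ev, "end"))
  expect_lt(abs(f_end$k / (v$rates$k2_0 * 0.1) - 1), 0.35)
  # levels: rises toward the full stroke
  expect_gt(f_start$y0, f_start$y0 + f_start$A)
})

test_that("fit_single_exponential is exact on noiseless data", {
  t <- seq(0, 1, by = 0.002)
  y <- 3 * exp(-7.5 * t) + 0.4
  f <- fit_single_exponential(list(time = t, mean = y))
  expect_equal(f$k, 7.5, tolerance = 1e-6)
  expect_equal(f$A, 3, tolerance = 1e-6)
  expect_equal(f$y0, 0.4, tolerance = 1e-6)
  expect_error(fit_single_exponential(list(time = t[1:10], mean = y[1:10])),
               ">= 30")
})

test_that("stiffness demodulation matches the state stiffness", {
  v <- fix_s267e()
  cfg <- sim_config(40, seed = 303)
  rig <- simulate_trap_trace(single_state_traj("rigor", 40), v$mech, cfg,
                             conditions(0.1))
  d <- demodulate_stiffness(rig, 0.5, 39.5)
  expect_lt(abs(stats::median(d$kappa) - 0.35), 0.02)
  det <- simulate_trap_trace(single_state_traj("detached", 40), v$mech, cfg,
                             conditions(0.1))
  dd <- demodulate_stiffness(det, 0.5, 39.5)
  expect_lt(stats::median(dd$kappa), 0.05)
  # no forcing in metadata -> error
  cfg0 <- sim_config(12, forcing_amp = 0, seed = 1)
  tr0 <- simulate_trap_trace(single_state_traj("rigor", 12), v$mech, cfg0,
                             conditions(0.1))
  expect_error(demodulate_stiffness(tr0, 1, 10), "forcing absent")
})

test_that("ensemble stiffness: plateaus, transition, WT control", {
  s <- sim_variant_trace(fix_s267e(), n_events = 45, seed = 304,
                         forcing_amp = 100)
  ev <- detect_events(s$trace)
  st <- ensemble_stiffness(s$trace, ev)
  expect_false(st$single_plateau)
  expect_lt(abs(st$plateau_rigor - 0.35), 0.025)
  expect_lt(st$plateau_pre, st$plateau_rigor)
  # transition rate consistent with the ADP-release rate (within the joint
  # uncertainty of a 10-ms-resolution ensemble fit)
  expect_gt(st$k1_stiff, 19.4 * 0.4)
  expect_lt(st$k1_stiff, 19.4 * 1.6)
  wt <- sim_variant_trace(fix_wt(), n_events = 45, seed = 305,
                          forcing_amp = 100)
  evw <- detect_events(wt$trace)
  stw <- ensemble_stiffness(wt$trace, evw)
  expect_true(stw$single_plateau)
  expect_lt(abs(stw$plateau_rigor - 0.25), 0.02)
})
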