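# Synthetic-data generator: Markov state sequences, exact-propagator traces
# against closed-form network oracles, Euler-Maruyama cross-check, stopped
# flow.

test_that("state-sequence dwells match the analytic cycle means", {
  v <- fix_s267e()
  cond <- conditions(0.1)
  traj <- simulate_state_sequence(v$rates, cond, 2500, seed = 7)
  ev <- attached_events(traj)
  n <- length(ev$dwells)
  expect_gt(n, 800)
  mu <- mean_attached_time(v$rates, cond)
  expect_lt(abs(mean(ev$dwells) - mu), 3 * stats::sd(ev$dwells) / sqrt(n))
  nd <- length(ev$detached)
  expect_lt(abs(mean(ev$detached) - 2), 3 * stats::sd(ev$detached) / sqrt(nd))
  # legal transition order only
  expect_true(all(rle(traj$state)$values %in%
                    c("detached", "post1_ADP", "rigor")))
  ord <- match(traj$state, c("detached", "post1_ADP", "rigor"))
  expect_true(all(diff(ord) %in% c(1, -2)))
})

test_that("k1 -> Inf degenerates attached dwells to Exp(k2 atp)", {
  r <- cycle_rates(1e6, 55, k_att = 2)
  cond <- conditions(0.1)
  traj <- simulate_state_sequence(r, cond, 1500, seed = 8)
  dw <- attached_events(traj)$dwells
  ks <- stats::ks.test(dw, "pexp", rate = 5.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("attached-dwell survival matches the hypoexponential closed form", {
  v <- fix_s267e()
  cond <- conditions(0.1)
  traj <- simulate_state_sequence(v$rates, cond, 5000, seed = 9)
  dw <- attached_events(traj)$dwells[1:2000]
  D <- stats::ks.test(dw, function(q)
    1 - hypoexp_surv(q, v$rates$k1_0, v$rates$k2_0 * cond$atp))$statistic
  expect_lt(unname(D), 0.05)
})

test_that("identical seed and config give a bit-identical trace", {
  v <- fix_s267e()
  traj <- single_state_traj("detached", 5)
  cfg <- sim_config(5, seed = 77)
  t1 <- simulate_trap_trace(traj, v$mech, cfg, conditions(0.1))
  t2 <- simulate_trap_trace(traj, v$mech, cfg, conditions(0.1))
  expect_identical(t1$x_driven, t2$x_driven)
  expect_identical(t1$x_passive, t2$x_passive)
  t3 <- simulate_trap_trace(traj, v$mech, sim_config(5, seed = 78),
                            conditions(0.1))
  expect_false(identical(t1$x_passive, t3$x_passive))
})

test_that("no-motor trace reproduces the analytic equipartition covariance", {
  mech <- fix_s267e()$mech
  cfg <- sim_config(200, forcing_amp = 0, seed = 101)
  tr <- simulate_trap_trace(single_state_traj("detached", 200), mech, cfg,
                            conditions(0.1))
  Cth <- decimated_covariance(mech, "detached", 4.07, cfg$internal_step,
                              cfg$navg)
  expect_lt(abs(var(tr$x_driven) / Cth[1, 1] - 1), 0.05)
  expect_lt(abs(var(tr$x_passive) / Cth[2, 2] - 1), 0.05)
  # instantaneous-sample covariance is kT K^-1; block averaging reduces it
  expect_lt(Cth[2, 2], network_covariance(mech, "detached")[2, 2])
})

test_that("driven-bead 100-Hz response matches the network transfer function", {
  mech <- fix_s267e()$mech
  cfg <- sim_config(50, seed = 102)
  tr <- simulate_trap_trace(single_state_traj("detached", 50), mech, cfg,
                            conditions(0.1))
  w <- 2 * pi * cfg$forcing_freq
  gain <- myotrap:::block_average_gain(cfg$forcing_freq, cfg$internal_step,
                                       cfg$navg)
  H <- network_transfer(mech, "detached", cfg$forcing_freq)
  for (ch in c("x_driven", "x_passive")) {
    amp <- Mod(2 * mean(tr[[ch]] * exp(-1i * w * tr$time)))
    i <- if (ch == "x_driven") 1 else 2
    expect_lt(abs(amp / (50 * gain * Mod(H[i])) - 1), 0.05)
  }
})

test_that("attached segments show the stroke and reduced variance", {
  v <- fix_s267e()
  cfg <- sim_config(60, forcing_amp = 0, seed = 103)
  rig <- simulate_trap_trace(single_state_traj("rigor", 60), v$mech, cfg,
                             conditions(0.1))
  det <- simulate_trap_trace(single_state_traj("detached", 60), v$mech, cfg,
                             conditions(0.1))
  expect_lt(var(rig$x_passive), var(det$x_passive) / 3)
  # mean displacement equals stroke x series-compliance factor (metadata)
  expect_lt(abs(mean(rig$x_passive) - rig$metadata$expected_displacement),
            0.15)
  expect_equal(rig$metadata$expected_displacement,
               v$mech$ws_total * series_compliance_factor(v$mech, "rigor"),
               tolerance = 1e-12)
})

test_that("Euler-Maruyama cross-check agrees with the exact propagator", {
  # the explicit scheme needs kappa*dt/gamma < 0.1 for every coordinate, so
  # give the rod a bead-sized drag for this comparison (the exact propagator
  # has no step-size restriction)
  mech <- fix_s267e()$mech
  mech$gamma_rod <- bead_drag(mech)
  cfg <- sim_config(0.02, seed = 1)
  dt <- 2e-7
  # deterministic part: forced response trajectories agree
  em <- em_integrate(mech, cfg, state = "rigor", dt = dt, duration = 0.02,
                     noise = FALSE)
  terms <- myotrap:::ou_state_terms(mech, "rigor", dt, 4.07, 0,
                                    cfg$forcing_freq, cfg$forcing_amp)
  n <- nrow(em)
  x <- terms$xc
  w <- 2 * pi * cfg$forcing_freq
  xp <- function(t) terms$Xr * sin(w * t) + terms$Xi * cos(w * t)
  ex <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    t0 <- (i - 1) * dt; t1 <- i * dt
    x <- terms$xc + xp(t1) + terms$Phi %*% (x - terms$xc - xp(t0))
    ex[i, ] <- x
  }
  expect_lt(max(abs(em - ex)), 0.02)
  # stochastic part: stationary variance within sampling error
  em2 <- em_integrate(mech, sim_config(0.02, forcing_amp = 0, seed = 1),
                      state = "rigor", dt = dt, duration = 0.02,
                      noise = TRUE, seed = 33)
  th <- network_covariance(mech, "rigor")[2, 2]
  expect_lt(abs(var(em2[-(1:1e4), "x2"]) / th - 1), 0.25)
  # stability refusal with the documented diagnostic
  expect_error(em_integrate(mech, cfg, dt = 2e-5), "unstable step")
})

test_that("stopped-flow generator matches its closed form", {
  tr <- simulate_stopped_flow(16.3, amplitude = 2, y0 = 0.5, noise_sd = 0,
                              n_points = 200, seed = 1)
  expect_equal(tr$signal, 0.5 + 2 * (1 - exp(-16.3 * tr$time)),
               tolerance = 1e-12)
  expect_equal(attr(tr, "truth_rate"), 16.3)
  expect_gte(nrow(tr), 50)
  # amplitude sign flip mirrors the transient
  up <- simulate_stopped_flow(5, amplitude = 1, noise_sd = 0, seed = 1)
  dn <- simulate_stopped_flow(5, amplitude = -1, noise_sd = 0, seed = 1)
  expect_equal(up$signal, -dn$signal, tolerance = 1e-12)
  expect_error(simulate_stopped_flow(10, duration = 0.1), "duration")
})
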