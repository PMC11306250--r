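# Closed-form cycle model: Bell load law, attached times, duty ratio,
# velocity, stall force, rigor occupancy.

test_that("load_rate follows the Bell law and validates inputs", {
  expect_equal(load_rate(19.4, 1.8, conditions(1, load = 0)), 19.4)
  # direct evaluation of the exponential as oracle
  expect_equal(load_rate(19.4, 1.8, conditions(1, load = 2, kT = 4.07)),
               19.4 * exp(-2 * 1.8 / 4.07), tolerance = 1e-12)
  expect_equal(round(load_rate(19.4, 1.8, conditions(1, load = 2)), 1), 8.0)
  expect_error(load_rate(-1, 1.8, conditions(1)), "k0")
  expect_error(load_rate(19.4, -0.1, conditions(1)), "d must")
  expect_error(conditions(1, kT = 0), "kT")
})

test_that("log load_rate is affine in F with slope -d/kT (machine precision)", {
  kT <- 4.07
  for (d in c(0, 1.8, 2.8)) {
    F <- seq(-4, 4, by = 0.5)
    lk <- vapply(F, function(f)
      log(load_rate(7.3, d, conditions(1, load = f, kT = kT))), numeric(1))
    slopes <- diff(lk) / diff(F)
    expect_equal(slopes, rep(-d / kT, length(slopes)), tolerance = 1e-12)
  }
})

test_that("mean_attached_time matches the sum of state means", {
  rE <- fix_s267e()$rates
  expect_equal(mean_attached_time(rE, conditions(0.1)),
               1 / 19.4 + 1 / (55 * 0.1), tolerance = 1e-12)
  rA <- myo6_variant("S267A")$rates
  expect_equal(round(mean_attached_time(rA, conditions(0.1)), 3), 0.430)
  # atp -> Inf limit is 1/k1
  expect_equal(mean_attached_time(rE, conditions(1e9)), 1 / 19.4,
               tolerance = 1e-6)
  expect_error(mean_attached_time(rE, conditions(0)), "atp")
  expect_identical(mean_attached_time(rE, conditions(0), zero_atp = "Inf"),
                   Inf)
})

test_that("mean_attached_time equals the hypoexponential Monte-Carlo mean", {
  rE <- fix_s267e()$rates
  cond <- conditions(0.1)
  n <- 1e5
  x <- hypoexp_sample(n, rE$k1_0, rE$k2_0 * cond$atp, seed = 42)
  se <- stats::sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - mean_attached_time(rE, cond)), 3 * se)
})

test_that("apparent duty ratio behaves at limits and reproduces the fold", {
  rE <- fix_s267e()$rates
  # k_att -> 0 gives duty -> 0
  r0 <- cycle_rates(19.4, 55, k_att = 1e-9)
  expect_lt(apparent_duty_ratio(r0, conditions(0.1)), 1e-8)
  # t_on = t_off -> 0.5
  cond <- conditions(0.1)
  t_on <- mean_attached_time(rE, cond)
  r5 <- cycle_rates(19.4, 55, k_att = 1 / t_on)
  expect_equal(apparent_duty_ratio(r5, cond), 0.5, tolerance = 1e-12)
  # S267A/S267E quotient in the t_off >> t_on limit ~ 1.85 ("factor of ~2")
  rA <- myo6_variant("S267A")$rates
  rAs <- cycle_rates(rA$k1_0, rA$k2_0, k_att = 0.01)
  rEs <- cycle_rates(rE$k1_0, rE$k2_0, k_att = 0.01)
  q <- apparent_duty_ratio(rAs, cond) / apparent_duty_ratio(rEs, cond)
  expect_equal(q, 1.85, tolerance = 0.01)
})

test_that("gliding velocity: magnitude, ratio, and scaling invariance", {
  vE <- fix_s267e(); vA <- myo6_variant("S267A")
  cond <- conditions(2)
  expect_equal(predicted_gliding_velocity(vE$mech, vE$rates, cond), 300,
               tolerance = 0.01)
  ratio <- predicted_gliding_velocity(vE$mech, vE$rates, cond) /
    predicted_gliding_velocity(vA$mech, vA$rates, cond)
  expect_equal(ratio, 3.9, tolerance = 0.02)
  # ws_total = 0 gives 0
  m0 <- fix_s267e()$mech; m0$ws_total <- 0
  expect_identical(predicted_gliding_velocity(m0, vE$rates, cond), 0)
  # velocity ratio depends only on the t_on ratio: scaling both rates of
  # both variants by c leaves the ratio unchanged
  sc <- 3.7
  rE2 <- cycle_rates(vE$rates$k1_0 * sc, vE$rates$k2_0 * sc)
  rA2 <- cycle_rates(vA$rates$k1_0 * sc, vA$rates$k2_0 * sc)
  ratio2 <- predicted_gliding_velocity(vE$mech, rE2, cond) /
    predicted_gliding_velocity(vA$mech, rA2, cond)
  expect_equal(ratio2, ratio, tolerance = 1e-12)
})

test_that("stall force is stroke times state stiffness", {
  m <- mech_params(18, kappa_pre = 0.25, kappa_rigor = 0.35)
  expect_equal(stall_force(m, "pre"), 4.5)
  expect_equal(stall_force(m, "rigor"), 6.3)
  expect_error(stall_force(m, "nucleotide-free"), "arg")
})

test_that("rigor occupancy: limits, value, complement identity, load trend", {
  rE <- fix_s267e()$rates
  expect_lt(rigor_occupancy(rE, conditions(1e9)), 1e-6)
  expect_equal(round(rigor_occupancy(rE, conditions(0.1)), 2), 0.78)
  # rigor + pre-rigor occupancy = 1 exactly
  for (atp in c(0.01, 0.1, 2)) for (F in c(-2, 0, 3)) {
    cond <- conditions(atp, load = F)
    pre <- (1 / load_rate(rE$k1_0, rE$d1, cond)) /
      mean_attached_time(rE, cond)
    expect_equal(rigor_occupancy(rE, cond) + pre, 1, tolerance = 1e-12)
  }
  # increasing in resisting load when d2 > d1
  occ <- vapply(c(0, 2, 4), function(F)
    rigor_occupancy(rE, conditions(2, load = F)), numeric(1))
  expect_true(all(diff(occ) > 0))
  # extrapolated to 1 mM ATP, rigor dominates well below the ~6.3 pN stall;
  # at 2 mM the crossing sits near (within ~15% of) stall
  f50_1 <- stats::uniroot(function(F)
    rigor_occupancy(rE, conditions(1, load = F)) - 0.5, c(0, 20))$root
  expect_lt(f50_1, 6.3)
  f50_2 <- stats::uniroot(function(F)
    rigor_occupancy(rE, conditions(2, load = F)) - 0.5, c(0, 20))$root
  expect_lt(f50_2, 1.15 * 6.3)
})
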