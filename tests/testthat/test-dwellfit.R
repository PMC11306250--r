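# Dwell-time and displacement estimators.

test_that("single-exponential dwells are recovered (degenerate case)", {
  set.seed(11)
  dw <- rexp(1000, 6)
  f <- cumulative_dwell_fit(dw)
  # dominant component carries the rate; secondary amplitude is small
  dom <- if (abs(f$A1) >= abs(f$A2)) c(f$k1, f$A2) else c(f$k2_obs, f$A1)
  expect_lt(abs(dom[1] / 6 - 1), 0.10)
  expect_gt(f$R2, 0.99)
  expect_error(cumulative_dwell_fit(rexp(20, 1)), ">= 50")
})

test_that("two sequential components are recovered from 2000 dwells", {
  dw <- hypoexp_sample(2000, 19.4, 5.5, seed = 12)
  f <- cumulative_dwell_fit(dw)
  # the slow rate is well conditioned; the fast rate of a sequential
  # process is weakly identified by the free-amplitude survival fit
  expect_lt(abs(f$k1 / 5.5 - 1), 0.10)
  expect_lt(abs(f$k2_obs / 19.4 - 1), 0.45)
  expect_true(f$amplitude_flag)  # hypoexponential: one negative amplitude
  expect_identical(f$n_events, 2000L)
})

test_that("survival-fit slow rate is consistent (bias shrinks with n)", {
  bias <- vapply(c(250, 1000, 4000), function(n) {
    errs <- vapply(1:3, function(r) {
      f <- cumulative_dwell_fit(hypoexp_sample(n, 19.4, 5.5,
                                               seed = 1000 * r + n))
      f$k1 - 5.5
    }, numeric(1))
    abs(mean(errs))
  }, numeric(1))
  expect_lt(bias[3], bias[1])
})

test_that("classify_rates labels by ATP invariance and refines by joint ML", {
  atps <- c(0.01, 0.1)
  dws <- lapply(atps, function(a)
    hypoexp_sample(1200, 19.4, 55 * a, seed = round(1e4 * a)))
  fits <- lapply(dws, cumulative_dwell_fit)
  cl <- classify_rates(fits, atps, dwells = dws)
  expect_true(cl$refined)
  expect_lt(abs(cl$k1_0 - 19.4), 2 * cl$k1_se + 2)
  expect_lt(abs(cl$k2_0 - 55), 2 * cl$k2_se + 3)
  # invariant to permuting the component order inside each DwellFit
  swap <- function(f) {
    g <- f
    g$A1 <- f$A2; g$k1 <- f$k2_obs; g$A2 <- f$A1; g$k2_obs <- f$k1
    g$stderr <- f$stderr[c("A2", "k2_obs", "A1", "k1")]
    names(g$stderr) <- c("A1", "k1", "A2", "k2_obs")
    g
  }
  cl2 <- classify_rates(lapply(fits, swap), atps, dwells = dws)
  expect_equal(cl2$k1_0, cl$k1_0, tolerance = 1e-6)
  expect_equal(cl2$k2_0, cl$k2_0, tolerance = 1e-6)
})

test_that("classify_rates exact-slope example and failure mode", {
  # noiseless fits: component 2 scales with ATP (0.55 -> 5.5 at 0.01/0.1 mM)
  mk <- function(k1, k2) structure(list(
    A1 = 1, k1 = k1, A2 = -0.3, k2_obs = k2,
    stderr = c(A1 = 0.01, k1 = 0.02 * k1, A2 = 0.01, k2_obs = 0.02 * k2),
    n_events = 1000L, R2 = 1), class = "dwell_fit")
  cl <- classify_rates(list(mk(0.55, 19.4), mk(19.4, 5.5)), c(0.01, 0.1),
                       refine = "none")
  expect_equal(cl$k2_0, 55, tolerance = 1e-9)
  expect_equal(cl$k1_0, 19.4, tolerance = 1e-9)
  # both components ATP-scaled: no invariant component -> error
  expect_error(
    classify_rates(list(mk(0.5, 1.5), mk(5, 15)), c(0.01, 0.1),
                   refine = "none"),
    "classification failure")
})

test_that("Gaussian working-stroke fit: recovery and shift equivariance", {
  set.seed(13)
  x <- rnorm(500, mean = 16.1, sd = 1.4)
  f <- displacement_gaussian_fit(x)
  expect_lt(abs(f$xc - 16.1), 2 * f$stderr[["xc"]] + 0.05)
  f2 <- displacement_gaussian_fit(x + 7)
  expect_equal(f2$xc - 7, f$xc, tolerance = 0.05)
  expect_error(displacement_gaussian_fit(rnorm(50)), ">= 100")
  # clearly bimodal input is flagged
  y <- c(rnorm(300, 0, 1), rnorm(300, 12, 1))
  expect_warning(fb <- displacement_gaussian_fit(y), "bimodal")
  expect_true(fb$bimodal)
})

test_that("apparent duty and on-rate from events", {
  ev <- data.frame(dwell = rep(0.25, 40))
  attr(ev, "total_time") <- 40 * 0.25
  expect_warning(d0 <- apparent_duty_and_onrate(ev), "zero detached")
  expect_equal(d0$duty, 1)
  expect_true(is.na(d0$on_rate))
  # synthetic S267E: duty near model value, on-rate recovers k_att
  s <- sim_variant_trace(n_events = 60, seed = 207)
  ev2 <- detect_events(s$trace)
  d <- apparent_duty_and_onrate(ev2)
  expect_lt(abs(d$on_rate - 0.5), 2 * 0.5 / sqrt(nrow(ev2)))
  model_duty <- apparent_duty_ratio(fix_s267e()$rates, s$cond)
  expect_lt(abs(d$duty - model_duty), 0.03)
})
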