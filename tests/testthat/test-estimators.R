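test_that("total noise is the squared coefficient of variation", {
  expect_equal(total_noise(rep(7, 100)), 0)
  set.seed(1)
  x <- stats::rpois(2e5, 40)
  expect_within_se(total_noise(x), 1 / 40, (1 / 40) * sqrt(2 / length(x)) * 2)
  expect_error(total_noise(rep(0, 10)), "zero or non-positive mean")
})

test_that("dual-reporter decomposition identity and limiting cases", {
  set.seed(2)
  x1 <- stats::rpois(500, 20)
  x2 <- stats::rpois(500, 20)

  d <- dual_reporter_decompose(x1, x2)
  # algebraic identity, exact as computed
  expect_identical(d$eta2_total, d$eta2_int + d$eta2_ext)
  # independent reporters at fixed parameters: no extrinsic noise
  expect_lt(abs(d$eta2_ext), 3 * (1 / 20) / sqrt(500))

  # perfectly correlated copies: all noise is extrinsic
  d2 <- dual_reporter_decompose(x1, x1)
  expect_equal(d2$eta2_ext, d2$eta2_total)
  expect_equal(d2$eta2_int, 0)

  expect_error(dual_reporter_decompose(x1, x2[-1]), "paired")
})

test_that("pathway-reporter estimator symmetry and scale robustness", {
  set.seed(3)
  z <- stats::rgamma(400, 4, rate = 2)
  x <- stats::rpois(400, 10 * z)
  y <- stats::rpois(400, 50 * z)
  a <- pathway_reporter_estimate(x, y)
  b <- pathway_reporter_estimate(y, x)
  expect_equal(a$eta2_ext, b$eta2_ext)
  # multiplying one species by a constant (detection efficiency / units)
  # leaves the normalised covariance unchanged
  s <- pathway_reporter_estimate(x, 17 * y)
  expect_equal(s$eta2_ext, a$eta2_ext, tolerance = 1e-12)
  # and it recovers the shared-factor noise (cv2 of z is 1/4)
  expect_lt(abs(a$eta2_ext - 0.25), 3 * 0.25 * sqrt(2 / 400) * 2)
})

test_that("M1 pathway reporters at fixed parameters detect no noise", {
  pop <- simulate_population(model_spec("M1"),
                             gene_params(KN = 50, KM = 10),
                             n_cells = 2000, seed = 31)
  est <- pathway_reporter_estimate(pop$nascent, pop$mature)
  # conditional independence: normalised covariance ~ 0 with
  # se ~ 1/(sqrt(n) sqrt(mean_x mean_y))
  expect_lt(abs(est$eta2_ext), 3 / sqrt(2000 * 5 * 50))
})

test_that("alpha factor matches its closed forms and quadrature", {
  expect_equal(alpha_factor(0.1), (1 / 1.1) / (1 / 0.1))
  expect_lt(alpha_factor(1e-6), 1e-5)  # alpha -> 0 as deltaP -> 0
  set.seed(4)
  dp <- sample_noise(noise_gamma(8, 0.0125), 2e5)
  expect_equal(alpha_factor(dp), alpha_gamma_quadrature(8, 0.0125),
               tolerance = 0.01)
  expect_error(alpha_factor(numeric(0)), "positive")
})

test_that("two-stage intrinsic overshoot matches the analytic value", {
  # normalised intrinsic covariance of mRNA and protein in the two-stage
  # model is deltaP/((1 + deltaP) * Km); a reduced-n version of the
  # full-scale closed-form check
  o <- intrinsic_overshoot(model_spec("M2"),
                           gene_params(Km = 50, Kp = 2, delta_p = 0.1),
                           pair = "mature-protein", n_samples = 8000,
                           seed = 41)
  truth <- 0.1 / (1.1 * 50)
  se <- sqrt((90.9^2 + 50 * 2800) / 8000) / (50 * 1000)
  expect_within_se(o, truth, se)
})

test_that("M1 dual and pathway estimators recover the injected noise", {
  # parameter recovery for transcription-rate noise of strength 0.2
  # (reduced-n version of the full recovery property)
  reps <- 10
  pr <- dr <- numeric(reps)
  for (j in seq_len(reps)) {
    pop <- simulate_population(model_spec("M1"),
                               gene_params(KN = 50, KM = 10),
                               noise = list(KN = noise_gamma(5, 10),
                                            KM = noise_gamma(8, 1.25)),
                               n_cells = 500, dual_reporter = TRUE,
                               seed = child_seed(99, j))
    pr[j] <- pathway_reporter_estimate(pop$nascent, pop$mature)$eta2_ext
    dr[j] <- dual_reporter_decompose(pop$mature, pop$mature2)$eta2_ext
  }
  expect_lt(abs(mean(pr) - 0.2), 3 * stats::sd(pr))
  expect_lt(abs(mean(dr) - 0.2), 3 * stats::sd(dr))
})
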