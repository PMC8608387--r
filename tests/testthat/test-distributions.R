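test_that("telegraph pmf matches the direct-series oracle and closed forms", {
  # 1F1(1; 2; -2) = (1 - exp(-2))/2
  expect_equal(dtelegraph(0, lambda = 1, mu = 1, K = 2),
               (1 - exp(-2)) / 2, tolerance = 1e-12)

  # direct alternating-series summation as independent oracle (small K)
  for (ps in list(c(2, 3, 8), c(1, 0.5, 5), c(5, 12, 15))) {
    n <- 0:40
    expect_equal(dtelegraph(n, ps[1], ps[2], ps[3]),
                 telegraph_pmf_direct(n, ps[1], ps[2], ps[3]),
                 tolerance = 1e-10)
  }

  # constitutive limit: mu = 0 is exactly Poisson(K)
  expect_equal(dtelegraph(0:60, lambda = 3, mu = 0, K = 20),
               stats::dpois(0:60, 20), tolerance = 1e-12)

  # bursty limit: mu >> lambda, K approaches NegBin(lambda, K/(mu+K))
  n <- 0:50
  expect_lt(max(abs(dtelegraph(n, 2, 1000, 1000) -
                      dnegbin_burst(n, r = 2, beta = 1))), 1e-3)

  # rate rescaling by delta leaves the law unchanged
  expect_equal(dtelegraph(0:30, 2, 3, 50, delta = 2),
               dtelegraph(0:30, 1, 1.5, 25), tolerance = 1e-14)

  expect_error(dtelegraph(0, lambda = -1, mu = 1, K = 2), "lambda > 0")
  expect_error(dtelegraph(-1, lambda = 1, mu = 1, K = 2), "non-negative")
})

test_that("pmfs are normalised over their truncation support", {
  cases <- list(
    function(n) dtelegraph(n, 2, 12, 100),
    function(n) dtelegraph(n, 1, 0.2, 800),   # large K, log-space regime
    function(n) dnegbin_burst(n, r = 2, beta = 10),
    function(n) compound_pmf(n, "poisson", "K", noise_gamma(3, 5)))
  moments <- list(telegraph_moments(2, 12, 100),
                  telegraph_moments(1, 0.2, 800),
                  c(mean = 20, var = 220),
                  c(mean = 15, var = 15 + 15 * 5))
  for (i in seq_along(cases)) {
    N <- pmf_support(cases[[i]], moments[[i]][["mean"]],
                     sqrt(moments[[i]][["var"]]))
    expect_lt(abs(1 - sum(cases[[i]](0:N))), 1e-6)
  }
})

test_that("limit_pmf conventions", {
  # degenerate Poisson rate: point mass at zero
  expect_equal(limit_pmf(0:3, "poisson", K = 0), c(1, 0, 0, 0))
  # NegBin(1, 1/2) is geometric 2^-(n+1)
  expect_equal(limit_pmf(0:10, "negbin", r = 1, beta = 1), 2^-(1:11),
               tolerance = 1e-14)
  # mean identity: r = lambda, beta = K/mu gives mean lambda*K/mu
  lam <- 2; K <- 60; mu <- 30
  n <- 0:400
  expect_equal(sum(n * limit_pmf(n, "negbin", r = lam, beta = K / mu)),
               lam * K / mu, tolerance = 1e-8)
  expect_error(limit_pmf(0, "negbin", r = 0, beta = 1), "r > 0")
})

test_that("telegraph sampler matches the pmf", {
  set.seed(5)
  x <- rtelegraph(4e4, 2, 4, 60)
  p <- dtelegraph(0:max(x), 2, 4, 60)
  mo <- telegraph_moments(2, 4, 60)
  expect_within_se(mean(x), mo[["mean"]], sqrt(mo[["var"]] / length(x)))
  # coarse-binned chi-square goodness of fit
  br <- c(-0.5, seq(4.5, 44.5, by = 5), Inf)
  obs <- table(cut(x, br))
  pr <- diff(c(0, vapply(br[-1], function(b) sum(p[0:max(x) <= b]),
                         numeric(1))))
  pr[length(pr)] <- 1 - sum(pr[-length(pr)])
  expect_gt(stats::chisq.test(obs, p = pr)$p.value, 1e-4)
})

test_that("compound pmf reproduces closed-form mixtures", {
  # Gamma-Poisson compound is negative binomial (classical identity)
  expect_equal(compound_pmf(0:10, "poisson", "K", noise_gamma(1, 1)),
               2^-(1:11), tolerance = 1e-8)

  # point-mass mixing returns the base law to machine-level accuracy
  expect_equal(compound_pmf(0:20, "telegraph", "K", noise_point(60),
                            fixed = list(lambda = 2, mu = 4)),
               dtelegraph(0:20, 2, 4, 60), tolerance = 1e-14)

  # scaled-beta noise on K of a narrow telegraph gives a wider telegraph
  q <- compound_pmf(0:40, "telegraph", "K",
                    noise_scaled_beta(100, 5, 9),
                    fixed = list(lambda = 2, mu = 3))
  expect_lt(max(abs(q - dtelegraph(0:40, 2, 12, 100))), 1e-8)

  # law of total expectation: compound mean equals E_f[base mean]
  spec <- noise_gamma(3, 5)
  n <- 0:pmf_support(function(m) compound_pmf(m, "telegraph", "K", spec,
                                              fixed = list(lambda = 2,
                                                           mu = 1)),
                     10, 10)
  q <- compound_pmf(n, "telegraph", "K", spec, fixed = list(lambda = 2,
                                                            mu = 1))
  expect_equal(sum(n * q), 15 * 2 / 3, tolerance = 1e-6)

  # varied parameter must belong to the base family
  expect_error(compound_pmf(0, "poisson", "mu", noise_gamma(1, 1)),
               "not a parameter")
  expect_error(compound_pmf(0, "telegraph", "K", noise_gamma(1, 1),
                            fixed = list(lambda = 2, zz = 1)),
               "unknown fixed")
})
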