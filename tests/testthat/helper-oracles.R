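# Independent oracles used to freeze expected values.

# Telegraph pmf by direct summation of the (alternating) confluent
# hypergeometric series 1F1(lambda + n; lambda + mu + n; -K). Numerically
# safe only for small K (heavy cancellation otherwise), which is exactly
# where it serves as an oracle independent of the Kummer-transform
# evaluation used by the package.
telegraph_pmf_direct <- function(n, lambda, mu, K, terms = 400) {
  vapply(n, function(nn) {
    a <- lambda + nn
    b <- lambda + mu + nn
    j <- seq_len(terms)
    f <- sum(c(1, cumprod((a + j - 1) / (b + j - 1) * (-K) / j)))
    exp(nn * log(K) + lgamma(lambda + nn) - lgamma(lambda) -
          lgamma(nn + 1) - (lgamma(b) - lgamma(lambda + mu))) * f
  }, numeric(1))
}

# alpha = E(1/(dp+1)) / E(1/dp) for dp ~ Gamma(shape, scale), by quadrature.
alpha_gamma_quadrature <- function(shape, scale) {
  up <- stats::qgamma(1 - 1e-12, shape = shape, scale = scale)
  num <- stats::integrate(function(x) 1 / (x + 1) *
                            stats::dgamma(x, shape, scale = scale),
                          0, up, rel.tol = 1e-10)$value
  den <- stats::integrate(function(x) 1 / x *
                            stats::dgamma(x, shape, scale = scale),
                          0, up, rel.tol = 1e-10)$value
  num / den
}

expect_within_se <- function(estimate, truth, se, k = 3) {
  expect_lt(abs(estimate - truth), k * se)
}
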