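#' The Telegraph (two-state promoter) copy-number distribution
#'
#' Stationary mRNA copy-number law of the two-state promoter model: the gene
#' switches on at rate `lambda` and off at rate `mu`, transcribes at rate `K`
#' while on, and transcripts decay at rate `delta`. All rates are internally
#' rescaled by `delta`, so only the ratios matter. The mass function is
#'
#' \deqn{p(n) = \frac{K^n \lambda^{(n)}}{n!\,(\lambda+\mu)^{(n)}}
#'   \,{}_1F_1(\lambda+n;\ \lambda+\mu+n;\ -K),}
#'
#' with \eqn{x^{(n)}} the rising factorial. The confluent hypergeometric
#' factor is evaluated through the Kummer transform
#' \eqn{{}_1F_1(a;b;-K) = e^{-K}\,{}_1F_1(b-a;b;K)}, whose series has
#' positive terms and is accumulated in log space, keeping the evaluation
#' stable for `K` up to several thousand.
#'
#' Limiting cases: `mu = 0` gives `Poisson(K)` (constitutive expression);
#' `mu -> Inf` at fixed `lambda` gives the negative binomial
#' `NegBin(lambda, K/(mu + K))` (instantaneously bursty expression, see
#' [dnegbin_burst()]).
#'
#' @param n vector of non-negative integer copy numbers.
#' @param lambda on-rate (> 0).
#' @param mu off-rate (>= 0). May be a vector recycled against `n`.
#' @param K transcription rate (> 0). May be a vector recycled against `n`.
#' @param delta mRNA degradation rate (> 0, conventionally 1).
#' @param log return log-probabilities?
#' @return numeric vector of probabilities.
#' @examples
#' dtelegraph(0, lambda = 1, mu = 1, K = 2)   # (1 - exp(-2))/2
#' @export
dtelegraph <- function(n, lambda, mu, K, delta = 1, log = FALSE) {
  check_telegraph_params(lambda, mu, K, delta)
  lambda <- lambda / delta; mu <- mu / delta; K <- K / delta
  len <- max(length(n), length(K), length(mu), length(lambda))
  n <- rep_len(n, len); K <- rep_len(K, len)
  mu <- rep_len(mu, len); lambda <- rep_len(lambda, len)
  if (any(n < 0) || any(n != floor(n))) {
    stop("n must be non-negative integers", call. = FALSE)
  }
  lp <- numeric(len)
  for (i in seq_len(len)) {
    if (K[i] == 0) { lp[i] <- if (n[i] == 0) 0 else -Inf; next }
    b <- lambda[i] + mu[i] + n[i]
    lp[i] <- n[i] * log(K[i]) +
      lgamma(lambda[i] + n[i]) - lgamma(lambda[i]) - lgamma(n[i] + 1) -
      (lgamma(b) - lgamma(lambda[i] + mu[i])) -
      K[i] + log1f1_pos(mu[i], b, K[i])
  }
  if (log) lp else exp(lp)
}

# log 1F1(a; b; x) for a >= 0, b > 0, x >= 0 (all series terms positive).
# Accumulated in log space; the term count covers the Poisson-like bulk of
# the series plus a guard band, after which terms decay geometrically.
log1f1_pos <- function(a, b, x) {
  if (x == 0 || a == 0) return(0)
  J <- ceiling(x + 12 * sqrt(x + 10) + 60)
  j <- seq_len(J)
  lt <- cumsum(log(a + j - 1) - log(b + j - 1) + log(x) - log(j))
  m <- max(0, lt)
  m + log(sum(exp(c(0, lt) - m)))
}

check_telegraph_params <- function(lambda, mu, K, delta = 1) {
  if (!all(is.finite(c(lambda, mu, K, delta))) ||
      any(lambda <= 0) || any(mu < 0) || any(K < 0) || any(delta <= 0)) {
    stop("Telegraph parameters require lambda > 0, mu >= 0, K >= 0, delta > 0",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample from the Telegraph distribution
#'
#' Exact sampler through the classical Poisson-Beta mixture: a Telegraph
#' variable is a Poisson variable whose rate is `K * B` with
#' `B ~ Beta(lambda, mu)`.
#'
#' @inheritParams dtelegraph
#' @param n number of draws.
#' @return integer vector of copy numbers.
#' @export
rtelegraph <- function(n, lambda, mu, K, delta = 1) {
  check_telegraph_params(lambda, mu, K, delta)
  lambda <- lambda / delta; mu <- mu / delta; K <- K / delta
  K <- rep_len(K, n)
  if (all(mu == 0)) return(stats::rpois(n, K))
  stats::rpois(n, K * stats::rbeta(n, lambda, rep_len(mu, n)))
}

#' Mean and variance of the Telegraph distribution
#'
#' @inheritParams dtelegraph
#' @return named vector `c(mean, var)`.
#' @export
telegraph_moments <- function(lambda, mu, K, delta = 1) {
  check_telegraph_params(lambda, mu, K, delta)
  lambda <- lambda / delta; mu <- mu / delta; K <- K / delta
  m <- K * lambda / (lambda + mu)
  v <- m + K^2 * lambda * mu / ((lambda + mu)^2 * (lambda + mu + 1))
  c(mean = m, var = v)
}

#' Poisson and negative binomial limits of the Telegraph model
#'
#' `dnegbin_burst` uses the burst-size convention `NegBin(r, beta/(beta+1))`
#' in which `beta` is the mean burst size and the mean is `beta * r`; it maps
#' onto [stats::dnbinom()] with `size = r` and `prob = 1/(1 + beta)` (note
#' the success/failure flip relative to the classical `(r, p)` convention).
#'
#' @param n vector of non-negative integers.
#' @param family `"poisson"` or `"negbin"`.
#' @param ... family parameters: `K` for Poisson; `r` (burst frequency) and
#'   `beta` (mean burst size) for the negative binomial.
#' @param log return log-probabilities?
#' @return numeric vector of probabilities.
#' @examples
#' limit_pmf(0:3, "negbin", r = 1, beta = 1)  # geometric 2^-(n+1)
#' @export
limit_pmf <- function(n, family = c("poisson", "negbin"), ..., log = FALSE) {
  family <- match.arg(family)
  p <- list(...)
  if (family == "poisson") {
    if (is.null(p$K) || p$K < 0) stop("poisson requires K >= 0", call. = FALSE)
    stats::dpois(n, p$K, log = log)
  } else {
    dnegbin_burst(n, r = p$r, beta = p$beta, log = log)
  }
}

#' @rdname limit_pmf
#' @param r burst frequency (negative binomial size).
#' @param beta mean burst size (> 0); may be a vector recycled against `n`.
#' @export
dnegbin_burst <- function(n, r, beta, log = FALSE) {
  if (is.null(r) || is.null(beta) || any(r <= 0) || any(beta <= 0)) {
    stop("negbin requires r > 0 and beta > 0", call. = FALSE)
  }
  stats::dnbinom(n, size = r, prob = 1 / (1 + beta), log = log)
}

#' Truncation support of a pmf
#'
#' Chooses a finite support `0:N` for a distribution given its mean and
#' standard deviation: starting from `mean + 10 * sd`, the support is grown
#' until the captured mass exceeds `1 - tol`.
#'
#' @param pmf function of a vector of integers returning probabilities.
#' @param mean,sd moments of the distribution.
#' @param tol maximum tail mass beyond the returned support.
#' @return integer `N`, the support maximum.
#' @export
pmf_support <- function(pmf, mean, sd, tol = 1e-8) {
  N <- max(10L, ceiling(mean + 10 * sd))
  mass <- sum(pmf(0:N))
  while (1 - mass > tol && N < 1e6) {
    extra <- N + seq_len(N)
    mass <- mass + sum(pmf(extra))
    N <- 2L * N
  }
  as.integer(N)
}

#' Export a pmf table as delimited text
#'
#' Writes a two-column table (`n`, `probability`) in UTF-8 CSV with a header
#' line.
#'
#' @param pmf function of integer vectors returning probabilities.
#' @param support_max last value of the support.
#' @param path output file.
#' @return the data frame, invisibly.
#' @export
write_pmf_table <- function(pmf, support_max, path) {
  n <- 0:support_max
  df <- data.frame(n = n, probability = pmf(n))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(df)
}

#' Compound (mixture) copy-number distribution
#'
#' Probability of `n` copies under a base law whose parameter `which_param`
#' varies across the population according to a [noise_spec()]:
#' \eqn{q(n) = \int p(n;\theta) f(\theta)\, d\theta}. The integral is taken
#' by adaptive Gauss-Kronrod quadrature ([stats::integrate()]) over the
#' noise support ([noise_support()]): the exact support for the bounded
#' families, and up to the `1 - 1e-10` quantile for the unbounded ones.
#'
#' @param n vector of non-negative integers.
#' @param base `"telegraph"`, `"poisson"` or `"negbin"`.
#' @param which_param name of the varied parameter: one of
#'   `"lambda"`, `"mu"`, `"K"` (telegraph), `"K"` (poisson), `"r"`, `"beta"`
#'   (negbin).
#' @param spec a [noise_spec()] for the varied parameter.
#' @param fixed named list of the remaining base parameters.
#' @param abs_tol absolute quadrature tolerance per point (default `1e-10`;
#'   the contract tolerance is `1e-8`).
#' @return numeric vector of probabilities.
#' @examples
#' # Gamma-Poisson mixture is negative binomial: NegBin(1, 1/2) here
#' compound_pmf(0:3, "poisson", "K", noise_gamma(1, 1))
#' @export
compound_pmf <- function(n, base = c("telegraph", "poisson", "negbin"),
                         which_param, spec, fixed = list(),
                         abs_tol = 1e-10) {
  base <- match.arg(base)
  stopifnot(inherits(spec, "noise_spec"))
  valid <- switch(base,
    telegraph = c("lambda", "mu", "K"),
    poisson = "K",
    negbin = c("r", "beta"))
  if (!which_param %in% valid) {
    stop("parameter '", which_param, "' is not a parameter of the ", base,
         " family", call. = FALSE)
  }
  if (length(bad <- setdiff(names(fixed), setdiff(valid, which_param)))) {
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pmf_at <- function(nn, theta) {
    args <- fixed
    args[[which_param]] <- theta
    switch(base,
      telegraph = dtelegraph(nn, lambda = args$lambda, mu = args$mu,
                             K = args$K),
      poisson = stats::dpois(nn, args$K),
      negbin = dnegbin_burst(nn, r = args$r, beta = args$beta))
  }
  if (spec$family == "point") {
    return(pmf_at(n, spec$hyper$value))
  }
  bounds <- noise_support(spec)
  vapply(n, function(nn) {
    stats::integrate(function(t) pmf_at(nn, t) * noise_density(spec, t),
                     bounds[1], bounds[2], rel.tol = 1e-10,
                     abs.tol = abs_tol, subdivisions = 500L,
                     stop.on.error = TRUE)$value
  }, numeric(1))
}
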