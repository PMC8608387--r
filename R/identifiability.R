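#' Non-identifiability representation cases
#'
#' A `representation_case` pairs a fixed-parameter copy-number law (the
#' *target*) with a compound law (the *base* family, one parameter varied
#' according to a [noise_spec()]) that is claimed to reproduce it exactly.
#' Five such representations exist:
#'
#' 1. `Tele(lambda, mu', K')` = `Tele(lambda, mu, K)` with
#'    `K ~ BetaK'(lambda + mu, mu' - mu)`, for any `mu < mu'`.
#' 2. `Tele(lambda, mu', K')` = `Pois(K)` with `K ~ BetaK'(lambda, mu')`
#'    (the `mu = 0` special case of 1; the classical Poisson-Beta mixture).
#' 3. `NegBin(lambda, beta/(beta+1))` = `Tele(lambda, mu, K)` with
#'    `K ~ Gamma(lambda + mu, beta)`, for any `mu >= 0`.
#' 4. `NegBin(lambda, beta/(beta+1))` = `Pois(K)` with
#'    `K ~ Gamma(lambda, beta)` (the `mu = 0` case of 3; the classical
#'    Gamma-Poisson mixture).
#' 5. `NegBin(lambda', b/(b+1))` = `NegBin(lambda, theta/(theta+1))` with
#'    burst-intensity noise `b/theta - 1 ~ BetaPrime(lambda - lambda',
#'    lambda')`, i.e. `theta ~ b * Beta(lambda', lambda - lambda')`, for any
#'    `lambda > lambda'` (beta noise on the *inverse* mean burst intensity).
#'
#' @param target list with elements `family` (`"telegraph"` or `"negbin"`)
#'   and its parameters (`lambda`, `mu`, `K` or `r`, `beta`).
#' @param base base family name passed to [compound_pmf()].
#' @param noise a [noise_spec()] on the varied parameter.
#' @param varied name of the varied base parameter.
#' @param fixed named list of the fixed base parameters.
#' @param id optional case label.
#' @return an object of class `representation_case`.
#' @export
representation_case <- function(target, base, noise, varied, fixed = list(),
                                id = NULL) {
  stopifnot(is.list(target), !is.null(target$family),
            inherits(noise, "noise_spec"))
  if (identical(target$family, "telegraph") &&
      identical(base, "telegraph") && identical(varied, "K") &&
      noise$family != "point") {
    if (!(fixed$mu < target$mu)) {
      stop("telegraph-over-telegraph representation requires mu < mu'",
           call. = FALSE)
    }
  }
  if (identical(target$family, "negbin") && identical(base, "negbin")) {
    if (!(fixed$r > target$r)) {
      stop("negbin-over-negbin representation requires lambda > lambda'",
           call. = FALSE)
    }
  }
  structure(list(target = target, base = base, noise = noise,
                 varied = varied, fixed = fixed,
                 id = if (is.null(id)) paste0(base, "->", target$family)
                      else id),
            class = "representation_case")
}

target_pmf_fun <- function(target) {
  switch(target$family,
    telegraph = function(n) dtelegraph(n, target$lambda, target$mu, target$K),
    negbin = function(n) dnegbin_burst(n, r = target$r, beta = target$beta),
    poisson = function(n) stats::dpois(n, target$K),
    stop("unknown target family ", target$family, call. = FALSE))
}

target_moments <- function(target) {
  switch(target$family,
    telegraph = telegraph_moments(target$lambda, target$mu, target$K),
    negbin = c(mean = target$r * target$beta,
               var = target$r * target$beta * (1 + target$beta)),
    poisson = c(mean = target$K, var = target$K))
}

#' Uniform-norm error of an integral representation
#'
#' Computes `max_n |target pmf - compound pmf|` over `0:support_max`. The
#' default support is the truncation support of the target law (mean +
#' 10 sd, grown until the tail mass drops below `1e-8`), which also covers
#' the compound side since the two laws are claimed equal.
#'
#' @param case a [representation_case()].
#' @param support_max optional integer support maximum.
#' @return the maximum absolute pmf difference, with attributes
#'   `"support_max"` and `"mean_gap"` (difference of means, target minus
#'   compound, over the truncated support).
#' @export
representation_error <- function(case, support_max = NULL) {
  stopifnot(inherits(case, "representation_case"))
  tf <- target_pmf_fun(case$target)
  if (is.null(support_max)) {
    mo <- target_moments(case$target)
    support_max <- pmf_support(tf, mo[["mean"]], sqrt(mo[["var"]]))
  }
  n <- 0:support_max
  pt <- tf(n)
  pc <- compound_pmf(n, base = case$base, which_param = case$varied,
                     spec = case$noise, fixed = case$fixed)
  err <- max(abs(pt - pc))
  structure(err, support_max = support_max,
            mean_gap = sum(n * pt) - sum(n * pc))
}

#' The shipped representation certification cases
#'
#' Ten cases: the five representations, each at two parameter sets. Rows 1,
#' 3 and 5 use the published comparison parameter sets; rows 2 and 4 (the
#' classical special cases) are certified at the row-1/row-3 target
#' parameter sets with a constitutive (`mu = 0`) base.
#'
#' @return named list of [representation_case()] objects.
#' @export
table1_cases <- function() {
  tele <- function(lambda, mu, K)
    list(family = "telegraph", lambda = lambda, mu = mu, K = K)
  nb <- function(r, beta) list(family = "negbin", r = r, beta = beta)
  list(
    row1a = representation_case(
      tele(2, 12, 100), "telegraph",
      noise_scaled_beta(100, 2 + 3, 12 - 3), "K",
      fixed = list(lambda = 2, mu = 3), id = "row1a"),
    row1b = representation_case(
      tele(1, 20, 100), "telegraph",
      noise_scaled_beta(100, 1 + 2, 20 - 2), "K",
      fixed = list(lambda = 1, mu = 2), id = "row1b"),
    row2a = representation_case(
      tele(2, 12, 100), "poisson",
      noise_scaled_beta(100, 2, 12), "K", id = "row2a"),
    row2b = representation_case(
      tele(1, 20, 100), "poisson",
      noise_scaled_beta(100, 1, 20), "K", id = "row2b"),
    row3a = representation_case(
      nb(10, 2), "telegraph",
      noise_gamma(10 + 2, 2), "K",
      fixed = list(lambda = 10, mu = 2), id = "row3a"),
    row3b = representation_case(
      nb(1, 1), "telegraph",
      noise_gamma(1 + 2, 1), "K",
      fixed = list(lambda = 1, mu = 2), id = "row3b"),
    row4a = representation_case(
      nb(10, 2), "poisson", noise_gamma(10, 2), "K", id = "row4a"),
    row4b = representation_case(
      nb(1, 1), "poisson", noise_gamma(1, 1), "K", id = "row4b"),
    row5a = representation_case(
      nb(10, 2), "negbin",
      noise_scaled_beta_prime(scale = 2, shape1 = 15 - 10, shape2 = 10),
      "beta", fixed = list(r = 15), id = "row5a"),
    row5b = representation_case(
      nb(2, 3), "negbin",
      noise_scaled_beta_prime(scale = 3, shape1 = 5 - 2, shape2 = 2),
      "beta", fixed = list(r = 5), id = "row5b")
  )
}

#' Certify all shipped representation cases
#'
#' @param cases list of cases (default [table1_cases()]).
#' @return data frame with columns `case`, `max_abs_error`, `mean_gap`,
#'   `support_max`.
#' @export
verify_representations <- function(cases = table1_cases()) {
  rows <- lapply(names(cases), function(nm) {
    e <- representation_error(cases[[nm]])
    data.frame(case = nm, max_abs_error = as.numeric(e),
               mean_gap = attr(e, "mean_gap"),
               support_max = attr(e, "support_max"))
  })
  do.call(rbind, rows)
}

#' Apparent burstiness under unimodal parameter noise
#'
#' Demonstrates that generic (here zero-truncated normal) noise on the
#' transcription rate or burst intensity produces copy-number samples that
#' resemble a burstier fixed-parameter law. Per cell one parameter value is
#' drawn from `noise`, then one copy number from the base law at that value;
#' the empirical histogram is compared to a named fixed-parameter reference
#' pmf by total-variation distance on the binned support.
#'
#' @param base list: `family` (`"telegraph"` or `"negbin"`) and its fixed
#'   parameters (the varied one omitted).
#' @param noise a [noise_spec()] for the varied parameter (`K` for
#'   telegraph, `beta` for negbin).
#' @param reference list naming the fixed-parameter reference law
#'   (same structure as `target` in [representation_case()]).
#' @param n_samples number of sampled cells.
#' @param seed optional integer seed.
#' @return list with `samples`, `histogram` (data frame `n`, `proportion`),
#'   `reference` (data frame `n`, `probability`) and `distance` (total
#'   variation).
#' @export
apparent_burstiness_demo <- function(base, noise, reference,
                                     n_samples = 1000, seed = NULL) {
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- sample_noise(noise, n_samples)
  x <- switch(base$family,
    telegraph = rtelegraph(n_samples, base$lambda, base$mu, K = theta),
    negbin = stats::rnbinom(n_samples, size = base$r,
                            prob = 1 / (1 + theta)),
    stop("unsupported base family ", base$family, call. = FALSE))
  rf <- target_pmf_fun(reference)
  mo <- target_moments(reference)
  N <- max(max(x), pmf_support(rf, mo[["mean"]], sqrt(mo[["var"]])))
  n <- 0:N
  emp <- tabulate(x + 1L, nbins = N + 1L) / n_samples
  ref <- rf(n)
  tv <- 0.5 * (sum(abs(emp - ref)) + (1 - sum(ref)))
  list(samples = x,
       histogram = data.frame(n = n, proportion = emp),
       reference = data.frame(n = n, probability = ref),
       distance = tv)
}
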