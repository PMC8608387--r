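#' Extrinsic-noise hyper-distributions
#'
#' A `noise_spec` describes how one kinetic parameter varies across a cell
#' population. Five families are supported:
#'
#' * `"point"`: a degenerate distribution (no extrinsic noise) at `value`.
#' * `"scaled-beta"`: `max * Beta(shape1, shape2)` on the interval
#'   `[0, max]`.
#' * `"gamma"`: `Gamma(shape, scale)` (mean `shape * scale`).
#' * `"scaled-beta-prime"`: the burst-intensity noise family of the
#'   negative-binomial representation; a value `theta` follows this law when
#'   `scale / theta - 1 ~ BetaPrime(shape1, shape2)`, equivalently
#'   `theta ~ scale * Beta(shape2, shape1)` with support `(0, scale)`. The
#'   *inverse* `1/theta` then lives on `(1/scale, Inf)` as a shifted, scaled
#'   beta prime variable.
#' * `"truncated-normal"`: a normal distribution with location `mean` and
#'   scale `sd`, truncated below at 0.
#'
#' @param family one of `"point"`, `"scaled-beta"`, `"gamma"`,
#'   `"scaled-beta-prime"`, `"truncated-normal"`.
#' @param ... family-specific hyperparameters (see Details).
#' @return an object of class `noise_spec`.
#' @examples
#' noise_spec("gamma", shape = 5, scale = 10)   # mean 50, cv2 = 0.2
#' noise_spec("scaled-beta", max = 300, shape1 = 1.5, shape2 = 7.5)
#' @export
noise_spec <- function(family = c("point", "scaled-beta", "gamma",
                                  "scaled-beta-prime", "truncated-normal"),
                       ...) {
  family <- match.arg(family)
  p <- list(...)
  need <- switch(family,
    "point" = "value",
    "scaled-beta" = c("max", "shape1", "shape2"),
    "gamma" = c("shape", "scale"),
    "scaled-beta-prime" = c("scale", "shape1", "shape2"),
    "truncated-normal" = c("mean", "sd"))
  if (!setequal(names(p), need)) {
    stop("noise_spec('", family, "') requires hyperparameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  p <- lapply(p[need], as.numeric)
  ok <- switch(family,
    "point" = p$value >= 0,
    "scaled-beta" = p$max > 0 && p$shape1 > 0 && p$shape2 > 0,
    "gamma" = p$shape > 0 && p$scale > 0,
    "scaled-beta-prime" = p$scale > 0 && p$shape1 > 0 && p$shape2 > 0,
    "truncated-normal" = p$sd > 0)
  if (!isTRUE(ok) || !all(vapply(p, is.finite, logical(1)))) {
    stop("invalid hyperparameters for noise_spec('", family, "')",
         call. = FALSE)
  }
  structure(list(family = family, hyper = p), class = "noise_spec")
}

#' @rdname noise_spec
#' @param value point-mass location.
#' @export
noise_point <- function(value) noise_spec("point", value = value)

#' @rdname noise_spec
#' @param max upper end of the scaled-beta support.
#' @param shape1,shape2 beta (or beta-prime) shape parameters.
#' @export
noise_scaled_beta <- function(max, shape1, shape2)
  noise_spec("scaled-beta", max = max, shape1 = shape1, shape2 = shape2)

#' @rdname noise_spec
#' @param shape,scale gamma shape and scale.
#' @export
noise_gamma <- function(shape, scale)
  noise_spec("gamma", shape = shape, scale = scale)

#' @rdname noise_spec
#' @param scale upper end of the support (the mean burst intensity of the
#'   target law in the representation results).
#' @export
noise_scaled_beta_prime <- function(scale, shape1, shape2)
  noise_spec("scaled-beta-prime", scale = scale, shape1 = shape1,
             shape2 = shape2)

#' @rdname noise_spec
#' @param mean,sd location and scale of the parent normal before truncation
#'   at zero.
#' @export
noise_truncated_normal <- function(mean, sd)
  noise_spec("truncated-normal", mean = mean, sd = sd)

#' Construct a scaled-beta noise_spec from a target mean and cv2
#'
#' Chooses the support maximum of a `scaled-beta` family so that
#' `max * shape1 / (shape1 + shape2)` equals `mean`. Used by the bursty-gene
#' benchmark drivers, where each parameter receives Beta-shaped noise scaled
#' to its mean value.
#'
#' @param mean target mean of the hyper-distribution.
#' @param shape1,shape2 beta shape parameters (these fix the cv2).
#' @return a `noise_spec`.
#' @export
noise_scaled_beta_mean <- function(mean, shape1, shape2) {
  noise_scaled_beta(max = mean * (shape1 + shape2) / shape1,
                    shape1 = shape1, shape2 = shape2)
}

#' @export
print.noise_spec <- function(x, ...) {
  h <- paste(names(x$hyper), signif(unlist(x$hyper), 6), sep = "=",
             collapse = ", ")
  m <- noise_moments(x)
  cat(sprintf("<noise_spec %s(%s)> mean=%.6g cv2=%.6g\n",
              x$family, h, m[["mean"]], m[["cv2"]]))
  invisible(x)
}

#' Exact moments of a noise hyper-distribution
#'
#' @param spec a [noise_spec()].
#' @return named numeric vector with elements `mean` and `cv2` (squared
#'   coefficient of variation).
#' @examples
#' noise_moments(noise_gamma(5, 10))  # mean 50, cv2 0.2
#' @export
noise_moments <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  h <- spec$hyper
  out <- switch(spec$family,
    "point" = c(h$value, 0),
    "scaled-beta" = {
      a <- h$shape1; b <- h$shape2
      c(h$max * a / (a + b), b / (a * (a + b + 1)))
    },
    "gamma" = c(h$shape * h$scale, 1 / h$shape),
    "scaled-beta-prime" = {
      # theta = scale * Beta(shape2, shape1)
      a <- h$shape2; b <- h$shape1
      c(h$scale * a / (a + b), b / (a * (a + b + 1)))
    },
    "truncated-normal" = {
      m <- h$mean; s <- h$sd
      alpha <- -m / s
      lambda <- exp(stats::dnorm(alpha, log = TRUE) -
                      stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
      mu <- m + s * lambda
      v <- s^2 * (1 + alpha * lambda - lambda^2)
      c(mu, v / mu^2)
    })
  c(mean = out[1], cv2 = out[2])
}

#' Sample from a noise hyper-distribution
#'
#' Draws are non-negative by construction; truncated-normal draws use the
#' inverse-CDF restricted to the positive half line (no rejection loop).
#'
#' @param spec a [noise_spec()].
#' @param n number of draws.
#' @param seed optional integer seed (set before drawing).
#' @return numeric vector of length `n`.
#' @export
sample_noise <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "noise_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  h <- spec$hyper
  switch(spec$family,
    "point" = rep(h$value, n),
    "scaled-beta" = h$max * stats::rbeta(n, h$shape1, h$shape2),
    "gamma" = stats::rgamma(n, shape = h$shape, scale = h$scale),
    "scaled-beta-prime" = h$scale * stats::rbeta(n, h$shape2, h$shape1),
    "truncated-normal" = {
      p0 <- stats::pnorm(0, h$mean, h$sd)
      stats::qnorm(p0 + stats::runif(n) * (1 - p0), h$mean, h$sd)
    })
}

#' Density of a noise hyper-distribution
#'
#' Not defined for the `point` family (degenerate); the compound-distribution
#' quadrature short-circuits point masses before calling this.
#'
#' @param spec a [noise_spec()].
#' @param x evaluation points.
#' @return numeric vector of density values.
#' @export
noise_density <- function(spec, x) {
  stopifnot(inherits(spec, "noise_spec"))
  h <- spec$hyper
  switch(spec$family,
    "point" = stop("the point family has no density", call. = FALSE),
    "scaled-beta" = stats::dbeta(x / h$max, h$shape1, h$shape2) / h$max,
    "gamma" = stats::dgamma(x, shape = h$shape, scale = h$scale),
    "scaled-beta-prime" =
      stats::dbeta(x / h$scale, h$shape2, h$shape1) / h$scale,
    "truncated-normal" = {
      keep <- x >= 0
      d <- numeric(length(x))
      d[keep] <- stats::dnorm(x[keep], h$mean, h$sd) /
        stats::pnorm(0, h$mean, h$sd, lower.tail = FALSE)
      d
    })
}

#' Quadrature support of a noise hyper-distribution
#'
#' Finite families return their exact support; unbounded families are cut at
#' the `1 - tail` quantile so that adaptive quadrature runs on a bounded,
#' reproducible interval.
#'
#' @param spec a [noise_spec()].
#' @param tail mass allowed beyond the upper cut (default `1e-10`).
#' @return length-2 numeric vector `c(lower, upper)`.
#' @export
noise_support <- function(spec, tail = 1e-10) {
  h <- spec$hyper
  switch(spec$family,
    "point" = c(h$value, h$value),
    "scaled-beta" = c(0, h$max),
    "gamma" = c(0, stats::qgamma(1 - tail, shape = h$shape, scale = h$scale)),
    "scaled-beta-prime" = c(0, h$scale),
    "truncated-normal" = {
      p0 <- stats::pnorm(0, h$mean, h$sd)
      c(0, stats::qnorm(p0 + (1 - tail) * (1 - p0), h$mean, h$sd))
    })
}

#' Serialise / deserialise a noise_spec
#'
#' Plain-list forms used by the YAML configuration files and the population
#' sample side-car metadata.
#'
#' @param spec a [noise_spec()].
#' @return `noise_spec_to_list`: a named list; `noise_spec_from_list`: a
#'   `noise_spec`.
#' @export
noise_spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  c(list(family = spec$family), spec$hyper)
}

#' @rdname noise_spec_to_list
#' @param x a named list with a `family` element, as produced by
#'   `noise_spec_to_list` or read from a config file.
#' @export
noise_spec_from_list <- function(x) {
  if (is.null(x$family)) stop("noise block is missing 'family'", call. = FALSE)
  do.call(noise_spec, c(list(family = x$family),
                        x[setdiff(names(x), "family")]))
}
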