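#' Total expression noise
#'
#' Squared coefficient of variation, `Var(x)/Mean(x)^2`, with the unbiased
#' (n-1) variance divisor.
#'
#' @param x vector of per-cell counts.
#' @return non-negative number.
#' @export
total_noise <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    stop("total noise is undefined for a zero or non-positive mean",
         call. = FALSE)
  }
  stats::var(x) / m^2
}

new_noise_decomposition <- function(total, ext, method, pair, n_cells) {
  structure(list(eta2_total = total, eta2_ext = ext, eta2_int = total - ext,
                 method = method, pair = pair, n_cells = n_cells),
            class = "noise_decomposition")
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat(sprintf(
    "<noise_decomposition (%s, %s, n=%d)>\n  eta2 total %.4f = int %.4f + ext %.4f\n",
    x$method, paste(x$pair, collapse = "-"), x$n_cells,
    x$eta2_total, x$eta2_int, x$eta2_ext))
  invisible(x)
}

#' @export
as.data.frame.noise_decomposition <- function(x, ...) {
  data.frame(method = x$method, pair = paste(x$pair, collapse = "-"),
             eta2_total = x$eta2_total, eta2_int = x$eta2_int,
             eta2_ext = x$eta2_ext, n_cells = x$n_cells)
}

#' Dual-reporter noise decomposition
#'
#' For paired per-cell counts of two conditionally independent, identically
#' distributed reporters, the extrinsic noise is the normalised covariance
#' `Cov(x1, x2) / (E(x1) E(x2))`; the total noise is the average of the two
#' copies' total noise, and the intrinsic component is the difference. The
#' identity `eta2_total = eta2_int + eta2_ext` holds exactly by
#' construction.
#'
#' @param x1,x2 paired count vectors (same cells).
#' @param pair optional reporter-pair label.
#' @return a `noise_decomposition`.
#' @export
dual_reporter_decompose <- function(x1, x2, pair = c("copy1", "copy2")) {
  if (length(x1) != length(x2)) {
    stop("dual reporters must be paired per cell (equal lengths)",
         call. = FALSE)
  }
  ext <- stats::cov(x1, x2) / (mean(x1) * mean(x2))
  total <- mean(c(total_noise(x1), total_noise(x2)))
  new_noise_decomposition(total, ext, "dual-reporter", pair, length(x1))
}

#' Pathway-reporter noise decomposition
#'
#' For paired per-cell counts of two distinct species from the same gene's
#' expression pathway (e.g. nascent and mature mRNA, or mRNA and protein),
#' the normalised covariance `Cov(x, y) / (E(x) E(y))` estimates the
#' extrinsic noise at the transcriptional level whenever the intrinsic
#' contribution to the covariance is negligible (see
#' [intrinsic_overshoot()] for its size). The total noise is computed on
#' the more upstream species `x`; the intrinsic component is reported
#' unclipped and can be negative when the extrinsic estimate overshoots.
#'
#' @param x counts of the upstream species.
#' @param y counts of the downstream species.
#' @param pair optional species-pair label.
#' @return a `noise_decomposition`.
#' @export
pathway_reporter_estimate <- function(x, y, pair = c("upstream",
                                                     "downstream")) {
  if (length(x) != length(y)) {
    stop("pathway reporters must be paired per cell (equal lengths)",
         call. = FALSE)
  }
  ext <- stats::cov(x, y) / (mean(x) * mean(y))
  total <- total_noise(x)
  new_noise_decomposition(total, ext, "pathway-reporter", pair, length(x))
}

#' Intrinsic overshoot of the pathway-reporter estimator
#'
#' The normalised covariance of a reporter pair at *fixed* parameters (no
#' extrinsic noise): the residual intrinsic correlation that biases the
#' pathway-reporter estimate upward when applied to a population with those
#' typical parameters. Estimated from `n_samples` independent stationary
#' SSA snapshots.
#'
#' @param model a [model_spec()].
#' @param params fixed [gene_params()].
#' @param pair one of `"nascent-mature"`, `"nascent-protein"`,
#'   `"mature-protein"`.
#' @param n_samples number of snapshots (>= 1000 recommended).
#' @param seed optional integer seed.
#' @param t_end optional relaxation time override.
#' @return the normalised covariance (a number, possibly negative).
#' @export
intrinsic_overshoot <- function(model, params,
                                pair = c("mature-protein",
                                         "nascent-protein",
                                         "nascent-mature"),
                                n_samples = 3000, seed = NULL,
                                t_end = NULL) {
  pair <- match.arg(pair)
  species <- strsplit(pair, "-", fixed = TRUE)[[1]]
  needs_protein <- "protein" %in% species
  pop <- simulate_population(model, params, noise = list(),
                             n_cells = n_samples, seed = seed,
                             t_end = t_end, track_protein = needs_protein)
  x <- pop[[species[1]]]
  y <- pop[[species[2]]]
  stats::cov(x, y) / (mean(x) * mean(y))
}

#' Protein-decay correction factor for the two-stage model
#'
#' The normalised intrinsic contribution to the mRNA-protein covariance of
#' the two-stage model is `alpha / E(Km)` with
#' `alpha = E(1/(deltaP + 1)) / E(1/deltaP)` (rates scaled so the mRNA
#' decay rate is 1). For a point mass at `deltaP` this is
#' `deltaP / (1 + deltaP)`, which is small whenever protein is longer-lived
#' than mRNA.
#'
#' @param delta_p_samples positive per-cell protein decay rates (a single
#'   value for the no-noise case).
#' @return the ratio `alpha`.
#' @export
alpha_factor <- function(delta_p_samples) {
  if (!length(delta_p_samples) || any(delta_p_samples <= 0)) {
    stop("delta_p samples must be positive", call. = FALSE)
  }
  mean(1 / (delta_p_samples + 1)) / mean(1 / delta_p_samples)
}
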