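#' Deterministic child seeds
#'
#' One root seed spawns independent per-replicate streams through a
#' Lehmer-style counter scheme modulo 2^31 - 1, so each replicate is
#' reproducible on its own and replicates can be re-run independently.
#'
#' @param seed root integer seed.
#' @param i counter (replicate/row index).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, i) {
  m <- 2147483647
  s <- (as.double(seed %% m) * 48271) %% m
  as.integer((s + as.double(i) * 16807) %% (m - 1) + 1)
}

#' Benchmark row sets for the constitutive and bursty comparisons
#'
#' `table2_rows()`/`table3_rows()`: transcription-rate noise rows for the
#' constitutive models (M1 nascent-mature and M2 mRNA-protein reporters):
#' no noise, and squared CVs 0.1, 0.2, 0.5 at mean rate 50. In every row
#' the companion rates carry their own noise (M1: maturation rate
#' Gamma(8, 1.25), mean 10, cv2 0.125; M2: translation rate Gamma(5, 0.4)
#' and protein decay Gamma(8, 0.0125), cv2 0.2 and 0.125), chosen to give
#' mean nascent 5 / mature 50 (M1) and mean mRNA 50 / protein 1000 (M2).
#'
#' `table4_rows()`: bursty-model (M4) mean-parameter rows
#' `(lambda, mu, KN, KP, deltaP)` spanning slow to fast switching, with
#' scaled Beta(5,6) noise (cv2 0.1) on `lambda`, `mu`, `KP`, `deltaP` and
#' scaled Beta(3,6) noise (cv2 0.2) on `KN`; the maturation rate is fixed
#' at `KM = 10` so that the mature-mRNA dual reporter and the pathway
#' reporters target the same extrinsic-noise quantity.
#'
#' @return a list of row definitions (label, theoretical extrinsic noise
#'   where applicable, and per-parameter noise specs).
#' @export
table2_rows <- function() {
  list(
    list(label = "KN=50", eta2_theory = 0, kn = noise_point(50)),
    list(label = "Beta133.3(6,10.5)", eta2_theory = 0.10,
         kn = noise_scaled_beta(400 / 3, 6, 10.5)),
    list(label = "Gamma(5,10)", eta2_theory = 0.20, kn = noise_gamma(5, 10)),
    list(label = "Beta300(1.5,7.5)", eta2_theory = 0.50,
         kn = noise_scaled_beta(300, 1.5, 7.5))
  )
}

#' @rdname table2_rows
#' @export
table3_rows <- function() table2_rows()

#' @rdname table2_rows
#' @export
table4_rows <- function() {
  mk <- function(lambda, mu, KN, KP, deltaP) {
    list(label = sprintf("lambda=%g mu=%g KN=%g KP=%g deltaP=%g",
                         lambda, mu, KN, KP, deltaP),
         mean = c(lambda = lambda, mu = mu, KN = KN, KP = KP,
                  deltaP = deltaP))
  }
  list(mk(0.5, 1, 150, 2, 0.1),
       mk(1, 2, 150, 2, 0.1),
       mk(1, 20, 1050, 2, 0.1),
       mk(2, 2, 100, 6, 0.3),
       mk(2, 20, 550, 6, 0.3),
       mk(10, 10, 100, 6, 0.3))
}

km_noise_m1 <- function() noise_gamma(8, 1.25)

#' Constitutive-model benchmark: nascent-mature pathway vs dual reporters
#'
#' For each transcription-noise row, simulates `replicates` populations of
#' `cells` cells of the M1 maturation model (per-cell `KN` from the row's
#' noise spec, `KM ~ Gamma(8, 1.25)`, `deltaM = 1`), estimating the
#' extrinsic noise with the nascent-mature pathway reporter and with dual
#' mature-mRNA reporters sharing each cell's parameters.
#'
#' @param replicates number of replicate simulations per row.
#' @param cells cells per replicate.
#' @param seed root seed (see [child_seed()]).
#' @param rows row definitions (default [table2_rows()]).
#' @return data frame with per-row estimator means and standard deviations
#'   over replicates, and a `"replicate_log"` attribute holding every
#'   per-replicate estimate.
#' @export
run_table2 <- function(replicates = 20, cells = 500, seed = 1,
                       rows = table2_rows()) {
  model <- model_spec("M1")
  log <- list()
  out <- lapply(seq_along(rows), function(i) {
    row <- rows[[i]]
    pr <- dr <- numeric(replicates)
    for (j in seq_len(replicates)) {
      s <- child_seed(seed, i * 100000 + j)
      pop <- simulate_population(
        model, gene_params(KN = noise_moments(row$kn)[["mean"]], KM = 10),
        noise = list(KN = row$kn, KM = km_noise_m1()),
        n_cells = cells, dual_reporter = TRUE, seed = s)
      pr[j] <- pathway_reporter_estimate(pop$nascent, pop$mature)$eta2_ext
      dr[j] <- dual_reporter_decompose(pop$mature, pop$mature2)$eta2_ext
    }
    log[[i]] <<- data.frame(row = row$label, replicate = seq_len(replicates),
                            pr_nm = pr, dr_mat = dr)
    data.frame(eta2_theory = row$eta2_theory, noise_KN = row$label,
               pr_nm_mean = mean(pr), pr_nm_sd = stats::sd(pr),
               dr_mat_mean = mean(dr), dr_mat_sd = stats::sd(dr))
  })
  res <- do.call(rbind, out)
  attr(res, "replicate_log") <- do.call(rbind, log)
  res
}

#' Two-stage-model benchmark: mRNA-protein pathway vs dual reporters
#'
#' As [run_table2()] but for the two-stage model M2: per-cell `Km` from the
#' row's noise spec, `Kp ~ Gamma(5, 0.4)`, `deltaP ~ Gamma(8, 0.0125)`,
#' `deltaM = 1`. The pathway estimate uses the mRNA-protein pair from a
#' single reporter; the dual estimate uses two mature-mRNA copies (the
#' protein stage does not feed back on mRNA, so it is omitted from the
#' dual-reporter runs).
#'
#' @inheritParams run_table2
#' @return as [run_table2()], with columns `pr_mp_*` and `dr_mat_*`.
#' @export
run_table3 <- function(replicates = 20, cells = 500, seed = 1,
                       rows = table3_rows()) {
  model <- model_spec("M2")
  noise_extra <- list(KP = noise_gamma(5, 0.4),
                      deltaP = noise_gamma(8, 0.0125))
  log <- list()
  out <- lapply(seq_along(rows), function(i) {
    row <- rows[[i]]
    pr <- dr <- numeric(replicates)
    for (j in seq_len(replicates)) {
      s <- child_seed(seed, 1000000 + i * 100000 + j)
      base <- gene_params(Km = noise_moments(row$kn)[["mean"]], Kp = 2,
                          delta_p = 0.1)
      pop <- simulate_population(model, base,
                                 noise = c(list(KN = row$kn), noise_extra),
                                 n_cells = cells, seed = s)
      pr[j] <- pathway_reporter_estimate(pop$mature, pop$protein)$eta2_ext
      popd <- simulate_population(model, base,
                                  noise = c(list(KN = row$kn), noise_extra),
                                  n_cells = cells, dual_reporter = TRUE,
                                  seed = child_seed(s, 7),
                                  track_protein = FALSE)
      dr[j] <- dual_reporter_decompose(popd$mature, popd$mature2)$eta2_ext
    }
    log[[i]] <<- data.frame(row = row$label, replicate = seq_len(replicates),
                            pr_mp = pr, dr_mat = dr)
    data.frame(eta2_theory = row$eta2_theory, noise_Km = row$label,
               pr_mp_mean = mean(pr), pr_mp_sd = stats::sd(pr),
               dr_mat_mean = mean(dr), dr_mat_sd = stats::sd(dr))
  })
  res <- do.call(rbind, out)
  attr(res, "replicate_log") <- do.call(rbind, log)
  res
}

table4_noise <- function(mean) {
  list(lambda = noise_scaled_beta_mean(mean[["lambda"]], 5, 6),
       mu = noise_scaled_beta_mean(mean[["mu"]], 5, 6),
       KN = noise_scaled_beta_mean(mean[["KN"]], 3, 6),
       KP = noise_scaled_beta_mean(mean[["KP"]], 5, 6),
       deltaP = noise_scaled_beta_mean(mean[["deltaP"]], 5, 6))
}

#' Bursty-model benchmark: pathway reporters vs dual reporters
#'
#' For each mean-parameter row of [table4_rows()], simulates the four-stage
#' bursty model M4 with per-cell scaled-Beta noise on `lambda`, `mu`, `KN`,
#' `KP` and `deltaP` (`KM = 10` fixed) and reports the mature-protein,
#' nascent-protein and nascent-mature pathway estimates alongside the dual
#' mature-mRNA reporter.
#'
#' @inheritParams run_table2
#' @param rows row definitions (default [table4_rows()]).
#' @return data frame of per-row means and standard deviations for
#'   `pr_mp`, `pr_np`, `pr_nm` and `dr_mat`, with a `"replicate_log"`
#'   attribute.
#' @export
run_table4 <- function(replicates = 20, cells = 500, seed = 1,
                       rows = table4_rows()) {
  model <- model_spec("M4")
  log <- list()
  out <- lapply(seq_along(rows), function(i) {
    row <- rows[[i]]
    m <- row$mean
    base <- gene_params(lambda = m[["lambda"]], mu = m[["mu"]],
                        KN = m[["KN"]], KM = 10, KP = m[["KP"]],
                        deltaP = m[["deltaP"]])
    noise <- table4_noise(m)
    est <- matrix(0, replicates, 4,
                  dimnames = list(NULL, c("pr_mp", "pr_np", "pr_nm",
                                          "dr_mat")))
    for (j in seq_len(replicates)) {
      s <- child_seed(seed, 2000000 + i * 100000 + j)
      pop <- simulate_population(model, base, noise = noise, n_cells = cells,
                                 seed = s)
      est[j, "pr_mp"] <-
        pathway_reporter_estimate(pop$mature, pop$protein)$eta2_ext
      est[j, "pr_np"] <-
        pathway_reporter_estimate(pop$nascent, pop$protein)$eta2_ext
      est[j, "pr_nm"] <-
        pathway_reporter_estimate(pop$nascent, pop$mature)$eta2_ext
      popd <- simulate_population(model, base, noise = noise,
                                  n_cells = cells, dual_reporter = TRUE,
                                  seed = child_seed(s, 7),
                                  track_protein = FALSE)
      est[j, "dr_mat"] <-
        dual_reporter_decompose(popd$mature, popd$mature2)$eta2_ext
    }
    log[[i]] <<- data.frame(row = row$label, replicate = seq_len(replicates),
                            est)
    data.frame(row = row$label, t(c(
      colMeans(est)[c("pr_mp", "pr_np", "pr_nm", "dr_mat")])),
      pr_mp_sd = stats::sd(est[, "pr_mp"]),
      pr_np_sd = stats::sd(est[, "pr_np"]),
      pr_nm_sd = stats::sd(est[, "pr_nm"]),
      dr_mat_sd = stats::sd(est[, "dr_mat"]))
  })
  res <- do.call(rbind, out)
  names(res)[2:5] <- c("pr_mp_mean", "pr_np_mean", "pr_nm_mean",
                       "dr_mat_mean")
  attr(res, "replicate_log") <- do.call(rbind, log)
  res
}

#' Intrinsic-overshoot heatmap for the bursty model
#'
#' Grid of [intrinsic_overshoot()] values for the four-stage model M4 at
#' fixed parameters: `deltaM = 1`, `KM = 20`, `KN` and `KP` chosen per grid
#' point to give mean nascent `nascent_mean` and mean protein
#' `protein_mean` (the implied mature mean is `nascent_mean * KM / deltaM`).
#' The default grid is a reduced 8 x 8 version of the published
#' `lambda in [0.5, 5]`, `deltaP in [0.01, 0.5]` sweep; pass finer grids and
#' `n_samples = 3000` for full fidelity (hours of computation).
#'
#' @param pair reporter pair, as in [intrinsic_overshoot()].
#' @param mu fixed off-rate (published panels use 2, 10, 20).
#' @param lambda,delta_p grid values.
#' @param n_samples SSA snapshots per pixel.
#' @param KM maturation rate.
#' @param nascent_mean,protein_mean target stationary means.
#' @param seed root seed.
#' @return matrix of overshoot estimates, `lambda` in rows and `delta_p`
#'   in columns.
#' @export
run_heatmap <- function(pair = "mature-protein", mu = 2,
                        lambda = seq(0.5, 5, length.out = 8),
                        delta_p = seq(0.01, 0.5, length.out = 8),
                        n_samples = 1000, KM = 20, nascent_mean = 5,
                        protein_mean = 1000, seed = 1) {
  model <- model_spec("M4")
  mature_mean <- nascent_mean * KM  # deltaM = 1
  out <- matrix(NA_real_, length(lambda), length(delta_p),
                dimnames = list(lambda = signif(lambda, 4),
                                delta_p = signif(delta_p, 4)))
  k <- 0
  for (i in seq_along(lambda)) {
    for (j in seq_along(delta_p)) {
      k <- k + 1
      KN <- nascent_mean * KM * (lambda[i] + mu) / lambda[i]
      KP <- protein_mean * delta_p[j] / mature_mean
      params <- gene_params(lambda = lambda[i], mu = mu, KN = KN, KM = KM,
                            KP = KP, deltaP = delta_p[j])
      out[i, j] <- intrinsic_overshoot(model, params, pair = pair,
                                       n_samples = n_samples,
                                       seed = child_seed(seed, 3000000 + k))
    }
  }
  out
}

generality_cases <- function() {
  # Multiscale base setting: moderately slow switching so that
  # activation-rate noise transfers to the transcription throughput
  # (elasticity ~ 0.5), copy numbers of order 5/10/100, and a slow protein
  # so the nascent-protein intrinsic overshoot is negligible (~0.01).
  ms3 <- gene_params(lambda = 1, mu = 1, lambda2 = 20, KN = 600, KM = 2,
                     KP = 1, deltaP = 0.1)
  lam1_noise <- list(lambda = noise_scaled_beta_mean(1, 3, 6))  # cv2 0.2
  list(
    `1` = list(
      description = "constitutive maturation with a fixed delay",
      model = model_spec("M4", maturation = "fixed", delay = 0.1),
      params = gene_params(lambda = 1, mu = 0, KN = 50),
      noise = list(KN = noise_gamma(5, 10)),
      pair = c("nascent", "mature"), track_protein = FALSE),
    `2` = list(
      description = "multiscale three-state bursting with protein",
      model = model_spec("MS3"),
      params = ms3, noise = lam1_noise,
      pair = c("nascent", "protein"), track_protein = TRUE),
    `3` = list(
      description = "multiscale model with fixed-delay maturation",
      model = model_spec("MS3", maturation = "fixed", delay = 0.5),
      params = ms3, noise = lam1_noise,
      pair = c("nascent", "protein"), track_protein = TRUE),
    `4` = list(
      description = paste("multiscale model with Erlang maturation and",
                          "cell-cycle features"),
      model = model_spec("MS3", maturation = "erlang", shape = 3, rate = 6,
                         cell_cycle = TRUE, cycle_rate = 1),
      params = ms3, noise = lam1_noise,
      pair = c("nascent", "protein"), track_protein = TRUE)
  )
}

#' Pathway vs dual reporters under more detailed expression dynamics
#'
#' Validation cases beyond the core models: (1) constitutive expression
#' with a fixed maturation delay; (2) the multiscale three-state bursting
#' model extended with protein; (3) the multiscale model with fixed-delay
#' maturation; (4) the multiscale model with Erlang maturation delays and
#' cell-cycle features (replication, dosage compensation, binomial
#' partitioning, Erlang cycle lengths). In each case the pathway-reporter
#' estimate is benchmarked against an in-run dual-reporter estimate; the
#' two target the same extrinsic-noise quantity because all species' means
#' share a common transcription-throughput factor.
#'
#' @param cases which cases to run (subset of 1:4).
#' @param replicates replicate simulations per case.
#' @param cells cells per replicate.
#' @param seed root seed.
#' @return data frame with per-case pathway and dual means, standard
#'   deviations, and the agreement margin `|pr_mean - dr_mean|`.
#' @export
run_generality <- function(cases = 1:4, replicates = 10, cells = 200,
                           seed = 1) {
  defs <- generality_cases()
  out <- lapply(cases, function(ci) {
    cs <- defs[[as.character(ci)]]
    pr <- dr <- numeric(replicates)
    for (j in seq_len(replicates)) {
      s <- child_seed(seed, 4000000 + ci * 100000 + j)
      pop <- simulate_population(cs$model, cs$params, noise = cs$noise,
                                 n_cells = cells, dual_reporter = TRUE,
                                 seed = s, track_protein = cs$track_protein)
      pr[j] <- pathway_reporter_estimate(pop[[cs$pair[1]]],
                                         pop[[cs$pair[2]]])$eta2_ext
      dr[j] <- dual_reporter_decompose(pop$mature, pop$mature2)$eta2_ext
    }
    data.frame(case = ci, description = cs$description,
               pair = paste(cs$pair, collapse = "-"),
               pr_mean = mean(pr), pr_sd = stats::sd(pr),
               dr_mean = mean(dr), dr_sd = stats::sd(dr),
               margin = abs(mean(pr) - mean(dr)),
               se_diff = stats::sd(pr - dr) / sqrt(replicates))
  })
  do.call(rbind, out)
}
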