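#' Gene-expression network specification
#'
#' Networks:
#' * `"M1"`: constitutive maturation model — nascent mRNA synthesised at
#'   `KN`, matured at `KM`, mature mRNA decays at `deltaM`.
#' * `"M2"`: two-stage model — mRNA at `KN` (alias `Km`), protein at `KP`
#'   (alias `Kp`), decays `deltaM`, `deltaP`.
#' * `"M3"`: three-stage model — `M2` plus two-state promoter switching
#'   (`lambda` on, `mu` off).
#' * `"M4"`: four-stage model — `M3` plus mRNA maturation (nascent species).
#' * `"MS3"`: multiscale three-state bursting model — inactive state `S0`,
#'   active states `S10` (transcription factors bound) and `S11`
#'   (polymerase paused); transcription from `S11` returns the gene to
#'   `S10`; plus maturation, translation and decay.
#'
#' Maturation can be first-order (`"rate"`, rate `KM`), a fixed delay
#' (`"fixed"`, duration `delay`), or an Erlang-distributed delay
#' (`"erlang"`, `shape` exponential stages at rate `rate`); delays are
#' drawn at scheduling time and executed through an event queue interleaved
#' exactly with the SSA. Cell-cycle features (only exercised with the
#' `MS3`/`M4`-class networks): time to replication and replication to
#' division are each Erlang(`replication_shape`, `cycle_rate`) and
#' Erlang(`division_shape`, `cycle_rate`); at replication the gene copy
#' number doubles (the new copy inherits the promoter state) and the
#' activation rate is multiplied by `dosage_factor`; at division each
#' molecule survives independently with probability 1/2 and one daughter is
#' followed.
#'
#' @param network one of `"M1"`, `"M2"`, `"M3"`, `"M4"`, `"MS3"`.
#' @param maturation `"rate"`, `"fixed"` or `"erlang"` (non-rate modes only
#'   for networks with a nascent species: M1, M4, MS3).
#' @param delay fixed maturation delay (time units of `1/deltaM`).
#' @param shape,rate Erlang delay shape and rate.
#' @param cell_cycle logical; enable the cell-cycle features.
#' @param cycle_rate rate of each Erlang stage; the total cycle length is
#'   Erlang(`replication_shape + division_shape`, `cycle_rate`).
#' @param replication_shape,division_shape Erlang shapes of the two cycle
#'   phases (default 12 each).
#' @param dosage_factor post-replication activation-rate multiplier
#'   (default 0.7).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(network = c("M1", "M2", "M3", "M4", "MS3"),
                       maturation = c("rate", "fixed", "erlang"),
                       delay = NULL, shape = NULL, rate = NULL,
                       cell_cycle = FALSE, cycle_rate = 1,
                       replication_shape = 12, division_shape = 12,
                       dosage_factor = 0.7) {
  network <- match.arg(network)
  maturation <- match.arg(maturation)
  if (maturation != "rate" && !network_has_nascent(network)) {
    stop("delayed maturation requires a network with a nascent species ",
         "(M1, M4 or MS3)", call. = FALSE)
  }
  if (maturation == "fixed" && (is.null(delay) || delay < 0)) {
    stop("fixed maturation requires delay >= 0", call. = FALSE)
  }
  if (maturation == "erlang" &&
      (is.null(shape) || is.null(rate) || shape < 1 || rate <= 0)) {
    stop("erlang maturation requires shape >= 1 and rate > 0", call. = FALSE)
  }
  if (cell_cycle && !network %in% c("M3", "M4", "MS3")) {
    stop("cell-cycle features require a promoter-switching network",
         call. = FALSE)
  }
  structure(list(network = network, maturation = maturation, delay = delay,
                 shape = shape, rate = rate, cell_cycle = cell_cycle,
                 cycle_rate = cycle_rate,
                 replication_shape = replication_shape,
                 division_shape = division_shape,
                 dosage_factor = dosage_factor),
            class = "model_spec")
}

network_has_nascent <- function(network) network %in% c("M1", "M4", "MS3")
network_has_protein <- function(network) network %in% c("M2", "M3", "M4", "MS3")
network_code <- function(network) {
  match(network, c("M1", "M2", "M3", "M4", "MS3"))
}
mat_mode_code <- function(model) {
  match(model$maturation, c("rate", "fixed", "erlang")) - 1L
}
mat_params <- function(model) {
  switch(model$maturation,
         rate = c(0, 0),
         fixed = c(model$delay, 0),
         erlang = c(model$shape, model$rate))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s, maturation=%s%s>\n", x$network, x$maturation,
              if (x$cell_cycle) ", cell-cycle on" else ""))
  invisible(x)
}

#' Kinetic rate parameters for one cell
#'
#' Canonical names are `lambda` (activation), `mu` (inactivation),
#' `lambda2` (MS3 polymerase binding/pause rate), `KN` (transcription),
#' `KM` (maturation rate), `KP` (translation), `deltaM` (mRNA decay,
#' conventionally 1 — it sets the time unit) and `deltaP` (protein decay).
#' Two-stage-model aliases `Km`, `Kp`, `delta_m`, `delta_p` are accepted
#' for `KN`, `KP`, `deltaM`, `deltaP`.
#'
#' @param lambda,mu,lambda2,KN,KM,KP,deltaM,deltaP non-negative rates.
#' @param Km,Kp,delta_m,delta_p aliases (two-stage model convention).
#' @return a named numeric vector of class `gene_params`.
#' @export
gene_params <- function(lambda = 1, mu = 0, lambda2 = 0, KN = 0, KM = 0,
                        KP = 0, deltaM = 1, deltaP = 0,
                        Km = NULL, Kp = NULL, delta_m = NULL,
                        delta_p = NULL) {
  if (!is.null(Km)) KN <- Km
  if (!is.null(Kp)) KP <- Kp
  if (!is.null(delta_m)) deltaM <- delta_m
  if (!is.null(delta_p)) deltaP <- delta_p
  p <- c(lambda = lambda, mu = mu, lambda2 = lambda2, KN = KN, KM = KM,
         KP = KP, deltaM = deltaM, deltaP = deltaP)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("all rates must be finite and non-negative", call. = FALSE)
  }
  structure(p, class = "gene_params")
}

param_order <- c("lambda", "mu", "lambda2", "KN", "KM", "KP",
                 "deltaM", "deltaP")

#' Default relaxation time for a steady-state snapshot
#'
#' The mRNA decay rate (`deltaM = 1`) sets the clock: 15 time units suffice
#' for the mRNA species. When protein is tracked, its autocorrelation time
#' `1/deltaP` dominates and the default becomes `max(15, 10/deltaP)`.
#'
#' @param model a [model_spec()].
#' @param deltaP per-cell protein decay rate(s).
#' @param track_protein logical; is protein simulated?
#' @return numeric vector of relaxation times.
#' @export
default_t_end <- function(model, deltaP, track_protein) {
  if (isTRUE(track_protein) && network_has_protein(model$network)) {
    pmax(15, 10 / pmax(deltaP, 1e-12))
  } else {
    rep_len(15, length(deltaP))
  }
}

#' One exact SSA realisation sampled at a fixed time
#'
#' Runs the network from the empty, inactive initial state to `t_end` and
#' returns the species counts. Delayed maturation events are scheduled at
#' synthesis time and executed at their firing time, interleaved exactly
#' with the SSA steps.
#'
#' @param model a [model_spec()].
#' @param params a [gene_params()] vector.
#' @param t_end snapshot time; defaults to [default_t_end()].
#' @param seed optional integer seed.
#' @param track_protein simulate the protein stage? Defaults to `TRUE` for
#'   networks with protein. Protein never feeds back on the mRNA stages, so
#'   disabling it leaves the mRNA marginals exact.
#' @return named integer vector `c(nascent, mature, protein, gene_state)`.
#' @export
ssa_snapshot <- function(model, params, t_end = NULL, seed = NULL,
                         track_protein = NULL) {
  pop <- simulate_population(model, params, noise = list(), n_cells = 1,
                             t_end = t_end, seed = seed,
                             track_protein = track_protein)
  c(nascent = pop$nascent[1], mature = pop$mature[1],
    protein = pop$protein[1], gene_state = pop$gene_state[1])
}

#' Simulate a population snapshot with extrinsic parameter variation
#'
#' For each cell one parameter vector is drawn (noisy parameters sampled
#' independently from their [noise_spec()]s — extrinsic-noise sources are
#' assumed independent), and one exact SSA realisation is run to its
#' relaxation time. In dual-reporter mode two conditionally independent
#' realisations share each cell's parameter draw (and, with the cell cycle
#' on, its division schedule), and both copies' counts are recorded.
#'
#' @param model a [model_spec()].
#' @param params mean parameters, a [gene_params()] vector. A parameter
#'   listed in `noise` takes its per-cell values (and its mean) from the
#'   noise spec instead.
#' @param noise named list of [noise_spec()] objects, names from
#'   `lambda`, `mu`, `lambda2`, `KN`, `KM`, `KP`, `deltaM`, `deltaP` (or
#'   the `Km`/`Kp`/`delta_m`/`delta_p` aliases).
#' @param n_cells number of cells.
#' @param dual_reporter record a second conditionally independent reporter
#'   copy per cell?
#' @param t_end relaxation time (scalar or per-cell); defaults to
#'   [default_t_end()].
#' @param n_cycles with the cell cycle on: total cycles simulated per cell;
#'   the snapshot is taken at a uniformly random time within the last cycle
#'   and the preceding cycles are burn-in.
#' @param seed optional integer seed.
#' @param track_protein see [ssa_snapshot()].
#' @return a `population_sample`: a data frame with one row per cell
#'   (columns `cell`, `nascent`, `mature`, `protein`, `gene_state`, the
#'   `*2` copies in dual-reporter mode, then the per-cell parameter draws),
#'   with the model, noise specs, seed and relaxation times in attributes.
#' @export
simulate_population <- function(model, params, noise = list(), n_cells,
                                dual_reporter = FALSE, t_end = NULL,
                                n_cycles = 6, seed = NULL,
                                track_protein = NULL) {
  stopifnot(inherits(model, "model_spec"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(track_protein)) {
    track_protein <- network_has_protein(model$network)
  }
  params <- as_gene_params(params)
  alias <- c(Km = "KN", Kp = "KP", delta_m = "deltaM", delta_p = "deltaP")
  if (length(noise)) {
    nm <- names(noise)
    nm[nm %in% names(alias)] <- alias[nm[nm %in% names(alias)]]
    names(noise) <- nm
    if (length(bad <- setdiff(nm, param_order))) {
      stop("noise given for unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  pm <- matrix(rep(unclass(params), each = n_cells), nrow = n_cells,
               dimnames = list(NULL, param_order))
  for (nm in names(noise)) pm[, nm] <- sample_noise(noise[[nm]], n_cells)

  n_rep <- if (dual_reporter) 2L else 1L
  if (isTRUE(model$cell_cycle)) {
    counts <- ssa_cellcycle_cpp(network_code(model$network), pm,
                                as.integer(n_cycles), model$cycle_rate,
                                as.integer(model$replication_shape),
                                as.integer(model$division_shape),
                                model$dosage_factor, track_protein,
                                mat_mode_code(model), mat_params(model)[1],
                                mat_params(model)[2], n_rep)
    t_end <- rep_len(NA_real_, n_cells)
  } else {
    if (is.null(t_end)) {
      t_end <- default_t_end(model, pm[, "deltaP"], track_protein)
    }
    t_end <- rep_len(t_end, n_cells)
    counts <- ssa_population_cpp(network_code(model$network), pm, t_end,
                                 track_protein, mat_mode_code(model),
                                 mat_params(model)[1], mat_params(model)[2],
                                 n_rep)
  }
  out <- data.frame(cell = seq_len(n_cells),
                    nascent = counts[, 1], mature = counts[, 2],
                    protein = counts[, 3], gene_state = counts[, 4])
  if (dual_reporter) {
    out$nascent2 <- counts[, 5]; out$mature2 <- counts[, 6]
    out$protein2 <- counts[, 7]; out$gene_state2 <- counts[, 8]
  }
  out <- cbind(out, as.data.frame(pm))
  attr(out, "model") <- model
  attr(out, "noise") <- noise
  attr(out, "seed") <- seed
  attr(out, "t_end") <- t_end
  attr(out, "track_protein") <- track_protein
  class(out) <- c("population_sample", "data.frame")
  out
}

as_gene_params <- function(params) {
  if (inherits(params, "gene_params")) return(params)
  do.call(gene_params, as.list(params))
}

#' Cell-cycle snapshot simulation
#'
#' Convenience wrapper around [simulate_population()] for cell-cycle
#' models: simulates `n_cycles` successive cycles (Erlang-distributed
#' replication and division phases, replication doubling the gene copy
#' number with dosage compensation, binomial partitioning at division, one
#' daughter followed) and snapshots each cell at a uniformly random time
#' within the final cycle, emulating an unsynchronised population.
#'
#' @inheritParams simulate_population
#' @return a `population_sample`.
#' @export
simulate_cell_cycle <- function(model, params, noise = list(), n_cells = 1,
                                n_cycles = 6, dual_reporter = FALSE,
                                seed = NULL, track_protein = NULL) {
  stopifnot(isTRUE(model$cell_cycle), n_cycles >= 3)
  simulate_population(model, params, noise = noise, n_cells = n_cells,
                      dual_reporter = dual_reporter, n_cycles = n_cycles,
                      seed = seed, track_protein = track_protein)
}

#' Reaction propensities at a given state
#'
#' Pure-R mirror of the simulation engine's mass-action propensities,
#' intended for inspection and testing.
#'
#' @param model a [model_spec()].
#' @param params a [gene_params()] vector.
#' @param state list with elements `gene` (0/1, or 0/1/2 for MS3), `nascent`,
#'   `mature`, `protein`.
#' @return data frame with columns `reaction` and `propensity`.
#' @export
propensity_table <- function(model, params, state) {
  p <- as_gene_params(params)
  g <- state$gene %||% 1L
  N <- state$nascent %||% 0L
  M <- state$mature %||% 0L
  P <- state$protein %||% 0L
  rows <- list()
  add <- function(reaction, propensity) {
    rows[[length(rows) + 1L]] <<- data.frame(reaction = reaction,
                                             propensity = propensity)
  }
  switch(model$network,
    M1 = add("synthesis_nascent", p[["KN"]]),
    M2 = add("synthesis_mrna", p[["KN"]]),
    M3 = {
      add("activation", if (g == 0) p[["lambda"]] else 0)
      add("inactivation", if (g == 1) p[["mu"]] else 0)
      add("synthesis_mrna", if (g == 1) p[["KN"]] else 0)
    },
    M4 = {
      add("activation", if (g == 0) p[["lambda"]] else 0)
      add("inactivation", if (g == 1) p[["mu"]] else 0)
      add("synthesis_nascent", if (g == 1) p[["KN"]] else 0)
    },
    MS3 = {
      add("S0_to_S10", if (g == 0) p[["lambda"]] else 0)
      add("S10_to_S0", if (g == 1) p[["mu"]] else 0)
      add("S10_to_S11", if (g == 1) p[["lambda2"]] else 0)
      add("S11_to_S0", if (g == 2) p[["mu"]] else 0)
      add("transcribe_S11_to_S10", if (g == 2) p[["KN"]] else 0)
    })
  if (network_has_nascent(model$network) && model$maturation == "rate") {
    add("maturation", p[["KM"]] * N)
  }
  add("decay_mature", p[["deltaM"]] * M)
  if (network_has_protein(model$network)) {
    add("translation", p[["KP"]] * M)
    add("decay_protein", p[["deltaP"]] * P)
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.population_sample <- function(x, ...) {
  m <- attr(x, "model")
  cat(sprintf("<population_sample: %d cells, %s%s>\n", nrow(x), m$network,
              if (!is.null(x$mature2)) ", dual-reporter" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
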