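#' Write / read a population sample as delimited text
#'
#' Comma-separated, "." decimal, header row, UTF-8, no quoting: one row per
#' cell with the species counts and the per-cell parameter draws. A YAML
#' side-car (`<path>.meta.yaml`) carries the model spec, noise specs, seed
#' and relaxation times, so a re-read sample reproduces the in-memory
#' original.
#'
#' @param sample a `population_sample` from [simulate_population()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(sample, path) {
  stopifnot(inherits(sample, "population_sample"))
  utils::write.csv(as.data.frame(sample), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  model <- attr(sample, "model")
  meta <- list(
    model = model[!vapply(model, is.null, logical(1))],
    noise = lapply(attr(sample, "noise"), noise_spec_to_list),
    seed = attr(sample, "seed"),
    t_end = attr(sample, "t_end"),
    track_protein = attr(sample, "track_protein"))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(df, "model") <- do.call(model_spec, meta$model[
      setdiff(names(meta$model), "class")])
    attr(df, "noise") <- lapply(meta$noise, noise_spec_from_list)
    attr(df, "seed") <- meta$seed
    attr(df, "t_end") <- as.numeric(meta$t_end)
    attr(df, "track_protein") <- meta$track_protein
    class(df) <- c("population_sample", "data.frame")
  }
  df
}

config_schema <- list(
  experiment = c("table2", "table3", "table4", "heatmap", "figure2",
                 "generality", "simulate"),
  top = c("experiment", "replicates", "cells", "seed", "scale", "model",
          "params", "noise", "rows", "pair", "mu", "lambda", "delta_p",
          "n_samples", "n_cells", "cases"))

#' Parse and validate an experiment / model configuration file
#'
#' YAML key-value configuration. Recognised top-level keys: `experiment`
#' (one of `table2`, `table3`, `table4`, `heatmap`, `figure2`,
#' `generality`, `simulate`), `replicates`, `cells`, `seed`, `scale`,
#' `model` (fields of [model_spec()]), `params` (fields of
#' [gene_params()]), `noise` (named blocks, each a [noise_spec()] in list
#' form), `rows`, `pair`, `mu`, `lambda`, `delta_p`, `n_samples`,
#' `n_cells`, `cases`. Unknown keys — at the top level, in the model block,
#' and in noise blocks — are rejected with an error naming the key.
#'
#' @param path YAML file path.
#' @return validated list with `model` as a `model_spec`, `params` as
#'   `gene_params` and `noise` as a named list of `noise_spec`s (where
#'   present), plus defaults `replicates = 20`, `cells = 500`, `seed = 1`,
#'   `scale = 1`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (length(bad <- setdiff(names(cfg), config_schema$top))) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$experiment) &&
      !cfg$experiment %in% config_schema$experiment) {
    stop("unknown experiment id: ", cfg$experiment, call. = FALSE)
  }
  if (!is.null(cfg$model)) {
    ok <- names(formals(model_spec))
    if (length(bad <- setdiff(names(cfg$model), ok))) {
      stop("unknown model key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg$model <- do.call(model_spec, cfg$model)
  }
  if (!is.null(cfg$params)) {
    ok <- names(formals(gene_params))
    if (length(bad <- setdiff(names(cfg$params), ok))) {
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg$params <- do.call(gene_params, cfg$params)
  }
  if (!is.null(cfg$noise)) {
    ok <- c(param_order, "Km", "Kp", "delta_m", "delta_p")
    if (length(bad <- setdiff(names(cfg$noise), ok))) {
      stop("noise on unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg$noise <- lapply(cfg$noise, noise_spec_from_list)
  }
  if (!is.null(cfg$rows)) {
    cfg$rows <- lapply(cfg$rows, function(r) {
      if (!is.null(r$kn)) r$kn <- noise_spec_from_list(r$kn)
      if (!is.null(r$mean)) r$mean <- unlist(r$mean)
      r
    })
  }
  cfg$replicates <- cfg$replicates %||% 20L
  cfg$cells <- cfg$cells %||% 500L
  cfg$seed <- cfg$seed %||% 1L
  cfg$scale <- cfg$scale %||% 1
  cfg
}

#' Write a run manifest
#'
#' JSON record written atomically (temp file + rename) alongside every CLI
#' output: command, config path, resolved parameters, seed, package
#' version, timestamps and output paths.
#'
#' @param path manifest path.
#' @param command command / subcommand name.
#' @param config config path or NULL.
#' @param seed integer seed.
#' @param outputs character vector of output paths.
#' @param extra optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = NULL, seed = NULL,
                           outputs = character(), extra = list()) {
  manifest <- c(list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("pathwaynoise")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs), extra)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Write noise-decomposition records as JSON lines
#'
#' @param decomps list of `noise_decomposition` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decompositions <- function(decomps, path) {
  if (inherits(decomps, "noise_decomposition")) decomps <- list(decomps)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (d in decomps) {
    writeLines(jsonlite::toJSON(unclass(d), auto_unbox = TRUE, digits = NA),
               con)
  }
  invisible(path)
}
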