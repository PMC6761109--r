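#' Run configuration
#'
#' Central, validated parameter set for every pipeline operation. Unknown
#' names are rejected so typos never silently fall back to defaults.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `psionic_config`.
#'
#' @details Defaults:
#' * `K = 7` latent regulatory programs (prediction is stable from K = 4
#'   upward; larger K separates tumor types better).
#' * `mu = 0.001` L1 penalty on S, `lambda = 0.001` Frobenius penalty on L.
#' * `lambda_ridge = 0.1` for the single-task ridge baseline.
#' * `n_folds = 10` held-out-gene cross-validation folds.
#' * `flank = 1e5` bp window around the transcription unit for peak-gene
#'   assignment; `promoter_window = 2000` bp around the TSS for the
#'   promoter-only feature filter.
#' * `overlap_frac = 0.75` reciprocal-of-shorter overlap for peak merging.
#' * `min_expressed_frac = 0.5`, `jaccard_threshold = 0.5` TF filters.
#' * `standardize = TRUE` z-scores feature columns before regression.
#' * `pseudocount = 1`, `log_input = FALSE` expression normalization.
#' * `tol = 1e-6`, `max_iter = 200` alternating-minimization convergence.
#' * `seed = 1` base RNG seed.
#' @export
psionic_config <- function(...) {
  defaults <- list(
    K = 7L, mu = 0.001, lambda = 0.001, lambda_ridge = 0.1,
    n_folds = 10L, flank = 1e5, promoter_window = 2000,
    overlap_frac = 0.75, min_expressed_frac = 0.5, jaccard_threshold = 0.5,
    standardize = TRUE, pseudocount = 1, log_input = FALSE,
    tol = 1e-6, max_iter = 200L, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "psionic_config")
}

#' @rdname psionic_config
#' @param path Path to a YAML or JSON file of overrides.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(psionic_config, as.list(vals))
}

validate_config <- function(cfg) {
  check_scalar(cfg$K, "K", lower = 1)
  check_scalar(cfg$mu, "mu", lower = 0)
  check_scalar(cfg$lambda, "lambda", lower = 0)
  check_scalar(cfg$lambda_ridge, "lambda_ridge", lower = 0)
  check_scalar(cfg$n_folds, "n_folds", lower = 2)
  check_scalar(cfg$flank, "flank", lower = 0)
  check_scalar(cfg$promoter_window, "promoter_window", lower = 0)
  if (cfg$overlap_frac <= 0 || cfg$overlap_frac > 1) {
    abort("overlap_frac must be in (0, 1].")
  }
  if (cfg$min_expressed_frac < 0 || cfg$min_expressed_frac > 1) {
    abort("min_expressed_frac must be in [0, 1].")
  }
  if (cfg$jaccard_threshold < 0 || cfg$jaccard_threshold > 1) {
    abort("jaccard_threshold must be in [0, 1].")
  }
  if (!is.logical(cfg$standardize) || !is.logical(cfg$log_input)) {
    abort("standardize and log_input must be logical.")
  }
  check_scalar(cfg$pseudocount, "pseudocount", lower = 0)
  check_scalar(cfg$tol, "tol", lower = 0, allow_zero = FALSE)
  check_scalar(cfg$max_iter, "max_iter", lower = 1)
  check_scalar(cfg$seed, "seed")
  invisible(cfg)
}

#' @export
print.psionic_config <- function(x, ...) {
  cat("<psionic_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
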