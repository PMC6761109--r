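# Model serialization: one self-contained JSON file. Scalar metadata and
# labels are plain JSON (diffable); numeric matrices are base64-encoded
# little-endian IEEE-754 doubles so that load(save(m)) is bit-identical.

MODEL_FORMAT_VERSION <- "1.0"

encode_matrix <- function(m) {
  list(
    dim = dim(m),
    data = jsonlite::base64_enc(writeBin(as.vector(m), raw(),
                                         size = 8L, endian = "little"))
  )
}

encode_vector <- function(v) {
  if (is.null(v)) return(NULL)
  list(names = names(v),
       data = jsonlite::base64_enc(writeBin(unname(v), raw(),
                                            size = 8L, endian = "little")))
}

decode_vector <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  raw <- jsonlite::base64_dec(x$data)
  setNames(readBin(raw, "double", n = length(raw) / 8L,
                   size = 8L, endian = "little"),
           x$names)
}

decode_matrix <- function(x, rownames = NULL, colnames = NULL) {
  raw <- jsonlite::base64_dec(x$data)
  v <- readBin(raw, what = "double", n = length(raw) / 8L,
               size = 8L, endian = "little")
  m <- matrix(v, nrow = x$dim[[1]], ncol = x$dim[[2]])
  dimnames(m) <- list(rownames, colnames)
  m
}

#' Save or load a fitted model
#'
#' Serializes a fitted multitask model ([fit_psionic()]) or single-task ridge
#' baseline ([fit_stl_ridge()]) to a single JSON file. Labels, penalties and
#' fit metadata (iterations, objective trace, seed) are stored as plain JSON;
#' matrices are stored bit-exactly, so reloading reproduces predictions
#' exactly.
#'
#' @param model A `psionic_model` or `psionic_stl` object.
#' @param path Output path (by convention `.psionic.json`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model object.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "psionic_model")) {
    payload <- list(
      format_version = MODEL_FORMAT_VERSION,
      model_class = "psionic_model",
      tf_ids = rownames(model$L),
      sample_ids = colnames(model$S),
      K = ncol(model$L),
      mu = model$mu, lambda = model$lambda,
      iterations = model$iterations,
      objective_trace = model$objective_trace,
      converged = model$converged,
      seed = model$seed,
      L = encode_matrix(model$L),
      S = encode_matrix(model$S),
      center = encode_vector(model$center), scale = encode_vector(model$scale)
    )
  } else if (inherits(model, "psionic_stl")) {
    payload <- list(
      format_version = MODEL_FORMAT_VERSION,
      model_class = "psionic_stl",
      tf_ids = rownames(model$W),
      sample_ids = colnames(model$W),
      lambda_ridge = model$lambda_ridge,
      W = encode_matrix(model$W),
      center = encode_vector(model$center), scale = encode_vector(model$scale)
    )
  } else {
    abort("`model` must be a psionic_model or psionic_stl object.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model file not found: %s", path))
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(sprintf("Cannot parse model file %s (truncated or corrupt): %s",
                                      path, conditionMessage(e)))
  )
  if (is.null(payload$format_version)) abort("Model file has no format_version.")
  if (!identical(as.character(payload$format_version), MODEL_FORMAT_VERSION)) {
    abort(sprintf("Model format version mismatch: file %s, supported %s.",
                  payload$format_version, MODEL_FORMAT_VERSION))
  }
  if (identical(payload$model_class, "psionic_model")) {
    L <- decode_matrix(payload$L, rownames = payload$tf_ids)
    S <- decode_matrix(payload$S, colnames = payload$sample_ids)
    colnames(L) <- paste0("program_", seq_len(ncol(L)))
    rownames(S) <- colnames(L)
    new_psionic_model(
      L = L, S = S, mu = payload$mu, lambda = payload$lambda,
      iterations = payload$iterations,
      objective_trace = as.numeric(payload$objective_trace),
      converged = isTRUE(payload$converged), seed = payload$seed,
      center = decode_vector(payload$center),
      scale = decode_vector(payload$scale)
    )
  } else if (identical(payload$model_class, "psionic_stl")) {
    W <- decode_matrix(payload$W, rownames = payload$tf_ids,
                       colnames = payload$sample_ids)
    new_psionic_stl(
      W = W, lambda_ridge = payload$lambda_ridge,
      center = decode_vector(payload$center),
      scale = decode_vector(payload$scale)
    )
  } else {
    abort(sprintf("Unknown model_class '%s' in %s.", payload$model_class, path))
  }
}
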