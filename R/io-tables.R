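#' Read a gene model table
#'
#' Reads a tab-separated table of gene models with columns `gene_id`, `chrom`,
#' `strand`, `tu_start`, `tu_end` (transcription-unit bounds, 0-based
#' half-open). The strand-aware TSS is derived: `tu_start` on `+`,
#' `tu_end - 1` on `-`.
#'
#' @param path Path to a TSV file with a header row.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `tu_start`,
#'   `tu_end`, `tss`.
#' @export
read_gene_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "strand", "tu_start", "tu_end")
  if (!all(need %in% names(df))) {
    abort(sprintf("Gene table must have columns %s.", paste(need, collapse = ", ")))
  }
  make_gene_models(df$gene_id, df$chrom, df$strand, df$tu_start, df$tu_end)
}

#' Construct a validated gene model table
#'
#' @param gene_id,chrom,strand,tu_start,tu_end Parallel vectors describing
#'   genes; coordinates 0-based half-open, strand `"+"` or `"-"`.
#' @return Tibble of gene models with derived `tss`.
#' @export
make_gene_models <- function(gene_id, chrom, strand, tu_start, tu_end) {
  if (anyDuplicated(gene_id)) abort("Duplicate gene_id in gene table.")
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  if (any(tu_start >= tu_end)) abort("tu_start must be < tu_end for every gene.")
  tibble(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    tu_start = as.numeric(tu_start),
    tu_end = as.numeric(tu_end),
    tss = ifelse(strand == "+", as.numeric(tu_start), as.numeric(tu_end) - 1)
  )
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a TSV whose header row holds sample ids and whose first column holds
#' gene ids. All cells must be numeric and present; duplicate gene ids are an
#' error.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2L) abort("Expression table needs a gene-id column plus >= 1 sample.")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    abort(sprintf("Duplicate gene id in expression table: %s",
                  genes[duplicated(genes)][1L]))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(vals), dimnames = list(genes, colnames(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("Non-numeric or missing value at gene '%s', sample '%s'.",
                  genes[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]))
  }
  num
}

#' Write a labelled numeric matrix as TSV
#'
#' Inverse of [read_expression()] (and used for feature and activity matrices):
#' first column holds row labels under the header `id_col`, remaining columns
#' are the matrix columns. Full `%.17g` precision is used so write/read
#' round-trips are bit-identical.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Header for the row-label column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  check_matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("`mat` must have row and column names.")
  }
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a motif-hit table
#'
#' Reads a FIMO-style TSV with columns `motif_id`, `peak_id`, `score` (and
#' optionally extra columns, ignored). Scores must be nonnegative; an absent
#' (peak, motif) pair means no hit.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `motif_id`, `peak_id`, `score`.
#' @export
read_motif_hits <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("motif_id", "peak_id", "score")
  if (!all(need %in% names(df))) {
    abort(sprintf("Motif-hit table must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  # base-R numeric conversion: correctly rounded, so %.17g text round-trips
  # bit-identically
  hits <- tibble(motif_id = as.character(df$motif_id),
                 peak_id = as.character(df$peak_id),
                 score = as.numeric(df$score))
  check_hits(hits)
  hits
}

#' @rdname read_motif_hits
#' @param hits Tibble of motif hits.
#' @export
write_motif_hits <- function(hits, path) {
  check_hits(hits)
  header <- "motif_id\tpeak_id\tscore"
  body <- sprintf("%s\t%s\t%.17g", hits$motif_id, hits$peak_id, hits$score)
  writeLines(c(header, body), path)
  invisible(path)
}

check_hits <- function(hits, name = "hits") {
  need <- c("motif_id", "peak_id", "score")
  if (!is.data.frame(hits) || !all(need %in% names(hits))) {
    abort(sprintf("`%s` must have columns %s.", name, paste(need, collapse = ", ")))
  }
  if (nrow(hits) > 0L) {
    if (any(!is.finite(hits$score))) abort(sprintf("`%s` has non-finite scores.", name))
    if (any(hits$score < 0)) abort(sprintf("`%s` has negative scores.", name))
    if (anyDuplicated(hits[c("motif_id", "peak_id")])) {
      abort(sprintf("`%s` has duplicate (motif_id, peak_id) pairs.", name))
    }
  }
  invisible(hits)
}

#' Normalize an expression matrix
#'
#' Applies the standard normalization for downstream regression: each sample
#' (column) is log10-transformed with a pseudocount (skipped when the input is
#' already on log scale) and then scaled to unit Euclidean norm.
#'
#' @param raw Gene-by-sample numeric matrix. On linear scale all values must
#'   be nonnegative.
#' @param pseudocount Added before log10 on linear-scale input. Default 1.
#' @param log_input Set `TRUE` when `raw` is already log-scale (e.g. log10
#'   RSEM); the log step is skipped but unit-normalization still applies.
#' @return Matrix of the same shape; every column has Euclidean norm 1.
#' @export
#' @examples
#' m <- matrix(c(9, 99), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' normalize_expression(m)  # (1, 2)/sqrt(5)
normalize_expression <- function(raw, pseudocount = 1, log_input = FALSE) {
  check_matrix(raw)
  check_scalar(pseudocount, "pseudocount", lower = 0)
  x <- raw
  if (!log_input) {
    if (any(x < 0)) abort("Negative values in linear-scale expression input.")
    x <- log10(x + pseudocount)
  }
  nrm <- sqrt(colSums(x^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0L) {
    abort(sprintf("Column '%s' is all zero after transformation; cannot unit-normalize.",
                  colnames(x)[zero[1L]] %||% as.character(zero[1L])))
  }
  sweep(x, 2L, nrm, "/")
}
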