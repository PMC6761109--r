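#' Filter TF motifs by expression of their gene
#'
#' A motif is retained when its TF gene is expressed (value above
#' `expressed_threshold` on the pre-normalization scale) in at least
#' `min_frac` of the samples of at least one tumor-type group.
#'
#' @param motif_ids Character vector of candidate motif ids (e.g.
#'   `colnames(X)`).
#' @param expression Gene-by-sample matrix on the pre-normalization scale.
#' @param tf_to_gene Named character vector mapping motif id -> gene id.
#'   Motifs without a mapping, or mapping to a gene absent from
#'   `expression`, are dropped with a warning.
#' @param type_labels Character/factor vector of tumor-type labels, one per
#'   expression column.
#' @param min_frac Minimum expressed fraction within a group. Default 0.5.
#' @param expressed_threshold Expression value strictly above which a sample
#'   counts as expressing the gene. Default 0.
#' @return Character vector of retained motif ids (input order preserved).
#' @export
filter_tfs_by_expression <- function(motif_ids, expression, tf_to_gene,
                                     type_labels, min_frac = 0.5,
                                     expressed_threshold = 0) {
  check_matrix(expression)
  if (length(type_labels) != ncol(expression)) {
    abort("`type_labels` must have one label per expression column.")
  }
  groups <- split(seq_along(type_labels), as.character(type_labels))
  if (any(lengths(groups) == 0L)) abort("Empty tumor-type group.")
  mapped_gene <- unname(tf_to_gene[motif_ids])
  unmappable <- is.na(mapped_gene) | !(mapped_gene %in% rownames(expression))
  if (any(unmappable)) {
    warn(sprintf("%d motif(s) not mappable to an expression gene; dropped (e.g. %s).",
                 sum(unmappable), paste(head(motif_ids[unmappable], 3L), collapse = ", ")))
  }
  keep_ids <- motif_ids[!unmappable]
  genes <- mapped_gene[!unmappable]
  if (length(keep_ids) == 0L) return(character())
  expressed <- expression[genes, , drop = FALSE] > expressed_threshold
  retained <- vapply(seq_along(keep_ids), function(i) {
    any(vapply(groups, function(idx) mean(expressed[i, idx]) >= min_frac,
               logical(1)))
  }, logical(1))
  keep_ids[retained]
}

#' Remove motifs with redundant target-peak sets
#'
#' Greedy fixpoint removal of redundant motifs: while any retained pair has a
#' Jaccard index above `threshold`, each motif involved in such a pair is
#' scored by its mean Jaccard index against all other retained motifs, and
#' the motif with the largest mean is removed (ties broken by removing the
#' lexicographically smallest motif id among the tied).
#'
#' @param target_sets Named list: motif id -> character vector of target peak
#'   ids. The Jaccard index of an empty set with any set is defined as 0.
#' @param threshold Jaccard index above which a pair counts as redundant.
#'   Default 0.5.
#' @return Character vector of retained motif ids (input order preserved).
#' @export
jaccard_redundancy_filter <- function(target_sets, threshold = 0.5) {
  if (is.null(names(target_sets)) || anyDuplicated(names(target_sets))) {
    abort("`target_sets` must be a uniquely named list.")
  }
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  sets <- lapply(target_sets, function(s) unique(as.character(s)))
  ids <- names(sets)
  jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
  }
  retained <- ids
  repeat {
    n <- length(retained)
    if (n < 2L) break
    J <- matrix(0, n, n, dimnames = list(retained, retained))
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        J[i, j] <- J[j, i] <- jaccard(sets[[retained[i]]], sets[[retained[j]]])
      }
    }
    offending <- which(apply(J > threshold, 1L, any))
    if (length(offending) == 0L) break
    mean_j <- rowSums(J[offending, , drop = FALSE]) / (n - 1L)
    worst <- offending[mean_j == max(mean_j)]
    drop_id <- sort(retained[worst])[1L]
    retained <- setdiff(retained, drop_id)
  }
  ids[ids %in% retained]
}

#' Regulatory locus complexity classes
#'
#' Counts the accessible regions assigned to each gene and labels genes by
#' tertile of the count distribution: boundaries at the 33rd and 66th
#' percentiles, boundary ties going to the lower class. Genes with no
#' assigned peak are included with count 0.
#'
#' @param assignment Peak-gene assignment from [assign_peaks_to_genes()].
#' @param gene_ids Gene universe; defaults to the assignment's `gene_ids`
#'   attribute.
#' @return Tibble with columns `gene_id`, `n_peaks`, `complexity`
#'   (factor low < medium < high).
#' @export
regulatory_complexity <- function(assignment, gene_ids = NULL) {
  gene_ids <- gene_ids %||% attr(assignment, "gene_ids")
  if (is.null(gene_ids)) abort("Supply `gene_ids` (assignment lacks a gene_ids attribute).")
  if (nrow(assignment) == 0L) abort("Empty assignment.")
  counts <- table(factor(assignment$gene_id[!is.na(assignment$gene_id)],
                         levels = gene_ids))
  n_peaks <- as.numeric(counts)
  q <- quantile(n_peaks, c(0.33, 0.66), names = FALSE)
  label <- ifelse(n_peaks <= q[1L], "low",
                  ifelse(n_peaks <= q[2L], "medium", "high"))
  tibble(
    gene_id = gene_ids,
    n_peaks = n_peaks,
    complexity = factor(label, levels = c("low", "medium", "high"))
  )
}
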