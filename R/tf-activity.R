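#' Test TF activities between two sample groups
#'
#' For every TF (row of the activity matrix), compares activity in the
#' labelled group against all remaining samples with a Welch (unequal
#' variance) two-sided t-test; the effect size is the difference of group
#' means. P values are adjusted across TFs by Benjamini-Hochberg FDR.
#'
#' @param W TF-by-sample activity matrix (see [infer_activities()]).
#' @param group Logical vector (or vector coercible to logical) marking the
#'   in-group samples; both groups need >= 2 samples.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble with one row per TF: `tf`, `effect` (mean in-group minus
#'   mean rest), `statistic`, `p_value`, `q_value`, `flag` (`"zero_variance"`
#'   when both groups are constant; such TFs get p = 1).
#' @export
#' @examples
#' W <- rbind(tf1 = c(1, 2, 3, 4, 5, 6))
#' colnames(W) <- paste0("s", 1:6)
#' group_association(W, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
group_association <- function(W, group, var_equal = FALSE) {
  check_matrix(W)
  group <- as.logical(group)
  if (length(group) != ncol(W) || anyNA(group)) {
    abort("`group` must be a logical vector with one value per sample.")
  }
  if (sum(group) < 2L || sum(!group) < 2L) {
    abort("Both groups need at least 2 samples.")
  }
  tfs <- rownames(W) %||% paste0("tf_", seq_len(nrow(W)))
  res <- purrr::map_dfr(seq_len(nrow(W)), function(i) {
    a <- W[i, group]
    b <- W[i, !group]
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble(tf = tfs[i], effect = mean(a) - mean(b),
                    statistic = 0, p_value = 1, flag = "zero_variance"))
    }
    ht <- t.test(a, b, var.equal = var_equal)
    tibble(tf = tfs[i], effect = mean(a) - mean(b),
           statistic = unname(ht$statistic), p_value = ht$p.value,
           flag = NA_character_)
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res[, c("tf", "effect", "statistic", "p_value", "q_value", "flag")]
}

#' One-vs-rest TF association scan across tumor types
#'
#' Runs [group_association()] for every tumor type against all others, ranks
#' TFs by absolute effect size within each comparison, and reports the union
#' of the top `k` TFs per comparison (the set shown in activity-difference
#' heatmaps).
#'
#' @inheritParams group_association
#' @param type_labels Tumor-type label per sample (>= 2 distinct types).
#' @param top_k Number of top TFs per comparison entering the union.
#' @return List with `associations` (tibble of all per-type results, with a
#'   `type` column) and `top_union` (character vector of TF ids).
#' @export
onevsrest_scan <- function(W, type_labels, top_k = 20L, var_equal = FALSE) {
  types <- sort(unique(as.character(type_labels)))
  if (length(types) < 2L) abort("Need >= 2 tumor types.")
  assoc <- purrr::map_dfr(types, function(ty) {
    dplyr::mutate(group_association(W, type_labels == ty, var_equal = var_equal),
                  type = ty, .before = 1L)
  })
  top_union <- assoc |>
    dplyr::group_by(.data$type) |>
    dplyr::slice_max(abs(.data$effect), n = top_k, with_ties = FALSE) |>
    dplyr::pull(.data$tf) |>
    unique() |>
    sort()
  list(associations = assoc, top_union = top_union)
}

#' Hierarchically cluster samples by TF activity
#'
#' Mean-centers each TF (row) of the activity matrix and clusters samples by
#' agglomerative hierarchical clustering, by default with average linkage on
#' correlation distance (1 - Pearson between sample activity vectors).
#'
#' @inheritParams group_association
#' @param distance `"correlation"` (default) or `"euclidean"`. A sample with
#'   constant centered activities has no defined correlation distance and
#'   triggers an error advising euclidean mode.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `hclust` (the tree), `leaf_order` (sample ids in
#'   dendrogram order) and `cut` function-ready labels via
#'   [stats::cutree()].
#' @export
cluster_activities <- function(W, distance = c("correlation", "euclidean"),
                               linkage = "average") {
  check_matrix(W)
  if (ncol(W) < 2L) abort("Need >= 2 samples to cluster.")
  distance <- match.arg(distance)
  if (is.null(colnames(W))) colnames(W) <- paste0("sample_", seq_len(ncol(W)))
  Wc <- W - rowMeans(W)
  d <- if (distance == "correlation") {
    if (any(apply(Wc, 2L, sd) == 0)) {
      abort("Constant sample activity vector: correlation distance undefined; use distance = 'euclidean'.")
    }
    as.dist(1 - cor(Wc))
  } else {
    stats::dist(t(Wc))
  }
  hc <- hclust(d, method = linkage)
  list(hclust = hc, leaf_order = hc$labels[hc$order], distance = distance,
       linkage = linkage)
}

#' Correlate one TF's activity with a phenotype
#'
#' Spearman correlation (average-rank ties) between a TF activity vector and
#' a numeric phenotype (e.g. drug-induced growth inhibition), with a seeded
#' permutation p value alongside the asymptotic one. When the number of
#' permutations requested covers all `n!` orderings the permutation null is
#' enumerated exhaustively, making the p value exact.
#'
#' @param activity Numeric activity vector (one TF across samples).
#' @param phenotype Paired numeric phenotype vector (n >= 3).
#' @param n_perm Permutation budget. Default 10000.
#' @param seed RNG seed for sampled permutations.
#' @return One-row tibble: `rho`, `p_asymptotic`, `p_permutation`, `n`,
#'   `exact` (whether the permutation null was enumerated).
#' @export
activity_phenotype_correlation <- function(activity, phenotype,
                                           n_perm = 10000L, seed = 1L) {
  n <- length(activity)
  if (length(phenotype) != n) abort("Vectors must be paired.")
  if (n < 3L) abort("Need n >= 3 samples.")
  if (sd(activity) == 0 || sd(phenotype) == 0) {
    abort("Constant vector: Spearman correlation undefined.")
  }
  rho <- cor(activity, phenotype, method = "spearman")
  p_asym <- suppressWarnings(
    stats::cor.test(activity, phenotype, method = "spearman")$p.value
  )
  exact <- factorial(n) <= n_perm
  perm_rhos <- if (exact) {
    perms <- all_permutations(n)
    apply(perms, 1L, function(p) cor(activity, phenotype[p], method = "spearman"))
  } else {
    with_seed(seed, vapply(seq_len(n_perm), function(i) {
      cor(activity, sample(phenotype), method = "spearman")
    }, numeric(1)))
  }
  tol <- 1e-12
  p_perm <- if (exact) {
    mean(abs(perm_rhos) >= abs(rho) - tol)
  } else {
    (1 + sum(abs(perm_rhos) >= abs(rho) - tol)) / (n_perm + 1)
  }
  tibble(rho = rho, p_asymptotic = p_asym, p_permutation = p_perm,
         n = n, exact = exact)
}

# All n! permutations of 1:n as rows (n small).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
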