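# Diagnostic plots. All return ggplot objects.

#' Plot per-sample cross-validation performance
#'
#' Per-sample Spearman correlations sorted by performance, one point per
#' sample, optionally colored by tumor type.
#'
#' @param object A `psionic_cv` object (or a list of them to overlay
#'   methods).
#' @param type_labels Optional tumor-type label per sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psionic_cv
#' @export
autoplot.psionic_cv <- function(object, type_labels = NULL, ...) {
  df <- tidy(object)
  if (!is.null(type_labels)) df$type <- type_labels
  df <- dplyr::arrange(df, .data$rho)
  df$rank <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$rho)) +
    ggplot2::geom_point(if (is.null(type_labels)) NULL else
      ggplot2::aes(color = .data$type)) +
    ggplot2::labs(x = "sample (sorted)", y = "Spearman rho",
                  title = sprintf("Held-out-gene CV (%s)", object$method)) +
    ggplot2::theme_minimal()
  p
}

#' Plot the objective trace of a multitask fit
#'
#' @param object A `psionic_model`.
#' @param ... Unused.
#' @return A ggplot object of objective vs outer iteration (non-increasing).
#' @method autoplot psionic_model
#' @export
autoplot.psionic_model <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective_trace) - 1L,
               objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "outer iteration", y = "objective",
                  title = "Alternating-minimization objective trace") +
    ggplot2::theme_minimal()
}

#' Volcano plot of motif enrichment on differential accessibility
#'
#' Effect size (log2 frequency ratio in the top differential peaks) against
#' -log10 Bonferroni-adjusted KS p value, one point per motif and direction.
#'
#' @param enrichment Result of [motif_enrichment()].
#' @param label_top Label this many motifs by largest `-log10(p)`.
#' @return A ggplot object.
#' @export
plot_enrichment_volcano <- function(enrichment, label_top = 10L) {
  df <- dplyr::bind_rows(
    tibble(motif_id = enrichment$motif_id, direction = "open",
           effect = enrichment$effect_up, p_adj = enrichment$p_up_adj),
    tibble(motif_id = enrichment$motif_id, direction = "closed",
           effect = enrichment$effect_down, p_adj = enrichment$p_down_adj)
  )
  df$neglogp <- -log10(pmax(df$p_adj, 1e-300))
  lab <- df |> dplyr::slice_max(.data$neglogp, n = label_top, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(.data$effect, .data$neglogp,
                                   color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$motif_id),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "effect size (log2 frequency ratio)",
                  y = "-log10 adjusted P") +
    ggplot2::theme_minimal()
}

#' Heatmap-style tile plot of TF activities
#'
#' TF-mean-centered activities for the union of top differential TFs, tiles
#' ordered by the sample dendrogram from [cluster_activities()].
#'
#' @param W TF-by-sample activity matrix.
#' @param tfs Subset of TF ids to show (default: all).
#' @param cluster Order samples by hierarchical clustering.
#' @return A ggplot object.
#' @export
plot_activity_heatmap <- function(W, tfs = NULL, cluster = TRUE) {
  check_matrix(W)
  if (!is.null(tfs)) W <- W[tfs, , drop = FALSE]
  Wc <- W - rowMeans(W)
  ord <- if (cluster && ncol(Wc) > 2L) {
    cluster_activities(W, distance = "euclidean")$leaf_order
  } else {
    colnames(Wc)
  }
  df <- as_tibble(as.data.frame.table(Wc, stringsAsFactors = FALSE))
  names(df) <- c("tf", "sample", "activity")
  df$sample <- factor(df$sample, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$tf,
                                   fill = .data$activity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "centered\nactivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
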