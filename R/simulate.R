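#' Simulate a regulatory genome: genes, peak atlas and motif hits
#'
#' Places genes on synthetic chromosomes with non-overlapping transcription
#' units spaced so that their +/- `flank` regulatory windows are disjoint,
#' draws a Poisson number of accessible peaks inside each gene's window,
#' optionally adds decoy peaks in the gaps outside every window, and draws
#' sparse motif hits per (peak, motif) with scores from `score_dist`
#' (defaults to a Uniform(5, 10) resembling -log10 motif-hit p values).
#'
#' @param n_genes,n_tfs Numbers of genes and motifs.
#' @param mean_peaks_per_gene Poisson mean of peaks per gene. Default 5.
#' @param hit_prob Bernoulli probability of a hit per (peak, motif).
#' @param score_dist Function `n -> n` nonnegative scores.
#' @param decoy_frac Decoy peaks as a fraction of gene-window peaks.
#' @param flank Regulatory window half-width (matches
#'   [assign_peaks_to_genes()]). Default 1e5.
#' @param gene_length,genes_per_chrom Layout parameters.
#' @param seed RNG seed; the same seed regenerates the genome bit-identically.
#' @return List with `genes` (gene models), `atlas` (interval tibble, sorted)
#'   and `hits` (motif-hit tibble).
#' @export
simulate_regulatory_genome <- function(n_genes, n_tfs,
                                       mean_peaks_per_gene = 5,
                                       hit_prob = 0.1,
                                       score_dist = function(n) runif(n, 5, 10),
                                       decoy_frac = 0.1,
                                       flank = 1e5,
                                       gene_length = 2e4,
                                       genes_per_chrom = 50L,
                                       seed = 1L) {
  check_scalar(n_genes, "n_genes", lower = 1)
  check_scalar(n_tfs, "n_tfs", lower = 1)
  check_scalar(mean_peaks_per_gene, "mean_peaks_per_gene", lower = 0,
               allow_zero = FALSE)
  if (hit_prob < 0 || hit_prob > 1) abort("hit_prob must be in [0, 1].")
  gap <- 4e4                      # inter-window gap hosting decoys
  spacing <- gene_length + 2 * flank + gap
  with_seed(seed, {
    idx <- seq_len(n_genes)
    chrom <- paste0("chrS", (idx - 1L) %/% genes_per_chrom + 1L)
    within <- (idx - 1L) %% genes_per_chrom
    tu_start <- flank + within * spacing
    tu_end <- tu_start + gene_length
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- make_gene_models(
      gene_id = sprintf("g%04d", idx), chrom = chrom, strand = strand,
      tu_start = tu_start, tu_end = tu_end
    )
    n_peaks <- rpois(n_genes, mean_peaks_per_gene)
    peak_rows <- purrr::map_dfr(idx[n_peaks > 0], function(i) {
      k <- n_peaks[i]
      width <- round(runif(k, 200, 800))
      lo <- genes$tu_start[i] - flank
      hi <- genes$tu_end[i] + flank
      start <- round(runif(k, lo, hi - width))
      tibble(chrom = genes$chrom[i], start = start, end = start + width,
             id = sprintf("pk_%s_%d", genes$gene_id[i], seq_len(k)))
    })
    n_decoy <- round(decoy_frac * nrow(peak_rows))
    if (n_decoy > 0) {
      di <- sample.int(n_genes, n_decoy, replace = TRUE)
      width <- round(runif(n_decoy, 200, 800))
      # the gap [window_end + 1kb, window_end + gap - 1kb] lies outside every window
      lo <- genes$tu_end[di] + flank + 1000
      start <- round(runif(n_decoy, lo, lo + gap - 2000 - width))
      peak_rows <- dplyr::bind_rows(peak_rows, tibble(
        chrom = genes$chrom[di], start = start, end = start + width,
        id = sprintf("pk_decoy_%d", seq_len(n_decoy))
      ))
    }
    atlas <- dplyr::arrange(peak_rows, .data$chrom, .data$start, .data$end)
    if (nrow(atlas) == 0L) abort("No peaks generated; increase mean_peaks_per_gene.")
    motif_ids <- sprintf("M%03d", seq_len(n_tfs))
    hit_mask <- matrix(runif(nrow(atlas) * n_tfs) < hit_prob,
                       nrow(atlas), n_tfs)
    hit_idx <- which(hit_mask, arr.ind = TRUE)
    hits <- tibble(
      motif_id = motif_ids[hit_idx[, 2L]],
      peak_id = atlas$id[hit_idx[, 1L]],
      score = score_dist(nrow(hit_idx))
    )
    hits <- dplyr::arrange(hits, .data$peak_id, .data$motif_id)
    list(genes = genes, atlas = atlas, hits = hits)
  })
}

# Latent-program support for each group. With a shared program, program 1 is
# in every group's support and the remaining slots cycle through the
# group-specific pool 2..K; without, supports cycle over all programs so
# groups can be fully orthogonal.
group_supports <- function(K_true, n_groups, support_size,
                           shared_program = TRUE) {
  if (support_size > K_true) abort("support_size must be <= K_true.")
  lapply(seq_len(n_groups), function(g) {
    if (!shared_program) {
      return(sort(unique(1L + (g - 1L + seq_len(support_size) - 1L) %% K_true)))
    }
    if (support_size == 1L || K_true == 1L) return(1L)
    extra <- 2L + (g - 1L + seq_len(support_size - 1L) - 1L) %% (K_true - 1L)
    sort(unique(c(1L, extra)))
  })
}

#' Simulate an expression cohort with planted latent programs
#'
#' Generates group-structured ground truth on top of a feature matrix:
#' latent programs `L0` (columns drawn from `coef_dist`, unit-normalized),
#' group supports in which program 1 is shared by all groups and the others
#' are group-specific, positive task weights `S0` on each task's group
#' support, and expression `y_t = X L0 s_t + noise` followed by per-sample
#' unit normalization (the same order as the real pipeline). Noise is
#' Gaussian, calibrated per task so that the noise-free signal explains
#' `target_r2` of the variance (or set `sigma` directly).
#'
#' @param X Gene-by-TF feature matrix (e.g. from
#'   [simulate_regulatory_genome()] + [aggregate_motif_scores()]).
#' @param K_true Number of planted latent programs.
#' @param T_ Number of tasks (samples).
#' @param n_groups Number of sample groups; default group sizes are
#'   proportional to (92, 255, 57, 272, 47), the tumor-type proportions the
#'   generator mirrors, scaled to `T_`.
#' @param group_sizes Optional explicit group sizes summing to `T_`.
#' @param support_size Programs per group's support (including the shared
#'   one). Default 2.
#' @param coef_dist Function `n -> n` values for `L0` entries.
#' @param sigma Noise s.d. (scalar, pre-normalization scale); overrides
#'   `target_r2`.
#' @param target_r2 Per-task fraction of variance explained by the planted
#'   signal. Default 0.5.
#' @param shared_program Keep program 1 in every group's support. Set
#'   `FALSE` for orthogonal group programs.
#' @param structure `"grouped"` (latent-program sharing, the default) or
#'   `"independent"` (every task gets its own iid model vector, i.e. no
#'   sharing at all; `K_true`, `n_groups` and `support_size` are ignored).
#' @param seed RNG seed; same seed, same cohort, bit-identical.
#' @return A `psionic_cohort` list: `X`, `Y` (unit-normalized), `L0`, `S0`,
#'   `W0 = L0 S0`, `labels`, `sigma` (per task), `r2` (per-task oracle R2),
#'   `seed`.
#' @export
simulate_cohort <- function(X, K_true = 4L, T_ = 60L, n_groups = 5L,
                            group_sizes = NULL, support_size = 2L,
                            coef_dist = rnorm, sigma = NULL,
                            target_r2 = 0.5, shared_program = TRUE,
                            structure = c("grouped", "independent"),
                            seed = 1L) {
  structure_mode <- match.arg(structure)
  if (structure_mode == "independent") {
    K_true <- T_
    n_groups <- min(n_groups, T_)
  }
  check_matrix(X)
  check_scalar(K_true, "K_true", lower = 1)
  check_scalar(T_, "T_", lower = 1)
  if (!is.null(sigma)) check_scalar(sigma, "sigma", lower = 0)
  d <- ncol(X)
  if (is.null(group_sizes)) {
    prop <- c(92, 255, 57, 272, 47)[seq_len(n_groups)]
    prop <- prop / sum(prop)
    group_sizes <- floor(prop * T_)
    rem <- T_ - sum(group_sizes)
    if (rem > 0) {
      top <- order(prop * T_ - group_sizes, decreasing = TRUE)[seq_len(rem)]
      group_sizes[top] <- group_sizes[top] + 1L
    }
  }
  if (sum(group_sizes) != T_) abort("group_sizes must sum to T_.")
  supports <- group_supports(K_true, n_groups, support_size, shared_program)
  with_seed(seed, {
    L0 <- matrix(coef_dist(d * K_true), d, K_true)
    L0 <- sweep(L0, 2L, sqrt(colSums(L0^2)), "/")
    dimnames(L0) <- list(colnames(X), paste0("program_", seq_len(K_true)))
    labels <- rep(paste0("group_", seq_len(n_groups)), group_sizes)
    S0 <- matrix(0, K_true, T_)
    if (structure_mode == "independent") {
      diag(S0) <- runif(T_, 0.5, 1.5)   # one private program per task
    } else {
      for (t in seq_len(T_)) {
        sup <- supports[[match(labels[t], paste0("group_", seq_len(n_groups)))]]
        S0[sup, t] <- runif(length(sup), 0.5, 1.5)
      }
    }
    sample_ids <- sprintf("s%03d", seq_len(T_))
    dimnames(S0) <- list(colnames(L0), sample_ids)
    signal <- X %*% L0 %*% S0
    sig_sd <- apply(signal, 2L, sd)
    sigma_t <- if (is.null(sigma)) {
      sig_sd * sqrt((1 - target_r2) / target_r2)
    } else {
      rep(sigma, T_)
    }
    noise <- sweep(matrix(rnorm(nrow(X) * T_), nrow(X), T_), 2L, sigma_t, "*")
    Y_raw <- signal + noise
    colnames(Y_raw) <- sample_ids
    rownames(Y_raw) <- rownames(X)
    Y <- normalize_expression(Y_raw, log_input = TRUE)
    r2 <- sig_sd^2 / (sig_sd^2 + sigma_t^2)
    structure(
      list(X = X, Y = Y, L0 = L0, S0 = S0, W0 = L0 %*% S0,
           labels = labels, sigma = sigma_t, r2 = r2, seed = seed,
           supports = supports),
      class = "psionic_cohort"
    )
  })
}

#' @export
print.psionic_cohort <- function(x, ...) {
  cat(sprintf("<psionic_cohort> %d genes x %d TFs, %d samples in %d groups, K_true = %d\n",
              nrow(x$X), ncol(x$X), ncol(x$Y), length(unique(x$labels)),
              ncol(x$L0)))
  cat(sprintf("  mean per-task oracle R2 = %.3f\n", mean(x$r2)))
  invisible(x)
}

#' Default desk-scale synthetic study
#'
#' One call producing the standard benchmark cohort: a simulated regulatory
#' genome (1000 genes, 100 motifs), its gene-by-TF feature matrix through the
#' real assignment/aggregation pipeline, and a planted cohort of 60 samples
#' in 5 groups with K_true = 4 programs at per-task R2 = 0.5.
#'
#' @param seed RNG seed.
#' @param n_genes,n_tfs,T_,K_true,target_r2 Override the defaults.
#' @return A `psionic_cohort`, with the generating `genes`, `atlas`, `hits`
#'   and `assignment` attached as attribute `genome`.
#' @export
simulate_default_study <- function(seed = 1L, n_genes = 1000L, n_tfs = 100L,
                                   T_ = 60L, K_true = 4L, target_r2 = 0.5) {
  genome <- simulate_regulatory_genome(n_genes, n_tfs, seed = derive_seed(seed, 1L))
  assignment <- assign_peaks_to_genes(genome$atlas, genome$genes)
  X <- aggregate_motif_scores(assignment, genome$hits,
                              motif_ids = sort(unique(genome$hits$motif_id)))
  cohort <- simulate_cohort(X, K_true = K_true, T_ = T_,
                            target_r2 = target_r2,
                            seed = derive_seed(seed, 2L))
  attr(cohort, "genome") <- c(genome, list(assignment = assignment))
  cohort
}

#' Compare a fitted model against planted ground truth
#'
#' Reports per-task Pearson correlation between fitted and true activity
#' vectors (on the original feature scale: fitted activities are mapped back
#' through the model's stored standardization) and matched-program
#' correlations, where fitted and true latent programs are paired by the
#' assignment maximizing total absolute correlation (signs are a gauge
#' freedom of the factorization, so absolute values are compared).
#'
#' @param model A fitted `psionic_model`.
#' @param cohort The `psionic_cohort` the model was fitted on.
#' @return List: `task_cor` (tibble `sample`, `cor`), `program_cor` (tibble
#'   `program_fit`, `program_true`, `abs_cor`), `mean_task_cor`,
#'   `mean_program_cor`.
#' @export
recovery_report <- function(model, cohort) {
  if (!inherits(model, "psionic_model")) abort("`model` must be a psionic_model.")
  W_fit <- infer_activities(model)
  L_fit <- model$L
  if (!is.null(model$scale)) {
    W_fit <- W_fit / model$scale
    L_fit <- L_fit / model$scale
  }
  tfs <- intersect(rownames(W_fit), rownames(cohort$W0))
  W_fit <- W_fit[tfs, , drop = FALSE]
  W0 <- cohort$W0[tfs, , drop = FALSE]
  task_cor <- vapply(seq_len(ncol(W0)), function(t) {
    if (sd(W_fit[, t]) == 0 || sd(W0[, t]) == 0) return(0)
    cor(W_fit[, t], W0[, t])
  }, numeric(1))
  C <- suppressWarnings(cor(L_fit[tfs, , drop = FALSE],
                            cohort$L0[tfs, , drop = FALSE]))
  C[!is.finite(C)] <- 0
  mt <- match_programs(abs(C))
  program_cor <- tibble(
    program_fit = colnames(L_fit)[mt$rows] %||% paste0("program_", mt$rows),
    program_true = colnames(cohort$L0)[mt$cols],
    abs_cor = abs(C)[cbind(mt$rows, mt$cols)]
  )
  list(
    task_cor = tibble(sample = colnames(W0), cor = task_cor),
    program_cor = program_cor,
    mean_task_cor = mean(task_cor),
    mean_program_cor = mean(program_cor$abs_cor)
  )
}

# Maximize the total score over one-to-one row/column assignments by
# enumerating permutations (K <= 8 in practice).
match_programs <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  k <- min(nr, nc)
  if (max(nr, nc) > 8L) {                       # greedy fallback
    rows <- integer(0); cols <- integer(0)
    s <- score
    for (i in seq_len(k)) {
      best <- which(s == max(s), arr.ind = TRUE)[1L, ]
      rows <- c(rows, best[1L]); cols <- c(cols, best[2L])
      s[best[1L], ] <- -Inf; s[, best[2L]] <- -Inf
    }
    return(list(rows = rows, cols = cols))
  }
  if (nr <= nc) {
    perms <- all_permutations(nc)
    best_val <- -Inf; best_perm <- NULL
    for (i in seq_len(nrow(perms))) {
      p <- perms[i, seq_len(k)]
      v <- sum(score[cbind(seq_len(k), p)])
      if (v > best_val) { best_val <- v; best_perm <- p }
    }
    list(rows = seq_len(k), cols = best_perm)
  } else {
    m <- match_programs(t(score))
    list(rows = m$cols, cols = m$rows)
  }
}
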