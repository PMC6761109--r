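#' Split genes into cross-validation folds
#'
#' Seeded permutation split of the gene set into `n_folds` folds whose sizes
#' differ by at most one. Folds split genes (not samples): models trained on
#' training-fold genes predict held-out genes in every sample. Reuse one fold
#' assignment across all compared methods.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_folds Number of folds (<= number of genes). Default 10.
#' @param seed RNG seed.
#' @return Named integer vector mapping gene id -> fold in `1:n_folds`.
#' @export
make_gene_folds <- function(gene_ids, n_folds = 10L, seed = 1L) {
  n <- length(gene_ids)
  if (n_folds > n) abort("`n_folds` exceeds the number of genes.")
  folds <- integer(n)
  folds[with_seed(seed, sample.int(n))] <- rep(seq_len(n_folds), length.out = n)
  setNames(folds, gene_ids)
}

#' Held-out-gene cross-validation
#'
#' For each fold, a model is fitted on the training-fold genes only (feature
#' standardization included, so no test information leaks) and used to
#' predict expression of the held-out genes. Predictions are pooled across
#' folds and scored per sample by Spearman correlation with the measured
#' expression.
#'
#' @param X Gene-by-TF feature matrix.
#' @param Y Gene-by-sample expression matrix (rows aligned with `X`).
#' @param method `"psionic"` (multitask) or `"stl"` (per-sample ridge).
#' @param folds Fold assignment from [make_gene_folds()] (one integer per
#'   gene row).
#' @param K,mu,lambda,lambda_ridge,tol,max_iter,standardize Passed to the
#'   fitting routine (see [fit_psionic()] / [fit_stl_ridge()]).
#' @param seed Seed recorded in the result and used for fit initialization.
#' @param return_models Keep the per-fold fitted models (for diagnostics).
#' @return A `psionic_cv` object: `rho` (tibble `sample`, `rho`), the pooled
#'   `predictions` matrix, `folds`, `method`, `seed`, and optionally
#'   `models`. `glance()` gives the mean/s.d./s.e. of rho across samples.
#' @export
crossvalidate <- function(X, Y, method = c("psionic", "stl"), folds,
                          K = 7, mu = 0.001, lambda = 0.001, lambda_ridge = 0.1,
                          tol = 1e-6, max_iter = 200L, standardize = TRUE,
                          seed = 1L, return_models = FALSE) {
  method <- match.arg(method)
  check_matrix(X); check_matrix(Y)
  if (length(folds) != nrow(X)) abort("`folds` must assign every gene row.")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sample_", seq_len(ncol(Y)))
  pred <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  models <- list()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    te <- !tr
    model <- if (method == "psionic") {
      fit_psionic(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], K = K,
                  mu = mu, lambda = lambda, lambda_ridge = lambda_ridge,
                  tol = tol, max_iter = max_iter, seed = derive_seed(seed, f),
                  standardize = standardize)
    } else {
      fit_stl_ridge(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                    lambda_ridge = lambda_ridge, standardize = standardize)
    }
    pred[te, ] <- predict(model, X[te, , drop = FALSE])
    if (return_models) models[[as.character(f)]] <- model
  }
  rho <- vapply(seq_len(ncol(Y)), function(t) {
    p <- pred[, t]
    if (sd(p) == 0) {
      warn(sprintf("Constant prediction for sample '%s'; rho recorded as 0.",
                   colnames(Y)[t]))
      return(0)
    }
    cor(p, Y[, t], method = "spearman")
  }, numeric(1))
  structure(
    list(rho = tibble(sample = colnames(Y), rho = rho),
         predictions = pred, folds = folds, method = method, seed = seed,
         models = if (return_models) models else NULL),
    class = "psionic_cv"
  )
}

#' @export
print.psionic_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<psionic_cv> method = %s, %d samples, %d folds\n",
              x$method, nrow(x$rho), length(unique(x$folds))))
  cat(sprintf("  mean Spearman rho = %.3f +/- %.3f (s.d.; s.e. %.3f)\n",
              g$mean_rho, g$sd_rho, g$se_rho))
  invisible(x)
}

#' @rdname crossvalidate
#' @param x A `psionic_cv` object.
#' @param ... Unused.
#' @method glance psionic_cv
#' @export
glance.psionic_cv <- function(x, ...) {
  r <- x$rho$rho
  tibble(method = x$method, n_samples = length(r),
         mean_rho = mean(r), sd_rho = sd(r), se_rho = sd(r) / sqrt(length(r)))
}

#' @rdname crossvalidate
#' @method tidy psionic_cv
#' @export
tidy.psionic_cv <- function(x, ...) {
  dplyr::mutate(x$rho, method = x$method)
}

#' Compare two methods by paired one-sided Wilcoxon signed-rank test
#'
#' Tests whether method A's per-sample correlations exceed method B's
#' (alternative: A > B). The exact null distribution is used for n <= 25
#' untied pairs, the normal approximation with continuity correction
#' otherwise.
#'
#' @param rho_A,rho_B Paired numeric vectors (per-sample correlations).
#' @return One-row tibble: `statistic` (V), `p_value`, `n`, `n_nonzero`.
#' @export
compare_methods <- function(rho_A, rho_B) {
  if (length(rho_A) != length(rho_B)) abort("Inputs must be paired (equal length).")
  d <- rho_A - rho_B
  n_all <- length(d)
  d <- d[d != 0]                 # zeros drop out of the signed-rank test
  if (length(d) == 0L) {
    warn("All paired differences are zero; p = 1.")
    return(tibble(statistic = 0, p_value = 1, n = n_all, n_nonzero = 0L))
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  p <- if (n <= 25L) {
    # exact tail P(V >= v_obs) under random sign flips, by dynamic
    # programming over doubled (hence integer) average ranks; valid with ties
    w <- as.integer(round(2 * r))
    f <- 1
    for (wi in w) {
      g <- c(f, rep(0, wi))
      idx <- seq.int(wi + 1L, wi + length(f))
      g[idx] <- g[idx] + f
      f <- g
    }
    sum(f[seq.int(as.integer(round(2 * v_obs)) + 1L, length(f))]) / 2^n
  } else {
    ht <- suppressWarnings(
      wilcox.test(d, alternative = "greater", mu = 0,
                  exact = FALSE, correct = TRUE)
    )
    ht$p.value
  }
  tibble(statistic = v_obs, p_value = p, n = n_all, n_nonzero = n)
}

#' Scan the number of latent programs
#'
#' For each candidate K, runs held-out-gene cross-validation (prediction
#' performance) and fits a full model whose activity matrix W is scored for
#' tumor-type separation by the mean silhouette width of samples, using
#' correlation distance on TF-mean-centered activities. The silhouette is a
#' proxy for how well K separates known subtypes; prediction tends to
#' plateau at moderate K while separation keeps improving.
#'
#' @inheritParams crossvalidate
#' @param K_values Integer vector of K values to scan.
#' @param type_labels Tumor-type label per sample (>= 2 distinct values
#'   required for the separation score, otherwise `NA`).
#' @return Tibble with columns `K`, `mean_rho`, `sd_rho`, `silhouette`.
#' @export
scan_K <- function(X, Y, K_values, folds, type_labels,
                   mu = 0.001, lambda = 0.001, lambda_ridge = 0.1,
                   tol = 1e-6, max_iter = 200L, seed = 1L) {
  if (any(K_values < 1)) abort("K_values must be >= 1.")
  purrr::map_dfr(K_values, function(k) {
    cv <- crossvalidate(X, Y, method = "psionic", folds = folds, K = k,
                        mu = mu, lambda = lambda, lambda_ridge = lambda_ridge,
                        tol = tol, max_iter = max_iter, seed = seed)
    fit <- fit_psionic(X, Y, K = k, mu = mu, lambda = lambda,
                       lambda_ridge = lambda_ridge, tol = tol,
                       max_iter = max_iter, seed = seed)
    W <- infer_activities(fit)
    sil <- if (length(unique(type_labels)) < 2L) {
      NA_real_
    } else {
      Wc <- W - rowMeans(W)
      dmat <- as.dist(1 - suppressWarnings(cor(Wc)))
      dmat[!is.finite(dmat)] <- 2
      mean(cluster::silhouette(as.integer(factor(type_labels)), dmat)[, "sil_width"])
    }
    g <- glance(cv)
    tibble(K = k, mean_rho = g$mean_rho, sd_rho = g$sd_rho, silhouette = sil)
  })
}

#' Select penalties by inner held-out-gene validation
#'
#' Grid search over (mu, lambda): a seeded fraction of the genes is held out
#' for validation, models are fitted on the rest, and the pair with the best
#' mean per-sample Spearman correlation on the validation genes wins (ties
#' go to the smaller penalties). Intended to run inside a training fold so
#' that selection never sees test genes.
#'
#' @inheritParams crossvalidate
#' @param mu_grid,lambda_grid Candidate penalty values (log-spaced grids by
#'   default).
#' @param val_frac Fraction of genes held out for validation. Default 0.2.
#' @return List with `mu`, `lambda` and the full `grid` tibble.
#' @export
select_hyperparams <- function(X, Y, K = 7,
                               mu_grid = 10^seq(-4, 0, by = 1),
                               lambda_grid = 10^seq(-4, 0, by = 1),
                               val_frac = 0.2, lambda_ridge = 0.1,
                               tol = 1e-6, max_iter = 200L, seed = 1L) {
  n <- nrow(X)
  n_val <- max(1L, round(val_frac * n))
  val <- with_seed(derive_seed(seed, 97L), sample.int(n, n_val))
  tr <- setdiff(seq_len(n), val)
  grid <- tidyr::expand_grid(mu = sort(mu_grid), lambda = sort(lambda_grid))
  grid$mean_rho <- purrr::map2_dbl(grid$mu, grid$lambda, function(m, l) {
    fit <- fit_psionic(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], K = K,
                       mu = m, lambda = l, lambda_ridge = lambda_ridge,
                       tol = tol, max_iter = max_iter, seed = seed)
    pred <- predict(fit, X[val, , drop = FALSE])
    mean(vapply(seq_len(ncol(Y)), function(t) {
      if (sd(pred[, t]) == 0) return(0)
      cor(pred[, t], Y[val, t], method = "spearman")
    }, numeric(1)))
  })
  best <- grid[order(-grid$mean_rho, grid$mu, grid$lambda), ][1L, ]
  list(mu = best$mu, lambda = best$lambda, grid = grid)
}
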