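new_psionic_model <- function(L, S, mu, lambda, iterations, objective_trace,
                              converged, seed, center = NULL, scale = NULL,
                              dropped_tfs = character()) {
  structure(
    list(L = L, S = S, mu = mu, lambda = lambda, iterations = iterations,
         objective_trace = objective_trace, converged = converged,
         seed = seed, center = center, scale = scale,
         dropped_tfs = dropped_tfs),
    class = "psionic_model"
  )
}

new_psionic_stl <- function(W, lambda_ridge, center = NULL, scale = NULL,
                            dropped_tfs = character()) {
  structure(
    list(W = W, lambda_ridge = lambda_ridge, center = center, scale = scale,
         dropped_tfs = dropped_tfs),
    class = "psionic_stl"
  )
}

#' Multitask objective value
#'
#' The joint learning cost: per-task mean squared error of the reconstruction
#' `X L s_t` against `y_t`, plus an L1 penalty on the task weight matrix S
#' (controls how many latent programs each sample uses) and a squared
#' Frobenius penalty on the latent program matrix L (keeps predictor weights
#' small):
#' \deqn{\sum_t \frac{1}{N}\|y_t - X L s_t\|^2 + \mu \|S\|_1 + \lambda \|L\|_F^2}
#'
#' @param L TF-by-K latent program matrix.
#' @param S K-by-T task weight matrix.
#' @param X N-by-TF feature matrix.
#' @param Y N-by-T expression matrix.
#' @param mu L1 penalty weight on S (>= 0).
#' @param lambda Frobenius penalty weight on L (>= 0).
#' @return Scalar objective value.
#' @export
psionic_objective <- function(L, S, X, Y, mu, lambda) {
  check_matrix(L); check_matrix(S); check_matrix(X); check_matrix(Y)
  check_scalar(mu, "mu", lower = 0)
  check_scalar(lambda, "lambda", lower = 0)
  N <- nrow(X)
  if (ncol(X) != nrow(L) || ncol(L) != nrow(S) ||
      nrow(Y) != N || ncol(Y) != ncol(S)) {
    abort("Inconsistent shapes: need X (N x d), L (d x K), S (K x T), Y (N x T).")
  }
  R <- Y - X %*% L %*% S
  sum(R * R) / N + mu * l1norm(S) + lambda * fnorm2(L)
}

#' S-step: sparse coding of each task on the latent programs
#'
#' With L fixed, each task decouples into an independent lasso problem
#' `min_s (1/N) ||y_t - (X L) s||^2 + mu ||s||_1`, solved by cyclic
#' coordinate descent to a KKT tolerance. Deterministic given its inputs.
#'
#' @inheritParams psionic_objective
#' @param S_init Optional warm-start K-by-T matrix (defaults to zeros).
#' @param tol Convergence tolerance on the largest coordinate change.
#' @param max_iter Maximum coordinate-descent sweeps per task.
#' @return K-by-T matrix S.
#' @export
update_S <- function(L, X, Y, mu, S_init = NULL, tol = 1e-12, max_iter = 10000L) {
  check_scalar(mu, "mu", lower = 0)
  N <- nrow(X)
  K <- ncol(L)
  T_ <- ncol(Y)
  Z <- X %*% L
  G <- crossprod(Z)              # K x K
  C <- crossprod(Z, Y)           # K x T
  thr <- mu * N / 2
  if (mu == 0) {
    qz <- qr(Z)
    if (qz$rank == K) {            # unpenalized case: exact least squares
      S <- qr.coef(qz, Y)
      dimnames(S) <- list(colnames(L), colnames(Y))
      return(S)
    }
  }
  S <- S_init %||% matrix(0, K, T_)
  for (t in seq_len(T_)) {
    s <- S[, t]
    c_t <- C[, t]
    for (iter in seq_len(max_iter)) {
      delta <- 0
      for (j in seq_len(K)) {
        r_j <- c_t[j] - sum(G[j, ] * s) + G[j, j] * s[j]
        s_new <- if (G[j, j] > 0) soft_threshold(r_j, thr) / G[j, j] else 0
        delta <- max(delta, abs(s_new - s[j]))
        s[j] <- s_new
      }
      if (delta < tol) break
    }
    S[, t] <- s
  }
  dimnames(S) <- list(colnames(L), colnames(Y))
  S
}

#' L-step: exact ridge update of the latent programs
#'
#' With S fixed, the objective is quadratic in L with stationarity condition
#' `(X'X/N) L (S S') + lambda L = (X'Y/N) S'`. This two-sided linear system is
#' solved exactly by diagonalizing the two symmetric matrices (a Sylvester
#' solve), avoiding the dK x dK Kronecker system while returning the same
#' minimizer.
#'
#' @inheritParams psionic_objective
#' @param XtX_n,XtY_n Optional precomputed `crossprod(X)/N` and
#'   `crossprod(X, Y)/N` (cached across iterations by [fit_psionic()]).
#' @return d-by-K matrix L.
#' @export
update_L <- function(S, X, Y, lambda, XtX_n = NULL, XtY_n = NULL) {
  check_scalar(lambda, "lambda", lower = 0)
  N <- nrow(X)
  A <- XtX_n %||% (crossprod(X) / N)
  Cfull <- XtY_n %||% (crossprod(X, Y) / N)
  B <- tcrossprod(S)             # K x K
  C <- Cfull %*% t(S)            # d x K
  eigA <- eigen(A, symmetric = TRUE)
  eigB <- eigen(B, symmetric = TRUE)
  denom <- outer(pmax(eigA$values, 0), pmax(eigB$values, 0)) + lambda
  if (any(denom < 1e-14)) {
    abort("L-step system is rank deficient; use lambda > 0.")
  }
  M <- crossprod(eigA$vectors, C) %*% eigB$vectors
  L <- eigA$vectors %*% (M / denom) %*% t(eigB$vectors)
  dimnames(L) <- list(colnames(X), rownames(S))
  L
}

#' Initialize the latent factorization from single-task ridge
#'
#' Fits the per-task ridge baseline, takes the thin SVD of its coefficient
#' matrix `W_stl = U D V'`, and splits the top-K part symmetrically:
#' `L = U_K D_K^{1/2}`, `S = D_K^{1/2} V_K'`. With K at the rank of `W_stl`
#' this reproduces it exactly; for smaller K it is the best rank-K
#' approximation.
#'
#' @inheritParams psionic_objective
#' @param lambda_ridge Ridge penalty for the initializing single-task fit.
#' @param K Number of latent programs.
#' @return List with elements `L` (d x K) and `S` (K x T).
#' @export
init_from_stl <- function(X, Y, lambda_ridge, K) {
  d <- ncol(X)
  T_ <- ncol(Y)
  if (K > min(d, T_)) abort("K must be <= min(n_features, n_tasks) for SVD init.")
  W <- fit_stl_ridge(X, Y, lambda_ridge, standardize = FALSE)$W
  sv <- svd(W)
  r <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-12)
  if (K > r) {
    warn(sprintf("K = %d exceeds the rank (%d) of the initializer; padding with zeros.",
                 K, r))
  }
  k_use <- min(K, r)
  sq <- sqrt(sv$d[seq_len(k_use)])
  L <- matrix(0, d, K)
  S <- matrix(0, K, T_)
  L[, seq_len(k_use)] <- sv$u[, seq_len(k_use), drop = FALSE] %*% diag(sq, k_use)
  S[seq_len(k_use), ] <- diag(sq, k_use) %*% t(sv$v[, seq_len(k_use), drop = FALSE])
  dimnames(L) <- list(colnames(X), paste0("program_", seq_len(K)))
  dimnames(S) <- list(colnames(L), colnames(Y))
  list(L = L, S = S)
}

#' Single-task ridge baseline
#'
#' Fits an independent ridge regression for every sample:
#' `w_t = argmin (1/N)||y_t - X w||^2 + lambda_ridge ||w||^2`, in closed form
#' `(X'X/N + lambda I)^{-1} X'y_t / N`.
#'
#' @inheritParams psionic_objective
#' @param lambda_ridge Ridge penalty (>= 0; 0 requires full-rank `X'X`).
#' @param standardize Z-score feature columns first (zero-variance columns
#'   are dropped with a warning).
#' @return A `psionic_stl` object with coefficient matrix `W` (TF x sample).
#' @export
fit_stl_ridge <- function(X, Y, lambda_ridge = 0.1, standardize = TRUE) {
  check_matrix(X); check_matrix(Y)
  check_scalar(lambda_ridge, "lambda_ridge", lower = 0)
  if (nrow(X) != nrow(Y)) abort("X and Y must share gene rows.")
  prep <- prep_features(X, standardize)
  Xs <- prep$X
  N <- nrow(Xs)
  M <- crossprod(Xs) / N + diag(lambda_ridge, ncol(Xs))
  W <- tryCatch(
    solve(M, crossprod(Xs, Y) / N),
    error = function(e) abort(paste0(
      "Ridge system is singular (lambda_ridge = 0 with rank-deficient X'X): ",
      conditionMessage(e)))
  )
  dimnames(W) <- list(colnames(Xs), colnames(Y))
  new_psionic_stl(W, lambda_ridge, center = prep$center, scale = prep$scale,
                  dropped_tfs = prep$dropped)
}

# Drop zero-variance columns; optionally z-score. Returns processed X plus
# the transform so it can be replayed on new data.
prep_features <- function(X, standardize) {
  if (is.null(colnames(X))) colnames(X) <- paste0("tf_", seq_len(ncol(X)))
  sds <- apply(X, 2L, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0L) {
    warn(sprintf("Dropping %d zero-variance feature column(s): %s",
                 length(dropped), paste(head(dropped, 3L), collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (standardize) {
    ctr <- colMeans(X)
    X <- sweep(sweep(X, 2L, ctr, "-"), 2L, sds, "/")
    list(X = X, center = ctr, scale = sds, dropped = dropped)
  } else {
    list(X = X, center = NULL, scale = NULL, dropped = dropped)
  }
}

apply_prep <- function(X_new, model) {
  tf_ids <- rownames(model$L) %||% rownames(model$W)
  missing <- setdiff(tf_ids, colnames(X_new))
  if (length(missing) > 0L) {
    abort(sprintf("X_new lacks model TF column(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  X <- X_new[, tf_ids, drop = FALSE]
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2L, model$center[tf_ids], "-"), 2L,
               model$scale[tf_ids], "/")
  }
  X
}

#' Fit the multitask latent-program model
#'
#' Alternating minimization of [psionic_objective()]: the S-step solves a
#' lasso per task ([update_S()]), the L-step is an exact ridge solve
#' ([update_L()]). Both steps decrease the objective, so the recorded trace
#' is non-increasing; the fit stops when the relative objective change drops
#' below `tol` or after `max_iter` outer iterations.
#'
#' @inheritParams psionic_objective
#' @param K Number of latent regulatory programs (clamped to
#'   `min(n_features, n_tasks)` with a warning).
#' @param init `"stl"` (SVD of the single-task ridge solution, the default)
#'   or `"random"` (seeded Gaussian).
#' @param lambda_ridge Ridge penalty used by the `"stl"` initializer.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum outer iterations.
#' @param seed RNG seed (only consumed by random initialization, but recorded
#'   always).
#' @param standardize Z-score feature columns before fitting; the transform
#'   is stored in the model and replayed by [predict()].
#' @return A `psionic_model` with components `L`, `S`, penalties, the
#'   objective trace and fit metadata. TF activities are `L %*% S`
#'   ([infer_activities()]).
#' @export
fit_psionic <- function(X, Y, K = 7, mu = 0.001, lambda = 0.001,
                        init = c("stl", "random"), lambda_ridge = 0.1,
                        tol = 1e-6, max_iter = 200L, seed = 1L,
                        standardize = TRUE) {
  check_matrix(X); check_matrix(Y)
  check_scalar(K, "K", lower = 1)
  check_scalar(mu, "mu", lower = 0)
  check_scalar(lambda, "lambda", lower = 0)
  init <- match.arg(init)
  if (nrow(X) != nrow(Y)) abort("X and Y must share gene rows.")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sample_", seq_len(ncol(Y)))
  prep <- prep_features(X, standardize)
  Xs <- prep$X
  d <- ncol(Xs); T_ <- ncol(Y); N <- nrow(Xs)
  if (K > min(d, T_)) {
    warn(sprintf("K = %d exceeds min(n_features, n_tasks) = %d; clamping.",
                 K, min(d, T_)))
    K <- min(d, T_)
  }
  K <- as.integer(K)
  if (init == "stl") {
    ini <- init_from_stl(Xs, Y, lambda_ridge, K)
    L <- ini$L; S <- ini$S
  } else {
    L <- with_seed(seed, matrix(rnorm(d * K, sd = 0.1), d, K))
    dimnames(L) <- list(colnames(Xs), paste0("program_", seq_len(K)))
    S <- matrix(0, K, T_, dimnames = list(colnames(L), colnames(Y)))
  }
  XtX_n <- crossprod(Xs) / N
  XtY_n <- crossprod(Xs, Y) / N
  trace <- psionic_objective(L, S, Xs, Y, mu, lambda)
  n_increase <- 0L
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    S <- update_S(L, Xs, Y, mu, S_init = S)
    L <- update_L(S, Xs, Y, lambda, XtX_n = XtX_n, XtY_n = XtY_n)
    obj <- psionic_objective(L, S, Xs, Y, mu, lambda)
    prev <- trace[length(trace)]
    if (obj > prev * (1 + 1e-8) + 1e-300) {
      n_increase <- n_increase + 1L
      if (n_increase >= 2L) {
        abort(sprintf("Objective increased twice (iteration %d): solver defect.", it))
      }
    }
    trace <- c(trace, obj)
    iterations <- it
    if (abs(prev - obj) < tol * max(prev, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  new_psionic_model(L = L, S = S, mu = mu, lambda = lambda,
                    iterations = iterations, objective_trace = trace,
                    converged = converged, seed = seed,
                    center = prep$center, scale = prep$scale,
                    dropped_tfs = prep$dropped)
}

#' Predict expression from a fitted model
#'
#' Applies the model's stored feature transform to `X_new` (columns matched
#' by TF label; a mismatch is an error naming the offending TFs) and returns
#' `X L S` (multitask) or `X W` (single-task).
#'
#' @param object A `psionic_model` or `psionic_stl`.
#' @param X_new Gene-by-TF feature matrix.
#' @param ... Unused.
#' @return Gene-by-sample matrix of predicted expression.
#' @export
predict.psionic_model <- function(object, X_new, ...) {
  X <- apply_prep(X_new, object)
  out <- X %*% object$L %*% object$S
  rownames(out) <- rownames(X_new)
  out
}

#' @rdname predict.psionic_model
#' @export
predict.psionic_stl <- function(object, X_new, ...) {
  X <- apply_prep(X_new, object)
  out <- X %*% object$W
  rownames(out) <- rownames(X_new)
  out
}

#' Inferred TF activities
#'
#' The TF-by-sample activity matrix `W = L S` (or the ridge coefficients for
#' the single-task baseline): each column is a sample's regulatory model,
#' each entry the inferred influence of one TF on that sample's expression.
#'
#' @param model A fitted `psionic_model` or `psionic_stl`.
#' @return Numeric TF-by-sample matrix.
#' @export
infer_activities <- function(model) {
  if (inherits(model, "psionic_model")) {
    model$L %*% model$S
  } else if (inherits(model, "psionic_stl")) {
    model$W
  } else {
    abort("`model` must be a psionic_model or psionic_stl.")
  }
}

#' @export
print.psionic_model <- function(x, ...) {
  cat(sprintf("<psionic_model> %d TFs x %d samples, K = %d programs\n",
              nrow(x$L), ncol(x$S), ncol(x$L)))
  cat(sprintf("  mu = %g, lambda = %g; %d iterations (%s); objective %.6g\n",
              x$mu, x$lambda, x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              tail(x$objective_trace, 1L)))
  cat(sprintf("  nonzero S entries: %d / %d\n",
              sum(x$S != 0), length(x$S)))
  invisible(x)
}

#' @export
print.psionic_stl <- function(x, ...) {
  cat(sprintf("<psionic_stl> %d TFs x %d samples, lambda_ridge = %g\n",
              nrow(x$W), ncol(x$W), x$lambda_ridge))
  invisible(x)
}

#' Tidy a fitted model into a long activity table
#'
#' @param x A `psionic_model` or `psionic_stl`.
#' @param matrix Which component to tidy: `"W"` (activities, default), `"L"`
#'   (latent programs) or `"S"` (task weights). The single-task baseline only
#'   has `"W"`.
#' @param ... Unused.
#' @return A long tibble (`tf`/`program`, `sample`, `value` columns as
#'   appropriate).
#' @method tidy psionic_model
#' @export
tidy.psionic_model <- function(x, matrix = c("W", "L", "S"), ...) {
  matrix <- match.arg(matrix)
  m <- switch(matrix, W = infer_activities(x), L = x$L, S = x$S)
  long <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE))
  names(long) <- switch(matrix,
                        W = c("tf", "sample", "activity"),
                        L = c("tf", "program", "weight"),
                        S = c("program", "sample", "weight"))
  long
}

#' @rdname tidy.psionic_model
#' @method tidy psionic_stl
#' @export
tidy.psionic_stl <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$W, stringsAsFactors = FALSE))
  names(long) <- c("tf", "sample", "activity")
  long
}

#' One-row fit summary
#'
#' @param x A `psionic_model` or `psionic_stl`.
#' @param ... Unused.
#' @return One-row tibble of fit metadata.
#' @method glance psionic_model
#' @export
glance.psionic_model <- function(x, ...) {
  tibble(
    n_tfs = nrow(x$L), n_samples = ncol(x$S), K = ncol(x$L),
    mu = x$mu, lambda = x$lambda,
    iterations = x$iterations, converged = x$converged,
    objective = tail(x$objective_trace, 1L),
    s_nonzero_frac = mean(x$S != 0)
  )
}

#' @rdname glance.psionic_model
#' @method glance psionic_stl
#' @export
glance.psionic_stl <- function(x, ...) {
  tibble(n_tfs = nrow(x$W), n_samples = ncol(x$W),
         lambda_ridge = x$lambda_ridge)
}
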