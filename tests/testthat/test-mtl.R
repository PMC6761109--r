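test_that("objective matches unit-column and exact-fit arithmetic", {
  N <- 10; T_ <- 2; d <- 3; K <- 2
  Y <- withr::with_seed(1, matrix(rnorm(N * T_), N, T_))
  Y <- sweep(Y, 2, sqrt(colSums(Y^2)), "/")
  X <- withr::with_seed(2, matrix(rnorm(N * d), N, d))
  expect_equal(psionic_objective(matrix(0, d, K), matrix(0, K, T_),
                                 X, Y, 0, 0), T_ / N)
  L <- withr::with_seed(3, matrix(rnorm(d * K), d, K))
  S <- withr::with_seed(4, matrix(rnorm(K * T_), K, T_))
  expect_equal(psionic_objective(L, S, X, X %*% L %*% S, 0, 0), 0)
})

test_that("objective matches a scalar-loop arithmetic oracle", {
  inst <- random_instance(N = 6, d = 3, K = 2, T_ = 2, seed = 5)
  mu <- 0.3; lambda <- 0.7
  got <- psionic_objective(inst$L, inst$S, inst$X, inst$Y, mu, lambda)
  # naive scalar loops
  N <- nrow(inst$X)
  loss <- 0
  for (t in 1:2) {
    for (i in 1:N) {
      pred <- 0
      for (j in 1:3) for (k in 1:2) {
        pred <- pred + inst$X[i, j] * inst$L[j, k] * inst$S[k, t]
      }
      loss <- loss + (inst$Y[i, t] - pred)^2 / N
    }
  }
  pen <- mu * sum(abs(inst$S)) + lambda * sum(inst$L^2)
  expect_equal(got, as.numeric(loss + pen), tolerance = 1e-12)
})

test_that("S-step satisfies the lasso zero condition and mu = 0 least squares", {
  inst <- random_instance(N = 40, d = 5, K = 2, T_ = 3, seed = 6)
  Z <- inst$X %*% inst$L
  mu_max <- 2 * max(abs(crossprod(Z, inst$Y))) / nrow(inst$X)
  S0 <- update_S(inst$L, inst$X, inst$Y, mu = mu_max * 1.0001)
  expect_true(all(S0 == 0))
  S_ls <- update_S(inst$L, inst$X, inst$Y, mu = 0)
  want <- qr.solve(Z, inst$Y)
  expect_equal(unname(S_ls), unname(want), tolerance = 1e-8)
  expect_error(update_S(inst$L, inst$X, inst$Y, mu = -1), "mu")
})

test_that("S-step agrees with glmnet as an independent solver", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(N = 50, d = 6, K = 4, T_ = 2, seed = 7)
  mu <- 0.05
  S <- update_S(inst$L, inst$X, inst$Y, mu = mu)
  Z <- inst$X %*% inst$L
  for (t in 1:2) {
    # glmnet minimizes 1/(2n)||y - Zb||^2 + lam||b||_1; ours has (1/n) loss,
    # so lam = mu / 2 gives the same minimizer.
    g <- glmnet::glmnet(Z, inst$Y[, t], alpha = 1, lambda = mu / 2,
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
    b <- as.numeric(g$beta)
    expect_equal(unname(S[, t]), b, tolerance = 1e-4)
    obj <- function(s) sum((inst$Y[, t] - Z %*% s)^2) / 50 + mu * sum(abs(s))
    expect_equal(obj(S[, t]), obj(b), tolerance = 1e-9)
  }
})

test_that("L-step is the exact stationary point of its subproblem", {
  inst <- random_instance(N = 30, d = 5, K = 3, T_ = 4, seed = 8)
  lambda <- 0.2
  L <- update_L(inst$S, inst$X, inst$Y, lambda)
  # gradient: 2((X'X/N) L (SS') + lambda L - (X'Y/N) S')
  N <- nrow(inst$X)
  grad <- 2 * ((crossprod(inst$X) / N) %*% L %*% tcrossprod(inst$S) +
                 lambda * L - (crossprod(inst$X, inst$Y) / N) %*% t(inst$S))
  expect_lt(max(abs(grad)), 1e-10)
  # S = 0 shrinks L to zero
  expect_true(all(update_L(matrix(0, 3, 4), inst$X, inst$Y, 0.5) == 0))
})

test_that("L-step with K = 1, T = 1, s = 1 reduces to ridge regression", {
  inst <- random_instance(N = 25, d = 4, K = 1, T_ = 1, seed = 9)
  lambda <- 0.3
  L <- update_L(matrix(1, 1, 1), inst$X, inst$Y[, 1, drop = FALSE], lambda)
  ridge <- fit_stl_ridge(inst$X, inst$Y[, 1, drop = FALSE],
                         lambda_ridge = lambda, standardize = FALSE)$W
  expect_equal(unname(L), unname(ridge), tolerance = 1e-10)
})

test_that("single-task ridge matches the normal equations and limits", {
  inst <- random_instance(N = 30, d = 5, K = 2, T_ = 3, seed = 10)
  W <- fit_stl_ridge(inst$X, inst$Y, lambda_ridge = 0.4,
                     standardize = FALSE)$W
  N <- nrow(inst$X)
  want <- solve(crossprod(inst$X) / N + diag(0.4, 5),
                crossprod(inst$X, inst$Y) / N)
  expect_equal(unname(W), unname(want), tolerance = 1e-10)
  # lambda -> large shrinks to zero
  W_big <- fit_stl_ridge(inst$X, inst$Y, lambda_ridge = 1e8,
                         standardize = FALSE)$W
  expect_lt(max(abs(W_big)), 1e-5)
  # lambda = 0 with square invertible X solves exactly
  Xs <- withr::with_seed(2, matrix(rnorm(16), 4, 4))
  Ys <- withr::with_seed(3, matrix(rnorm(8), 4, 2))
  W0 <- fit_stl_ridge(Xs, Ys, lambda_ridge = 0, standardize = FALSE)$W
  expect_equal(unname(W0), unname(solve(Xs, Ys)), tolerance = 1e-8)
})

test_that("SVD initialization reconstructs low-rank targets (Eckart-Young)", {
  u <- withr::with_seed(4, rnorm(6)); v <- withr::with_seed(5, rnorm(4))
  # rank-1 W_stl via a noiseless construction around ridge: check the SVD
  # identity directly on a synthetic coefficient matrix
  X <- diag(6)
  Y <- X %*% (u %*% t(v))            # ridge at ~0 recovers u v'
  ini <- init_from_stl(X, Y, lambda_ridge = 1e-10, K = 1)
  expect_equal(unname(ini$L %*% ini$S), u %*% t(v), tolerance = 1e-6)

  W <- withr::with_seed(6, matrix(rnorm(24), 6, 4))
  Y2 <- diag(6) %*% W
  ini2 <- init_from_stl(diag(6), Y2, lambda_ridge = 1e-12, K = 2)
  sv <- svd(W)
  best2 <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  expect_equal(unname(ini2$L %*% ini2$S), best2, tolerance = 1e-6)
  # full K reconstructs exactly
  ini4 <- init_from_stl(diag(6), Y2, lambda_ridge = 1e-12, K = 4)
  expect_equal(unname(ini4$L %*% ini4$S), W, tolerance = 1e-8)
})

test_that("alternating fit recovers a noise-free planted model", {
  co <- small_cohort(seed = 21, n_genes = 150, n_tfs = 20, T_ = 10,
                     K_true = 2, target_r2 = 0.999999)
  fit <- fit_psionic(co$X, co$Y, K = 2, mu = 1e-6, lambda = 1e-6, seed = 1,
                     standardize = FALSE)
  expect_lt(tail(fit$objective_trace, 1), 1e-4)
  rec <- recovery_report(fit, co)
  expect_gt(rec$mean_task_cor, 0.99)
})

test_that("fitting is deterministic and the trace non-increasing", {
  co <- small_cohort(seed = 22, n_genes = 100, n_tfs = 12, T_ = 8, K_true = 2)
  f1 <- fit_psionic(co$X, co$Y, K = 3, seed = 42)
  f2 <- fit_psionic(co$X, co$Y, K = 3, seed = 42)
  expect_identical(f1$L, f2$L)
  expect_identical(f1$S, f2$S)
  expect_identical(f1$objective_trace, f2$objective_trace)
  tr <- f1$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(head(tr, -1), 1e-12)))
})

test_that("with mu = 0 and K = T the multitask fit nests single-task ridge", {
  co <- small_cohort(seed = 23, n_genes = 120, n_tfs = 10, T_ = 6, K_true = 2)
  lam <- 0.05
  fit_mtl <- fit_psionic(co$X, co$Y, K = 6, mu = 0, lambda = lam, seed = 1)
  stl <- fit_stl_ridge(co$X, co$Y, lambda_ridge = lam)
  # compare penalized training objectives on the same standardized features
  Xs <- sweep(sweep(co$X[, rownames(stl$W)], 2, stl$center, "-"),
              2, stl$scale, "/")
  N <- nrow(Xs)
  loss <- function(W) sum((co$Y - Xs %*% W)^2) / N + lam * sum(W^2)
  obj_mtl <- {
    W <- fit_mtl$L %*% fit_mtl$S
    # the MTL objective bounds the ridge objective via ||W||_F^2 <= ||L||_F^2 ||S||_F^2;
    # compare achieved prediction + ridge-equivalent penalty through the
    # training loss alone, which the nesting argument guarantees:
    sum((co$Y - Xs %*% W)^2) / N
  }
  obj_stl <- sum((co$Y - Xs %*% stl$W)^2) / N
  expect_lte(obj_mtl, obj_stl + 1e-8)
})

test_that("K is clamped with a warning and zero-variance columns are dropped", {
  co <- small_cohort(seed = 24, n_genes = 80, n_tfs = 10, T_ = 5, K_true = 2)
  expect_warning(fit_psionic(co$X, co$Y, K = 50, seed = 1), "clamping")
  Xz <- cbind(co$X, dead = 0)
  expect_warning(fit_psionic(Xz, co$Y, K = 2, seed = 1), "zero-variance")
})

test_that("increasing mu does not increase S sparsity on average", {
  nnz <- sapply(1:8, function(s) {
    co <- small_cohort(seed = 100 + s, n_genes = 100, n_tfs = 12, T_ = 8,
                       K_true = 2)
    sapply(c(1e-4, 3e-2), function(m) {
      sum(fit_psionic(co$X, co$Y, K = 3, mu = m, seed = 1)$S != 0)
    })
  })
  expect_lte(mean(nnz[2, ]), mean(nnz[1, ]))
})

test_that("prediction applies the stored transform and checks labels", {
  co <- small_cohort(seed = 25, n_genes = 90, n_tfs = 10, T_ = 5, K_true = 2)
  fit <- fit_psionic(co$X, co$Y, K = 2, seed = 1)
  expect_equal(dim(predict(fit, co$X)), dim(co$Y))
  X0 <- co$X; X0[] <- 0
  # all-zero new features standardize to a constant prediction per sample
  p0 <- predict(fit_psionic(co$X, co$Y, K = 2, seed = 1, standardize = FALSE),
                X0)
  expect_true(all(p0 == 0))
  Xbad <- co$X[, -1]
  expect_error(predict(fit, Xbad), colnames(co$X)[1])
  # per-task loop oracle
  pred <- predict(fit, co$X)
  Xs <- sweep(sweep(co$X[, rownames(fit$L)], 2, fit$center, "-"),
              2, fit$scale, "/")
  W <- fit$L %*% fit$S
  for (t in c(1, 3)) {
    expect_equal(unname(pred[, t]), as.numeric(Xs %*% W[, t]),
                 tolerance = 1e-12)
  }
})

test_that("activities are the L-S product and gauge invariant", {
  l <- matrix(c(1, -2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "program_1"))
  s <- matrix(c(2, 0.5), 1, 2, dimnames = list("program_1", c("s1", "s2")))
  m <- psionic:::new_psionic_model(L = l, S = s, mu = 0, lambda = 0,
                                   iterations = 0, objective_trace = 0,
                                   converged = TRUE, seed = 1)
  expect_equal(infer_activities(m), l %*% s)

  co <- small_cohort(seed = 26, n_genes = 80, n_tfs = 10, T_ = 5, K_true = 2)
  fit <- fit_psionic(co$X, co$Y, K = 3, seed = 1)
  W <- infer_activities(fit)
  perm <- c(2, 3, 1); flip <- diag(c(1, -1, 1))
  L2 <- fit$L[, perm] %*% flip
  S2 <- flip %*% fit$S[perm, ]
  expect_equal(unname(L2 %*% S2), unname(W), tolerance = 1e-12)
  # element-wise triple-sum oracle
  w_oracle <- matrix(0, nrow(fit$L), ncol(fit$S))
  for (i in seq_len(nrow(fit$L))) for (t in seq_len(ncol(fit$S))) {
    w_oracle[i, t] <- sum(fit$L[i, ] * fit$S[, t])
  }
  expect_equal(unname(W), w_oracle, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in tabular form", {
  co <- small_cohort(seed = 27, n_genes = 80, n_tfs = 10, T_ = 5, K_true = 2)
  fit <- fit_psionic(co$X, co$Y, K = 2, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("tf", "sample", "activity"))
  expect_equal(nrow(td), nrow(fit$L) * ncol(fit$S))
  gl <- glance(fit)
  expect_equal(gl$K, 2)
  expect_true(gl$objective > 0)
})
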