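# Independent brute-force oracles. Deliberately naive implementations,
# sharing no code with the package internals they check.

# Pairwise-fixpoint merge: repeatedly find the first (chrom, start, end, id)
# ordered pair overlapping by more than `frac` of the shorter interval and
# replace it by the union.
oracle_merge <- function(iv, frac) {
  iv <- iv[order(iv$chrom, iv$start, iv$end, iv$id), ]
  repeat {
    n <- nrow(iv)
    found <- NULL
    for (i in seq_len(max(n - 1L, 0L))) {
      for (j in seq(i + 1L, length.out = n - i)) {
        if (iv$chrom[i] != iv$chrom[j]) next
        ov <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j])
        if (ov <= 0) next
        shorter <- min(iv$end[i] - iv$start[i], iv$end[j] - iv$start[j])
        if (ov > frac * shorter) { found <- c(i, j); break }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) break
    i <- found[1L]; j <- found[2L]
    merged <- data.frame(chrom = iv$chrom[i],
                         start = min(iv$start[i], iv$start[j]),
                         end = max(iv$end[i], iv$end[j]),
                         id = paste(iv$id[i], iv$id[j], sep = "|"))
    iv <- rbind(iv[-c(i, j), ], merged)
    iv <- iv[order(iv$chrom, iv$start, iv$end, iv$id), ]
  }
  tibble::as_tibble(iv)
}

# All-pairs peak-gene assignment with the window + nearest-TSS rule.
oracle_assign <- function(atlas, genes, flank = 1e5) {
  out <- data.frame(peak_id = atlas$id, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (p in seq_len(nrow(atlas))) {
    best_g <- NA_character_; best_d <- Inf
    for (g in seq_len(nrow(genes))) {
      if (atlas$chrom[p] != genes$chrom[g]) next
      wlo <- genes$tu_start[g] - flank
      whi <- genes$tu_end[g] + flank
      if (atlas$start[p] < whi && atlas$end[p] > wlo) {
        mid <- (atlas$start[p] + atlas$end[p]) / 2
        d <- abs(mid - genes$tss[g])
        if (d < best_d || (d == best_d && genes$gene_id[g] < best_g)) {
          best_d <- d; best_g <- genes$gene_id[g]
        }
      }
    }
    if (!is.na(best_g)) { out$gene_id[p] <- best_g; out$distance[p] <- best_d }
  }
  tibble::as_tibble(out)
}

# Triple-loop max aggregation.
oracle_aggregate <- function(assignment, hits, motif_ids, gene_ids) {
  X <- matrix(0, length(gene_ids), length(motif_ids),
              dimnames = list(gene_ids, motif_ids))
  for (gi in seq_along(gene_ids)) {
    peaks <- assignment$peak_id[!is.na(assignment$gene_id) &
                                  assignment$gene_id == gene_ids[gi]]
    for (mi in seq_along(motif_ids)) {
      best <- 0
      for (r in seq_len(nrow(hits))) {
        if (hits$motif_id[r] == motif_ids[mi] && hits$peak_id[r] %in% peaks) {
          best <- max(best, hits$score[r])
        }
      }
      X[gi, mi] <- best
    }
  }
  X
}

# Direct simulation of the redundancy-removal rule.
oracle_jaccard_filter <- function(sets, threshold) {
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  kept <- names(sets)
  repeat {
    n <- length(kept)
    if (n < 2) break
    pair_bad <- rep(FALSE, n)
    J <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      J[i, j] <- jac(sets[[kept[i]]], sets[[kept[j]]])
      if (J[i, j] > threshold) pair_bad[i] <- TRUE
    }
    if (!any(pair_bad)) break
    means <- sapply(seq_len(n), function(i) mean(J[i, -i]))
    cand <- which(pair_bad & means == max(means[pair_bad]))
    kept <- setdiff(kept, sort(kept[cand])[1])
  }
  names(sets)[names(sets) %in% kept]
}

# 2-D lasso objective for grid + polish minimization.
oracle_lasso2_obj <- function(s, Z, y, mu) {
  r <- y - Z %*% s
  sum(r * r) / length(y) + mu * sum(abs(s))
}

oracle_lasso2_min <- function(Z, y, mu, span = 3, step = 0.05) {
  g <- seq(-span, span, by = step)
  Sg <- rbind(rep(g, each = length(g)), rep(g, times = length(g)))
  R <- matrix(y, nrow(Z), ncol(Sg)) - Z %*% Sg
  vals <- colSums(R^2) / length(y) + mu * colSums(abs(Sg))
  best <- Sg[, which.min(vals)]
  pol <- optim(best, oracle_lasso2_obj, Z = Z, y = y, mu = mu,
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  min(min(vals), pol$value)
}

# Exhaustive sign-flip enumeration of the one-sided Wilcoxon signed-rank
# null: P(V >= v_obs) with V = sum of ranks of positive differences.
oracle_signflip_p <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    if (sum(r[signs]) >= v_obs) count <- count + 1L
  }
  count / 2^n
}

# Exhaustive permutation p for |Spearman rho| (two-sided).
oracle_perm_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  obs <- abs(cor(x, y, method = "spearman"))
  vals <- sapply(perms(seq_len(n)), function(p) {
    abs(cor(x, y[p], method = "spearman"))
  })
  mean(vals >= obs - 1e-12)
}

# One-sided two-sample KS statistic via step-through ECDF comparison.
oracle_ks_stat <- function(x, y, direction) {
  grid <- sort(unique(c(x, y)))
  fx <- sapply(grid, function(g) mean(x <= g))
  fy <- sapply(grid, function(g) mean(y <= g))
  if (direction == "up") max(0, max(fy - fx)) else max(0, max(fx - fy))
}

random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 5000,
                             max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE),
    id = sprintf("iv%03d", seq_len(n))
  )
}
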