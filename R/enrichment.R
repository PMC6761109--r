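#' One-sided KS shift test for a motif's peaks
#'
#' Compares the distribution of differential-accessibility log2 fold changes
#' of the peaks carrying a motif against the background atlas distribution,
#' with a two-sample one-sided Kolmogorov-Smirnov test in each direction.
#' The background is all differential peaks and by default includes the
#' member peaks; a disjoint-background mode is available.
#'
#' @param diff Tibble with columns `peak_id` (unique) and `log2fc` (finite).
#' @param members Character vector of member peak ids (must be a subset of
#'   `diff$peak_id`; at least `min_members`).
#' @param background `"include"` (default: background = all peaks) or
#'   `"disjoint"` (background = non-member peaks).
#' @param min_members Minimum member-set size. Default 10.
#' @return One-row tibble: `ks_stat_up`, `p_up` (members shifted toward
#'   higher log2FC), `ks_stat_down`, `p_down`, `n_members`, `n_background`.
#'   One-sided p values come from the asymptotic Smirnov distribution, or the
#'   exact distribution when the smaller sample has fewer than 30 values.
#' @export
motif_shift_test <- function(diff, members, background = c("include", "disjoint"),
                             min_members = 10L) {
  background <- match.arg(background)
  check_diff_table(diff)
  members <- unique(as.character(members))
  if (length(members) == 0L) abort("Empty member set.")
  if (!all(members %in% diff$peak_id)) {
    abort("`members` contains peak ids absent from `diff`.")
  }
  if (length(members) < min_members) {
    abort(sprintf("Member set smaller than the floor (%d < %d).",
                  length(members), min_members))
  }
  is_mem <- diff$peak_id %in% members
  x <- diff$log2fc[is_mem]
  y <- if (background == "include") diff$log2fc else diff$log2fc[!is_mem]
  up <- ks_one_sided(x, y, direction = "up")
  down <- ks_one_sided(x, y, direction = "down")
  tibble(ks_stat_up = up$stat, p_up = up$p,
         ks_stat_down = down$stat, p_down = down$p,
         n_members = length(x), n_background = length(y))
}

# One-sided two-sample KS. direction = "up": member values stochastically
# larger (member ECDF below background ECDF).
ks_one_sided <- function(x, y, direction = c("up", "down")) {
  direction <- match.arg(direction)
  m <- length(x); n <- length(y)
  grid <- sort(unique(c(x, y)))
  Fx <- findInterval(grid, sort(x)) / m
  Fy <- findInterval(grid, sort(y)) / n
  gap <- if (direction == "up") Fy - Fx else Fx - Fy
  stat <- max(0, max(gap))
  p <- if (min(m, n) < 30 && exists("psmirnov", where = asNamespace("stats"))) {
    # exact only without ties between the samples; fall back otherwise
    if (!any(duplicated(c(x, y)))) {
      stats::psmirnov(stat, sizes = c(m, n), two.sided = FALSE,
                      lower.tail = FALSE)
    } else {
      exp(-2 * stat^2 * m * n / (m + n))
    }
  } else {
    exp(-2 * stat^2 * m * n / (m + n))
  }
  list(stat = stat, p = min(1, max(p, 0)))
}

check_diff_table <- function(diff) {
  need <- c("peak_id", "log2fc")
  if (!is.data.frame(diff) || !all(need %in% names(diff))) {
    abort("`diff` must have columns peak_id and log2fc.")
  }
  if (anyDuplicated(diff$peak_id)) abort("`diff` has duplicate peak ids.")
  if (any(!is.finite(diff$log2fc))) abort("`diff` has non-finite log2fc.")
  invisible(diff)
}

#' Motif occurrence in the most differential peaks
#'
#' Counts member peaks among the `k` most opened (top by log2FC) and `k`
#' most closed (bottom) differential peaks, against the motif's background
#' occurrence among all differential peaks. The effect size is the log2
#' ratio of foreground to background frequency, with a 0.5 pseudocount on
#' both counts. Ties at rank `k` are broken by peak id.
#'
#' @inheritParams motif_shift_test
#' @param k Number of peaks per direction. Default 5000.
#' @return One-row tibble: `fg_up`, `fg_down`, `bg`, `n_total`, `effect_up`,
#'   `effect_down`.
#' @export
topk_occurrence <- function(diff, members, k = 5000L) {
  check_diff_table(diff)
  members <- unique(as.character(members))
  n_total <- nrow(diff)
  if (k > n_total) abort("`k` exceeds the number of differential peaks.")
  ord_up <- order(-diff$log2fc, diff$peak_id)
  ord_down <- order(diff$log2fc, diff$peak_id)
  top_up <- diff$peak_id[ord_up[seq_len(k)]]
  top_down <- diff$peak_id[ord_down[seq_len(k)]]
  fg_up <- sum(members %in% top_up)
  fg_down <- sum(members %in% top_down)
  bg <- sum(members %in% diff$peak_id)
  eff <- function(fg) log2(((fg + 0.5) / k) / ((bg + 0.5) / n_total))
  tibble(fg_up = fg_up, fg_down = fg_down, bg = bg, n_total = n_total,
         effect_up = eff(fg_up), effect_down = eff(fg_down))
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per test, with `m` the number of motifs tested in the
#' comparison ("plot").
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param m Number of tests; defaults to `length(p)`.
#' @return Adjusted p values.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must be in [0, 1].")
  pmin(1, p * m)
}

#' Motif enrichment over a differential-accessibility table
#'
#' Runs the KS shift test and the top-k occurrence counts for every motif in
#' a membership table and applies the Bonferroni correction across motifs
#' (separately for each direction).
#'
#' @inheritParams motif_shift_test
#' @param membership Tibble with columns `motif_id`, `peak_id` listing which
#'   peaks carry which motif.
#' @param k Top/bottom peak-set size for the occurrence counts.
#' @return Tibble with one row per motif: KS statistics and p values in both
#'   directions, occurrence counts, effect sizes, and Bonferroni-adjusted
#'   `p_up_adj`, `p_down_adj`.
#' @export
motif_enrichment <- function(diff, membership, k = 5000L,
                             background = c("include", "disjoint"),
                             min_members = 10L) {
  background <- match.arg(background)
  if (!all(c("motif_id", "peak_id") %in% names(membership))) {
    abort("`membership` must have columns motif_id and peak_id.")
  }
  sets <- split(membership$peak_id, membership$motif_id)
  res <- purrr::map_dfr(names(sets), function(m) {
    shift <- motif_shift_test(diff, sets[[m]], background = background,
                              min_members = min_members)
    occ <- topk_occurrence(diff, sets[[m]], k = k)
    dplyr::bind_cols(tibble(motif_id = m), shift, occ)
  })
  res$p_up_adj <- adjust_bonferroni(res$p_up, nrow(res))
  res$p_down_adj <- adjust_bonferroni(res$p_down, nrow(res))
  res
}
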