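# Randomization controls for the feature pipeline. Both destroy the
# motif-to-gene signal while conserving per-peak and per-motif hit counts,
# providing negative controls for the cross-validation comparison.

#' Shuffle motif identities within each peak
#'
#' For every peak, the multiset of hit scores is kept but reassigned to a
#' uniformly drawn set of motif labels of the same size. Scores travel with
#' the draw under a canonical pairing (sampled labels sorted, scores in the
#' order of the original hits sorted by motif id), so a peak hit by every
#' motif is returned unchanged. The total number of hits is conserved
#' exactly; motif identity is destroyed.
#'
#' @param hits Motif-hit tibble (`motif_id`, `peak_id`, `score`).
#' @param seed RNG seed.
#' @param motif_universe Labels to draw from; defaults to all motifs present
#'   in `hits`.
#' @return A motif-hit tibble of the same size, sorted by (peak, motif).
#' @export
randomize_motif_hits <- function(hits, seed = 1L, motif_universe = NULL) {
  check_hits(hits)
  motifs <- sort(unique(motif_universe %||% hits$motif_id))
  with_seed(seed, {
    out <- hits |>
      dplyr::arrange(.data$peak_id, .data$motif_id) |>
      dplyr::group_by(.data$peak_id) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        if (n > length(motifs)) {
          abort(sprintf("Peak '%s' has more hits than available motif labels.",
                        key$peak_id))
        }
        tibble(motif_id = sort(sample(motifs, n)), score = df$score)
      }) |>
      dplyr::ungroup()
  })
  dplyr::arrange(out[, c("motif_id", "peak_id", "score")],
                 .data$peak_id, .data$motif_id)
}

#' Shuffle peak locations within each motif and rebuild features
#'
#' For every motif, the set of peaks carrying a hit is replaced by an
#' equal-size uniform sample of atlas peaks; scores are carried over under
#' the same canonical pairing as [randomize_motif_hits()] (so a motif hitting
#' every atlas peak leaves the features unchanged). The gene-by-TF matrix is
#' then rebuilt through the real assignment and aggregation steps.
#'
#' @param atlas Interval tibble of atlas peaks.
#' @param hits Motif-hit tibble.
#' @param genes Gene model tibble.
#' @param seed RNG seed.
#' @param flank Assignment window, as in [assign_peaks_to_genes()].
#' @return The rebuilt feature matrix; the shuffled hit table is attached as
#'   attribute `hits`.
#' @export
randomize_peak_locations <- function(atlas, hits, genes, seed = 1L, flank = 1e5) {
  check_intervals(atlas, "atlas")
  check_hits(hits)
  if (any(!hits$peak_id %in% atlas$id)) {
    abort("Motif hits reference peaks absent from the atlas.")
  }
  peak_ids <- atlas$id
  with_seed(seed, {
    shuffled <- hits |>
      dplyr::arrange(.data$motif_id, .data$peak_id) |>
      dplyr::group_by(.data$motif_id) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        if (n > length(peak_ids)) {
          abort(sprintf("Motif '%s' has more hits than atlas peaks.", key$motif_id))
        }
        tibble(peak_id = sort(sample(peak_ids, n)), score = df$score)
      }) |>
      dplyr::ungroup()
  })
  shuffled <- dplyr::arrange(shuffled[, c("motif_id", "peak_id", "score")],
                             .data$peak_id, .data$motif_id)
  assignment <- assign_peaks_to_genes(atlas, genes, flank = flank)
  X <- aggregate_motif_scores(assignment, shuffled,
                              motif_ids = sort(unique(hits$motif_id)))
  attr(X, "hits") <- shuffled
  X
}
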