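#' Merge reproducible peaks into an atlas
#'
#' Combines per-sample (or per-cell-line) reproducible peak sets into a single
#' genome-wide atlas of accessible regions. Two peaks are merged into their
#' union when they overlap by more than `overlap_frac` of the shorter
#' interval; merging repeats until no qualifying pair remains (fixpoint).
#' Merging is deterministic: at each step the first qualifying pair in
#' (chrom, start, end, id) order is merged.
#'
#' @param peak_sets A list of interval tibbles (see [read_bed()]), each
#'   internally non-overlapping. Names, if present, label provenance; ids are
#'   prefixed with the set name when duplicated across sets.
#' @param overlap_frac Fraction of the shorter interval that must be covered
#'   for a merge, in (0, 1]. Default 0.75.
#' @param reciprocal If `TRUE` require the overlap to exceed `overlap_frac`
#'   of both intervals rather than the shorter one.
#' @return An interval tibble sorted by (chrom, start, end); merged peak ids
#'   join their parents with `"|"`. Attribute `provenance` lists the input
#'   set names.
#' @export
merge_reproducible_peaks <- function(peak_sets, overlap_frac = 0.75,
                                     reciprocal = FALSE) {
  if (!is.list(peak_sets)) abort("`peak_sets` must be a list of interval tibbles.")
  if (overlap_frac <= 0 || overlap_frac > 1) abort("`overlap_frac` must be in (0, 1].")
  if (length(peak_sets) == 0L) {
    return(structure(tibble(chrom = character(), start = double(),
                            end = double(), id = character()),
                     provenance = character()))
  }
  set_names <- names(peak_sets) %||% paste0("set", seq_along(peak_sets))
  set_names[set_names == ""] <- paste0("set", which(set_names == ""))
  for (s in peak_sets) check_intervals(s)
  all <- dplyr::bind_rows(peak_sets)
  if (nrow(all) > 0L && anyDuplicated(all$id)) {
    all <- dplyr::bind_rows(lapply(seq_along(peak_sets), function(i) {
      s <- peak_sets[[i]]
      s$id <- paste0(set_names[i], ":", s$id)
      s
    }))
  }
  out <- merge_fixpoint(all, overlap_frac, reciprocal)
  structure(out, provenance = set_names)
}

merge_fixpoint <- function(iv, overlap_frac, reciprocal) {
  iv <- dplyr::arrange(iv, .data$chrom, .data$start, .data$end, .data$id)
  if (nrow(iv) < 2L) return(iv)
  repeat {
    gr <- intervals_to_granges(iv)
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE,
                                        ignore.strand = TRUE)
    if (length(hits) == 0L) break
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(iv$end[qh], iv$end[sh]) - pmax(iv$start[qh], iv$start[sh])
    w1 <- iv$end[qh] - iv$start[qh]
    w2 <- iv$end[sh] - iv$start[sh]
    denom <- if (reciprocal) pmax(w1, w2) else pmin(w1, w2)
    qualify <- ov > overlap_frac * denom
    if (!any(qualify)) break
    i <- pmin(qh, sh)[qualify]
    j <- pmax(qh, sh)[qualify]
    pick <- order(i, j)[1L]
    a <- i[pick]; b <- j[pick]
    merged <- tibble(
      chrom = iv$chrom[a],
      start = min(iv$start[a], iv$start[b]),
      end = max(iv$end[a], iv$end[b]),
      id = paste(iv$id[a], iv$id[b], sep = "|")
    )
    iv <- dplyr::bind_rows(iv[-c(a, b), ], merged)
    iv <- dplyr::arrange(iv, .data$chrom, .data$start, .data$end, .data$id)
  }
  iv
}

#' Assign atlas peaks to genes
#'
#' A peak is a candidate for a gene when it overlaps the gene's regulatory
#' window: the transcription unit extended by `flank` bp on both sides
#' (upstream of the TSS and downstream of the 3' end together cover both
#' flanks, so the window is strand-symmetric). Among candidate genes the peak
#' is assigned to the nearest one by distance from the peak midpoint to the
#' TSS; ties go to the lexicographically smaller `gene_id`. Peaks with no
#' candidate gene stay unassigned (`gene_id` `NA`).
#'
#' @param atlas Interval tibble of peaks.
#' @param genes Gene model tibble (see [make_gene_models()]).
#' @param flank Window extension in bp. Default 100000.
#' @return Tibble with columns `peak_id`, `gene_id` (`NA` when unassigned)
#'   and `distance` (midpoint-to-TSS, `NA` when unassigned); one row per
#'   atlas peak, in atlas order. Attribute `gene_ids` carries the full gene
#'   universe for downstream matrix construction.
#' @export
assign_peaks_to_genes <- function(atlas, genes, flank = 1e5) {
  check_intervals(atlas, "atlas")
  check_scalar(flank, "flank", lower = 0)
  unknown <- setdiff(unique(atlas$chrom), unique(genes$chrom))
  if (length(unknown) > 0L) {
    warn(sprintf("Atlas chromosome(s) absent from gene table (peaks left unassigned): %s",
                 paste(unknown, collapse = ", ")))
  }
  assignment <- tibble(peak_id = atlas$id,
                       gene_id = NA_character_,
                       distance = NA_real_)
  if (nrow(atlas) > 0L && nrow(genes) > 0L) {
    peak_gr <- intervals_to_granges(atlas)
    win_gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = pmax(genes$tu_start - flank, 0) + 1,
                                end = genes$tu_end + flank)
    )
    suppressWarnings(
      hits <- GenomicRanges::findOverlaps(peak_gr, win_gr, ignore.strand = TRUE)
    )
    if (length(hits) > 0L) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      mid <- (atlas$start[qh] + atlas$end[qh]) / 2
      dist <- abs(mid - genes$tss[sh])
      cand <- tibble(peak_idx = qh, gene_id = genes$gene_id[sh], distance = dist)
      best <- cand |>
        dplyr::arrange(.data$peak_idx, .data$distance, .data$gene_id) |>
        dplyr::distinct(.data$peak_idx, .keep_all = TRUE)
      assignment$gene_id[best$peak_idx] <- best$gene_id
      assignment$distance[best$peak_idx] <- best$distance
    }
  }
  structure(assignment, gene_ids = genes$gene_id)
}

#' Keep only promoter-proximal peaks
#'
#' Feature-ablation filter: retains atlas peaks overlapping any gene's
#' promoter, defined as TSS +/- `window` bp. Used to compare full
#' (promoter + enhancer) features against promoter-only features.
#'
#' @inheritParams assign_peaks_to_genes
#' @param window Half-width of the promoter window in bp. Default 2000.
#' @return The filtered interval tibble (atlas order preserved).
#' @export
promoter_filter <- function(atlas, genes, window = 2000) {
  check_intervals(atlas, "atlas")
  check_scalar(window, "window", lower = 0)
  if (nrow(atlas) == 0L || nrow(genes) == 0L) return(atlas[0L, ])
  peak_gr <- intervals_to_granges(atlas)
  prom_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(genes$tss - window, 0) + 1,
                              end = genes$tss + window + 1)
  )
  suppressWarnings(
    keep <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(peak_gr, prom_gr, ignore.strand = TRUE)
    ))
  )
  atlas[sort(keep), ]
}

#' Aggregate motif-hit scores into a gene-by-TF feature matrix
#'
#' For every gene and motif, the feature value is the maximum hit score of
#' that motif across all peaks assigned to the gene; genes with no assigned
#' peak (or no hit) get 0. Columns are the sorted motif ids so the matrix is
#' reproducible across runs.
#'
#' @param assignment Peak-gene assignment from [assign_peaks_to_genes()].
#' @param hits Motif-hit tibble (`motif_id`, `peak_id`, `score`).
#' @param motif_ids Motifs to include as columns; defaults to all motifs in
#'   `hits`.
#' @param gene_ids Gene universe for the rows; defaults to the `gene_ids`
#'   attribute of `assignment`.
#' @return Numeric matrix, genes x motifs, nonnegative.
#' @export
aggregate_motif_scores <- function(assignment, hits, motif_ids = NULL,
                                   gene_ids = NULL) {
  check_hits(hits)
  gene_ids <- gene_ids %||% attr(assignment, "gene_ids")
  if (is.null(gene_ids)) abort("Supply `gene_ids` (assignment lacks a gene_ids attribute).")
  motif_ids <- sort(unique(motif_ids %||% hits$motif_id))
  unknown <- setdiff(unique(hits$peak_id), assignment$peak_id)
  if (length(unknown) > 0L) {
    abort(sprintf("Motif hit(s) reference peak id(s) absent from the atlas: %s",
                  paste(head(unknown, 3L), collapse = ", ")))
  }
  X <- matrix(0, nrow = length(gene_ids), ncol = length(motif_ids),
              dimnames = list(gene_ids, motif_ids))
  if (nrow(hits) > 0L && length(motif_ids) > 0L) {
    keyed <- dplyr::inner_join(
      hits[hits$motif_id %in% motif_ids, ],
      assignment[!is.na(assignment$gene_id), c("peak_id", "gene_id")],
      by = "peak_id"
    )
    if (nrow(keyed) > 0L) {
      agg <- keyed |>
        dplyr::group_by(.data$gene_id, .data$motif_id) |>
        dplyr::summarise(score = max(.data$score), .groups = "drop")
      X[cbind(match(agg$gene_id, gene_ids), match(agg$motif_id, motif_ids))] <-
        agg$score
    }
  }
  X
}
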