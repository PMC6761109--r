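#' Read genomic intervals from a BED file
#'
#' Parses a headerless, tab-separated BED file into a tibble of intervals.
#' Coordinates are taken verbatim as 0-based half-open (BED convention); no
#' chromosome-name normalization is applied. If a fourth column is present it
#' is used as the interval id, otherwise ids `peak_<n>` are generated in file
#' order.
#'
#' @param path Path to a BED file with at least three tab-separated columns.
#' @return A tibble with columns `chrom` (character), `start`, `end`
#'   (0-based half-open integers) and `id` (character), in file order.
#' @seealso [write_bed()], [merge_reproducible_peaks()]
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tp1", bed)
#' read_bed(bed)
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = double(),
                  end = double(), id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("Malformed BED line %d: fewer than 3 tab-separated fields.",
                  bad[1L]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed BED line %d: non-numeric coordinates.", bad[1L]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    abort(sprintf("Malformed BED line %d: start >= end.", bad[1L]))
  }
  id <- ifelse(nf >= 4L,
               vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_,
                      character(1)),
               NA_character_)
  auto <- is.na(id)
  id[auto] <- paste0("peak_", which(auto))
  if (anyDuplicated(id)) {
    abort(sprintf("Duplicate interval id in %s: %s",
                  path, id[duplicated(id)][1L]))
  }
  tibble(chrom = chrom, start = start, end = end, id = id)
}

#' Write genomic intervals to a BED file
#'
#' Inverse of [read_bed()]: writes a tab-separated, headerless four-column BED
#' file (chrom, start, end, id) so that `read_bed(write_bed(x, f))` is the
#' identity.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`, `id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals)
  lines <- sprintf("%s\t%s\t%s\t%s", intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   intervals$id)
  writeLines(lines, path)
  invisible(path)
}

check_intervals <- function(x, name = "intervals") {
  need <- c("chrom", "start", "end", "id")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns %s.",
                  name, paste(need, collapse = ", ")))
  }
  if (nrow(x) > 0L) {
    if (any(x$start >= x$end)) abort(sprintf("`%s` has start >= end.", name))
    if (anyDuplicated(x$id)) abort(sprintf("`%s` has duplicate ids.", name))
  }
  invisible(x)
}

# Convert an interval tibble to a GRanges (1-based closed, as GRanges expects).
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end),
    id = intervals$id
  )
}
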