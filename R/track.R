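#' Binned coverage track
#'
#' Container for per-bin tag counts of one sequencing library (one ChIP or
#' input channel of one sample). Coordinates are 0-based half-open; bin `i`
#' of chromosome `c` covers `[(i-1)*bin_width, i*bin_width)`.
#'
#' @param counts Named list with one non-negative numeric vector per
#'   chromosome (tag counts per bin).
#' @param bin_width Bin width in bp.
#' @param sample_id Library identifier.
#' @param channel `"chip"` or `"input"`.
#' @param library_size Total mapped tags; defaults to `sum(counts)`, which is
#'   exact for synthetic tracks.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(counts, bin_width, sample_id = "sample",
                           channel = c("chip", "input"),
                           library_size = NULL) {
  channel <- match.arg(channel)
  if (!is.list(counts) || is.null(names(counts)) || any(names(counts) == ""))
    .stopf("`counts` must be a named list of per-chromosome bin vectors")
  if (!.is_count(bin_width, positive = TRUE))
    .stopf("`bin_width` must be a positive integer")
  for (chrom in names(counts)) {
    v <- counts[[chrom]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0))
      .stopf("counts for %s must be non-negative and complete", chrom)
  }
  total <- sum(vapply(counts, sum, numeric(1)))
  library_size <- library_size %||% total
  if (library_size < 0) .stopf("`library_size` must be non-negative")
  structure(
    list(counts = lapply(counts, as.numeric),
         bin_width = as.integer(bin_width),
         sample_id = sample_id,
         channel = channel,
         library_size = library_size,
         normalized = FALSE),
    class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s [%s]%s\n", x$sample_id, x$channel,
              if (x$normalized) " (RPM)" else ""))
  cat(sprintf("  %d chromosome(s), bin width %d bp, library size %.0f\n",
              length(x$counts), x$bin_width, x$library_size))
  invisible(x)
}

.track_chrom_lengths <- function(track) {
  vapply(track$counts, length, integer(1)) * track$bin_width
}

.check_compatible_tracks <- function(a, b) {
  if (a$bin_width != b$bin_width)
    .stopf("tracks have different bin widths (%d vs %d)",
           a$bin_width, b$bin_width)
  if (!identical(sort(names(a$counts)), sort(names(b$counts))) ||
      !identical(.track_chrom_lengths(a)[names(a$counts)],
                 .track_chrom_lengths(b)[names(a$counts)]))
    .stopf("tracks are binned over different chromosome sets")
  invisible(TRUE)
}

#' Reads-per-million normalization
#'
#' Scales every bin count by `1e6 / library_size`.
#'
#' @param track A [coverage_track()].
#' @return A `coverage_track` whose values are RPM per bin.
#' @export
rpm <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$library_size <= 0)
    .stopf("cannot RPM-normalize a track with zero library size")
  track$counts <- lapply(track$counts, function(v) v * 1e6 / track$library_size)
  track$normalized <- TRUE
  track
}

# Tag count of `track` inside [start, end) intervals on one chromosome,
# fractional at bin boundaries.
.track_region_counts <- function(track, chrom, starts, ends) {
  v <- track$counts[[chrom]]
  if (is.null(v)) .stopf("unknown chromosome '%s' in track %s",
                         chrom, track$sample_id)
  .region_sums(v, starts, ends, track$bin_width)
}
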