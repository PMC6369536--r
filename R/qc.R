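#' Fraction of reads in peaks (FRiP)
#'
#' @param track A [coverage_track()].
#' @param peaks A `peak_set` or any data frame with `chrom`, `start`, `end`.
#' @return Fraction of the library's tags falling inside peak intervals
#'   (0 when there are no peaks).
#' @export
qc_frip <- function(track, peaks) {
  stopifnot(inherits(track, "coverage_track"))
  if (nrow(peaks) == 0) return(0)
  if (track$library_size <= 0) return(0)
  total <- 0
  for (chrom in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == chrom, , drop = FALSE]
    if (is.null(track$counts[[chrom]])) next
    total <- total + sum(.track_region_counts(track, chrom, p$start, p$end))
  }
  min(total / track$library_size, 1)
}

#' Between-replicate correlation over TSS-centered windows
#'
#' Pearson correlation of `log(1 + RPKM)` values over non-overlapping
#' fixed-width genomic windows centered on gene TSSs, the standard
#' within-sample consistency QC for ChIP libraries.
#'
#' @param track_a,track_b [coverage_track()]s with identical binning.
#' @param ann A `genome_annotation`.
#' @param region_width Window width in bp (default 10 kb).
#' @return Pearson correlation coefficient.
#' @export
qc_replicate_correlation <- function(track_a, track_b, ann,
                                     region_width = 10000) {
  .check_compatible_tracks(track_a, track_b)
  chrom_lengths <- .track_chrom_lengths(track_a)
  half <- region_width %/% 2L
  xa <- numeric()
  xb <- numeric()
  for (chrom in unique(ann$chrom)) {
    if (is.null(track_a$counts[[chrom]])) next
    tss <- sort(ann$tss[ann$chrom == chrom])
    starts <- pmax(tss - half, 0)
    ends <- pmin(tss + half, chrom_lengths[[chrom]])
    # greedy non-overlapping selection, left to right
    keep <- logical(length(starts))
    last_end <- -1
    for (i in seq_along(starts)) {
      if (starts[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- ends[i]
      }
    }
    xa <- c(xa, .track_region_counts(track_a, chrom, starts[keep],
                                     ends[keep]))
    xb <- c(xb, .track_region_counts(track_b, chrom, starts[keep],
                                     ends[keep]))
  }
  if (length(xa) < 3) .stopf("too few usable TSS windows for correlation")
  rpkm <- function(x, lib) x * 1e9 / (max(lib, 1) * region_width)
  stats::cor(log1p(rpkm(xa, track_a$library_size)),
             log1p(rpkm(xb, track_b$library_size)))
}

#' Strand-oriented TSS metaprofile
#'
#' Mean RPM per bin over windows of +/- `window` bp around every TSS,
#' oriented 5' to 3' (minus-strand windows are reversed), for the ChIP and
#' input channels separately. Windows running off a chromosome end are
#' truncated by masking (NA bins are dropped from the mean) with a message.
#'
#' @param chip,input [coverage_track()]s with identical binning.
#' @param ann A `genome_annotation`.
#' @param window Half-window in bp (default 2000); must be a multiple of the
#'   bin width.
#' @return List of class `tss_profile`: `offset` (bp of each bin start
#'   relative to the TSS, transcription direction), `chip`, `input` (mean
#'   RPM per bin), `n_genes`.
#' @export
tss_metaprofile <- function(chip, input, ann, window = 2000) {
  .check_compatible_tracks(chip, input)
  bw <- chip$bin_width
  if (window %% bw != 0) .stopf("`window` must be a multiple of the bin width")
  k <- as.integer(2L * window %/% bw)
  chip_r <- rpm(chip)
  input_r <- rpm(input)
  acc_chip <- acc_input <- numeric(k)
  n_obs <- numeric(k)
  n_trunc <- 0L
  for (i in seq_len(nrow(ann))) {
    chrom <- ann$chrom[i]
    v <- chip_r$counts[[chrom]]
    if (is.null(v)) next
    nbins <- length(v)
    tss <- ann$tss[i]
    idx <- if (ann$strand[i] == "+") {
      (tss - window) %/% bw + 1L + 0:(k - 1L)
    } else {
      (tss + 1L + window) %/% bw - 0:(k - 1L)
    }
    ok <- idx >= 1L & idx <= nbins
    if (!all(ok)) n_trunc <- n_trunc + 1L
    acc_chip[ok] <- acc_chip[ok] + v[idx[ok]]
    acc_input[ok] <- acc_input[ok] + input_r$counts[[chrom]][idx[ok]]
    n_obs[ok] <- n_obs[ok] + 1
  }
  if (n_trunc > 0)
    message(sprintf("tss_metaprofile: %d window(s) truncated at chromosome edges",
                    n_trunc))
  structure(list(offset = seq(-window, window - bw, by = bw),
                 chip = acc_chip / pmax(n_obs, 1),
                 input = acc_input / pmax(n_obs, 1),
                 n_genes = nrow(ann), window = window, bin_width = bw),
            class = "tss_profile")
}
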