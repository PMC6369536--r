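# On-disk formats. Interval files are 0-based half-open (BED convention);
# pileup and VCF positions are 1-based.

.read_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  list(lines = lines[keep], line_no = which(keep))
}

#' Read a BED file
#'
#' Accepts 3-6 column BED; coordinates stay 0-based half-open.
#'
#' @param path File path.
#' @return Data frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  parsed <- .read_lines(path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (length(parsed$lines) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    .stopf("line %d: BED records need at least 3 fields",
           parsed$line_no[which(nf < 3)[1]])
  nc <- min(max(nf), 6L)
  mat <- t(vapply(fields, function(f) f[seq_len(nc)], character(nc)))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- cols[seq_len(nc)]
  out$start <- suppressWarnings(as.integer(out$start))
  out$end <- suppressWarnings(as.integer(out$end))
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0)
    .stopf("line %d: non-numeric BED coordinates", parsed$line_no[bad[1]])
  bad <- which(out$start >= out$end)
  if (length(bad) > 0)
    .stopf("line %d: BED start >= end (%d >= %d)", parsed$line_no[bad[1]],
           out$start[bad[1]], out$end[bad[1]])
  if (!is.null(out$score)) out$score <- suppressWarnings(as.numeric(out$score))
  out
}

#' Write intervals as BED
#'
#' @param intervals Data frame with at least `chrom`, `start`, `end`;
#'   optional `name`, `score`, `strand` columns are written in BED order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  # optional columns must be contiguous from the left for valid BED
  cols <- cols[seq_len(match(FALSE, c("chrom", "start", "end", "name",
                                      "score", "strand") %in% cols,
                             nomatch = 7L) - 1L)]
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Records must be non-overlapping and aligned to the bin grid; adjacent
#' equal-value runs (as written by [write_bedgraph()]) are re-expanded to
#' uniform bins.
#'
#' @param path File path.
#' @param bin_width Bin width in bp.
#' @param chrom_lengths Optional named chromosome lengths; inferred from the
#'   rightmost record per chromosome otherwise.
#' @param sample_id,channel Passed to [coverage_track()].
#' @param library_size Optional; defaults to the total read count.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, bin_width, chrom_lengths = NULL,
                          sample_id = basename(path), channel = "chip",
                          library_size = NULL) {
  parsed <- .read_lines(path)
  if (length(parsed$lines) == 0) {
    counts <- lapply(chrom_lengths %||% stats::setNames(integer(), character()),
                     function(len) rep(0, len %/% bin_width))
    return(coverage_track(counts, bin_width, sample_id, channel,
                          library_size = library_size %||% 0))
  }
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    .stopf("line %d: bedGraph records need 4 fields",
           parsed$line_no[which(nf < 4)[1]])
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = as.numeric(vapply(fields, `[`, character(1), 2L)),
    end = as.numeric(vapply(fields, `[`, character(1), 3L)),
    value = as.numeric(vapply(fields, `[`, character(1), 4L)),
    line = parsed$line_no, stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value))
    .stopf("bedGraph contains non-numeric fields")
  bad <- which(df$start %% bin_width != 0 | df$end %% bin_width != 0 |
                 df$start >= df$end)
  if (length(bad) > 0)
    .stopf("line %d: bedGraph record not aligned to the %d-bp bin grid",
           df$line[bad[1]], bin_width)
  counts <- list()
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      .stopf("overlapping bedGraph records on %s near line %d", chrom,
             d$line[which(d$start[-1] < d$end[-nrow(d)])[1] + 1L])
    len <- (chrom_lengths[[chrom]] %||% max(d$end))
    v <- rep(0, len %/% bin_width)
    for (i in seq_len(nrow(d))) {
      lo <- d$start[i] %/% bin_width + 1L
      hi <- d$end[i] %/% bin_width
      v[lo:hi] <- d$value[i]
    }
    counts[[chrom]] <- v
  }
  if (!is.null(chrom_lengths)) {
    for (chrom in setdiff(names(chrom_lengths), names(counts)))
      counts[[chrom]] <- rep(0, chrom_lengths[[chrom]] %/% bin_width)
    counts <- counts[names(chrom_lengths)]
  }
  coverage_track(counts, bin_width, sample_id, channel,
                 library_size = library_size)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent bins with equal value are merged into one record; the whole
#' chromosome is covered (zero runs included) so bin re-expansion on read is
#' lossless.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bw <- track$bin_width
  for (chrom in names(track$counts)) {
    v <- track$counts[[chrom]]
    if (length(v) == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths) * bw
    starts <- ends - r$lengths * bw
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, as.integer(starts),
                       as.integer(ends), format(r$values, trim = TRUE,
                                                scientific = FALSE)),
               con)
  }
  invisible(path)
}

# ---- annotation / expression tables ---------------------------------------

#' Read/write the gene annotation table
#'
#' Typed TSV with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open); the TSS is derived from the strand on read.
#' Chromosome lengths ride along as `#chrom_lengths:` header comments.
#'
#' @param path File path.
#' @return A `genome_annotation` data frame.
#' @export
read_annotation <- function(path) {
  all_lines <- readLines(path)
  hdr <- grep("^#chrom_length\t", all_lines, value = TRUE)
  chrom_lengths <- NULL
  if (length(hdr) > 0) {
    parts <- strsplit(hdr, "\t", fixed = TRUE)
    chrom_lengths <- stats::setNames(
      as.integer(vapply(parts, `[`, character(1), 3L)),
      vapply(parts, `[`, character(1), 2L))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0)
    df <- data.frame(gene_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     stringsAsFactors = FALSE)
  .as_annotation(df[, c("gene_id", "chrom", "start", "end", "strand")],
                 chrom_lengths %||%
                   vapply(split(df$end, df$chrom), max, numeric(1)))
}

#' @rdname read_annotation
#' @param ann A `genome_annotation`.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  cl <- attr(ann, "chrom_lengths")
  writeLines(sprintf("#chrom_length\t%s\t%d", names(cl), as.integer(cl)), con)
  utils::write.table(ann[, c("gene_id", "chrom", "start", "end", "strand",
                             "tss")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an expression matrix as TSV (genes x samples)
#'
#' Sample metadata (`condition`, `replicate`) is recovered from the
#' `<condition>_r<replicate>` column naming used throughout the package.
#'
#' @param path File path.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df)
  nm <- colnames(values)
  cond <- sub("_r[0-9]+$", "", nm)
  rep_id <- as.integer(sub("^.*_r", "", nm))
  structure(list(values = values,
                 samples = data.frame(sample = nm, condition = cond,
                                      replicate = rep_id,
                                      stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' @rdname read_expression
#' @param em An `expression_matrix`.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
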