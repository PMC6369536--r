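#' Consensus-rule SNP calling from pileup columns
#'
#' A SNP is called at a column when strictly more than `threshold` (default
#' 80%) of the reads covering the position carry one and the same alternate
#' base: the most frequent single alternate (A/C/G/T, strand-pooled) is
#' compared against the full declared depth. Columns below `min_depth` are
#' skipped and counted in a message. The strictly-greater-than comparison
#' means an alternate fraction of exactly 0.8 is never called.
#'
#' @param columns A `pileup` data frame from [read_pileup()].
#' @param threshold Alternate-read fraction that must be exceeded.
#' @param min_depth Minimum column depth considered (default 4).
#' @param sample_id Sample label attached to the calls.
#' @param alt_mode `"max"` (default) applies the rule to the single most
#'   frequent alternate; `"sum"` applies it to the pooled count of all
#'   alternates (the reported allele is still the most frequent one).
#' @return Data frame of class `variant_set`: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `depth`, `af`, `sample`, sorted by (chrom, pos).
#' @export
call_snps <- function(columns, threshold = 0.80, min_depth = 4,
                      sample_id = "sample", alt_mode = c("max", "sum")) {
  alt_mode <- match.arg(alt_mode)
  stopifnot(is.data.frame(columns))
  if (!.is_fraction(threshold)) .stopf("`threshold` must lie in [0, 1]")
  shallow <- columns$depth < min_depth
  if (any(shallow))
    message(sprintf("call_snps: skipped %d column(s) below depth %d",
                    sum(shallow), min_depth))
  cols <- columns[!shallow, , drop = FALSE]
  rows <- list()
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(cols))) {
    cand <- setdiff(bases, cols$ref[i])
    counts <- unlist(cols[i, cand])
    best <- which.max(counts)
    support <- if (alt_mode == "max") counts[best] else sum(counts)
    if (support / cols$depth[i] > threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cols$chrom[i], pos = cols$pos[i], ref = cols$ref[i],
        alt = cand[best], depth = cols$depth[i],
        af = unname(support) / cols$depth[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), depth = integer(), af = numeric(),
               stringsAsFactors = FALSE)
  out$sample <- rep(sample_id, nrow(out))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold, min_depth = min_depth,
            class = c("variant_set", "data.frame"))
}

#' Extract indel events passing the consensus rule
#'
#' Applies the same strictly-greater-than fraction rule to the reads
#' supporting each distinct insertion/deletion event at a column.
#'
#' @inheritParams call_snps
#' @return Data frame: `chrom`, `pos`, `type` (`ins`/`del`), `seq`,
#'   `count`, `depth`, `af`.
#' @export
extract_indels <- function(columns, threshold = 0.80, min_depth = 4) {
  stopifnot(is.data.frame(columns))
  rows <- list()
  for (i in seq_len(nrow(columns))) {
    if (columns$depth[i] < min_depth) next
    ev <- columns$indels[[i]]
    if (is.null(ev) || nrow(ev) == 0) next
    for (j in seq_len(nrow(ev))) {
      af <- ev$count[j] / columns$depth[i]
      if (af > threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = columns$chrom[i], pos = columns$pos[i],
          type = ev$type[j], seq = ev$seq[j], count = ev$count[j],
          depth = columns$depth[i], af = af, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), type = character(),
               seq = character(), count = integer(), depth = integer(),
               af = numeric(), stringsAsFactors = FALSE)
}

#' Compare SNP sets between two samples
#'
#' Exact set algebra on variant keys. By default the key is
#' (chrom, pos, alt) so the same position with different substitutions
#' counts as different variants; `by = "position"` keys on (chrom, pos)
#' alone, mirroring a plain positional interval comparison.
#'
#' @param sample_a,sample_b `variant_set` data frames.
#' @param by `"position_alt"` (default) or `"position"`.
#' @return List of class `snp_diff`: `a_only`, `b_only`, `shared` (data
#'   frames sorted by chrom, pos), and `by`.
#' @export
diff_snp_sets <- function(sample_a, sample_b,
                          by = c("position_alt", "position")) {
  by <- match.arg(by)
  key <- function(v) {
    if (by == "position_alt") paste(v$chrom, v$pos, v$alt, sep = ":")
    else paste(v$chrom, v$pos, sep = ":")
  }
  ka <- key(sample_a)
  kb <- key(sample_b)
  sort_v <- function(v) {
    v <- v[order(v$chrom, v$pos, v$alt %||% ""), , drop = FALSE]
    rownames(v) <- NULL
    v
  }
  structure(list(a_only = sort_v(sample_a[!ka %in% kb, , drop = FALSE]),
                 b_only = sort_v(sample_b[!kb %in% ka, , drop = FALSE]),
                 shared = sort_v(sample_a[ka %in% kb, , drop = FALSE]),
                 by = by),
            class = "snp_diff")
}
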