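#' Call enriched narrow peaks against an input track
#'
#' Per-bin one-sided Poisson upper-tail test of the ChIP count against a
#' local background expectation taken from the input channel, in the style
#' of narrow-mode model-free peak callers: the Poisson mean for each bin is
#' the larger of the genome-wide mean and a centered running mean (default
#' +/-5 kb) of the library-ratio-scaled input counts. P-values are adjusted
#' genome-wide by Benjamini-Hochberg; bins with `q <= q_threshold` and a
#' count strictly above expectation are merged into peaks when adjacent.
#'
#' Tag counts are aggregated over a centered sliding window
#' (`2*smooth_bins+1` bins, approximating fragment-pileup smoothing) before
#' testing; window sums of Poisson counts remain Poisson, so the test stays
#' exact.
#'
#' @param chip,input [coverage_track()]s with identical binning.
#' @param q_threshold BH-adjusted significance cutoff (default 0.01).
#' @param local_half_width Half-width in bp of the local background window.
#' @param smooth_bins Half-width in bins of the sliding aggregation window
#'   (0 disables smoothing).
#' @return Data frame of class `peak_set`: `peak_id`, `chrom`, `start`,
#'   `end`, `summit` (bp of the maximum-count bin), `enrichment` (ChIP RPM
#'   minus input RPM per bp over the peak), `pvalue`, `qvalue` (minima over
#'   member bins).
#' @export
call_peaks <- function(chip, input, q_threshold = 0.01,
                       local_half_width = 5000, smooth_bins = 2) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  .check_compatible_tracks(chip, input)
  if (!.is_fraction(q_threshold) || q_threshold <= 0)
    .stopf("`q_threshold` must lie in (0, 1]")
  bw <- chip$bin_width
  half_bins <- as.integer(local_half_width %/% bw)
  # scale input to the chip *background* level: the per-bin median is robust
  # to peak contamination of the chip library, unlike the total-count ratio
  med_chip <- stats::median(unlist(chip$counts, use.names = FALSE))
  med_input <- stats::median(unlist(input$counts, use.names = FALSE))
  ratio <- if (is.finite(med_chip) && is.finite(med_input) &&
               med_chip > 0 && med_input > 0) {
    med_chip / med_input
  } else if (input$library_size > 0) {
    chip$library_size / input$library_size
  } else 1
  scaled <- lapply(input$counts, function(v) v * ratio)
  global_mean <- mean(unlist(scaled, use.names = FALSE))
  lambda <- lapply(scaled, function(v)
    pmax(.running_mean(v, half_bins), global_mean, 1e-9))
  xs <- lapply(chip$counts, .running_sum, half_bins = smooth_bins)
  ls <- lapply(lambda, .running_sum, half_bins = smooth_bins)
  pvals <- mapply(function(x, lam) stats::ppois(x - 1, lam,
                                                lower.tail = FALSE),
                  xs, ls, SIMPLIFY = FALSE)
  qvals_flat <- stats::p.adjust(unlist(pvals, use.names = FALSE),
                                method = "BH")
  nb <- vapply(pvals, length, integer(1))
  qvals <- split(qvals_flat, rep(seq_along(pvals), nb))
  names(qvals) <- names(pvals)
  rows <- list()
  for (chrom in names(chip$counts)) {
    x <- chip$counts[[chrom]]
    sig <- qvals[[chrom]] <= q_threshold & xs[[chrom]] > ls[[chrom]]
    if (!any(sig)) next
    r <- rle(sig)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    keep <- r$values
    lo <- lo[keep]
    hi <- hi[keep]
    run <- rep.int(seq_along(lo), hi - lo + 1L)
    bins <- sequence(hi - lo + 1L, from = lo)
    # per-run aggregates, vectorized over all peaks of the chromosome
    ord <- order(run, -x[bins], bins)
    first_of_run <- !duplicated(run[ord])
    summit_bin <- bins[ord][first_of_run]
    chip_sum <- rowsum(x[bins], run)[, 1]
    input_sum <- rowsum(input$counts[[chrom]][bins], run)[, 1]
    p_min <- vapply(split(pvals[[chrom]][bins], run), min, numeric(1))
    q_min <- vapply(split(qvals[[chrom]][bins], run), min, numeric(1))
    start <- (lo - 1L) * bw
    end <- hi * bw
    chip_rpm <- chip_sum * 1e6 / max(chip$library_size, 1)
    input_rpm <- input_sum * 1e6 / max(input$library_size, 1)
    rows[[chrom]] <- data.frame(
      chrom = chrom, start = start, end = end,
      summit = as.integer((summit_bin - 1L) * bw + bw %/% 2L),
      enrichment = (chip_rpm - input_rpm) / (end - start),
      pvalue = unname(p_min), qvalue = unname(q_min),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               summit = integer(), enrichment = numeric(),
               pvalue = numeric(), qvalue = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$peak_id <- if (nrow(out) > 0)
    sprintf("%s_peak_%d", chip$sample_id, seq_len(nrow(out))) else character()
  rownames(out) <- NULL
  structure(out, bin_width = bw, class = c("peak_set", "data.frame"))
}

# 1:1 matching of overlapping peaks between two replicates; ties broken by
# largest overlap, then leftmost start.
.match_peaks <- function(rep1, rep2) {
  pairs <- list()
  for (chrom in intersect(unique(rep1$chrom), unique(rep2$chrom))) {
    a <- which(rep1$chrom == chrom)
    b <- which(rep2$chrom == chrom)
    ir1 <- IRanges::IRanges(rep1$start[a] + 1L, rep1$end[a])
    ir2 <- IRanges::IRanges(rep2$start[b] + 1L, rep2$end[b])
    ov <- IRanges::findOverlaps(ir1, ir2)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(ir1[qh], ir2[sh]))
    pairs[[chrom]] <- data.frame(i = a[qh], j = b[sh], overlap = w,
                                 start = rep1$start[a[qh]])
  }
  if (length(pairs) == 0)
    return(data.frame(i = integer(), j = integer()))
  p <- do.call(rbind, pairs)
  ord <- order(-p$overlap, p$start)
  pi <- p$i[ord]
  pj <- p$j[ord]
  used_i <- logical(nrow(rep1))
  used_j <- logical(nrow(rep2))
  keep <- logical(length(pi))
  for (k in seq_along(pi)) {
    if (!used_i[pi[k]] && !used_j[pj[k]]) {
      keep[k] <- TRUE
      used_i[pi[k]] <- TRUE
      used_j[pj[k]] <- TRUE
    }
  }
  data.frame(i = pi[keep], j = pj[keep])
}

# Two-component rank-consistency estimate of per-pair irreproducibility.
# Matched peak scores are rank-transformed to [0,1] in each replicate; the
# absolute rank difference d is modelled as a mixture of an irreproducible
# component (d ~ |U-V| for independent uniforms, density 2(1-d)) and a
# reproducible component (truncated exponential concentrated at 0), fitted
# by EM. Returns the posterior probability of the irreproducible component.
.rank_irreproducibility <- function(s1, s2, max_iter = 200, tol = 1e-9) {
  n <- length(s1)
  if (n == 0) return(numeric())
  u1 <- rank(s1, ties.method = "average") / (n + 1)
  u2 <- rank(s2, ties.method = "average") / (n + 1)
  d <- abs(u1 - u2)
  if (all(d < 1e-12)) return(rep(0, n))
  f0 <- 2 * (1 - d)
  pi1 <- 0.8
  lam <- min(1 / max(mean(d), 1e-6), 1e5)
  g <- rep(pi1, n)
  for (it in seq_len(max_iter)) {
    f1 <- lam * exp(-lam * d) / max(1 - exp(-lam), 1e-12)
    g_new <- pi1 * f1 / (pi1 * f1 + (1 - pi1) * f0)
    pi1_new <- min(max(mean(g_new), 1e-4), 1 - 1e-4)
    dbar <- sum(g_new * d) / max(sum(g_new), 1e-12)
    lam_new <- min(1 / max(dbar, 1e-8), 1e6)
    done <- abs(pi1_new - pi1) < tol && abs(lam_new - lam) / lam < tol
    pi1 <- pi1_new
    lam <- lam_new
    g <- g_new
    if (done) break
  }
  1 - g
}

#' Filter peaks for between-replicate reproducibility
#'
#' Matches overlapping peaks between two replicates 1:1 (largest overlap,
#' then leftmost), scores each matched pair's rank consistency on
#' `-log10(pvalue)` via a two-component mixture (see details in the package
#' vignette), and merges pairs whose estimated irreproducibility is at or
#' below `idr_threshold` into consensus tags. With identical replicate lists
#' every pair passes at any threshold; with unrelated replicate scores the
#' passing fraction collapses toward zero.
#'
#' @param rep1,rep2 `peak_set`s from two biological replicates.
#' @param idr_threshold Irreproducibility cutoff (default 0.01, i.e. 1%).
#' @return Data frame of class `consensus_tags`: `tag_id`, `chrom`, `start`,
#'   `end`, `irreproducibility` (max over members), `members`
#'   (semicolon-joined member peak ids). Overlapping merged pairs are
#'   themselves merged.
#' @export
reproducible_peaks <- function(rep1, rep2, idr_threshold = 0.01) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0) {
    message("reproducible_peaks: a replicate has no peaks; empty consensus")
    return(.empty_consensus())
  }
  m <- .match_peaks(rep1, rep2)
  if (nrow(m) == 0) return(.empty_consensus())
  # significance ranks; enrichment breaks the ties left by p-value underflow
  score_rank <- function(p, enr) {
    r <- integer(length(p))
    r[order(p, -enr)] <- seq_along(p)
    -r
  }
  irr <- .rank_irreproducibility(
    score_rank(rep1$pvalue[m$i], rep1$enrichment[m$i]),
    score_rank(rep2$pvalue[m$j], rep2$enrichment[m$j]))
  pass <- irr <= idr_threshold
  if (!any(pass)) return(.empty_consensus())
  merged <- data.frame(
    chrom = rep1$chrom[m$i[pass]],
    start = pmin(rep1$start[m$i[pass]], rep2$start[m$j[pass]]),
    end = pmax(rep1$end[m$i[pass]], rep2$end[m$j[pass]]),
    irr = irr[pass],
    members = paste(rep1$peak_id[m$i[pass]], rep2$peak_id[m$j[pass]],
                    sep = ";"),
    stringsAsFactors = FALSE)
  .reduce_tags(merged)
}

.empty_consensus <- function() {
  structure(data.frame(tag_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       irreproducibility = numeric(), members = character(),
                       stringsAsFactors = FALSE),
            class = c("consensus_tags", "data.frame"))
}

.reduce_tags <- function(df) {
  rows <- list()
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    rows[[chrom]] <- data.frame(
      chrom = chrom,
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      irreproducibility = as.numeric(tapply(d$irr, grp, max)),
      members = as.character(tapply(d$members, grp, paste, collapse = ";")),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- data.frame(tag_id = sprintf("tag_%d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("consensus_tags", "data.frame"))
}

#' Merge consensus tags across conditions into reference tags
#'
#' Takes per-condition consensus tag sets and reduces the union of their
#' intervals into one conglomerate reference set, the coordinate frame on
#' which temporal trajectories are quantified.
#'
#' @param tag_sets List of `consensus_tags` data frames.
#' @return A `consensus_tags` data frame (irreproducibility is the max over
#'   contributing tags).
#' @export
consensus_tags <- function(tag_sets) {
  stopifnot(is.list(tag_sets))
  tag_sets <- Filter(function(x) nrow(x) > 0, tag_sets)
  if (length(tag_sets) == 0) return(.empty_consensus())
  df <- do.call(rbind, lapply(tag_sets, function(x)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               irr = x$irreproducibility, members = x$members,
               stringsAsFactors = FALSE)))
  .reduce_tags(df)
}
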