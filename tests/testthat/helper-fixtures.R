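# shared fixtures: tiny configs and hand-built tracks

tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 60, n_chroms = 1, seed = 11)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# constant-valued single-chromosome track
const_track <- function(value, nbins = 200, bw = 50, chrom = "chr1",
                        lib = NULL, channel = "chip", id = "trk") {
  coverage_track(stats::setNames(list(rep(value, nbins)), chrom), bw,
                 sample_id = id, channel = channel, library_size = lib)
}

# track with a triangular peak (summit height h at bin-aligned summit bp,
# half-width hw) over a constant background
triangle_track <- function(background, h, summit, hw, nbins = 200, bw = 50,
                           chrom = "chr1", lib = NULL, channel = "chip",
                           id = "trk") {
  v <- rep(background, nbins)
  edges <- (seq_len(nbins) - 1L) * bw
  v <- v + h * pmax(0, 1 - abs(edges - summit) / hw)
  coverage_track(stats::setNames(list(v), chrom), bw, sample_id = id,
                 channel = channel, library_size = lib)
}

# minimal annotation data frame
toy_annotation <- function(tss, strand = "+", chrom = "chr1",
                           chrom_len = 1e6, gene_len = 500) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss, tss - gene_len + 1L)
  df <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
                   start = as.integer(start),
                   end = as.integer(start + gene_len),
                   strand = strand, stringsAsFactors = FALSE)
  acetylscape:::.as_annotation(
    df, stats::setNames(rep(chrom_len, length(unique(chrom))),
                        unique(chrom)))
}

# expression matrix with exact condition means and +/- eps replicate spread
toy_expression <- function(means, eps = 1e-3, n_reps = 2) {
  conds <- colnames(means)
  values <- do.call(cbind, lapply(conds, function(cc) {
    sapply(seq_len(n_reps), function(r)
      means[, cc] + eps * (-1)^r)
  }))
  colnames(values) <- paste0(rep(conds, each = n_reps), "_r",
                             rep(seq_len(n_reps), length(conds)))
  rownames(values) <- rownames(means)
  structure(list(values = values,
                 samples = data.frame(
                   sample = colnames(values),
                   condition = rep(conds, each = n_reps),
                   replicate = rep(seq_len(n_reps), length(conds)),
                   stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

# exhaustive two-sided Fisher p over all tables with the observed margins,
# written from the hypergeometric mass with lchoose (independent oracle)
fisher_enumeration_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  hyper <- function(x)
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  xs <- max(0, k - n2):min(k, m)
  probs <- vapply(xs, hyper, numeric(1))
  min(sum(probs[probs <= hyper(a) * (1 + 1e-7)]), 1)
}

# one raw mpileup line with an explicit declared depth
pileup_line <- function(bases, depth, chrom = "chr1", pos = 100,
                        ref = "C") {
  sprintf("%s\t%d\t%s\t%d\t%s\t%s", chrom, pos, ref, depth, bases,
          strrep("I", depth))
}

write_pileup_lines <- function(lines, path = tempfile(fileext = ".pileup")) {
  writeLines(lines, path)
  path
}
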