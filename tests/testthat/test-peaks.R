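test_that("RPM normalization scales linearly and conserves totals", {
  trk <- const_track(200, nbins = 10, lib = 2e6)
  r <- rpm(trk)
  expect_equal(r$counts$chr1, rep(100, 10))
  expect_equal(sum(r$counts$chr1) * trk$library_size / 1e6,
               sum(trk$counts$chr1))
  z <- const_track(0, nbins = 10, lib = 2e6)
  expect_equal(rpm(z)$counts$chr1, rep(0, 10))
  expect_error(rpm(const_track(0, lib = 0)), "zero library")
})

test_that("no peaks are called when chip equals the scaled input", {
  chip <- const_track(5, nbins = 500, channel = "chip")
  input <- const_track(5, nbins = 500, channel = "input")
  pk <- call_peaks(chip, input)
  expect_equal(nrow(pk), 0)
})

test_that("a planted 10x triangular peak is recovered with an exact Poisson p", {
  bg <- 5; h <- 50; bw <- 50; hw <- 250; summit <- 5000
  chip <- triangle_track(bg, h, summit, hw, nbins = 400, bw = bw)
  input <- const_track(bg, nbins = 400, bw = bw, channel = "input")
  pk <- call_peaks(chip, input, q_threshold = 0.01)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$summit - summit), bw)  # summit within one bin
  expect_lte(pk$start, summit)
  expect_gte(pk$end, summit)
  # oracle: scaled lambda is bg per bin; the summit window (+/-2 bins) sums
  # the triangle at bin edges: h*(0.6+0.8+1+0.8+0.6) plus 5 background bins
  x_summit <- 5 * bg + h * (0.6 + 0.8 + 1 + 0.8 + 0.6)
  p_oracle <- ppois(x_summit - 1, 5 * bg, lower.tail = FALSE)
  expect_equal(pk$pvalue, p_oracle, tolerance = 1e-12)
})

test_that("q_threshold = 1 turns every enriched bin into peak cover", {
  counts <- c(5, 5, 9, 5, 5, 5, 9, 9, 5, 5)
  chip <- coverage_track(list(chr1 = counts), 50, channel = "chip")
  input <- coverage_track(list(chr1 = rep(5, 10)), 50, channel = "input",
                          library_size = chip$library_size)
  pk <- call_peaks(chip, input, q_threshold = 1, smooth_bins = 0)
  covered <- sort(unlist(mapply(seq, pk$start / 50 + 1, pk$end / 50,
                                SIMPLIFY = FALSE)))
  expect_equal(covered, which(counts > 5))
})

test_that("raising a planted peak never lowers its significance", {
  bg <- 5
  p_at <- vapply(c(20, 40, 80, 160), function(h) {
    chip <- triangle_track(bg, h, 5000, 250, nbins = 400)
    input <- const_track(bg, nbins = 400, channel = "input",
                         lib = chip$library_size)
    pk <- call_peaks(chip, input)
    pk$pvalue[1]
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("identical replicate peak lists all pass reproducibility", {
  chip <- triangle_track(5, 50, 5000, 250, nbins = 400)
  set.seed(1)
  many <- coverage_track(list(chr1 = rpois(400, 5) +
                                as.integer(runif(400) < 0.1) * 60), 50)
  input <- const_track(5, nbins = 400, channel = "input",
                       lib = many$library_size)
  pk <- call_peaks(many, input)
  expect_gt(nrow(pk), 5)
  tags <- reproducible_peaks(pk, pk, idr_threshold = 1e-6)
  expect_equal(nrow(tags), nrow(pk))  # every pair passes, nothing merged away
  expect_true(all(tags$irreproducibility <= 1e-6))
})

test_that("permuted replicate scores collapse the passing fraction", {
  pass_frac <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 300
    start <- sort(sample.int(1e6, n)) * 2L
    pk1 <- structure(
      data.frame(chrom = "chr1", start = start, end = start + 500,
                 summit = start + 250L,
                 enrichment = runif(n), pvalue = 10^-runif(n, 1, 50),
                 qvalue = 0, peak_id = sprintf("p%d", 1:n),
                 stringsAsFactors = FALSE),
      class = c("peak_set", "data.frame"))
    pk2 <- pk1
    prm <- sample.int(n)
    pk2$pvalue <- pk1$pvalue[prm]
    pk2$enrichment <- pk1$enrichment[prm]
    tags <- suppressMessages(reproducible_peaks(pk1, pk2,
                                                idr_threshold = 0.01))
    nrow(tags) / n
  }, numeric(1))
  expect_lt(mean(pass_frac), 0.1)
})

test_that("reproducibility filtering is symmetric and handles empties", {
  cfg <- tiny_cfg(seed = 23)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tracks <- make_tracks(cfg, ann, truth)
  p1 <- call_peaks(tracks$d0$r1$chip, tracks$d0$r1$input)
  p2 <- call_peaks(tracks$d0$r2$chip, tracks$d0$r2$input)
  t12 <- reproducible_peaks(p1, p2)
  t21 <- reproducible_peaks(p2, p1)
  expect_equal(t12[c("chrom", "start", "end")],
               t21[c("chrom", "start", "end")])

  empty <- p1[0, ]
  expect_message(out <- reproducible_peaks(empty, p2), "no peaks")
  expect_equal(nrow(out), 0)

  # non-overlapping replicate lists give an empty consensus
  p2_shift <- p2
  p2_shift$start <- p2$start + 1e6
  p2_shift$end <- p2$end + 1e6
  expect_equal(nrow(reproducible_peaks(p1, p2_shift)), 0)
})

test_that("FRiP is 1 when all tags fall inside peaks and 0 without peaks", {
  counts <- rep(0, 100); counts[40:45] <- 20
  trk <- coverage_track(list(chr1 = counts), 50)
  peaks <- data.frame(chrom = "chr1", start = 39 * 50, end = 45 * 50)
  expect_equal(qc_frip(trk, peaks), 1)
  expect_equal(qc_frip(trk, peaks[0, ]), 0)
  half <- data.frame(chrom = "chr1", start = 39 * 50, end = 42 * 50)
  expect_equal(qc_frip(trk, half), sum(counts[40:42]) / sum(counts))
})

test_that("replicate correlation is 1 against itself and ~0 under the null", {
  cfg <- tiny_cfg(n_genes = 80, seed = 31)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tracks <- make_tracks(cfg, ann, truth)
  a <- tracks$d0$r1$chip
  expect_equal(qc_replicate_correlation(a, a, ann), 1)
  set.seed(5)
  nb <- length(a$counts$chr1)
  null1 <- coverage_track(list(chr1 = rpois(nb, 3)), a$bin_width)
  null2 <- coverage_track(list(chr1 = rpois(nb, 3)), a$bin_width)
  r <- qc_replicate_correlation(null1, null2, ann)
  expect_lt(abs(r), 2.5 * 2 / sqrt(80))
})

test_that("TSS metaprofiles are symmetric and strand-orientation invariant", {
  bw <- 50; W <- 500
  ann_plus <- toy_annotation(tss = c(5000, 20000))
  chip <- triangle_track(2, 40, 5000, 250, nbins = 500, bw = bw)
  chip$counts$chr1 <- chip$counts$chr1 +
    40 * pmax(0, 1 - abs((0:499) * bw - 20000) / 250)
  input <- const_track(2, nbins = 500, bw = bw, channel = "input",
                       lib = chip$library_size)
  prof <- tss_metaprofile(chip, input, ann_plus, window = W)
  k <- length(prof$chip)
  expect_equal(prof$chip[2:k], rev(prof$chip)[1:(k - 1)], tolerance = 1e-12)

  # mirrored genome + minus-strand annotation reproduces the same profile
  L <- 500 * bw
  mirror <- chip
  mirror$counts$chr1 <- rev(chip$counts$chr1)
  m_input <- input
  m_input$counts$chr1 <- rev(input$counts$chr1)
  ann_minus <- toy_annotation(tss = L - 1 - c(5000, 20000), strand = "-",
                              chrom_len = L)
  prof_m <- tss_metaprofile(mirror, m_input, ann_minus, window = W)
  expect_equal(prof_m$chip, prof$chip, tolerance = 1e-12)
  expect_equal(prof_m$input, prof$input, tolerance = 1e-12)
})

test_that("metaprofile central enrichment tracks the planted decay", {
  cfg <- synth_config(n_genes = 300, n_chroms = 1, frac_deg = 0.5,
                      planted_or = 1, change_rate_nondeg = 0.99,
                      frac_pattern_b = 0, seed = 77)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tracks <- make_tracks(cfg, ann, truth)
  # force a common RPM scale so the ratio reflects counts, not library drift
  setlib <- function(trk) { trk$library_size <- 1e6; trk }
  p0 <- tss_metaprofile(setlib(tracks$d0$r1$chip), setlib(tracks$d0$r1$input),
                        ann, window = 500)
  p9 <- tss_metaprofile(setlib(tracks$d9$r1$chip), setlib(tracks$d9$r1$input),
                        ann, window = 500)
  centre <- (length(p0$chip) %/% 2):(length(p0$chip) %/% 2 + 1)
  ratio <- sum(p9$chip[centre] - p9$input[centre]) /
    sum(p0$chip[centre] - p0$input[centre])
  expect_equal(ratio, 0.3, tolerance = 0.05)
})
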