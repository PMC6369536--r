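test_that("annotation layout respects spacing, strand convention and sizing", {
  cfg <- synth_config(n_genes = 10, gene_spacing = 10000,
                      genome_length = 200000, seed = 4)
  ann <- make_annotation(cfg)
  expect_equal(nrow(ann), 10)
  expect_false(anyDuplicated(ann$gene_id) > 0)
  # non-overlap within each chromosome
  for (chrom in unique(ann$chrom)) {
    a <- ann[ann$chrom == chrom, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1)
      expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }
  # TSS is the 5' end: start for +, end-1 for -
  expect_equal(ann$tss[ann$strand == "+"], ann$start[ann$strand == "+"])
  expect_equal(ann$tss[ann$strand == "-"], ann$end[ann$strand == "-"] - 1L)
  expect_true(all(ann$tss >= ann$start & ann$tss < ann$end))
})

test_that("empty annotation is valid and survives a file round trip", {
  cfg <- synth_config(n_genes = 0, seed = 1)
  ann <- make_annotation(cfg)
  expect_equal(nrow(ann), 0)
  path <- tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(nrow(back), 0)
})

test_that("a genome too small for the requested genes is rejected", {
  expect_error(synth_config(n_genes = 100, gene_spacing = 10000,
                            genome_length = 50000),
               "genome too small")
})

test_that("simulated summit coverage matches the analytic Poisson mean", {
  cfg <- tiny_cfg(seed = 21)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tracks <- make_tracks(cfg, ann, truth)
  # analytic mean at the summit bin of each TSS peak, derived here from the
  # triangle definition rather than the generator internals
  tp_mult <- function(pat, ti)
    switch(pat, A = cfg$peak_height_grid$A[ti],
           B = cfg$peak_height_grid$B_tss[ti],
           flat = cfg$peak_height_grid$flat[ti])
  for (ti in c(1L, 4L)) {
    lam <- obs <- 0
    for (r in seq_len(cfg$n_reps_chip)) {
      trk <- tracks[[cfg$time_points[ti]]][[r]]$chip
      for (i in seq_len(nrow(ann))) {
        bin <- ann$tss[i] %/% cfg$bin_width + 1L
        # triangle is evaluated at bin left edges; minus-strand TSSs sit
        # inside their bin, so the summit bin sees a reduced height
        off <- ann$tss[i] - (bin - 1L) * cfg$bin_width
        lam <- lam + cfg$background_rate * cfg$bin_width +
          cfg$peak_summit_rate * truth$genes$peak_strength[i] *
          tp_mult(truth$genes$pattern[i], ti) *
          (1 - off / cfg$peak_half_width)
        obs <- obs + trk$counts[[ann$chrom[i]]][bin]
      }
    }
    # total over ~120 summit bins is Poisson(lam): check within 4 sd
    expect_lt(abs(obs - lam), 4 * sqrt(lam))
  }
})

test_that("zero background rate gives all-zero input tracks", {
  cfg <- tiny_cfg(background_rate = 0, seed = 5)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tracks <- make_tracks(cfg, ann, truth)
  for (tp in cfg$time_points)
    expect_true(all(unlist(tracks[[tp]][[1]]$input$counts) == 0))
})

test_that("equal seeds give identical tracks and tags are conserved", {
  cfg <- tiny_cfg(seed = 9)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  t1 <- make_tracks(cfg, ann, truth)
  t2 <- make_tracks(cfg, ann, truth)
  expect_identical(t1, t2)
  trk <- t1$d0$r1$chip
  expect_equal(sum(unlist(trk$counts)), trk$library_size)
})

test_that("planted A and B patterns separate in the d3 -> d6 increment", {
  cfg <- tiny_cfg(n_genes = 120, frac_pattern_b = 0.3, seed = 30)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tracks <- make_tracks(cfg, ann, truth)
  summit_cov <- function(tp, summits, chroms) {
    trk <- tracks[[tp]][[1]]$chip
    sum(vapply(seq_along(summits), function(i)
      trk$counts[[chroms[i]]][summits[i] %/% cfg$bin_width + 1L],
      numeric(1)))
  }
  a_sel <- truth$genes$pattern == "A"
  b_sel <- truth$genes$pattern == "B"
  dir <- ifelse(ann$strand == "+", 1L, -1L)
  body <- ann$tss + dir * cfg$pattern_b_offset
  expect_lt(summit_cov("d6", ann$tss[a_sel], ann$chrom[a_sel]),
            summit_cov("d3", ann$tss[a_sel], ann$chrom[a_sel]))
  expect_gt(summit_cov("d6", body[b_sel], ann$chrom[b_sel]),
            summit_cov("d3", body[b_sel], ann$chrom[b_sel]))
})

test_that("planted_or = 1 decouples peak change from DEG status", {
  cfg <- synth_config(n_genes = 4000, planted_or = 1, seed = 2)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tab <- build_table(
    stats::setNames(truth$genes$deg, truth$genes$gene_id),
    stats::setNames(truth$genes$peak_change, truth$genes$gene_id),
    universe = truth$genes$gene_id)
  or <- odds_ratio_test(tab)
  expect_lt(abs(log(or$odds_ratio)), 0.3)
})

test_that("coupling calibration: truth odds ratio averages to planted_or", {
  ors <- vapply(1:20, function(s) {
    cfg <- synth_config(n_genes = 5000, planted_or = 3, seed = 100 + s)
    ann <- make_annotation(cfg)
    truth <- make_truth(cfg, ann)
    tab <- build_table(
      stats::setNames(truth$genes$deg, truth$genes$gene_id),
      stats::setNames(truth$genes$peak_change, truth$genes$gene_id),
      universe = truth$genes$gene_id)
    odds_ratio_test(tab)$odds_ratio
  }, numeric(1))
  expect_lt(abs(mean(ors) - 3) / 3, 0.10)
})

test_that("zero expression noise gives identical replicates", {
  cfg <- tiny_cfg(noise_sd = 0, seed = 8)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  em <- make_expression(cfg, truth)
  for (cc in unique(em$samples$condition)) {
    v <- em$values[, em$samples$condition == cc, drop = FALSE]
    expect_true(all(v == v[, 1]))
  }
})

test_that("rescue movement encodes the planted class geometry", {
  cfg <- tiny_cfg(n_genes = 400, noise_sd = 0, seed = 14)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  em <- make_expression(cfg, truth)
  cm <- rowMeans(em$values[, em$samples$condition == "control"])
  dm <- rowMeans(em$values[, em$samples$condition == "depleted"])
  tm <- rowMeans(em$values[, em$samples$condition == "treated"])
  g <- truth$genes
  full <- g$rescue_class == "full"
  expect_equal(tm[full], cm[full])
  part <- g$rescue_class == "partial"
  expect_equal(tm[part] - cm[part],
               (dm[part] - cm[part]) * (1 - cfg$rescue_movement[["partial"]]))
  none <- g$rescue_class == "not_sensitive"
  expect_equal(tm[none], dm[none])
})

test_that("generated pileups carry planted variants and parse cleanly", {
  cfg <- tiny_cfg(seed = 17, n_variants = 8)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  pu <- make_pileups(cfg, truth)
  path <- tempfile(fileext = ".pileup")
  write_pileup(pu$sample_a, path)
  cols <- read_pileup(path)  # declared-vs-parsed depth validated on read
  expect_equal(nrow(cols), nrow(pu$sample_a))
  # the planted sub-threshold insertion is visible to the parser
  n_ins <- sum(vapply(cols$indels, function(x)
    sum(x$count[x$type == "ins"]), numeric(1)))
  expect_gt(n_ins, 0)
  # high-fraction variants dominate their columns
  v <- truth$variants[truth$variants$frac_a >= 0.9, ]
  key <- paste(cols$chrom, cols$pos)
  for (i in seq_len(nrow(v))) {
    row <- cols[key == paste(v$chrom[i], v$pos[i]), ]
    expect_gt(row[[v$alt[i]]] / row$depth, 0.5)
  }
})

test_that("infeasible coupling configurations are rejected at config time", {
  expect_error(synth_config(change_rate_nondeg = 0), "feasible")
  expect_error(synth_config(frac_deg = 1), "frac_deg")
  expect_error(synth_config(planted_or = -1), "odds ratio")
})
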