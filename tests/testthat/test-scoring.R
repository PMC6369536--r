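test_that("AUC score handles constant, equal and triangular enrichment", {
  # 0.4 RPM/bp chip vs 0.1 RPM/bp input over a 500-bp tag -> 0.3 exactly
  chip <- const_track(20, lib = 1e6)                 # 20 RPM/bin = 0.4/bp
  input <- const_track(5, lib = 1e6, channel = "input")
  tag <- data.frame(chrom = "chr1", start = 2000, end = 2500)
  expect_equal(auc_score(tag, chip, input), 0.3, tolerance = 1e-12)

  expect_equal(auc_score(tag, chip, chip), 0, tolerance = 1e-15)

  # triangular peak: discrete sum equals the closed-form integral h*hw/bw
  bg <- 5; h <- 37; hw <- 250; bw <- 50; summit <- 5000
  chip_t <- triangle_track(bg, h, summit, hw, nbins = 400, lib = 1e6)
  input_t <- const_track(bg, nbins = 400, lib = 1e6, channel = "input")
  tag_t <- data.frame(chrom = "chr1", start = summit - hw, end = summit + hw)
  expected <- (h * hw / bw) * (1e6 / 1e6) / (2 * hw)
  got <- auc_score(tag_t, chip_t, input_t)
  expect_lt(abs(got - expected) / expected, 1e-9)

  expect_error(auc_score(data.frame(chrom = "chr1", start = 5, end = 5),
                         chip, input), "zero-length")
})

test_that("AUC is additive over a split tag (length-weighted mean)", {
  set.seed(3)
  chip <- coverage_track(list(chr1 = rpois(200, 8)), 50, lib = 2e6)
  input <- coverage_track(list(chr1 = rpois(200, 4)), 50, lib = 1e6,
                          channel = "input")
  whole <- data.frame(chrom = "chr1", start = 1000, end = 4000)
  parts <- data.frame(chrom = "chr1", start = c(1000, 1720, 2500),
                      end = c(1720, 2500, 4000))
  v_whole <- auc_score(whole, chip, input)
  v_parts <- auc_score(parts, chip, input)
  w <- parts$end - parts$start
  expect_equal(sum(v_parts * w) / sum(w), v_whole, tolerance = 1e-12)
})

test_that("AUC responds to library scaling exactly as RPM demands", {
  chip <- const_track(20, lib = 1e6)
  input <- const_track(5, lib = 1e6, channel = "input")
  tag <- data.frame(chrom = "chr1", start = 2000, end = 2500)
  base <- auc_score(tag, chip, input)

  # doubling counts and libraries together leaves the score unchanged
  chip2 <- chip; chip2$counts$chr1 <- chip$counts$chr1 * 2
  chip2$library_size <- 2e6
  input2 <- input; input2$counts$chr1 <- input$counts$chr1 * 2
  input2$library_size <- 2e6
  expect_equal(auc_score(tag, chip2, input2), base, tolerance = 1e-12)

  # doubling libraries with unchanged counts halves the score
  chip3 <- chip; chip3$library_size <- 2e6
  input3 <- input; input3$library_size <- 2e6
  expect_equal(auc_score(tag, chip3, input3), base / 2, tolerance = 1e-12)
})

test_that("tags are assigned to the nearest TSS within the 2-kb window", {
  ann <- toy_annotation(tss = 10000)
  # 1,500 bp upstream of the TSS -> assigned
  a <- assign_to_gene(data.frame(chrom = "chr1", start = 11500, end = 11900),
                      ann)
  expect_equal(a$gene_id, "g001")
  expect_equal(a$distance, 1500)
  # 2,500 bp away -> beyond the promoter window, unassigned
  a <- assign_to_gene(data.frame(chrom = "chr1", start = 12500, end = 12900),
                      ann)
  expect_true(is.na(a$gene_id))
  # TSS inside the tag -> distance zero
  a <- assign_to_gene(data.frame(chrom = "chr1", start = 9900, end = 10200),
                      ann)
  expect_equal(a$distance, 0)
  # exactly at the cutoff is still assigned
  a <- assign_to_gene(data.frame(chrom = "chr1", start = 12000, end = 12400),
                      ann)
  expect_equal(a$gene_id, "g001")
  expect_equal(a$distance, 2000)
})

test_that("equidistant TSS ties break to the smaller gene id, deterministically", {
  ann <- toy_annotation(tss = c(10000, 14000))
  tag <- data.frame(chrom = "chr1", start = 11900, end = 12100)
  # distances: left 11900-10000 = 1900; right 14000-12099 = 1901 -> left
  a <- assign_to_gene(tag, ann)
  expect_equal(a$gene_id, "g001")
  tag_tied <- data.frame(chrom = "chr1", start = 11901, end = 12100)
  # both distances 1901 -> lexicographically smaller id
  for (i in 1:3)
    expect_equal(assign_to_gene(tag_tied, ann)$gene_id, "g001")
  # restricting the eligible gene set redirects the assignment
  a <- assign_to_gene(tag, ann, genes = "g002")
  expect_equal(a$gene_id, "g002")
})

test_that("trajectories are centered, floored, and flag planted changes", {
  tags <- sprintf("t%d", 1:3)
  times <- c("d0", "d3", "d6", "d9")
  base <- c(100, 100, 40)
  mult <- rbind(c(1, 1, 1, 1),                # flat
                c(1, 0.7, 0.45, 0.3),         # decaying
                c(1, 1, 1, 1))
  scores <- array(NA_real_, c(3, 4, 2), dimnames = list(tags, times, NULL))
  counts <- scores
  for (r in 1:2) {
    scores[, , r] <- base * mult
    counts[, , r] <- 50 * base * mult
  }
  libs <- matrix(1e5, 4, 2, dimnames = list(times, NULL))
  tm <- build_trajectories(scores, counts = counts, lib_sizes = libs,
                           test = "count")
  expect_equal(unname(tm$lfc[, "d0"]), c(0, 0, 0))
  expect_equal(unname(tm$lfc["t1", ]), rep(0, 4))
  expect_true(all(diff(tm$lfc["t2", ]) < 0))     # strictly decreasing
  expect_equal(unname(tm$lfc["t2", "d9"]), log2(0.3), tolerance = 1e-12)
  expect_true(tm$changed[["t2"]])
  expect_false(tm$changed[["t1"]])

  # a missing replicate falls back to the mean of the remaining ones
  scores[1, "d3", 2] <- NA
  tm2 <- build_trajectories(scores, counts = counts, lib_sizes = libs,
                            test = "count")
  expect_equal(unname(tm2$lfc["t1", "d3"]), 0)
  expect_true(tm2$imputed[["t1"]])
})

test_that("tags with no positive score are dropped with a message", {
  scores <- array(c(-1, 5), c(2, 2, 2),
                  dimnames = list(c("neg", "pos"), c("d0", "d9"), NULL))
  scores["neg", , ] <- -1
  scores["pos", , ] <- 5
  expect_message(tm <- build_trajectories(scores, test = "t"), "dropped 1")
  expect_equal(tm$tag_ids, "pos")
})

test_that("trajectory clustering recovers planted patterns and is order-stable", {
  set.seed(9)
  n_a <- 60; n_b <- 10
  a_rows <- matrix(rep(c(0, -0.5, -1.2, -1.7), each = n_a), n_a) +
    rnorm(n_a * 4, 0, 0.1)
  b_rows <- matrix(rep(c(0, 0.6, 0.9, -0.8), each = n_b), n_b) +
    rnorm(n_b * 4, 0, 0.1)
  m <- rbind(a_rows, b_rows)
  rownames(m) <- sprintf("t%02d", seq_len(nrow(m)))
  colnames(m) <- c("d0", "d3", "d6", "d9")
  cl <- cluster_trajectories(m, k = 2)
  expect_equal(unname(cl$label[1:n_a]), rep("A", n_a))
  expect_equal(unname(cl$label[(n_a + 1):(n_a + n_b)]), rep("B", n_b))

  prm <- sample.int(nrow(m))
  cl_prm <- cluster_trajectories(m[prm, ], k = 2)
  expect_equal(cl_prm$label[match(cl$tag_id, cl_prm$tag_id)], cl$label)

  expect_error(cluster_trajectories(m[1:3, ], k = 5), "k = 5")
})

test_that("identical trajectories fall through the shape rule to 'other'", {
  m <- matrix(0, 10, 4,
              dimnames = list(sprintf("t%d", 1:10), c("d0", "d3", "d6", "d9")))
  cl <- cluster_trajectories(m, k = 2)
  expect_true(all(cl$label == "other"))
})

test_that("summit-mode assignment uses the summit coordinate only", {
  ann <- toy_annotation(tss = 10000)
  tag <- data.frame(chrom = "chr1", start = 11500, end = 14500,
                    summit = 13000L)
  expect_equal(assign_to_gene(tag, ann)$distance, 1500)          # interval
  expect_true(is.na(assign_to_gene(tag, ann, mode = "summit")$gene_id))
  tag$summit <- 11800L
  expect_equal(assign_to_gene(tag, ann, mode = "summit")$distance, 1800)
})
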