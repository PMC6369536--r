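#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator that emulates the
#' structure of a progressive mtDNA-depletion time course: a small genome with
#' promoter acetylation peaks whose heights follow planted temporal patterns,
#' an expression matrix whose differential-expression status is statistically
#' coupled to promoter peak change at a planted odds ratio, a treatment arm
#' that rescues a subset of the expression changes, and mpileup files with
#' planted single-nucleotide variants.
#'
#' Defaults mirror the emulated study design: four depletion time points
#' (days 0/3/6/9), two ChIP replicates and three expression replicates per
#' condition, ~30% differentially expressed genes, a planted peak-change /
#' DEG odds ratio of 2.4, and ~70% of treatment-sensitive genes rescued
#' (split between full and partial rescue).
#'
#' @param n_genes Number of gene models.
#' @param n_chroms Number of chromosomes genes are spread over.
#' @param gene_spacing Genomic slot size per gene (bp).
#' @param gene_length Gene body length (bp).
#' @param genome_length Total genome size (bp); computed from the gene layout
#'   when `NULL`. Supplying a value too small for the requested genes is an
#'   error.
#' @param frac_deg Fraction of genes that are differentially expressed
#'   (depleted vs control).
#' @param planted_or Odds ratio coupling promoter peak change to DEG status.
#' @param change_rate_nondeg Marginal probability that a non-DEG gene carries
#'   a peak change. The study does not pin this marginal down, so it is an
#'   explicit parameter; together with `frac_deg` and `planted_or` it fixes
#'   the 2x2 coupling table.
#' @param time_points Ordered condition labels of the depletion time course.
#' @param n_reps_chip ChIP/input replicates per time point.
#' @param n_reps_expr Expression replicates per condition.
#' @param bin_width Coverage bin width (bp).
#' @param peak_half_width Half-width of the triangular promoter peak (bp);
#'   must be a multiple of `bin_width` so peak areas have a closed form.
#' @param peak_summit_rate Expected tags per bin at the summit of a
#'   full-height (multiplier 1.0, strength 1.0) peak.
#' @param peak_strength_sdlog Lognormal sdlog of the per-gene peak strength
#'   multiplier (constant across time and replicates), emulating the broad
#'   intensity distribution of real promoter peaks; 0 gives identical
#'   strengths.
#' @param peak_height_grid Per-pattern enrichment multipliers over
#'   `time_points`: pattern `A` decays monotonically, pattern `B` keeps the
#'   decaying TSS peak (`B_tss`) but gains a transient displaced peak in the
#'   gene body (`B_body`), `flat` is constant.
#' @param pattern_b_offset Displacement (bp) of the pattern-B gene-body peak
#'   downstream of the TSS.
#' @param frac_pattern_b Among genes with a peak change, fraction following
#'   pattern B (the rest follow pattern A).
#' @param background_rate Expected background tags per bp (both channels).
#' @param read_depth Optional target expected tags per library; when given,
#'   all rates are scaled so the expected total matches it.
#' @param baseline_expr Mean baseline log2 expression.
#' @param deg_logfc Magnitude of the planted DEG log2 fold change (sign
#'   random per gene).
#' @param noise_sd Log2-scale expression noise SD per replicate.
#' @param sensitive_fraction Fraction of DEGs whose expression responds to
#'   the treatment arm.
#' @param rescue_fraction Fraction of sensitive genes whose change is fully
#'   or partially rescued (split evenly); the remainder are exacerbated.
#' @param rescue_movement Named movement fractions toward the control mean
#'   for each generated rescue class (negative = moves away).
#' @param n_variants Planted single-nucleotide variants in the pileups.
#' @param pileup_depth Read depth per pileup column.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1000,
                         n_chroms = 2,
                         gene_spacing = 2000,
                         gene_length = 1000,
                         genome_length = NULL,
                         frac_deg = 0.30,
                         planted_or = 2.4,
                         change_rate_nondeg = 0.30,
                         time_points = c("d0", "d3", "d6", "d9"),
                         n_reps_chip = 2,
                         n_reps_expr = 3,
                         bin_width = 50,
                         peak_half_width = 250,
                         peak_summit_rate = 40,
                         peak_strength_sdlog = 0.5,
                         peak_height_grid = list(
                           A      = c(1.00, 0.70, 0.45, 0.30),
                           B_tss  = c(1.00, 0.70, 0.45, 0.30),
                           B_body = c(0.30, 1.20, 1.60, 0.40),
                           flat   = c(1.00, 1.00, 1.00, 1.00)),
                         pattern_b_offset = 600,
                         frac_pattern_b = 0.10,
                         background_rate = 0.1,
                         read_depth = NULL,
                         baseline_expr = 8,
                         deg_logfc = 2,
                         noise_sd = 0.25,
                         sensitive_fraction = 0.18,
                         rescue_fraction = 0.70,
                         rescue_movement = c(full = 1, partial = 0.7,
                                             exacerbated = -0.75),
                         n_variants = 12,
                         pileup_depth = 40,
                         seed = 1L) {
  cfg <- as.list(environment())
  cfg$pad <- 2L * max(2000L, as.integer(peak_half_width + pattern_b_offset))
  if (!.is_count(n_genes)) .stopf("`n_genes` must be a non-negative integer")
  if (!.is_count(n_chroms, positive = TRUE)) .stopf("`n_chroms` must be positive")
  if (!.is_count(gene_spacing, positive = TRUE) ||
      !.is_count(gene_length, positive = TRUE) || gene_length > gene_spacing)
    .stopf("`gene_length` must be a positive integer no larger than `gene_spacing`")
  needed <- .synth_genome_length(cfg)
  if (is.null(genome_length)) {
    cfg$genome_length <- needed
  } else if (genome_length < needed) {
    .stopf(paste0("genome too small: %d genes with spacing %d on %d ",
                  "chromosome(s) need >= %d bp, got %d"),
           n_genes, gene_spacing, n_chroms, needed, genome_length)
  }
  if (!(frac_deg > 0 && frac_deg < 1))
    .stopf("`frac_deg` must lie strictly inside (0, 1)")
  if (!is.numeric(planted_or) || planted_or < 0)
    .stopf("`planted_or` must be a non-negative odds ratio")
  if (!(change_rate_nondeg > 0 && change_rate_nondeg < 1))
    .stopf(paste0("`change_rate_nondeg` = %g leaves no feasible 2x2 coupling ",
                  "table for planted_or = %g; it must lie strictly inside ",
                  "(0, 1)"), change_rate_nondeg, planted_or)
  if (length(time_points) < 2 || anyDuplicated(time_points))
    .stopf("`time_points` must be >= 2 unique ordered labels")
  for (nm in c("A", "B_tss", "B_body", "flat")) {
    if (length(peak_height_grid[[nm]]) != length(time_points))
      .stopf("peak_height_grid$%s must have one multiplier per time point", nm)
    if (any(peak_height_grid[[nm]] < 0))
      .stopf("peak height multipliers must be non-negative")
  }
  if (!.is_count(n_reps_chip, positive = TRUE) ||
      !.is_count(n_reps_expr, positive = TRUE))
    .stopf("replicate counts must be positive integers")
  if (peak_half_width %% bin_width != 0)
    .stopf("`peak_half_width` must be a multiple of `bin_width`")
  if (background_rate < 0 || peak_summit_rate < 0 || noise_sd < 0 ||
      peak_strength_sdlog < 0)
    .stopf("rates and noise must be non-negative")
  if (!.is_fraction(frac_pattern_b) || !.is_fraction(sensitive_fraction) ||
      !.is_fraction(rescue_fraction))
    .stopf("fractions must lie in [0, 1]")
  if (!all(c("full", "partial", "exacerbated") %in% names(rescue_movement)))
    .stopf("`rescue_movement` must name full, partial and exacerbated")
  if (!.is_count(seed)) .stopf("`seed` must be a non-negative integer")
  structure(cfg, class = "synth_config")
}

.synth_genome_length <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  cfg$n_chroms * (per_chrom * cfg$gene_spacing + 2L * cfg$pad)
}

# P(change | DEG) implied by the coupling odds ratio
.coupling_p1 <- function(planted_or, p0) {
  odds1 <- planted_or * p0 / (1 - p0)
  odds1 / (1 + odds1)
}

#' Generate the synthetic genome annotation
#'
#' Lays out `n_genes` non-overlapping gene models over `n_chroms`
#' chromosomes, one per `gene_spacing` slot, with random strand. The TSS is
#' the 5' end: `start` for plus-strand genes, `end - 1` for minus-strand
#' genes (0-based half-open coordinates).
#'
#' @param cfg A [synth_config()].
#' @return A `genome_annotation` data frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`, plus a `chrom_lengths` attribute.
#' @export
make_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  per_chrom <- ceiling(cfg$n_genes / max(cfg$n_chroms, 1L))
  chrom_len <- per_chrom * cfg$gene_spacing + 2L * cfg$pad
  chrom_len <- ceiling(chrom_len / cfg$bin_width) * cfg$bin_width
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  if (cfg$n_genes == 0) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), tss = integer(),
                      stringsAsFactors = FALSE)
    return(.as_annotation(ann, stats::setNames(rep(chrom_len, cfg$n_chroms),
                                               chroms)))
  }
  idx <- seq_len(cfg$n_genes) - 1L
  chrom_i <- idx %/% per_chrom + 1L
  slot <- idx %% per_chrom
  offset <- (cfg$gene_spacing - cfg$gene_length) %/% 2L
  offset <- (offset %/% cfg$bin_width) * cfg$bin_width  # bin-aligned TSSs
  start <- cfg$pad + slot * cfg$gene_spacing + offset
  end <- start + cfg$gene_length
  strand <- .with_seed(cfg$seed, sample(c("+", "-"), cfg$n_genes,
                                        replace = TRUE))
  ann <- data.frame(
    gene_id = sprintf("g%05d", seq_len(cfg$n_genes)),
    chrom = chroms[chrom_i],
    start = as.integer(start),
    end = as.integer(end),
    strand = strand,
    stringsAsFactors = FALSE)
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  .as_annotation(ann, stats::setNames(rep(chrom_len, cfg$n_chroms), chroms))
}

.as_annotation <- function(df, chrom_lengths) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
  if (anyDuplicated(df$gene_id)) .stopf("gene ids must be unique")
  if (any(df$start >= df$end)) .stopf("gene start must be < end")
  if (is.null(df$tss))
    df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  structure(df, chrom_lengths = chrom_lengths,
            class = c("genome_annotation", "data.frame"))
}

#' Draw the per-gene ground-truth ledger
#'
#' Samples DEG status, promoter peak-change status (coupled at the planted
#' odds ratio), temporal peak pattern (A: monotone decay; B: transient
#' displaced gain; flat: no change), treatment sensitivity and rescue class,
#' and the planted variant table for the pileup generator.
#'
#' @param cfg A [synth_config()].
#' @param ann Annotation from [make_annotation()].
#' @return A list of class `truth_ledger` with elements `genes` and
#'   `variants`.
#' @export
make_truth <- function(cfg, ann) {
  stopifnot(inherits(cfg, "synth_config"), inherits(ann, "genome_annotation"))
  n <- nrow(ann)
  p0 <- cfg$change_rate_nondeg
  p1 <- .coupling_p1(cfg$planted_or, p0)
  genes <- .with_seed(cfg$seed + 1L, {
    deg <- stats::runif(n) < cfg$frac_deg
    change <- stats::runif(n) < ifelse(deg, p1, p0)
    pattern <- ifelse(change,
                      ifelse(stats::runif(n) < cfg$frac_pattern_b, "B", "A"),
                      "flat")
    sign <- sample(c(-1, 1), n, replace = TRUE)
    logfc <- ifelse(deg, sign * cfg$deg_logfc, 0)
    sensitive <- deg & stats::runif(n) < cfg$sensitive_fraction
    u <- stats::runif(n)
    rescue <- rep("not_sensitive", n)
    rescue[sensitive] <- ifelse(
      u[sensitive] < cfg$rescue_fraction / 2, "full",
      ifelse(u[sensitive] < cfg$rescue_fraction, "partial", "exacerbated"))
    baseline <- stats::rnorm(n, cfg$baseline_expr, 1)
    strength <- stats::rlnorm(n, 0, cfg$peak_strength_sdlog)
    data.frame(gene_id = ann$gene_id, pattern = pattern,
               peak_change = change, deg = deg, logfc = logfc,
               sensitive = sensitive, rescue_class = rescue,
               baseline = baseline, peak_strength = strength,
               stringsAsFactors = FALSE)
  })
  variants <- .with_seed(cfg$seed + 11L, .plant_variants(cfg, ann))
  structure(list(genes = genes, variants = variants), class = "truth_ledger")
}

.plant_variants <- function(cfg, ann) {
  nv <- cfg$n_variants
  chrom_lengths <- attr(ann, "chrom_lengths")
  if (nv == 0 || length(chrom_lengths) == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), frac_a = numeric(),
                      frac_b = numeric(), stringsAsFactors = FALSE))
  }
  chrom <- sample(names(chrom_lengths), nv, replace = TRUE)
  pos <- vapply(chrom, function(cc)
    sample.int(chrom_lengths[[cc]] - 10L, 1L) + 5L, integer(1))
  # spread variants so no two columns (variant or flanking context) collide
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  if (nv > 1) {
    for (i in 2:nv) {
      if (chrom[i] == chrom[i - 1] && pos[i] - pos[i - 1] < 5L)
        pos[i] <- pos[i - 1] + 5L
    }
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  # scenarios: sample-A-only, sample-B-only, shared, and sub-threshold
  scen <- rep_len(c("a_only", "b_only", "shared", "low"), nv)
  hi <- function(k) sample(c(1, 0.97, 0.92), k, replace = TRUE)
  lo <- function(k) sample(c(0.45, 0.2), k, replace = TRUE)
  frac_a <- frac_b <- numeric(nv)
  frac_a[scen == "a_only"] <- hi(sum(scen == "a_only"))
  frac_b[scen == "b_only"] <- hi(sum(scen == "b_only"))
  sh <- scen == "shared"
  frac_a[sh] <- hi(sum(sh)); frac_b[sh] <- frac_a[sh]
  lw <- scen == "low"
  frac_a[lw] <- lo(sum(lw)); frac_b[lw] <- lo(sum(lw))
  out <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, frac_a = frac_a, frac_b = frac_b,
                    scenario = scen, stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# Expected (noise-free) per-bin tag rate of the chip channel at one time
# point: triangular peaks evaluated at bin left edges, over flat background.
.chip_rate <- function(cfg, ann, truth, time_index) {
  chrom_lengths <- attr(ann, "chrom_lengths")
  bw <- cfg$bin_width
  hw <- cfg$peak_half_width
  grid <- cfg$peak_height_grid
  rates <- lapply(chrom_lengths, function(len)
    rep(cfg$background_rate * bw, len %/% bw))
  if (nrow(truth$genes) == 0) return(rates)
  pat <- truth$genes$pattern
  sg <- truth$genes$peak_strength %||% rep(1, nrow(truth$genes))
  mult <- ifelse(pat == "flat", grid$flat[time_index],
                 grid$A[time_index])  # A and B_tss share the decay profile
  mult[pat == "B"] <- grid$B_tss[time_index]
  dir <- ifelse(ann$strand == "+", 1L, -1L)
  is_b <- pat == "B"
  summits <- c(ann$tss, ann$tss[is_b] + dir[is_b] * cfg$pattern_b_offset)
  heights <- cfg$peak_summit_rate *
    c(sg * mult, sg[is_b] * grid$B_body[time_index])
  chroms <- c(ann$chrom, ann$chrom[is_b])
  m <- as.integer(hw %/% bw)
  offsets <- (-(m + 1L)):(m + 1L)
  for (chrom in names(rates)) {
    sel <- which(chroms == chrom & heights > 0)
    if (length(sel) == 0) next
    nb <- length(rates[[chrom]])
    ctr <- summits[sel] %/% bw + 1L                    # bin holding summit
    bins <- rep(ctr, each = length(offsets)) + offsets
    edges <- (bins - 1L) * bw                          # bin left edges
    tri <- pmax(0, 1 - abs(edges - rep(summits[sel],
                                       each = length(offsets))) / hw)
    contrib <- tri * rep(heights[sel], each = length(offsets))
    ok <- bins >= 1L & bins <= nb & contrib > 0
    if (!any(ok)) next
    add <- rowsum(contrib[ok], bins[ok])
    idx <- as.integer(rownames(add))
    rates[[chrom]][idx] <- rates[[chrom]][idx] + add[, 1]
  }
  rates
}

.input_rate <- function(cfg, ann) {
  chrom_lengths <- attr(ann, "chrom_lengths")
  lapply(chrom_lengths, function(len)
    rep(cfg$background_rate * cfg$bin_width, len %/% cfg$bin_width))
}

#' Simulate binned ChIP and input coverage tracks
#'
#' Draws Poisson tag counts per bin with mean equal to the flat background
#' rate plus, for the chip channel, a triangular peak at every gene TSS whose
#' summit height follows the gene's planted temporal pattern. Pattern-B genes
#' additionally gain a displaced gene-body peak with a transient
#' rise-and-return trajectory. Input tracks carry background only.
#'
#' @param cfg A [synth_config()].
#' @param ann Annotation from [make_annotation()].
#' @param truth Ledger from [make_truth()].
#' @return Nested list `tracks[[time]][[rep]]` with elements `chip` and
#'   `input`, each a [coverage_track()].
#' @export
make_tracks <- function(cfg, ann, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "truth_ledger"))
  input_rate <- .input_rate(cfg, ann)
  scale <- 1
  if (!is.null(cfg$read_depth)) {
    exp_tot <- sum(vapply(.chip_rate(cfg, ann, truth, 1L), sum, numeric(1)))
    if (exp_tot > 0) scale <- cfg$read_depth / exp_tot
  }
  .with_seed(cfg$seed + 2L, {
    out <- list()
    for (ti in seq_along(cfg$time_points)) {
      tp <- cfg$time_points[ti]
      chip_rate <- .chip_rate(cfg, ann, truth, ti)
      out[[tp]] <- lapply(seq_len(cfg$n_reps_chip), function(r) {
        draw <- function(rate, channel) {
          counts <- lapply(rate, function(v) stats::rpois(length(v), v * scale))
          names(counts) <- names(rate)
          coverage_track(counts, cfg$bin_width,
                         sample_id = sprintf("%s_%s_r%d", channel, tp, r),
                         channel = channel)
        }
        list(chip = draw(chip_rate, "chip"),
             input = draw(input_rate, "input"))
      })
      names(out[[tp]]) <- paste0("r", seq_len(cfg$n_reps_chip))
    }
    out
  })
}

#' Simulate the expression matrix
#'
#' Log2-scale values: per-gene baseline, plus the planted fold change in the
#' depleted condition for DEGs, plus Gaussian replicate noise. The treated
#' condition moves sensitive genes toward (or away from) the control mean
#' according to their rescue class.
#'
#' @param cfg A [synth_config()].
#' @param truth Ledger from [make_truth()].
#' @return List of class `expression_matrix` with `values` (genes x samples)
#'   and `samples` metadata (`sample`, `condition`, `replicate`).
#' @export
make_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "truth_ledger"))
  g <- truth$genes
  n <- nrow(g)
  conds <- c("control", "depleted", "treated")
  movement <- rep(0, n)
  sens <- g$rescue_class != "not_sensitive"
  movement[sens] <- cfg$rescue_movement[g$rescue_class[sens]]
  means <- cbind(control = g$baseline,
                 depleted = g$baseline + g$logfc,
                 treated = g$baseline + g$logfc * (1 - movement))
  samples <- data.frame(
    sample = paste0(rep(conds, each = cfg$n_reps_expr), "_r",
                    rep(seq_len(cfg$n_reps_expr), times = length(conds))),
    condition = rep(conds, each = cfg$n_reps_expr),
    replicate = rep(seq_len(cfg$n_reps_expr), times = length(conds)),
    stringsAsFactors = FALSE)
  values <- .with_seed(cfg$seed + 3L, {
    m <- means[, samples$condition, drop = FALSE] +
      matrix(stats::rnorm(n * nrow(samples), 0, cfg$noise_sd),
             nrow = n)
    dimnames(m) <- list(g$gene_id, samples$sample)
    m
  })
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

# ---- pileup generation ----------------------------------------------------

# Compose one mpileup base string with `ref_n` reference matches, `alt_n`
# alternate reads of `alt`, optional '*' deletions and indel suffixes.
.pileup_bases <- function(ref_n, alt = NULL, alt_n = 0, del_n = 0,
                          indel = NULL, indel_n = 0) {
  syms <- c(sample(c(".", ","), ref_n, replace = TRUE),
            if (alt_n > 0) sample(c(toupper(alt), tolower(alt)), alt_n,
                                  replace = TRUE),
            rep("*", del_n))
  syms <- sample(syms)
  if (length(syms) == 0) return("*")
  if (indel_n > 0 && !is.null(indel)) {
    at <- sample(seq_along(syms), min(indel_n, length(syms)))
    syms[at] <- paste0(syms[at], indel)
  }
  syms[1] <- paste0("^]", syms[1])
  syms[length(syms)] <- paste0(syms[length(syms)], "$")
  paste(syms, collapse = "")
}

#' Simulate mpileup files for two samples
#'
#' For every planted variant, emits a pileup column whose alternate-read
#' count is Binomial(depth, true fraction), flanked by pure-reference context
#' columns; a sub-threshold insertion is planted in one context column per
#' sample to exercise indel bookkeeping.
#'
#' @param cfg A [synth_config()].
#' @param truth Ledger from [make_truth()] (provides the variant table).
#' @return List of class `synth_pileups` with two `pileup_text` data frames
#'   (`sample_a`, `sample_b`; columns chrom/pos/ref/depth/bases/quals) and
#'   the expected-call tables `expected_a`, `expected_b` (variants whose true
#'   fraction exceeds 0.8).
#' @export
make_pileups <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "truth_ledger"))
  v <- truth$variants
  depth <- cfg$pileup_depth
  build <- function(frac_col, seed_off) {
    .with_seed(cfg$seed + seed_off, {
      rows <- list()
      for (i in seq_len(nrow(v))) {
        alt_n <- stats::rbinom(1L, depth, v[[frac_col]][i])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = v$chrom[i], pos = v$pos[i], ref = v$ref[i], depth = depth,
          bases = .pileup_bases(depth - alt_n, v$alt[i], alt_n),
          stringsAsFactors = FALSE)
        # reference context column next to the variant
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = v$chrom[i], pos = v$pos[i] + 1L,
          ref = sample(c("A", "C", "G", "T"), 1L), depth = depth,
          bases = .pileup_bases(depth), stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, rows)
      df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
      if (nrow(df) > 0) {
        # plant one sub-threshold insertion on a context column
        ctx <- which(!paste(df$chrom, df$pos) %in% paste(v$chrom, v$pos))
        if (length(ctx) > 0) {
          j <- ctx[1]
          df$bases[j] <- .pileup_bases(depth, indel = "+2AT",
                                       indel_n = max(1L, depth %/% 5L))
        }
      }
      df$quals <- vapply(df$depth, function(d)
        paste(sample(strsplit("FGHHIIJJ", "")[[1]], d, replace = TRUE),
              collapse = ""), character(1))
      rownames(df) <- NULL
      df
    })
  }
  expected <- function(frac_col) {
    keep <- v[[frac_col]] > 0.8
    v[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  }
  structure(list(sample_a = build("frac_a", 21L),
                 sample_b = build("frac_b", 22L),
                 expected_a = expected("frac_a"),
                 expected_b = expected("frac_b")),
            class = "synth_pileups")
}
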