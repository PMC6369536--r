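# End-to-end orchestration: synthesize -> peaks -> score -> degs ->
# associate -> snps, in memory (analyze_chip / synthetic_association) or on
# disk with a run manifest (run_pipeline).

#' ChIP arm of the pipeline, in memory
#'
#' Calls peaks per time point and replicate, filters them for
#' between-replicate reproducibility, merges the per-time consensus sets
#' into reference tags, scores every tag in every library with the AUC
#' score, and builds the temporal trajectory matrix.
#'
#' @param tracks Nested list `tracks[[time]][[rep]]$chip/$input` as produced
#'   by [make_tracks()].
#' @param q_threshold,local_half_width Passed to [call_peaks()].
#' @param idr_threshold Passed to [reproducible_peaks()].
#' @param reference,alpha,min_lfc Passed to [build_trajectories()].
#' @return List: `tags` (reference `consensus_tags`), `scores` (tag x time x
#'   replicate AUC array), `trajectories` (a `trajectory_matrix`),
#'   `peaks_per_time` (counts of reproducible tags per time point).
#' @export
analyze_chip <- function(tracks, q_threshold = 0.01, local_half_width = 5000,
                         idr_threshold = 0.01, reference = NULL,
                         alpha = 0.05, min_lfc = 0.4) {
  times <- names(tracks)
  per_time <- lapply(times, function(tp) {
    reps <- tracks[[tp]]
    peaks <- lapply(reps, function(r)
      call_peaks(r$chip, r$input, q_threshold, local_half_width))
    if (length(peaks) >= 2) {
      reproducible_peaks(peaks[[1]], peaks[[2]], idr_threshold)
    } else {
      # single replicate: every peak stands alone
      p <- peaks[[1]]
      if (nrow(p) == 0) return(.empty_consensus())
      .reduce_tags(data.frame(chrom = p$chrom, start = p$start, end = p$end,
                              irr = 0, members = p$peak_id,
                              stringsAsFactors = FALSE))
    }
  })
  names(per_time) <- times
  tags <- consensus_tags(per_time)
  if (nrow(tags) == 0) .stopf("no reproducible consensus tags found")
  n_reps <- length(tracks[[1]])
  dn <- list(tags$tag_id, times, paste0("r", seq_len(n_reps)))
  scores <- array(NA_real_, dim = c(nrow(tags), length(times), n_reps),
                  dimnames = dn)
  counts <- array(NA_real_, dim = dim(scores), dimnames = dn)
  lib_sizes <- matrix(NA_real_, length(times), n_reps,
                      dimnames = list(times, dn[[3]]))
  for (tp in times) {
    for (r in seq_len(n_reps)) {
      trk <- tracks[[tp]][[r]]
      for (chrom in unique(tags$chrom)) {
        sel <- tags$chrom == chrom
        counts[sel, tp, r] <- .track_region_counts(trk$chip, chrom,
                                                   tags$start[sel],
                                                   tags$end[sel])
      }
      # background (outside-tag) normalization: genome-wide signal loss
      # must not inflate the apparent enrichment of unchanged tags
      eff <- trk$chip$library_size - sum(counts[, tp, r])
      lib_sizes[tp, r] <- eff
      chip_eff <- trk$chip
      chip_eff$library_size <- max(eff, 1)
      scores[, tp, r] <- auc_score(tags, chip_eff, trk$input)
    }
  }
  traj <- build_trajectories(scores, reference = reference, alpha = alpha,
                             min_lfc = min_lfc, test = "count",
                             counts = counts, lib_sizes = lib_sizes)
  list(tags = tags, scores = scores, counts = counts,
       lib_sizes = lib_sizes, trajectories = traj,
       peaks_per_time = vapply(per_time, nrow, integer(1)))
}

# Per-gene peak-change flags: a gene changed iff >= 1 assigned tag is
# flagged changed in the trajectory matrix.
.gene_change_flags <- function(tags, traj, ann, max_dist = 2000,
                               genes = NULL) {
  asn <- assign_to_gene(tags, ann, max_dist = max_dist, genes = genes)
  changed_tags <- traj$tag_ids[traj$changed]
  flags <- stats::setNames(rep(FALSE, nrow(ann)), ann$gene_id)
  hit <- asn$gene_id[!is.na(asn$gene_id) & asn$tag_id %in% changed_tags]
  flags[unique(hit)] <- TRUE
  flags
}

#' Run the synthetic association study end to end, in memory
#'
#' Generates annotation, truth, tracks and expression from `cfg`, runs the
#' ChIP arm ([analyze_chip()]), assigns changed tags to promoters, calls
#' DEGs, and tests the DEG x peak-change association over the full gene
#' universe.
#'
#' @param cfg A [synth_config()].
#' @param q_threshold,idr_threshold,traj_alpha,min_lfc ChIP-arm thresholds.
#' @param deg_alpha,deg_adjust DEG-calling thresholds.
#' @param max_dist Tag-to-TSS assignment distance (bp).
#' @return List: `result` (an `association_result`), `table`, `deg`,
#'   `chip`, `truth`, `ann`, plus `truth_result` (the same association
#'   computed from the planted truth flags, for calibration checks).
#' @export
synthetic_association <- function(cfg, q_threshold = 0.01,
                                  idr_threshold = 0.01, traj_alpha = 0.01,
                                  min_lfc = 0.4, deg_alpha = 0.01,
                                  deg_adjust = "BH",
                                  deg_moderation = "eb", max_dist = 2000) {
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tracks <- make_tracks(cfg, ann, truth)
  chip <- analyze_chip(tracks, q_threshold = q_threshold,
                       idr_threshold = idr_threshold, alpha = traj_alpha,
                       min_lfc = min_lfc)
  change_flags <- .gene_change_flags(chip$tags, chip$trajectories, ann,
                                     max_dist = max_dist)
  em <- make_expression(cfg, truth)
  deg <- call_degs(em, c("depleted", "control"), alpha = deg_alpha,
                   adjust = deg_adjust, moderation = deg_moderation)
  deg_flags <- stats::setNames(deg$deg, deg$gene_id)
  tab <- build_table(deg_flags, change_flags, universe = ann$gene_id)
  truth_tab <- build_table(
    stats::setNames(truth$genes$deg, truth$genes$gene_id),
    stats::setNames(truth$genes$peak_change, truth$genes$gene_id),
    universe = ann$gene_id)
  list(result = odds_ratio_test(tab), table = tab, deg = deg, chip = chip,
       truth = truth, ann = ann,
       truth_result = odds_ratio_test(truth_tab))
}

#' Write every synthetic input to disk
#'
#' Materializes the generator outputs under `outdir`: the annotation table,
#' per-(time, replicate, channel) bedGraph tracks, the expression TSV, two
#' mpileup files, and the ground-truth ledger tables.
#'
#' @param cfg A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
write_synth_data <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  ann <- make_annotation(cfg)
  truth <- make_truth(cfg, ann)
  tracks <- make_tracks(cfg, ann, truth)
  em <- make_expression(cfg, truth)
  pileups <- make_pileups(cfg, truth)
  write_annotation(ann, file.path(outdir, "annotation.tsv"))
  paths <- list()
  for (tp in names(tracks)) {
    for (r in seq_along(tracks[[tp]])) {
      for (ch in c("chip", "input")) {
        p <- file.path(outdir, "tracks",
                       sprintf("%s_%s_r%d.bedgraph", ch, tp, r))
        write_bedgraph(tracks[[tp]][[r]][[ch]], p)
        paths[[sprintf("%s_%s_r%d", ch, tp, r)]] <- p
      }
    }
  }
  write_expression(em, file.path(outdir, "expression.tsv"))
  write_pileup(pileups$sample_a, file.path(outdir, "sample_a.pileup"))
  write_pileup(pileups$sample_b, file.path(outdir, "sample_b.pileup"))
  utils::write.table(truth$genes, file.path(outdir, "truth", "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$variants,
                     file.path(outdir, "truth", "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(ann = ann, truth = truth, tracks = tracks, em = em,
                 pileups = pileups, track_paths = paths))
}

#' Run the full pipeline from a config into a run directory
#'
#' Stages: `synth` (generate and write all inputs), `peaks` (read tracks
#' back from disk, call and filter peaks), `score` (AUC trajectories and
#' pattern clustering), `degs` (differential expression plus
#' sensitivity/rescue), `associate` (DEG x peak-change odds ratio and
#' expression/enrichment concordance), `snps` (pileup -> VCF -> set
#' comparison). Any stage failure aborts with an error naming the stage.
#' Every threshold, the seed and the hash of each written file are recorded
#' in `manifest.json`.
#'
#' @param cfg A [synth_config()].
#' @param outdir Run directory.
#' @param q_threshold,idr_threshold,traj_alpha,min_lfc,deg_alpha,deg_adjust,
#'   max_dist,snp_threshold,min_depth,tss_window Stage thresholds; all are
#'   echoed into the manifest.
#' @return Invisibly, a list with stage results and the manifest.
#' @export
run_pipeline <- function(cfg, outdir, q_threshold = 0.01,
                         idr_threshold = 0.01, traj_alpha = 0.01,
                         min_lfc = 0.4, deg_alpha = 0.01, deg_adjust = "BH",
                         deg_moderation = "eb", max_dist = 2000,
                         snp_threshold = 0.8, min_depth = 4,
                         tss_window = 2000) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  stages_run <- character()

  synth <- stage("synth", write_synth_data(cfg, outdir))
  stages_run <- c(stages_run, "synth")
  ann <- synth$ann

  chip <- stage("peaks", {
    chrom_lengths <- attr(ann, "chrom_lengths")
    tracks <- list()
    for (tp in cfg$time_points) {
      tracks[[tp]] <- lapply(seq_len(cfg$n_reps_chip), function(r) {
        read_one <- function(ch) {
          p <- synth$track_paths[[sprintf("%s_%s_r%d", ch, tp, r)]]
          read_bedgraph(p, cfg$bin_width, chrom_lengths = chrom_lengths,
                        sample_id = sprintf("%s_%s_r%d", ch, tp, r),
                        channel = ch)
        }
        list(chip = read_one("chip"), input = read_one("input"))
      })
    }
    res <- analyze_chip(tracks, q_threshold = q_threshold,
                        idr_threshold = idr_threshold, alpha = traj_alpha,
                        min_lfc = min_lfc)
    write_bed(data.frame(chrom = res$tags$chrom, start = res$tags$start,
                         end = res$tags$end, name = res$tags$tag_id,
                         stringsAsFactors = FALSE),
              file.path(outdir, "consensus_tags.bed"))
    res$profile <- tss_metaprofile(tracks[[1]][[1]]$chip,
                                   tracks[[1]][[1]]$input, ann,
                                   window = tss_window)
    res
  })
  stages_run <- c(stages_run, "peaks")

  score <- stage("score", {
    traj <- chip$trajectories
    labels <- if (sum(traj$changed) >= 2)
      cluster_trajectories(traj, k = 2) else NULL
    tm <- data.frame(tag_id = traj$tag_ids, traj$lfc,
                     changed = traj$changed, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!is.null(labels))
      tm$pattern <- labels$label[match(tm$tag_id, labels$tag_id)]
    utils::write.table(tm, file.path(outdir, "trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(trajectories = traj, clusters = labels)
  })
  stages_run <- c(stages_run, "score")

  degs <- stage("degs", {
    em <- synth$em
    deg <- call_degs(em, c("depleted", "control"), alpha = deg_alpha,
                     adjust = deg_adjust, moderation = deg_moderation)
    rescue <- classify_sensitivity_and_rescue(em, alpha = deg_alpha,
                                              adjust = deg_adjust,
                                              moderation = deg_moderation)
    utils::write.table(deg, file.path(outdir, "degs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rescue, file.path(outdir, "rescue.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(deg = deg, rescue = rescue)
  })
  stages_run <- c(stages_run, "degs")

  assoc <- stage("associate", {
    change_flags <- .gene_change_flags(chip$tags, chip$trajectories, ann,
                                       max_dist = max_dist)
    deg_flags <- stats::setNames(degs$deg$deg, degs$deg$gene_id)
    tab <- build_table(deg_flags, change_flags, universe = ann$gene_id)
    res <- odds_ratio_test(tab)
    # concordance of expression direction with promoter enrichment change
    traj <- chip$trajectories
    last <- colnames(traj$lfc)[ncol(traj$lfc)]
    asn <- assign_to_gene(chip$tags, ann, max_dist = max_dist)
    tag_delta <- traj$lfc[, last]
    gene_delta <- tapply(tag_delta[match(asn$tag_id, traj$tag_ids)],
                         asn$gene_id, mean, na.rm = TRUE)
    conc <- concordance(stats::setNames(degs$deg$logfc, degs$deg$gene_id),
                        gene_delta)
    report <- data.frame(
      a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      odds_ratio = res$odds_ratio, ci_lo = res$ci[1], ci_hi = res$ci[2],
      p = res$p, method = res$method,
      rule = sprintf("tag changed at BH q<%g & |lfc|>=%g within %d bp of TSS",
                     traj_alpha, min_lfc, max_dist))
    utils::write.table(report, file.path(outdir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(result = res, table = tab, concordance = conc)
  })
  stages_run <- c(stages_run, "associate")

  snps <- stage("snps", {
    meta <- c(snp_threshold = format(snp_threshold),
              min_depth = format(min_depth))
    va <- call_snps(read_pileup(file.path(outdir, "sample_a.pileup")),
                    threshold = snp_threshold, min_depth = min_depth,
                    sample_id = "sample_a")
    vb <- call_snps(read_pileup(file.path(outdir, "sample_b.pileup")),
                    threshold = snp_threshold, min_depth = min_depth,
                    sample_id = "sample_b")
    write_vcf(va, file.path(outdir, "sample_a.vcf"), meta = meta)
    write_vcf(vb, file.path(outdir, "sample_b.vcf"), meta = meta)
    dd <- diff_snp_sets(va, vb)
    utils::write.table(
      data.frame(set = c("a_only", "b_only", "shared"),
                 n = c(nrow(dd$a_only), nrow(dd$b_only), nrow(dd$shared))),
      file.path(outdir, "snp_diff.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(a = va, b = vb, diff = dd)
  })
  stages_run <- c(stages_run, "snps")

  manifest <- stage("manifest", {
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    man <- list(
      package = "acetylscape",
      version = as.character(utils::packageVersion("acetylscape")),
      seed = cfg$seed,
      stages = stages_run,
      thresholds = list(q_threshold = q_threshold,
                        deg_moderation = deg_moderation,
                        idr_threshold = idr_threshold,
                        traj_alpha = traj_alpha, min_lfc = min_lfc,
                        deg_alpha = deg_alpha, deg_adjust = deg_adjust,
                        max_dist = max_dist, snp_threshold = snp_threshold,
                        min_depth = min_depth, tss_window = tss_window),
      files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      sub(paste0(outdir, "/?"), "", files))))
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })

  invisible(list(synth = synth, chip = chip, score = score, degs = degs,
                 assoc = assoc, snps = snps, manifest = manifest))
}
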