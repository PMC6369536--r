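#' Length-adjusted net enrichment (AUC) score
#'
#' For each tag interval, the RPM-adjusted ChIP signal minus the
#' RPM-adjusted input background, divided by the interval length in bp:
#' a per-bp net enrichment that is negative when ChIP falls below
#' background. Partial bins at interval boundaries contribute
#' proportionally, so the score is additive over sub-intervals.
#'
#' @param tags Data frame with `chrom`, `start`, `end` (e.g. a
#'   `consensus_tags`).
#' @param chip,input [coverage_track()]s with identical binning.
#' @return Numeric vector of scores, one per tag (RPM/bp).
#' @export
auc_score <- function(tags, chip, input) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  .check_compatible_tracks(chip, input)
  if (nrow(tags) == 0) return(numeric())
  if (any(tags$end <= tags$start)) .stopf("zero-length tag interval")
  out <- numeric(nrow(tags))
  for (chrom in unique(tags$chrom)) {
    sel <- tags$chrom == chrom
    chip_sum <- .track_region_counts(chip, chrom, tags$start[sel],
                                     tags$end[sel])
    input_sum <- .track_region_counts(input, chrom, tags$start[sel],
                                      tags$end[sel])
    out[sel] <- (chip_sum * 1e6 / max(chip$library_size, 1) -
                   input_sum * 1e6 / max(input$library_size, 1)) /
      (tags$end[sel] - tags$start[sel])
  }
  out
}

#' Assign tags to the nearest gene TSS within a distance cutoff
#'
#' Distance is measured from the tag interval to the TSS: zero when the TSS
#' falls inside the tag, otherwise the gap to the nearest tag edge. Tags
#' farther than `max_dist` from every TSS are unassigned. Equidistant ties
#' go to the lexicographically smaller gene id.
#'
#' @param tags Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `tag_id`.
#' @param ann A `genome_annotation`; restrict the eligible (e.g. expressed)
#'   gene set via `genes`.
#' @param max_dist Maximum tag-to-TSS distance in bp (default 2000, i.e. the
#'   2-kb promoter window).
#' @param genes Optional character vector of eligible gene ids.
#' @param mode `"interval"` (default) measures distance from the whole tag
#'   interval; `"summit"` measures from the tag's summit coordinate only
#'   (requires a `summit` column).
#' @return Data frame `tag_id`, `gene_id` (NA when unassigned), `distance`.
#' @export
assign_to_gene <- function(tags, ann, max_dist = 2000, genes = NULL,
                           mode = c("interval", "summit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ann, "genome_annotation"))
  if (mode == "summit") {
    if (is.null(tags$summit)) .stopf("summit mode needs a `summit` column")
    tags$start <- tags$summit
    tags$end <- tags$summit + 1L
  }
  if (!is.null(genes)) ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  n <- nrow(tags)
  tag_id <- tags$tag_id %||% sprintf("tag_%d", seq_len(n))
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  for (chrom in unique(tags$chrom)) {
    g <- ann[ann$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0) next
    ord <- order(g$tss, g$gene_id)
    tss <- g$tss[ord]
    ids <- g$gene_id[ord]
    sel <- which(tags$chrom == chrom)
    i1 <- findInterval(tags$start[sel] - 1L, tss)   # rightmost TSS < start
    i2 <- findInterval(tags$end[sel] - 1L, tss)     # rightmost TSS <= end-1
    for (k in seq_along(sel)) {
      t <- sel[k]
      if (i2[k] > i1[k]) {                  # TSS inside the tag
        inside <- ids[(i1[k] + 1L):i2[k]]
        gene_id[t] <- min(inside)
        distance[t] <- 0
      } else {
        d_left <- if (i1[k] >= 1L) tags$start[t] - tss[i1[k]] else Inf
        d_right <- if (i1[k] < length(tss))
          tss[i1[k] + 1L] - (tags$end[t] - 1L) else Inf
        d <- min(d_left, d_right)
        if (is.finite(d) && d <= max_dist) {
          cand <- c(if (d_left == d) ids[i1[k]],
                    if (d_right == d) ids[i1[k] + 1L])
          gene_id[t] <- min(cand)
          distance[t] <- d
        }
      }
    }
  }
  data.frame(tag_id = tag_id, gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Build temporal enrichment trajectories for consensus tags
#'
#' Takes per-(time, replicate) AUC scores, averages replicates, clamps
#' values below a positivity floor (the given quantile of positive
#' replicate-mean scores) and expresses each time point as log2 fold
#' relative to the reference. Per-tag, per-time significance against the
#' reference is assessed either by an exact conditional binomial test on
#' summed tag counts given the library sizes (`test = "count"`, the default
#' when counts are supplied: with Poisson tags and two replicates per
#' condition this is calibrated and far more powerful than a 2-df t-test)
#' or by a pooled-variance two-sample t-test on replicate scores
#' (`test = "t"`), with BH adjustment across tags either way. A tag is
#' flagged `changed` when any time point is significant at `alpha` with
#' |log2 fold| of at least `min_lfc`. Tags with no positive replicate-mean
#' score at any time are dropped with a message.
#'
#' @param scores 3-d array `[tag, time, replicate]` with dimnames.
#' @param reference Reference time label (default the first column).
#' @param alpha BH-adjusted significance level for the per-time test.
#' @param min_lfc Minimum |log2 fold| versus reference for a time point to
#'   count as changed.
#' @param floor_quantile Quantile of positive scores used as positivity
#'   floor before taking logs.
#' @param test `"count"`, `"t"`, or `"auto"` (count when counts are given).
#' @param counts Optional 3-d array like `scores` of raw chip tag counts per
#'   tag.
#' @param lib_sizes Optional time x replicate matrix of chip library sizes
#'   matching `counts`.
#' @return List of class `trajectory_matrix`: `lfc` (tags x times, reference
#'   column 0), `pvalue`/`qvalue` (tags x non-reference times), `changed`,
#'   `tag_ids`, `reference`, `dropped`.
#' @export
build_trajectories <- function(scores, reference = NULL, alpha = 0.05,
                               min_lfc = 0.4, floor_quantile = 0.01,
                               test = c("auto", "count", "t"),
                               counts = NULL, lib_sizes = NULL) {
  stopifnot(length(dim(scores)) == 3)
  test <- match.arg(test)
  if (test == "auto") test <- if (is.null(counts)) "t" else "count"
  if (test == "count" && (is.null(counts) || is.null(lib_sizes)))
    .stopf("test = \"count\" needs `counts` and `lib_sizes`")
  times <- dimnames(scores)[[2]]
  reference <- reference %||% times[1]
  if (!reference %in% times) .stopf("reference time '%s' not found", reference)
  M <- apply(scores, c(1, 2), mean, na.rm = TRUE)
  has_missing <- apply(scores, 1, anyNA)
  drop <- apply(M <= 0 | !is.finite(M), 1, all)
  if (any(drop))
    message(sprintf("build_trajectories: dropped %d tag(s) with no positive score",
                    sum(drop)))
  M <- M[!drop, , drop = FALSE]
  scores <- scores[!drop, , , drop = FALSE]
  if (!is.null(counts)) counts <- counts[!drop, , , drop = FALSE]
  pos <- M[M > 0]
  floor_val <- if (length(pos) > 0)
    stats::quantile(pos, floor_quantile, names = FALSE, type = 1) else 1e-9
  Mf <- pmax(M, floor_val)
  lfc <- log2(Mf / Mf[, reference])
  other <- setdiff(times, reference)
  pv <- matrix(NA_real_, nrow(M), length(other),
               dimnames = list(rownames(M), other))
  slab <- function(arr, tp) {
    x <- arr[, tp, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = dim(arr)[3])
    x
  }
  if (test == "t") {
    y <- slab(scores, reference)
    for (tp in other) pv[, tp] <- .pooled_t_rows(slab(scores, tp), y)
  } else {
    c0 <- rowSums(slab(counts, reference), na.rm = TRUE)
    l0 <- sum(lib_sizes[reference, ])
    for (tp in other) {
      ct <- rowSums(slab(counts, tp), na.rm = TRUE)
      w <- sum(lib_sizes[tp, ]) / (sum(lib_sizes[tp, ]) + l0)
      pv[, tp] <- .binom_p_rows(round(ct), round(ct + c0), w)
    }
  }
  qv <- apply(pv, 2, stats::p.adjust, method = "BH")
  if (is.null(dim(qv))) qv <- matrix(qv, nrow = nrow(pv),
                                     dimnames = dimnames(pv))
  changed <- rowSums(qv < alpha & abs(lfc[, other, drop = FALSE]) >= min_lfc,
                     na.rm = TRUE) > 0
  structure(list(lfc = lfc, pvalue = pv, qvalue = qv, changed = changed,
                 tag_ids = rownames(M), reference = reference,
                 dropped = sum(drop), imputed = has_missing[!drop],
                 alpha = alpha, min_lfc = min_lfc, test = test),
            class = "trajectory_matrix")
}

# Exact two-sided binomial p-values (point-probability method), one test
# per element of x/n; the conditional test of two Poisson totals.
.binom_p_rows <- function(x, n, w) {
  vapply(seq_along(x), function(i) {
    if (n[i] <= 0) return(1)
    dens <- stats::dbinom(0:n[i], n[i], w)
    min(sum(dens[dens <= dens[x[i] + 1L] * (1 + 1e-7)]), 1)
  }, numeric(1))
}

# Row-wise pooled-variance two-sample t-test p-values (NA-tolerant).
.pooled_t_rows <- function(x, y) {
  nx <- rowSums(!is.na(x))
  ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE)
  my <- rowMeans(y, na.rm = TRUE)
  vx <- .row_vars(x)
  vy <- .row_vars(y)
  df <- nx + ny - 2
  sp2 <- (pmax(nx - 1, 0) * ifelse(is.na(vx), 0, vx) +
            pmax(ny - 1, 0) * ifelse(is.na(vy), 0, vy)) / pmax(df, 1)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), pmax(df, 1))
  p[df < 1 | nx < 1 | ny < 1] <- NA_real_
  p[is.nan(p)] <- 1  # zero variance and equal means
  p
}

#' Cluster temporal trajectories into pattern classes
#'
#' Ward-linkage agglomerative clustering (Ward's method on Euclidean
#' distances) of trajectory rows, cut at `k`. Cluster labels are mapped onto
#' pattern semantics from the cluster centroid: a centroid with an interior
#' maximum (transient rise that returns) is pattern `B`; a monotone
#' non-increasing centroid with net loss is pattern `A`; anything else is
#' `other`.
#'
#' @param tm A `trajectory_matrix` (its `changed` rows are clustered by
#'   default) or a plain numeric matrix of trajectories.
#' @param k Number of clusters (default 2).
#' @param rows For a `trajectory_matrix`: `"changed"` (default) or `"all"`.
#' @return Data frame `tag_id`, `cluster`, `label`, with the centroid matrix
#'   in attribute `centroids`.
#' @export
cluster_trajectories <- function(tm, k = 2, rows = c("changed", "all")) {
  rows <- match.arg(rows)
  if (inherits(tm, "trajectory_matrix")) {
    m <- tm$lfc
    if (rows == "changed") m <- m[tm$changed, , drop = FALSE]
  } else {
    m <- as.matrix(tm)
  }
  if (nrow(m) < k)
    .stopf("cannot cut %d trajectories into k = %d clusters", nrow(m), k)
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(m[cl == g, , drop = FALSE])))
  labels <- apply(centroids, 1, .label_centroid)
  out <- data.frame(tag_id = rownames(m) %||% sprintf("row_%d", seq_len(nrow(m))),
                    cluster = unname(cl), label = labels[cl],
                    stringsAsFactors = FALSE)
  attr(out, "centroids") <- centroids
  out
}

# Shape rule mapping a centroid to pattern semantics.
.label_centroid <- function(cent, tol = 1e-8) {
  if (length(cent) < 3) return("other")
  pk <- which.max(cent)
  interior_max <- pk > 1 && pk < length(cent) &&
    cent[pk] > cent[1] + tol && cent[pk] > cent[length(cent)] + tol
  if (interior_max) return("B")
  d <- diff(cent)
  if (all(d <= tol) && any(d < -tol)) return("A")
  "other"
}
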