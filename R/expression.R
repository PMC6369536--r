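#' Call differentially expressed genes
#'
#' Per-gene one-way ANOVA across the requested condition groups (which
#' reduces to the pooled-variance two-sample t-test for two groups),
#' computed row-wise over the expression matrix, with optional
#' Benjamini-Hochberg adjustment. For a two-condition contrast the log2
#' fold change is `mean(first) - mean(second)`.
#'
#' @param em An `expression_matrix` (`values` genes x samples, `samples`
#'   metadata with a `condition` column).
#' @param contrast Character vector of two or more condition labels; for two
#'   conditions, ordered `c(test, reference)`.
#' @param alpha Significance level for the DEG flag.
#' @param adjust `"none"` (flag on raw p, matching a plain per-gene ANOVA at
#'   the stated alpha) or `"BH"` (flag on FDR-adjusted q).
#' @param moderation `"none"` (plain per-gene ANOVA) or `"eb"`
#'   (empirical-Bayes variance shrinkage across genes via
#'   [limma::squeezeVar()], which adds prior degrees of freedom to the
#'   denominator; recommended for few-replicate designs).
#' @return Data frame of class `deg_table`: `gene_id`, `logfc`, `p`, `q`,
#'   `deg`; the thresholds used are carried in attributes.
#' @export
call_degs <- function(em, contrast, alpha = 0.05,
                      adjust = c("none", "BH"),
                      moderation = c("none", "eb")) {
  adjust <- match.arg(adjust)
  moderation <- match.arg(moderation)
  stopifnot(inherits(em, "expression_matrix"))
  if (length(contrast) < 2) .stopf("`contrast` needs at least two conditions")
  missing <- setdiff(contrast, em$samples$condition)
  if (length(missing) > 0)
    .stopf("condition(s) not in the expression matrix: %s",
           paste(missing, collapse = ", "))
  groups <- lapply(contrast, function(cc)
    em$values[, em$samples$condition == cc, drop = FALSE])
  sizes <- vapply(groups, ncol, integer(1))
  if (any(sizes < 2))
    .stopf("every contrast group needs >= 2 replicates (got %s)",
           paste(sizes, collapse = ", "))
  p <- .row_anova(groups, moderation = moderation)
  q <- stats::p.adjust(p, method = "BH")
  logfc <- if (length(groups) == 2)
    rowMeans(groups[[1]]) - rowMeans(groups[[2]]) else NA_real_
  flag_on <- if (adjust == "BH") q else p
  out <- data.frame(gene_id = rownames(em$values), logfc = logfc, p = p,
                    q = q, deg = flag_on < alpha, stringsAsFactors = FALSE)
  structure(out, alpha = alpha, adjust = adjust, moderation = moderation,
            contrast = contrast,
            class = c("deg_table", "data.frame"))
}

# Row-wise one-way ANOVA over a list of per-group matrices, optionally with
# empirical-Bayes shrinkage of the within-group variance.
.row_anova <- function(groups, moderation = "none") {
  k <- length(groups)
  sizes <- vapply(groups, ncol, integer(1))
  N <- sum(sizes)
  means <- vapply(groups, rowMeans, numeric(nrow(groups[[1]])))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  grand <- as.vector(means %*% sizes) / N
  ssb <- as.vector((means - grand)^2 %*% sizes)
  ssw <- Reduce(`+`, lapply(groups, function(g)
    (ncol(g) - 1L) * .row_vars(g)))
  df2 <- N - k
  s2 <- ssw / df2
  if (moderation == "eb" && length(s2) > 1) {
    sq <- limma::squeezeVar(s2, df = df2)
    s2 <- sq$var.post
    df2 <- df2 + sq$df.prior
  }
  f <- (ssb / (k - 1)) / s2
  p <- stats::pf(f, k - 1, df2, lower.tail = FALSE)
  p[ssb == 0 & (is.na(s2) | s2 == 0)] <- 1  # flat gene across all samples
  p[is.nan(p)] <- 1
  p
}

#' Two one-sided tests (TOST) of equivalence
#'
#' Welch two-sample TOST against symmetric equivalence bounds
#' `(-delta, +delta)`: the equivalence p-value is the larger of the two
#' one-sided t-test p-values of the mean difference against each bound.
#' When both groups are exactly constant the test degenerates: p is 0 if
#' the observed difference lies strictly inside the bounds, 1 otherwise.
#'
#' @param a,b Numeric vectors (e.g. log2 enrichment of two statistical
#'   groups).
#' @param delta Positive equivalence half-width, on the scale of the data.
#' @return List of class `tost`: `p`, `estimate` (mean difference), `df`,
#'   `delta`.
#' @export
tost_equivalence <- function(a, b, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    .stopf("`delta` must be a single positive bound")
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) .stopf("both groups need >= 2 observations")
  m <- mean(a) - mean(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  se <- sqrt(va / na + vb / nb)
  if (se == 0) {
    p <- if (abs(m) < delta) 0 else 1
    return(structure(list(p = p, estimate = m, df = Inf, delta = delta),
                     class = "tost"))
  }
  df <- se^4 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p_lower <- stats::pt((m + delta) / se, df, lower.tail = FALSE)
  p_upper <- stats::pt((m - delta) / se, df)
  structure(list(p = max(p_lower, p_upper), estimate = m, df = df,
                 delta = delta),
            class = "tost")
}

#' Classify treatment sensitivity and rescue of expression changes
#'
#' Among DEGs (depleted vs control), a gene is treatment-sensitive when its
#' expression differs between the treated and untreated depleted conditions
#' at `alpha`. Sensitive genes are then classified from the depleted-vs-
#' control fold change `fc_d` and the treated-vs-control fold change `fc_t`
#' (log2), with movement fraction `m = (fc_d - fc_t) / fc_d`:
#' \itemize{
#'   \item `full`: `|fc_t| <= full_band` (expression returned to control);
#'   \item `exacerbated`: `m < 0` (moved away from control);
#'   \item `partial`: moved at least `partial_frac` of the way toward
#'     control without overshooting past the reflected magnitude
#'     (`|fc_t| < |fc_d|`);
#'   \item `none`: any other sensitive gene.
#' }
#' The four labels partition the sensitive set; thresholds are echoed in the
#' attributes of the result.
#'
#' @param em An `expression_matrix` containing all three conditions.
#' @param control,depleted,treated Condition labels.
#' @param alpha Significance level for both the DEG and sensitivity tests.
#' @param adjust,moderation Multiplicity handling and variance moderation
#'   passed to [call_degs()].
#' @param partial_frac Minimum movement fraction toward control for a
#'   partial rescue (default 0.5).
#' @param full_band Absolute log2 band around the control mean within which
#'   a gene counts as fully rescued (default 0.25).
#' @return Data frame of class `rescue_table`: `gene_id`, `deg`,
#'   `sensitive`, `fc_depleted`, `fc_treated`, `movement`, `rescue_class`.
#' @export
classify_sensitivity_and_rescue <- function(em, control = "control",
                                            depleted = "depleted",
                                            treated = "treated",
                                            alpha = 0.05,
                                            adjust = c("none", "BH"),
                                            moderation = c("none", "eb"),
                                            partial_frac = 0.5,
                                            full_band = 0.25) {
  adjust <- match.arg(adjust)
  moderation <- match.arg(moderation)
  stopifnot(inherits(em, "expression_matrix"))
  if (!treated %in% em$samples$condition)
    .stopf("treated condition '%s' missing from the expression matrix",
           treated)
  deg <- call_degs(em, c(depleted, control), alpha = alpha, adjust = adjust,
                   moderation = moderation)
  sens <- call_degs(em, c(treated, depleted), alpha = alpha, adjust = adjust,
                    moderation = moderation)
  cm <- rowMeans(em$values[, em$samples$condition == control, drop = FALSE])
  tm <- rowMeans(em$values[, em$samples$condition == treated, drop = FALSE])
  fc_d <- deg$logfc
  fc_t <- tm - cm
  is_deg <- deg$deg
  sensitive <- is_deg & sens$deg
  movement <- (fc_d - fc_t) / fc_d
  cls <- rep(NA_character_, nrow(deg))
  cls[sensitive] <- "none"
  full <- sensitive & abs(fc_t) <= full_band
  exac <- sensitive & !full & movement < 0
  part <- sensitive & !full & !exac & movement >= partial_frac &
    abs(fc_t) < abs(fc_d)
  cls[full] <- "full"
  cls[exac] <- "exacerbated"
  cls[part] <- "partial"
  out <- data.frame(gene_id = deg$gene_id, deg = is_deg,
                    sensitive = sensitive, fc_depleted = fc_d,
                    fc_treated = fc_t, movement = movement,
                    rescue_class = cls, stringsAsFactors = FALSE)
  structure(out, alpha = alpha, adjust = adjust,
            partial_frac = partial_frac, full_band = full_band,
            class = c("rescue_table", "data.frame"))
}
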