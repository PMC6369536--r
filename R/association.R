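#' Build the DEG x peak-change contingency table
#'
#' Cross-tabulates differential-expression status against promoter
#' peak-change status over an explicit expressed-gene universe. Both flag
#' vectors must be named by gene and cover the whole universe; genes outside
#' the universe are ignored.
#'
#' @param deg_flags Named logical vector: gene is differentially expressed.
#' @param change_flags Named logical vector: gene carries a significant
#'   promoter peak change.
#' @param universe Character vector of expressed gene ids.
#' @return List of class `contingency_table` with counts `a` (DEG, changed),
#'   `b` (DEG, unchanged), `c` (non-DEG, changed), `d` (non-DEG, unchanged).
#' @export
build_table <- function(deg_flags, change_flags, universe) {
  if (length(universe) == 0) .stopf("empty gene universe")
  if (anyDuplicated(universe)) .stopf("duplicated ids in the gene universe")
  miss_deg <- setdiff(universe, names(deg_flags))
  miss_chg <- setdiff(universe, names(change_flags))
  if (length(miss_deg) + length(miss_chg) > 0)
    .stopf("flags missing for universe gene(s): %s",
           paste(utils::head(unique(c(miss_deg, miss_chg)), 5),
                 collapse = ", "))
  dg <- deg_flags[universe]
  ch <- change_flags[universe]
  if (anyNA(dg) || anyNA(ch)) .stopf("flags contain NA over the universe")
  structure(list(a = sum(dg & ch), b = sum(dg & !ch),
                 c = sum(!dg & ch), d = sum(!dg & !ch)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("DEG", "non-DEG"),
                              c("changed", "unchanged")))
  print(m)
  invisible(x)
}

# Two-sided Fisher exact p by the point-probability method: the sum of
# hypergeometric probabilities of all tables (same margins) no more likely
# than the observed one, with the customary (1 + 1e-7) relative slack
# against floating-point ties.
.fisher_p_twosided <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n2, k)
  d_obs <- stats::dhyper(a, m, n2, k)
  min(sum(dens[dens <= d_obs * (1 + 1e-7)]), 1)
}

#' Odds-ratio association test on a 2x2 table
#'
#' The odds ratio is `(a*d)/(b*c)`, with the Haldane-Anscombe +0.5
#' correction applied to every cell iff any cell is zero; the 95% CI is the
#' Woolf logit interval on the (corrected) counts. The default p-value is
#' the two-sided Fisher exact test by the point-probability method on the
#' raw counts; `method = "chi2"` uses the continuity-corrected chi-squared
#' test instead (useful for very large tables).
#'
#' @param tab A `contingency_table` from [build_table()].
#' @param method `"fisher"` (exact, default) or `"chi2"`.
#' @param conf_level Confidence level for the Woolf interval.
#' @return List of class `association_result`: `odds_ratio`, `ci` (length
#'   2), `p`, `method`, `table`, `haldane` (whether the correction was
#'   applied).
#' @export
odds_ratio_test <- function(tab, method = c("fisher", "chi2"),
                            conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(tab, "contingency_table"))
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
    .stopf("degenerate contingency table margin; odds ratio undefined")
  haldane <- any(c(a, b, cc, d) == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (d + h))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- if (method == "fisher") {
    .fisher_p_twosided(a, b, cc, d)
  } else {
    m <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    unname(stats::chisq.test(m, correct = TRUE)$p.value)
  }
  structure(list(odds_ratio = or, ci = ci, p = p, method = method,
                 table = tab, conf_level = conf_level, haldane = haldane),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR = %.3f (%d%% CI %.3f-%.3f), p = %.3g [%s%s]\n",
              x$odds_ratio, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$p, x$method,
              if (x$haldane) ", Haldane-corrected" else ""))
  invisible(x)
}

#' Concordance between expression and enrichment directionality
#'
#' Pairs per-gene expression log fold changes with per-gene promoter
#' enrichment deltas and reports the fraction of genes whose signs agree,
#' the Spearman rank correlation, and the per-gene scatter table.
#'
#' @param expr_logfc Named numeric vector of expression log2 fold changes.
#' @param enrichment_delta Named numeric vector of enrichment changes.
#' @param channel Label for the enrichment channel (bookkeeping only).
#' @return List of class `concordance_result`: `sign_concordance`,
#'   `spearman_rho`, `n`, `channel`, `table`.
#' @export
concordance <- function(expr_logfc, enrichment_delta, channel = "chip") {
  common <- intersect(names(expr_logfc), names(enrichment_delta))
  common <- common[!is.na(expr_logfc[common]) &
                     !is.na(enrichment_delta[common])]
  if (length(common) == 0)
    .stopf("no genes shared between expression and enrichment vectors")
  x <- expr_logfc[common]
  y <- enrichment_delta[common]
  nz <- x != 0 & y != 0
  frac <- mean(sign(x[nz]) == sign(y[nz]))
  rho <- stats::cor(x, y, method = "spearman")
  structure(list(sign_concordance = frac, spearman_rho = rho,
                 n = length(common), channel = channel,
                 table = data.frame(gene_id = common, expr_logfc = unname(x),
                                    enrichment_delta = unname(y),
                                    stringsAsFactors = FALSE)),
            class = "concordance_result")
}
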