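# Minimal VCFv4.2 emission/ingestion for consensus-rule SNP calls.

#' Write SNP calls as VCFv4.2
#'
#' Emits a minimal VCF with `DP` (depth) and `AF` (alternate fraction) INFO
#' fields. Records are sorted by (chrom, pos); unsorted input is sorted on
#' write with a message. Caller parameters can be recorded in the header.
#'
#' @param variants Data frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `depth`, `af`.
#' @param path Output path.
#' @param meta Optional named character vector written as extra
#'   `##<name>=<value>` header lines (e.g. the call threshold and minimum
#'   depth used).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, meta = NULL) {
  needed <- c("chrom", "pos", "ref", "alt", "depth", "af")
  stopifnot(all(needed %in% names(variants)))
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants))) && nrow(variants) > 1)
    message("write_vcf: records were not sorted; sorting by (chrom, pos)")
  variants <- variants[ord, , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=acetylscape %s",
            as.character(utils::packageVersion("acetylscape"))),
    if (!is.null(meta)) sprintf("##%s=%s", names(meta), unname(meta)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%s",
            variants$chrom, as.integer(variants$pos), variants$ref,
            variants$alt, as.integer(variants$depth),
            format(variants$af, trim = TRUE, digits = 6))
  } else {
    character()
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path File path.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `depth`, `af`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), af = numeric(),
                      stringsAsFactors = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[`, character(1), 8L)
  get_info <- function(key) {
    m <- regmatches(info, regexpr(sprintf("(?<=%s=)[^;]+", key), info,
                                  perl = TRUE))
    as.numeric(m)
  }
  data.frame(chrom = vapply(f, `[`, character(1), 1L),
             pos = as.integer(vapply(f, `[`, character(1), 2L)),
             ref = vapply(f, `[`, character(1), 4L),
             alt = vapply(f, `[`, character(1), 5L),
             depth = as.integer(get_info("DP")),
             af = get_info("AF"),
             stringsAsFactors = FALSE)
}
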