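# samtools-mpileup text parsing. The base string grammar consumed here:
#   '.' / ','        match to the reference (forward / reverse strand)
#   ACGTN / acgtn    mismatch (strand-coded case; pooled case-insensitively)
#   '^q'             read start: '^' plus one mapping-quality character
#   '$'              read end marker
#   '+n<seq>'/'-n<seq>'  insertion/deletion of n bases following this base
#   '*'              deleted base (placeholder counted in depth)

.parse_base_string <- function(s, depth, where) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  ref_n <- 0L
  del_n <- 0L
  ins <- character()
  del <- character()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {            # read start: skip the quality character too
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "." || ch == ",") {
      ref_n <- ref_n + 1L
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (is.na(len) || j + len - 1L > n)
        .stopf("%s: malformed indel run in pileup base string", where)
      seq <- toupper(paste(chars[j:(j + len - 1L)], collapse = ""))
      if (ch == "+") ins <- c(ins, seq) else del <- c(del, seq)
      i <- j + len
    } else if (ch == "*") {
      del_n <- del_n + 1L
      i <- i + 1L
    } else if (toupper(ch) %in% names(counts)) {
      b <- toupper(ch)
      counts[b] <- counts[b] + 1L
      i <- i + 1L
    } else {
      .stopf("%s: unexpected character '%s' in pileup base string", where, ch)
    }
  }
  total <- ref_n + sum(counts) + del_n
  if (total != depth)
    .stopf("%s: declared depth %d but parsed %d read bases", where, depth,
           total)
  list(ref_n = ref_n, counts = counts, del_n = del_n, ins = ins, del = del)
}

#' Parse samtools mpileup text
#'
#' Reads the 6-column mpileup format (chrom, 1-based position, reference
#' base, depth, base string, base qualities) and resolves each base string
#' into reference-match and per-alternate counts. Forward- and reverse-strand
#' symbols are pooled case-insensitively; read-start (`^q`), read-end (`$`)
#' and indel (`+n`/`-n`) runs are consumed per the format grammar, and a
#' declared-vs-parsed depth mismatch is an error naming the position.
#'
#' @param path Path to an mpileup text file.
#' @return Data frame of class `pileup` with one row per column: `chrom`,
#'   `pos`, `ref`, `depth`, `ref_count`, `A`, `C`, `G`, `T`, `N`, `del`
#'   (deleted-base placeholders) and a list column `indels` of per-column
#'   indel event tables (`type`, `seq`, `count`).
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5)
      .stopf("line %d: mpileup records need at least 5 fields", k)
    depth <- as.integer(f[4])
    where <- sprintf("%s:%s", f[1], f[2])
    p <- .parse_base_string(f[5], depth, where)
    indels <- if (length(p$ins) + length(p$del) > 0) {
      ev <- rbind(
        if (length(p$ins)) data.frame(type = "ins", seq = p$ins,
                                      stringsAsFactors = FALSE),
        if (length(p$del)) data.frame(type = "del", seq = p$del,
                                      stringsAsFactors = FALSE))
      stats::aggregate(list(count = rep(1L, nrow(ev))),
                       by = ev[c("type", "seq")], FUN = sum)
    } else {
      data.frame(type = character(), seq = character(), count = integer(),
                 stringsAsFactors = FALSE)
    }
    out[[k]] <- list(chrom = f[1], pos = as.integer(f[2]),
                     ref = toupper(f[3]), depth = depth,
                     ref_count = p$ref_n, counts = p$counts, del = p$del_n,
                     indels = indels)
  }
  df <- data.frame(
    chrom = vapply(out, `[[`, character(1), "chrom"),
    pos = vapply(out, `[[`, integer(1), "pos"),
    ref = vapply(out, `[[`, character(1), "ref"),
    depth = vapply(out, `[[`, integer(1), "depth"),
    ref_count = vapply(out, `[[`, integer(1), "ref_count"),
    stringsAsFactors = FALSE)
  cmat <- t(vapply(out, `[[`, c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L),
                   "counts"))
  df <- cbind(df, as.data.frame(cmat))
  df$del <- vapply(out, `[[`, integer(1), "del")
  df$indels <- I(lapply(out, `[[`, "indels"))
  class(df) <- c("pileup", "data.frame")
  df
}

#' Write an mpileup-format table
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `depth`, `bases`
#'   and optionally `quals` (as produced by [make_pileups()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(df, path) {
  stopifnot(all(c("chrom", "pos", "ref", "depth", "bases") %in% names(df)))
  quals <- df$quals %||% strrep("I", df$depth)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%s\t%s", df$chrom, as.integer(df$pos),
                     df$ref, as.integer(df$depth), df$bases, quals),
             path)
  invisible(path)
}
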