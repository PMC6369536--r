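# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x) &&
    x == floor(x) && (if (positive) x > 0 else x >= 0)
}

.is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# row-wise sample variances of a numeric matrix (NA-tolerant)
.row_vars <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  v[n < 2L] <- NA_real_
  v
}

# run `code` under a fixed RNG state, restoring it afterwards
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% (.Machine$integer.max - 1L)), code)
}

# centered running sum with partial windows at the edges
.running_sum <- function(x, half_bins) {
  n <- length(x)
  if (half_bins <= 0L || n == 0L) return(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_bins, 1L)
  hi <- pmin(i + half_bins, n)
  cs[hi + 1L] - cs[lo]
}

# centered running mean with partial windows at the edges
.running_mean <- function(x, half_bins) {
  n <- length(x)
  if (half_bins <= 0L || n == 0L) return(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_bins, 1L)
  hi <- pmin(i + half_bins, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sum of a binned step function over [start, end) with fractional end bins.
# `vals` holds one value per bin of width `bw` starting at coordinate 0.
.region_sums <- function(vals, starts, ends, bw) {
  n <- length(vals)
  cs <- c(0, cumsum(vals))
  G <- function(p) {
    p <- pmin(pmax(p, 0), n * bw)
    i <- pmin(floor(p / bw), n - 1e-9)
    i <- as.integer(i)
    frac <- p - i * bw
    full <- cs[i + 1L]
    part <- ifelse(i < n, vals[pmin(i + 1L, n)] * frac / bw, 0)
    full + part
  }
  G(ends) - G(starts)
}
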