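# Internal helpers shared across modules.

# stop() with call. = FALSE everywhere so users see the message, not internals
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .fail("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    .fail("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    .fail("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper) .fail("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# data.frame of 0-based half-open intervals -> GRanges (1-based closed)
.df_to_gr <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = as.character(df[[chrom]]),
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]])
  )
}

# Quantile normalization of the columns of a matrix; the reference
# distribution is the mean of the column-sorted values, ties averaged.
.quantile_normalize <- function(x) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  sorted <- apply(x, 2L, sort)
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    # fractional ranks (ties) interpolate between adjacent reference values
    out[, j] <- stats::approx(seq_len(n), ref, xout = r, rule = 2)$y
  }
  out
}

# Benjamini-Hochberg, kept as a named wrapper for readability at call sites
.bh <- function(p) stats::p.adjust(p, method = "BH")
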