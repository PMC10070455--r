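#' Contact map container
#'
#' A `contact_map` holds one chromosome's binned, symmetric Hi-C contact
#' matrix together with its resolution and (after balancing) the per-bin
#' correction weights. Bins are 0-based; genomic intervals derived from bins
#' follow the BED 0-based half-open convention.
#'
#' @param counts Symmetric, non-negative numeric matrix of contact counts.
#' @param resolution Bin size in bp.
#' @param chrom Chromosome label.
#' @param weights Optional per-bin balancing weights (positive on unmasked
#'   bins, `NA` on masked bins).
#' @param balanced `FALSE` for raw counts, otherwise the balancing method
#'   label (`"VC"` or `"ICE"`).
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(counts, resolution, chrom = "chr1", weights = NULL,
                        balanced = FALSE) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    .fail("'counts' must be a square matrix")
  if (any(counts < 0, na.rm = TRUE)) .fail("contact counts must be >= 0")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8)
    .fail("'counts' must be symmetric")
  .check_number(resolution, "resolution", lower = 0, strict_lower = TRUE)
  n <- nrow(counts)
  if (!is.null(weights)) {
    if (length(weights) != n) .fail("'weights' must have length n_bins")
    if (any(weights[!is.na(weights)] <= 0))
      .fail("balancing weights must be positive on unmasked bins")
  }
  structure(
    list(chrom = chrom, resolution = as.integer(resolution), n_bins = n,
         counts = counts, weights = weights, balanced = balanced),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins @ %d bp, total %.4g, balanced: %s\n",
              x$chrom, x$n_bins, x$resolution, sum(x$counts),
              as.character(x$balanced)))
  invisible(x)
}

#' Read a contact map from text
#'
#' Sparse format is whitespace-separated `bin1 bin2 count` with 0-based bins
#' and one record per bin pair (upper or lower triangle; mirrored duplicates
#' with equal counts are collapsed, conflicting duplicates are an error).
#' Dense format is a whitespace-separated full matrix.
#'
#' @param path File to read.
#' @param n_bins Number of bins (required for sparse format).
#' @param resolution Bin size in bp.
#' @param chrom Chromosome label.
#' @param format `"sparse"` or `"dense"`.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, n_bins = NULL, resolution, chrom = "chr1",
                             format = c("sparse", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    return(contact_map(m, resolution, chrom))
  }
  if (is.null(n_bins)) .fail("'n_bins' is required for sparse format")
  df <- utils::read.table(path, col.names = c("bin1", "bin2", "count"),
                          colClasses = "numeric")
  if (nrow(df) == 0) {
    return(contact_map(matrix(0, n_bins, n_bins), resolution, chrom))
  }
  bad <- which(df$bin1 < 0 | df$bin1 >= n_bins | df$bin2 < 0 |
                 df$bin2 >= n_bins)
  if (length(bad))
    .fail("line %d: bin %d out of range [0, %d)", bad[1],
          max(df$bin1[bad[1]], df$bin2[bad[1]]), n_bins)
  neg <- which(df$count < 0)
  if (length(neg)) .fail("line %d: negative count %g", neg[1], df$count[neg[1]])
  # canonicalize to upper triangle and collapse mirrored duplicates
  i <- pmin(df$bin1, df$bin2)
  j <- pmax(df$bin1, df$bin2)
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    agg <- tapply(df$count, key, function(v) {
      if (length(unique(v)) > 1L)
        .fail("conflicting duplicate records for bin pair (%s)",
              names(which.max(table(v))))
      v[1]
    })
    first <- !duplicated(key)
    i <- i[first]; j <- j[first]
    cnt <- as.numeric(agg[key[first]])
  } else {
    cnt <- df$count
  }
  m <- matrix(0, n_bins, n_bins)
  m[cbind(i + 1L, j + 1L)] <- cnt
  m[cbind(j + 1L, i + 1L)] <- cnt
  contact_map(m, resolution, chrom)
}

#' Write a contact map to text
#'
#' Sparse output is canonical: upper triangle (including diagonal), non-zero
#' entries only, sorted by `bin1` then `bin2`, 0-based bins.
#'
#' @param map A [contact_map()].
#' @param path Output file.
#' @param format `"sparse"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("sparse", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(map$counts, path, row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  ut <- which(upper.tri(map$counts, diag = TRUE) & map$counts != 0,
              arr.ind = TRUE)
  df <- data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                   count = map$counts[ut])
  df <- df[order(df$bin1, df$bin2), ]
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Bins masked for balancing/eigen analysis: zero-coverage bins plus the
# lowest mask_frac quantile of positive bin sums (standard low-coverage mask).
.mask_bins <- function(counts, mask_frac) {
  rs <- rowSums(counts)
  masked <- rs == 0
  pos <- rs[rs > 0]
  if (mask_frac > 0 && length(pos)) {
    thr <- stats::quantile(pos, mask_frac)
    masked <- masked | (rs < thr)  # strict: a constant map masks nothing
  }
  masked
}

#' Balance a contact map
#'
#' Vanilla-coverage (VC) divides each entry by the product of its row and
#' column sums and rescales to preserve the matrix total. Iterative correction
#' (ICE) repeatedly divides by normalized bin sums until the coefficient of
#' variation of unmasked bin sums falls below `tol`.
#'
#' @param map Raw [contact_map()].
#' @param method `"ICE"` or `"VC"`.
#' @param max_iter Maximum ICE iterations.
#' @param tol Convergence tolerance on the coefficient of variation of
#'   unmasked bin sums.
#' @param mask_low_coverage_frac Fraction of lowest-coverage (positive-sum)
#'   bins masked before balancing; zero-sum bins are always masked.
#' @return A balanced [contact_map()] with `weights` filled in.
#' @export
balance <- function(map, method = c("ICE", "VC"), max_iter = 200, tol = 1e-4,
                    mask_low_coverage_frac = 0.02) {
  method <- match.arg(method)
  if (!identical(map$balanced, FALSE)) .fail("map is already balanced")
  m <- map$counts
  if (sum(m) == 0) .fail("cannot balance an all-zero matrix")
  masked <- .mask_bins(m, mask_low_coverage_frac)
  if (all(masked)) .fail("all bins masked; nothing to balance")
  m[masked, ] <- 0
  m[, masked] <- 0
  total <- sum(m)
  w <- rep(1, map$n_bins)
  if (method == "VC") {
    rs <- rowSums(m)
    rs_safe <- ifelse(rs > 0, rs, 1)
    raw <- m / outer(rs_safe, rs_safe)
    scale <- total / sum(raw)
    b <- raw * scale
    w <- ifelse(rs > 0, rs_safe / sqrt(scale), NA)
  } else {
    b <- m
    converged <- FALSE
    cv <- NA_real_
    for (it in seq_len(max_iter)) {
      rs <- rowSums(b)
      live <- !masked & rs > 0
      mu <- mean(rs[live])
      cv <- stats::sd(rs[live]) / mu
      if (is.na(cv) || cv < tol) { converged <- TRUE; break }
      s <- ifelse(live, rs / mu, 1)
      b <- b / outer(s, s)
      w <- w * s
    }
    if (!converged)
      .fail("ICE did not converge in %d iterations (residual CV %.3g > %.3g)",
            max_iter, cv, tol)
    # keep the total on the raw-count scale; fold the rescale into the
    # weights so that balanced * w_i * w_j always recovers the raw counts
    res_scale <- total / sum(b)
    b <- b * res_scale
    w <- w / sqrt(res_scale)
  }
  w[masked] <- NA
  contact_map(b, map$resolution, map$chrom, weights = w, balanced = method)
}

#' Distance-decay curve
#'
#' Mean contact per (optionally log-spaced) distance stratum. With
#' `log_bin_factor = 1` every bin-distance is its own stratum. Strata with no
#' contacts are reported with value 0.
#'
#' @param map A [contact_map()].
#' @param log_bin_factor Multiplicative stratum growth factor (>= 1).
#' @param condition Optional label stored on the curve.
#' @return A data.frame with columns `distance` (bp, geometric stratum
#'   center), `value` (mean contact per pair), `n_pairs`.
#' @export
decay_curve <- function(map, log_bin_factor = 1.3, condition = NA_character_) {
  .check_number(log_bin_factor, "log_bin_factor", lower = 1)
  n <- map$n_bins
  res <- map$resolution
  d <- seq_len(n - 1L)
  # per-distance totals via diagonal sums
  tot <- vapply(d, function(k) {
    idx <- seq_len(n - k)
    sum(map$counts[cbind(idx, idx + k)])
  }, numeric(1))
  npair <- n - d
  if (log_bin_factor == 1) {
    out <- data.frame(distance = d * res, value = tot / npair,
                      n_pairs = npair)
  } else {
    edges <- res
    while (edges[length(edges)] < n * res)
      edges <- c(edges, edges[length(edges)] * log_bin_factor)
    stratum <- findInterval(d * res, edges)
    agg_t <- tapply(tot, stratum, sum)
    agg_n <- tapply(npair, stratum, sum)
    ids <- as.integer(names(agg_t))
    centers <- sqrt(edges[ids] * pmin(edges[ids + 1L], n * res))
    out <- data.frame(distance = centers, value = as.numeric(agg_t / agg_n),
                      n_pairs = as.numeric(agg_n))
  }
  attr(out, "condition") <- condition
  attr(out, "resolution") <- res
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Differential decay between two curves
#'
#' Per-stratum `log2((a + pc) / (b + pc))`. The default pseudocount is the
#' smallest positive stratum mean observed in either curve.
#'
#' @param curve_a,curve_b Decay curves from [decay_curve()] on matching strata.
#' @param pseudocount Optional pseudocount; default described above.
#' @return Data.frame with `distance` and `log2_ratio`.
#' @export
differential_decay <- function(curve_a, curve_b, pseudocount = NULL) {
  if (nrow(curve_a) != nrow(curve_b) ||
      any(abs(curve_a$distance - curve_b$distance) > 1e-6))
    .fail("decay curves must share identical distance strata")
  if (is.null(pseudocount)) {
    pos <- c(curve_a$value[curve_a$value > 0], curve_b$value[curve_b$value > 0])
    pseudocount <- if (length(pos)) min(pos) else 1
  }
  data.frame(distance = curve_a$distance,
             log2_ratio = log2((curve_a$value + pseudocount) /
                                 (curve_b$value + pseudocount)))
}

#' Fit a power-law exponent to a decay curve
#'
#' Least-squares regression of `log10(value)` on `log10(distance)` over the
#' requested range; the reported exponent is the negated slope.
#'
#' @param curve A [decay_curve()] result.
#' @param fit_range Length-2 bp range (inclusive) used for the fit.
#' @return List with `exponent`, `se`, `n_strata`.
#' @export
fit_power_law <- function(curve, fit_range = range(curve$distance)) {
  keep <- curve$distance >= fit_range[1] & curve$distance <= fit_range[2] &
    curve$value > 0
  if (sum(keep) < 5)
    .fail("need >= 5 strata with positive values in fit range (have %d)",
          sum(keep))
  fit <- stats::lm(log10(value) ~ log10(distance), data = curve[keep, ])
  co <- suppressWarnings(summary(fit))$coefficients  # exact curves fit perfectly
  list(exponent = -co[2, 1], se = co[2, 2], n_strata = sum(keep))
}

#' Map-resolution check
#'
#' A resolution passes when the fraction of bins whose marginal count strictly
#' exceeds `count_threshold` is at least `pass_fraction`.
#'
#' @param map Raw [contact_map()].
#' @param count_threshold Contacts a bin must exceed (strict).
#' @param pass_fraction Minimum passing fraction of bins.
#' @return List with `pass` (logical) and `fraction`.
#' @export
estimate_resolution <- function(map, count_threshold = 1000,
                                pass_fraction = 0.8) {
  rs <- rowSums(map$counts)
  frac <- mean(rs > count_threshold)
  list(pass = frac >= pass_fraction, fraction = frac)
}

# 2D box-filter smoothing with half-window h (mean over the valid
# (2h+1)x(2h+1) neighborhood; edges use the truncated neighborhood).
.smooth2d <- function(m, h) {
  if (h == 0) return(m)
  n <- nrow(m)
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (di in -h:h) {
    ri <- max(1, 1 - di):min(n, n - di)
    for (dj in -h:h) {
      cj <- max(1, 1 - dj):min(n, n - dj)
      acc[ri, cj] <- acc[ri, cj] + m[ri + di, cj + dj]
      cnt[ri, cj] <- cnt[ri, cj] + 1
    }
  }
  acc / cnt
}

#' Stratum-adjusted correlation coefficient
#'
#' Reproducibility between two maps of the same chromosome and resolution:
#' both matrices are mean-filter smoothed, then per-distance-stratum Pearson
#' correlations are averaged with weights `N_d * sqrt(var_a * var_b)`.
#' Zero-variance strata are skipped with a warning.
#'
#' @param map_a,map_b [contact_map()]s on the same bins.
#' @param smoothing_half_window_bins Half-window of the 2D mean filter.
#' @param max_distance_bp Largest stratum distance used.
#' @return The SCC, a number in `[-1, 1]`.
#' @export
scc <- function(map_a, map_b, smoothing_half_window_bins = 1,
                max_distance_bp = 5e6) {
  if (map_a$n_bins != map_b$n_bins || map_a$resolution != map_b$resolution)
    .fail("maps must share binning")
  n <- map_a$n_bins
  a <- .smooth2d(map_a$counts, smoothing_half_window_bins)
  b <- .smooth2d(map_b$counts, smoothing_half_window_bins)
  dmax <- min(n - 1L, floor(max_distance_bp / map_a$resolution))
  num <- 0; den <- 0; skipped <- 0L
  for (k in seq_len(dmax)) {
    idx <- seq_len(n - k)
    x <- a[cbind(idx, idx + k)]
    y <- b[cbind(idx, idx + k)]
    vx <- stats::var(x); vy <- stats::var(y)
    if (is.na(vx) || is.na(vy) || vx == 0 || vy == 0) {
      skipped <- skipped + 1L
      next
    }
    w <- length(x) * sqrt(vx * vy)
    num <- num + w * stats::cor(x, y)
    den <- den + w
  }
  if (skipped > 0)
    warning(sprintf("%d degenerate (zero-variance) strata skipped", skipped))
  if (den == 0) .fail("no informative strata for SCC")
  num / den
}

#' Classical MDS embedding of a distance matrix
#'
#' Wraps [stats::cmdscale()] with a deterministic orientation: each output
#' dimension is flipped so the first sample's coordinate is non-negative.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g. `1 - scc`).
#' @param k Number of dimensions.
#' @return An `n x k` coordinate matrix.
#' @export
mds_embed <- function(d, k = 2) {
  d <- as.matrix(d)
  if (any(abs(diag(d)) > 1e-12)) .fail("distance matrix must have zero diagonal")
  if (max(abs(d - t(d))) > 1e-8) .fail("distance matrix must be symmetric")
  n <- nrow(d)
  if (all(d == 0)) return(matrix(0, n, k))
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k))
  if (ncol(xy) < k) xy <- cbind(xy, matrix(0, n, k - ncol(xy)))
  for (j in seq_len(k)) if (xy[1, j] < 0) xy[, j] <- -xy[, j]
  xy
}

# Observed/expected matrix: each diagonal divided by its mean over unmasked
# pairs. Masked bins get NA. Used by compartments, saddle, APA and loops.
.obs_exp <- function(counts, masked = NULL) {
  n <- nrow(counts)
  if (is.null(masked)) masked <- rep(FALSE, n)
  m <- counts
  m[masked, ] <- NA
  m[, masked] <- NA
  oe <- matrix(NA_real_, n, n)
  for (k in 0:(n - 1L)) {
    idx <- seq_len(n - k)
    v <- m[cbind(idx, idx + k)]
    mu <- mean(v, na.rm = TRUE)
    if (!is.na(mu) && mu > 0) {
      oe[cbind(idx, idx + k)] <- v / mu
      oe[cbind(idx + k, idx)] <- v / mu
    }
  }
  oe
}
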