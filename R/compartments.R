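#' Call A/B compartments from a balanced contact map
#'
#' Eigendecomposition of the correlation matrix of the distance-normalized
#' (observed/expected) map. Among the first `n_components` eigenvectors, the
#' one with the largest absolute correlation with gene density is selected
#' (GC content breaks near-ties), and its sign is flipped so that correlation
#' with gene density is positive: A compartment = positive score.
#'
#' @param map A balanced [contact_map()].
#' @param gene_density_track Per-bin gene density (numeric vector of length
#'   `n_bins`, or a data.frame with a `value` column binned at map resolution).
#' @param gc_track Optional per-bin GC content, same formats.
#' @param n_components Number of leading eigenvectors considered.
#' @param min_abs_cor Below this absolute gene-density correlation the
#'   orientation is ambiguous and an error is raised rather than guessing.
#' @return A `compartment_track`: list with `chrom`, `resolution`, `score`
#'   (signed per-bin, `NA` on masked bins), `component` (selected index), and
#'   orientation diagnostics `cor_gene_density`, `cor_gc`.
#' @export
call_compartments <- function(map, gene_density_track, gc_track = NULL,
                              n_components = 3, min_abs_cor = 0.1) {
  as_vec <- function(x) if (is.data.frame(x)) x$value else x
  gd <- as_vec(gene_density_track)
  gc <- if (is.null(gc_track)) NULL else as_vec(gc_track)
  if (length(gd) != map$n_bins)
    .fail("gene density track must have one value per bin")
  masked <- if (!is.null(map$weights)) is.na(map$weights) else
    rowSums(map$counts) == 0
  if (all(masked)) .fail("all bins masked on this chromosome")
  oe <- .obs_exp(map$counts, masked)
  keep <- which(!masked)
  oe_k <- oe[keep, keep, drop = FALSE]
  oe_k[!is.finite(oe_k)] <- 0
  cm <- suppressWarnings(stats::cor(oe_k))
  cm[!is.finite(cm)] <- 0
  eig <- eigen(cm, symmetric = TRUE)
  n_components <- min(n_components, length(keep))
  cors_gd <- numeric(n_components)
  cors_gc <- rep(NA_real_, n_components)
  for (k in seq_len(n_components)) {
    v <- eig$vectors[, k]
    cors_gd[k] <- suppressWarnings(stats::cor(v, gd[keep]))
    if (!is.null(gc))
      cors_gc[k] <- suppressWarnings(stats::cor(v, gc[keep]))
  }
  cors_gd[is.na(cors_gd)] <- 0
  best <- which.max(abs(cors_gd))
  # GC as tiebreaker when another component is within 0.02 of the best
  near <- which(abs(abs(cors_gd) - abs(cors_gd[best])) < 0.02)
  if (length(near) > 1 && !is.null(gc) && !all(is.na(cors_gc[near])))
    best <- near[which.max(abs(cors_gc[near]))]
  if (abs(cors_gd[best]) < min_abs_cor)
    .fail(paste0("orientation ambiguous: no leading eigenvector correlates ",
                 "with gene density (max |r| = %.3f)"), abs(cors_gd[best]))
  v <- eig$vectors[, best] * sqrt(max(eig$values[best], 0))
  if (cors_gd[best] < 0) v <- -v
  score <- rep(NA_real_, map$n_bins)
  score[keep] <- v
  structure(list(chrom = map$chrom, resolution = map$resolution,
                 score = score, component = best,
                 cor_gene_density = abs(cors_gd[best]),
                 cor_gc = cors_gc[best]),
            class = "compartment_track")
}

#' Saddle matrix of a compartment track
#'
#' Bins are ranked by compartment score into `n_groups` equal-size percentile
#' groups (ties broken by rank order); cell (g, h) is `log2` of the mean
#' observed/expected contact over all bin pairs in groups g and h (diagonal
#' pairs excluded). Group 1 is the strongest B, group `n_groups` the
#' strongest A.
#'
#' @param map A balanced [contact_map()].
#' @param track A `compartment_track` (or numeric score vector) aligned with
#'   the map.
#' @param n_groups Number of percentile groups.
#' @return A `saddle_summary`: list with `matrix` (log2 scale,
#'   `n_groups x n_groups`), `n_groups`, `group_of_bin`.
#' @export
saddle <- function(map, track, n_groups = 50) {
  score <- if (inherits(track, "compartment_track")) track$score else track
  if (length(score) != map$n_bins) .fail("track and map are not aligned")
  masked <- if (!is.null(map$weights)) is.na(map$weights) else
    rowSums(map$counts) == 0
  ok <- which(!masked & is.finite(score))
  if (length(ok) < n_groups) .fail("fewer informative bins than groups")
  oe <- .obs_exp(map$counts, masked)
  ord <- ok[order(score[ok])]                       # ties -> original order
  grp_of <- rep(NA_integer_, map$n_bins)
  grp_of[ord] <- ceiling(seq_along(ord) * n_groups / length(ord))
  acc <- matrix(0, n_groups, n_groups)
  cnt <- matrix(0, n_groups, n_groups)
  n <- map$n_bins
  ut <- which(upper.tri(oe), arr.ind = TRUE)
  gi <- grp_of[ut[, 1]]
  gj <- grp_of[ut[, 2]]
  v <- oe[ut]
  good <- !is.na(gi) & !is.na(gj) & is.finite(v)
  gi <- gi[good]; gj <- gj[good]; v <- v[good]
  for (pair in list(cbind(gi, gj), cbind(gj, gi))) {
    sums <- tapply(v, list(pair[, 1], pair[, 2]), sum)
    ns <- tapply(v, list(pair[, 1], pair[, 2]), length)
    ridx <- as.integer(rownames(sums))
    cidx <- as.integer(colnames(sums))
    sums[is.na(sums)] <- 0
    ns[is.na(ns)] <- 0
    acc[ridx, cidx] <- acc[ridx, cidx] + sums
    cnt[ridx, cidx] <- cnt[ridx, cidx] + ns
  }
  # the two orientations double-count symmetric (g==h) cells consistently,
  # so the mean is unaffected
  mat <- log2(acc / cnt)
  structure(list(matrix = mat, n_groups = n_groups, group_of_bin = grp_of),
            class = "saddle_summary")
}

#' Compartment interaction strengths from a saddle matrix
#'
#' Mean log2 enrichment over the corner blocks of the saddle matrix, returned
#' on the enrichment (ratio) scale: `AA` uses the top `top_fraction` of score
#' percentiles, `BB` the bottom, and `AB` the off-diagonal corner.
#'
#' @param saddle_matrix The log2-scale matrix from [saddle()], or a
#'   `saddle_summary`.
#' @param top_fraction Fraction of percentile groups in each corner.
#' @return Named vector `c(AA, BB, AB)` on the ratio scale.
#' @export
compartment_strength <- function(saddle_matrix, top_fraction = 0.2) {
  m <- if (inherits(saddle_matrix, "saddle_summary")) saddle_matrix$matrix else
    saddle_matrix
  n <- nrow(m)
  k <- max(1L, round(top_fraction * n))
  bot <- seq_len(k)
  top <- (n - k + 1L):n
  corner <- function(rows, cols) 2^mean(m[rows, cols], na.rm = TRUE)
  c(AA = corner(top, top), BB = corner(bot, bot), AB = corner(bot, top))
}

#' Compartmentalization score
#'
#' `log((AA * BB) / AB^2)` in the given base (default 2). Zero when the three
#' strengths are equal; invariant under joint rescaling of all three.
#'
#' @param AA,BB,AB Corner strengths on the ratio scale (> 0).
#' @param base Logarithm base.
#' @return The score (scalar).
#' @export
compartmentalization_score <- function(AA, BB, AB, base = 2) {
  for (v in c(AA, BB, AB)) .check_number(v, "strength", lower = 0,
                                         strict_lower = TRUE)
  log((AA * BB) / AB^2, base = base)
}

#' Differential compartment testing across samples
#'
#' Scores are quantile-normalized across samples; per bin, the
#' between-condition difference of means is converted to a squared
#' Mahalanobis distance against the pooled replicate variance, with a
#' chi-square p-value (1 d.f.), Benjamini-Hochberg FDR, and a switch class
#' from the signs of the two condition means.
#'
#' @param scores Numeric matrix, bins x samples (or list of
#'   `compartment_track`s).
#' @param conditions Character vector of per-sample condition labels; exactly
#'   two distinct conditions, the first level taken as the reference ("PR").
#' @param fdr_threshold Significance threshold on the FDR.
#' @param ridge Variance floor added when replicate variance is degenerate
#'   (applied with a warning).
#' @return A data.frame (`diff_compartment_table`) with per-bin columns
#'   `bin, score_pr, score_cr, mdist, p, fdr, significant, class`.
#' @export
differential_compartments <- function(scores, conditions,
                                      fdr_threshold = 0.3, ridge = 1e-8) {
  if (is.list(scores) && !is.data.frame(scores) && !is.matrix(scores))
    scores <- do.call(cbind, lapply(scores, function(t) t$score))
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) .fail("need at least 2 samples")
  if (length(conditions) != ncol(scores))
    .fail("one condition label per sample is required")
  lev <- unique(conditions)
  if (length(lev) != 2) .fail("exactly two conditions are required")
  complete <- stats::complete.cases(scores)
  qn <- scores
  qn[complete, ] <- .quantile_normalize(scores[complete, , drop = FALSE])
  a <- qn[, conditions == lev[1], drop = FALSE]   # reference (PR)
  b <- qn[, conditions == lev[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 && n2 < 2)
    .fail("at least one condition needs replicates to estimate variance")
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  resid <- cbind(a - mean_a, b - mean_b)
  dfree <- (n1 - 1) + (n2 - 1)
  pooled_var <- sum(resid[complete, ]^2, na.rm = TRUE) /
    (sum(complete) * dfree)
  if (!is.finite(pooled_var) || pooled_var <= ridge) {
    warning(sprintf("degenerate replicate variance; ridge %.1e applied", ridge))
    pooled_var <- pooled_var + ridge
  }
  var_d <- pooled_var * (1 / n1 + 1 / n2)
  d <- mean_b - mean_a
  mdist <- d^2 / var_d
  p <- stats::pchisq(mdist, df = 1, lower.tail = FALSE)
  fdr <- rep(NA_real_, length(p))
  fdr[complete] <- .bh(p[complete])
  cls <- paste0(ifelse(mean_a > 0, "A", "B"), ifelse(mean_b > 0, "A", "B"))
  cls[!complete] <- NA
  out <- data.frame(bin = seq_len(nrow(scores)) - 1L,
                    score_pr = mean_a, score_cr = mean_b,
                    mdist = mdist, p = p, fdr = fdr,
                    significant = !is.na(fdr) & fdr < fdr_threshold,
                    class = cls)
  class(out) <- c("diff_compartment_table", "data.frame")
  out
}

#' Classify compartment switches between two conditions
#'
#' Per-bin class from the sign pair (reference, rewired): positive = A.
#' Fractions are reported over all classified bins and, when significance
#' flags are given, over significant bins only; each reporting mode sums to 1.
#'
#' @param track_pr,track_cr Signed score vectors (or `compartment_track`s).
#' @param significant Optional logical vector of per-bin significance flags.
#' @return List with `class` (per-bin), `fractions_all`,
#'   `fractions_significant` (or `NULL`).
#' @export
classify_switches <- function(track_pr, track_cr, significant = NULL) {
  sp <- if (inherits(track_pr, "compartment_track")) track_pr$score else track_pr
  sc <- if (inherits(track_cr, "compartment_track")) track_cr$score else track_cr
  if (length(sp) != length(sc)) .fail("tracks must be aligned")
  cls <- ifelse(is.na(sp) | is.na(sc), NA,
                paste0(ifelse(sp > 0, "A", "B"), ifelse(sc > 0, "A", "B")))
  lv <- c("AA", "AB", "BA", "BB")
  frac <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(stats::setNames(rep(NA_real_, 4), lv))
    tab <- table(factor(x, levels = lv))
    as.numeric(tab) / length(x) -> f
    stats::setNames(f, lv)
  }
  out <- list(class = cls, fractions_all = frac(cls))
  out$fractions_significant <-
    if (is.null(significant)) NULL else frac(cls[which(significant)])
  out
}

#' Merge significant same-class bins into switch regions
#'
#' Adjacent significant bins of the same class become one region (BED
#' 0-based half-open coordinates).
#'
#' @param diff_table Output of [differential_compartments()].
#' @param class_vector Optional per-bin class overriding the table's.
#' @param chrom Chromosome label.
#' @param resolution Bin size in bp.
#' @return Data.frame `chrom, start, end, class`.
#' @export
switch_regions <- function(diff_table, class_vector = NULL, chrom = "chr1",
                           resolution = 1L) {
  cls <- if (is.null(class_vector)) diff_table$class else class_vector
  sig <- diff_table$significant & !is.na(cls)
  bins <- diff_table$bin
  keep <- which(sig)
  if (!length(keep))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character()))
  runs <- split(keep, cumsum(c(1, diff(keep) != 1 |
                                 cls[keep][-1] != cls[keep][-length(keep)])))
  do.call(rbind, lapply(runs, function(ix) {
    data.frame(chrom = chrom, start = bins[ix[1]] * resolution,
               end = (bins[ix[length(ix)]] + 1) * resolution,
               class = cls[ix[1]])
  })) -> out
  rownames(out) <- NULL
  out
}

#' Count genes in compartment switch categories
#'
#' A gene counts toward a class when its interval overlaps (>= 1 bp) any
#' region of that class; a gene can count in several classes. Active total =
#' AA + BA, inactive total = BB + AB.
#'
#' @param gene_bed Data.frame `chrom, start, end, gene` (0-based half-open).
#' @param class_regions Data.frame `chrom, start, end, class` (e.g. from
#'   [switch_regions()]).
#' @return List with `counts` (named per class), `active_total`,
#'   `inactive_total`, and `genes` (per-class gene lists).
#' @export
genes_in_switch_categories <- function(gene_bed, class_regions) {
  lv <- c("AA", "AB", "BA", "BB")
  counts <- stats::setNames(integer(4), lv)
  genes <- stats::setNames(vector("list", 4), lv)
  if (nrow(gene_bed) && nrow(class_regions)) {
    g <- .df_to_gr(gene_bed)
    for (cl in lv) {
      reg <- class_regions[class_regions$class == cl, , drop = FALSE]
      if (!nrow(reg)) next
      hits <- GenomicRanges::findOverlaps(g, .df_to_gr(reg))
      idx <- unique(S4Vectors::queryHits(hits))
      counts[cl] <- length(idx)
      genes[[cl]] <- gene_bed$gene[idx]
    }
  }
  list(counts = counts,
       active_total = unname(counts["AA"] + counts["BA"]),
       inactive_total = unname(counts["BB"] + counts["AB"]),
       genes = genes)
}
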