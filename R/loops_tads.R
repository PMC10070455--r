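#' Call chromatin loops with donut-style local-enrichment filters
#'
#' The balanced map is first normalized by its global distance decay
#' (observed/expected). Each tested pixel is then compared against the most
#' demanding of four local background estimates -- the donut ring, the
#' horizontal and vertical stripes, and the lower-left quadrant. The local
#' enrichment ratio is estimated in balanced space, but the Poisson
#' upper-tail test is evaluated on the raw counts (recovered through the
#' balancing weights), so count noise is modeled on the scale where it is
#' actually Poisson. P-values are corrected across all tested pixels
#' (Benjamini-Hochberg) and calls passing the FDR threshold are reduced by
#' non-maximum suppression within the donut radius.
#'
#' @param map A balanced [contact_map()] (raw maps are accepted and treated
#'   as having unit weights).
#' @param p_threshold Per-pixel p-value prefilter for candidate status.
#' @param fdr_threshold FDR threshold on the corrected p-values.
#' @param donut_radius_bins Outer Chebyshev radius of the local filters; the
#'   central 3x3 block is excluded everywhere.
#' @param min_distance_bins Smallest bin distance tested.
#' @param max_distance_bins Largest bin distance tested (default: whole map).
#' @return Data.frame of loop calls sorted by position: `bin1, bin2`
#'   (0-based), anchor intervals in bp (`start1,end1,start2,end2`), `obs`,
#'   `expected`, `enrichment`, `p`, `fdr`, `size` (anchor midpoint distance,
#'   bp).
#' @export
call_loops <- function(map, p_threshold = 0.1, fdr_threshold = 0.05,
                       donut_radius_bins = 5, min_distance_bins = 2,
                       max_distance_bins = NULL) {
  n <- map$n_bins
  R <- as.integer(donut_radius_bins)
  if (2 * R + 1 > n) .fail("donut larger than the matrix")
  if (is.null(max_distance_bins)) max_distance_bins <- n - 1L
  w <- if (is.null(map$weights)) rep(1, n) else map$weights
  masked <- is.na(w)
  # all background estimation happens on the raw-count scale (recovered
  # through the balancing weights), where the noise is actually Poisson;
  # weight variation between a pixel and its local background cells would
  # otherwise distort the filter ratios
  wsafe <- ifelse(masked, 1, w)
  m <- map$counts * outer(wsafe, wsafe)
  ed <- numeric(n)                       # ed[k+1] = mean raw at distance k
  for (k in 0:(n - 1L)) {
    idx <- seq_len(n - k)
    v <- m[cbind(idx, idx + k)]
    ed[k + 1L] <- mean(v[!masked[idx] & !masked[idx + k]])
  }
  ed[!is.finite(ed)] <- 0
  edm <- matrix(ed[abs(outer(seq_len(n), seq_len(n), "-")) + 1L], n, n)
  oe <- ifelse(edm > 0, m / edm, 0)
  # tested pixels: upper triangle within the distance band, unmasked bins
  pix <- which(upper.tri(m), arr.ind = TRUE)
  dist <- pix[, 2] - pix[, 1]
  keep <- dist >= min_distance_bins & dist <= max_distance_bins &
    !masked[pix[, 1]] & !masked[pix[, 2]]
  pix <- pix[keep, , drop = FALSE]
  if (!nrow(pix)) .fail("no pixels in the tested band")
  i <- pix[, 1]; j <- pix[, 2]
  offs <- expand.grid(di = -R:R, dj = -R:R)
  cheb <- pmax(abs(offs$di), abs(offs$dj))
  offs <- offs[cheb >= 2, ]
  # 3-wide horizontal/vertical stripes, lower-left quadrant, donut = rest
  filt_of <- with(offs, ifelse(abs(di) <= 1, "h", ifelse(abs(dj) <= 1, "v",
                  ifelse(di >= 2 & dj <= -2, "ll", "donut"))))
  filters <- c("donut", "h", "v", "ll")
  acc <- matrix(0, length(i), 4, dimnames = list(NULL, filters))
  cnt <- matrix(0, length(i), 4, dimnames = list(NULL, filters))
  for (r in seq_len(nrow(offs))) {
    f <- filt_of[r]
    ii <- i + offs$di[r]
    jj <- j + offs$dj[r]
    # background cells stay off the near-diagonal (distance >= 2), where the
    # contact texture differs qualitatively from the tested band
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & (jj - ii) >= 2
    ok[ok] <- !masked[ii[ok]] & !masked[jj[ok]]
    idx <- which(ok)
    acc[idx, f] <- acc[idx, f] + oe[cbind(ii[idx], jj[idx])]
    cnt[idx, f] <- cnt[idx, f] + 1
  }
  ratio <- acc / pmax(cnt, 1)
  ratio[cnt == 0] <- 0
  # most demanding local background estimate
  expected <- pmax(ratio[, 1], ratio[, 2], ratio[, 3], ratio[, 4]) * edm[pix]
  obs <- m[pix]
  p <- stats::ppois(round(obs) - 1, lambda = pmax(expected, 1e-12),
                    lower.tail = FALSE)
  fdr <- .bh(p)
  hit <- which(obs > expected & p < p_threshold & fdr < fdr_threshold)
  if (!length(hit)) {
    out <- data.frame(bin1 = integer(), bin2 = integer(), start1 = numeric(),
                      end1 = numeric(), start2 = numeric(), end2 = numeric(),
                      obs = numeric(), expected = numeric(),
                      enrichment = numeric(), p = numeric(), fdr = numeric(),
                      size = numeric())
    return(out)
  }
  enr <- obs[hit] / pmax(expected[hit], 1e-12)
  ord <- hit[order(-enr)]
  kept <- integer(0)
  for (h in ord) {
    if (!length(kept) ||
        all(pmax(abs(i[kept] - i[h]), abs(j[kept] - j[h])) > R))
      kept <- c(kept, h)
  }
  res <- map$resolution
  out <- data.frame(bin1 = i[kept] - 1L, bin2 = j[kept] - 1L,
                    obs = obs[kept], expected = expected[kept],
                    enrichment = obs[kept] / pmax(expected[kept], 1e-12),
                    p = p[kept], fdr = fdr[kept])
  out$start1 <- out$bin1 * res; out$end1 <- (out$bin1 + 1) * res
  out$start2 <- out$bin2 * res; out$end2 <- (out$bin2 + 1) * res
  out$size <- (out$bin2 - out$bin1) * res
  out <- out[order(out$bin1, out$bin2),
             c("bin1", "bin2", "start1", "end1", "start2", "end2", "obs",
               "expected", "enrichment", "p", "fdr", "size")]
  rownames(out) <- NULL
  out
}

# flank-tolerant match of 0-based half-open intervals: intervals match when
# the gap between them is strictly smaller than the flank (equivalently,
# overlap after one of them is expanded by the flank on both sides)
.flank_overlap <- function(s1, e1, s2, e2, flank) {
  s1 < (e2 + flank) & s2 < (e1 + flank)
}

#' Partition two loop sets into common and condition-specific loops
#'
#' Two loops match when both anchor-1 intervals and both anchor-2 intervals
#' lie within a `flank_bins * resolution` flank of each other (gap strictly
#' smaller than the flank). Matching is greedy one-to-one in input order, so
#' the common count partitions both input totals exactly.
#'
#' @param loops_pr,loops_cr Loop tables with `start1,end1,start2,end2` (bp).
#' @param flank_bins Flank, in bins, allowed when testing anchor overlap.
#' @param resolution Bin size in bp.
#' @return List with `common` (data.frame of matched index pairs
#'   `pr_idx, cr_idx`), `pr_specific`, `cr_specific` (row indices), and
#'   `counts`.
#' @export
classify_loop_sets <- function(loops_pr, loops_cr, flank_bins = 1,
                               resolution) {
  flank <- flank_bins * resolution
  matched_cr <- rep(FALSE, nrow(loops_cr))
  pairs <- NULL
  for (a in seq_len(nrow(loops_pr))) {
    cand <- which(!matched_cr &
      .flank_overlap(loops_pr$start1[a], loops_pr$end1[a],
                     loops_cr$start1, loops_cr$end1, flank) &
      .flank_overlap(loops_pr$start2[a], loops_pr$end2[a],
                     loops_cr$start2, loops_cr$end2, flank))
    if (length(cand)) {
      matched_cr[cand[1]] <- TRUE
      pairs <- rbind(pairs, data.frame(pr_idx = a, cr_idx = cand[1]))
    }
  }
  if (is.null(pairs)) pairs <- data.frame(pr_idx = integer(),
                                          cr_idx = integer())
  pr_specific <- setdiff(seq_len(nrow(loops_pr)), pairs$pr_idx)
  cr_specific <- which(!matched_cr)
  list(common = pairs, pr_specific = pr_specific, cr_specific = cr_specific,
       counts = c(common = nrow(pairs), pr_specific = length(pr_specific),
                  cr_specific = length(cr_specific),
                  pr_total = nrow(loops_pr), cr_total = nrow(loops_cr)))
}

#' Partition pooled loop anchors into common and condition-specific regions
#'
#' Anchors from both conditions' loops are pooled (optionally after removing
#' anchors overlapping excluded regions), overlapping or abutting anchors are
#' merged, and each merged region is classified: common when it captures
#' anchors from loops of both conditions (allowing the flank), otherwise
#' specific to the condition it came from.
#'
#' @param loops_pr,loops_cr Loop tables with `start1,end1,start2,end2` (bp)
#'   and a `chrom` column optional (single-chromosome assumed otherwise).
#' @param flank_bins Flank, in bins, used when assigning member anchors.
#' @param resolution Bin size in bp.
#' @param exclude Optional data.frame `chrom, start, end` of excluded regions
#'   (anchors overlapping them are dropped before merging).
#' @param chrom Chromosome label used when the loop tables carry none.
#' @return Data.frame `chrom, start, end, category` with
#'   `category` in `{common, PR-specific, CR-specific}`, plus a `counts`
#'   attribute.
#' @export
classify_anchor_sets <- function(loops_pr, loops_cr, flank_bins = 1,
                                 resolution, exclude = NULL, chrom = "chr1") {
  take_anchors <- function(loops, cond) {
    if (!nrow(loops)) return(NULL)
    data.frame(start = c(loops$start1, loops$start2),
               end = c(loops$end1, loops$end2), condition = cond)
  }
  anchors <- rbind(take_anchors(loops_pr, "PR"), take_anchors(loops_cr, "CR"))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), category = character())
  if (is.null(anchors) || !nrow(anchors)) return(empty)
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- rep(FALSE, nrow(anchors))
    for (r in seq_len(nrow(exclude)))
      drop <- drop | (anchors$start < exclude$end[r] &
                        exclude$start[r] < anchors$end)
    anchors <- anchors[!drop, , drop = FALSE]
    if (!nrow(anchors)) return(empty)
  }
  ir <- IRanges::IRanges(start = anchors$start + 1L, end = anchors$end)
  red <- IRanges::reduce(ir, min.gapwidth = 1L)   # merges abutting anchors
  flank <- flank_bins * resolution
  # member anchors assigned with the same gap-smaller-than-flank tolerance
  hits <- IRanges::findOverlaps(red, ir, maxgap = max(0L, flank - 1L))
  cond_pr <- anchors$condition == "PR"
  has_pr <- has_cr <- rep(FALSE, length(red))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  has_pr[unique(qh[cond_pr[sh]])] <- TRUE
  has_cr[unique(qh[!cond_pr[sh]])] <- TRUE
  category <- ifelse(has_pr & has_cr, "common",
                     ifelse(has_pr, "PR-specific", "CR-specific"))
  out <- data.frame(chrom = chrom, start = IRanges::start(red) - 1L,
                    end = IRanges::end(red), category = category)
  attr(out, "counts") <- table(factor(out$category,
                                      c("common", "PR-specific",
                                        "CR-specific")))
  out
}

#' Aggregate peak analysis
#'
#' Observed/expected submatrices centered on each loop pixel are averaged;
#' the reported strength is the center pixel divided by the mean of the
#' lower-left corner quadrant (the short-distance background).
#'
#' @param map A balanced [contact_map()].
#' @param loops Loop table with `bin1`, `bin2` (0-based).
#' @param window_bins Half-window of the aggregated submatrix.
#' @param corner_size Side of the corner quadrant used for the ratio.
#' @return List with `matrix` (`(2w+1) x (2w+1)` mean obs/exp), `ratio`,
#'   `n_used`.
#' @export
apa <- function(map, loops, window_bins = 10, corner_size = 3) {
  n <- map$n_bins
  w <- as.integer(window_bins)
  if (2 * w + 1 > n) .fail("window does not fit in the matrix")
  masked <- if (!is.null(map$weights)) is.na(map$weights) else
    rowSums(map$counts) == 0
  oe <- .obs_exp(map$counts, masked)
  acc <- matrix(0, 2 * w + 1, 2 * w + 1)
  cnt <- matrix(0, 2 * w + 1, 2 * w + 1)
  used <- 0L
  for (r in seq_len(nrow(loops))) {
    i <- loops$bin1[r] + 1L
    j <- loops$bin2[r] + 1L
    # near-diagonal windows sample the mirrored triangle, which is valid for
    # a symmetric matrix; only the center itself must stay off-diagonal
    if (i - w < 1 || j + w > n || j - i <= 2) next
    sub <- oe[(i - w):(i + w), (j - w):(j + w)]
    fin <- is.finite(sub)
    acc[fin] <- acc[fin] + sub[fin]
    cnt[fin] <- cnt[fin] + 1
    used <- used + 1L
  }
  if (used == 0) .fail("no loops usable for APA (too close to edges/diagonal)")
  mat <- acc / pmax(cnt, 1)
  mat[cnt == 0] <- NA
  center <- mat[w + 1, w + 1]
  cs <- corner_size
  corner <- mat[(2 * w + 2 - cs):(2 * w + 1), 1:cs, drop = FALSE]
  list(matrix = mat, ratio = center / mean(corner, na.rm = TRUE),
       n_used = used)
}

#' Insulation score track
#'
#' Per-bin log2 of the mean contact in the `window x window` square straddling
#' the bin, relative to the chromosome-wide mean of such squares. Edge bins
#' where the square does not fit get `NA`.
#'
#' @param map A balanced [contact_map()].
#' @param window_bins Window size in bins (>= 1).
#' @return Data.frame `bin` (0-based), `score`.
#' @export
insulation_track <- function(map, window_bins = 5) {
  .check_number(window_bins, "window_bins", lower = 1)
  n <- map$n_bins
  w <- as.integer(window_bins)
  m <- map$counts
  vals <- rep(NA_real_, n)
  for (b in (w + 1):(n - w)) {
    vals[b] <- mean(m[(b - w):(b - 1), (b + 1):(b + w)])
  }
  mu <- mean(vals, na.rm = TRUE)
  score <- ifelse(vals > 0 & mu > 0, log2(vals / mu), NA)
  data.frame(bin = seq_len(n) - 1L, score = score)
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are local minima of the insulation score whose prominence (the
#' smaller of the maximal score rises within `prominence_window_bins` on each
#' side) reaches `delta_threshold`; boundaries closer than
#' `min_separation_bins` are resolved greedily by prominence.
#'
#' @param track Output of [insulation_track()].
#' @param delta_threshold Minimum prominence (log2 units).
#' @param min_separation_bins Minimum distance between reported boundaries.
#' @param prominence_window_bins Search window for the flanking maxima
#'   (default `max(min_separation_bins, 5)`).
#' @param resolution Bin size (bp) used for the TAD table.
#' @param chrom Chromosome label for the TAD table.
#' @return List with `boundaries` (data.frame `bin, score, prominence`) and
#'   `tads` (consecutive-boundary intervals, bp and bins).
#' @export
call_tad_boundaries <- function(track, delta_threshold = 0.1,
                                min_separation_bins = 3,
                                prominence_window_bins = NULL,
                                resolution = 1L, chrom = "chr1") {
  s <- track$score
  n <- length(s)
  pw <- if (is.null(prominence_window_bins))
    max(min_separation_bins, 5) else prominence_window_bins
  cand <- integer(0)
  prom <- numeric(0)
  for (b in 2:(n - 1)) {
    if (is.na(s[b])) next
    left <- s[max(1, b - 1)]; right <- s[min(n, b + 1)]
    if (is.na(left) || is.na(right)) next
    if (s[b] <= left && s[b] <= right) {
      lw <- s[max(1, b - pw):(b - 1)]
      rw <- s[(b + 1):min(n, b + pw)]
      rise <- min(max(lw, na.rm = TRUE), max(rw, na.rm = TRUE)) - s[b]
      if (is.finite(rise) && rise >= delta_threshold) {
        cand <- c(cand, b)
        prom <- c(prom, rise)
      }
    }
  }
  keep <- integer(0)
  for (b in cand[order(-prom)]) {
    if (!length(keep) || all(abs(keep - b) >= min_separation_bins))
      keep <- c(keep, b)
  }
  keep <- sort(keep)
  boundaries <- data.frame(bin = keep - 1L,
                           score = s[keep],
                           prominence = prom[match(keep, cand)])
  tads <- if (length(keep) >= 2) {
    data.frame(chrom = chrom,
               start_bin = keep[-length(keep)] - 1L, end_bin = keep[-1] - 1L,
               start = (keep[-length(keep)] - 1L) * resolution,
               end = (keep[-1] - 1L) * resolution)
  } else {
    data.frame(chrom = character(), start_bin = integer(),
               end_bin = integer(), start = numeric(), end = numeric())
  }
  list(boundaries = boundaries, tads = tads)
}

#' Annotate anchors with CTCF motif content
#'
#' Counts stranded motifs per anchor: `multiple` (>= 2), `single` (1); anchors
#' with none are expanded by one bin on each side and re-tested, yielding
#' `adjacent-only` or `none`.
#'
#' @param anchors Data.frame `chrom, start, end` (0-based half-open).
#' @param motif_bed6 Data.frame `chrom, start, end, name, score, strand`.
#' @param resolution Bin size in bp (flank used for the re-test).
#' @return `anchors` with added `n_motifs` and `ctcf_category`.
#' @export
annotate_ctcf <- function(anchors, motif_bed6, resolution) {
  out <- anchors
  if (!nrow(anchors)) {
    out$n_motifs <- integer(0)
    out$ctcf_category <- character(0)
    return(out)
  }
  count_in <- function(s, e) {
    vapply(seq_along(s), function(k)
      sum(motif_bed6$start < e[k] & s[k] < motif_bed6$end &
            motif_bed6$chrom == anchors$chrom[k]), integer(1))
  }
  n0 <- if (nrow(motif_bed6)) count_in(anchors$start, anchors$end) else
    rep(0L, nrow(anchors))
  cat <- ifelse(n0 >= 2, "multiple", ifelse(n0 == 1, "single", NA))
  zero <- which(is.na(cat))
  if (length(zero) && nrow(motif_bed6)) {
    n1 <- count_in(pmax(0, anchors$start[zero] - resolution),
                   anchors$end[zero] + resolution)
    cat[zero] <- ifelse(n1 >= 1, "adjacent-only", "none")
  } else cat[zero] <- "none"
  out$n_motifs <- n0
  out$ctcf_category <- cat
  out
}

#' Classify loop CTCF convergence
#'
#' For each loop, the motif nearest the anchor midpoint determines the anchor
#' strand; classes follow the convergent-CTCF convention: `+` at the left
#' anchor and `-` at the right is `convergent`, equal strands `tandem`,
#' `-`/`+` `divergent`, a motif at one anchor only `one-sided`, neither
#' `none`.
#'
#' @param loops Loop table with `start1,end1,start2,end2` (bp).
#' @param motif_bed6 Stranded motif table.
#' @return Character vector of per-loop classes.
#' @export
loop_convergence <- function(loops, motif_bed6) {
  anchor_strand <- function(s, e) {
    hit <- which(motif_bed6$start < e & s < motif_bed6$end)
    if (!length(hit)) return(NA_character_)
    mid <- (s + e) / 2
    mmid <- (motif_bed6$start[hit] + motif_bed6$end[hit]) / 2
    motif_bed6$strand[hit[which.min(abs(mmid - mid))]]
  }
  vapply(seq_len(nrow(loops)), function(r) {
    sl <- anchor_strand(loops$start1[r], loops$end1[r])
    sr <- anchor_strand(loops$start2[r], loops$end2[r])
    if (is.na(sl) && is.na(sr)) return("none")
    if (is.na(sl) || is.na(sr)) return("one-sided")
    if (sl == "+" && sr == "-") return("convergent")
    if (sl == "-" && sr == "+") return("divergent")
    "tandem"
  }, character(1))
}

#' Permutation (circular-shift) region enrichment
#'
#' The statistic is the number of query regions overlapping any reference
#' region. The null circularly shifts all query positions by a common random
#' offset within the chromosome universe, preserving query length and spacing
#' structure. The empirical p-value is `(1 + #(null >= obs)) / (1 + n_perm)`
#' for enrichment and mirrored for depletion.
#'
#' @param query_regions,reference_regions Data.frames `chrom, start, end`
#'   (single chromosome).
#' @param universe Data.frame `chrom, start, end`: one covering interval.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List `observed, null_mean, z, p_enriched, p_depleted, p,
#'   direction`.
#' @export
permutation_enrichment <- function(query_regions, reference_regions, universe,
                                   n_perm = 1000, seed = 1L) {
  .check_number(n_perm, "n_perm", lower = 100)
  u0 <- universe$start[1]
  L <- universe$end[1] - universe$start[1]
  if (any(query_regions$start < u0 | query_regions$end > u0 + L))
    .fail("universe must cover all query regions")
  ref_ir <- if (nrow(reference_regions))
    IRanges::IRanges(reference_regions$start + 1L, reference_regions$end)
  else IRanges::IRanges()
  count_overlap <- function(starts, ends) {
    if (!length(ref_ir)) return(0L)
    q <- IRanges::IRanges(starts + 1L, ends)
    sum(IRanges::countOverlaps(q, ref_ir) > 0)
  }
  shift_count <- function(off) {
    s <- (query_regions$start - u0 + off) %% L
    e <- s + (query_regions$end - query_regions$start)
    wrap <- e > L
    # wrapped regions split into the two arcs
    s_all <- c(s[!wrap] + u0, s[wrap] + u0, rep(u0, sum(wrap)))
    e_all <- c(e[!wrap] + u0, rep(u0 + L, sum(wrap)), e[wrap] - L + u0)
    if (!length(ref_ir)) return(0L)
    q <- IRanges::IRanges(s_all + 1L, e_all)  # zero-width arcs stay empty
    hit <- IRanges::countOverlaps(q, ref_ir) > 0
    nw <- sum(!wrap)
    sum(hit[seq_len(nw)]) +
      sum(hit[nw + seq_len(sum(wrap))] | hit[nw + sum(wrap) + seq_len(sum(wrap))])
  }
  obs <- count_overlap(query_regions$start, query_regions$end)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k)
    shift_count(floor(stats::runif(1, 0, L))), numeric(1))
  p_enr <- (1 + sum(null >= obs)) / (1 + n_perm)
  p_dep <- (1 + sum(null <= obs)) / (1 + n_perm)
  direction <- if (obs <= mean(null)) "depleted" else "enriched"
  z <- if (stats::sd(null) > 0) (obs - mean(null)) / stats::sd(null) else NA_real_
  list(observed = obs, null_mean = mean(null), z = z,
       p_enriched = p_enr, p_depleted = p_dep,
       p = if (direction == "enriched") p_enr else p_dep,
       direction = direction)
}

#' Loop size statistics across categories
#'
#' Median anchor-midpoint distance per category, pairwise two-sided Wilcoxon
#' rank-sum tests, and counts in the conventional size ranges (< 100 kb,
#' 100 kb-1 Mb, > 1 Mb).
#'
#' @param sizes Named list of numeric loop sizes (bp) per category.
#' @return List with `medians`, `wilcoxon` (data.frame of pairwise p-values),
#'   `size_ranges` (matrix categories x ranges).
#' @export
loop_size_stats <- function(sizes) {
  if (!length(sizes) || any(!vapply(sizes, length, integer(1))))
    .fail("each compared category needs at least one loop")
  medians <- vapply(sizes, stats::median, numeric(1))
  cats <- names(sizes)
  pw <- NULL
  if (length(cats) > 1) {
    cmb <- utils::combn(cats, 2)
    pw <- data.frame(a = cmb[1, ], b = cmb[2, ],
                     p = apply(cmb, 2, function(ab)
                       suppressWarnings(stats::wilcox.test(
                         sizes[[ab[1]]], sizes[[ab[2]]],
                         alternative = "two.sided"))$p.value))
  }
  ranges <- t(vapply(sizes, function(x)
    c(`<100kb` = sum(x < 1e5), `100kb-1Mb` = sum(x >= 1e5 & x <= 1e6),
      `>1Mb` = sum(x > 1e6)), numeric(3)))
  list(medians = medians, wilcoxon = pw, size_ranges = ranges)
}
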