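#' Binned coverage log2 ratio between two conditions
#'
#' Optionally rescales the numerator track to the denominator's total (depth
#' normalization), then computes `log2((cr + pc) / (pr + pc))` per bin.
#'
#' @param cov_cr,cov_pr Numeric coverage vectors on the same bins, or
#'   data.frames with a `value` column.
#' @param pseudocount Pseudocount added to both tracks.
#' @param scale_to_equal_totals Rescale `cov_cr` so both tracks sum equally.
#' @return Numeric vector of per-bin log2 ratios.
#' @export
coverage_log2_ratio <- function(cov_cr, cov_pr, pseudocount = 1,
                                scale_to_equal_totals = TRUE) {
  as_vec <- function(x) if (is.data.frame(x)) x$value else x
  a <- as_vec(cov_cr); b <- as_vec(cov_pr)
  if (length(a) != length(b)) .fail("coverage tracks must share binning")
  if (any(a < 0) || any(b < 0)) .fail("coverage must be non-negative")
  if (scale_to_equal_totals && sum(a) > 0) a <- a * (sum(b) / sum(a))
  log2((a + pseudocount) / (b + pseudocount))
}

# max absolute circular-split t statistic for a segment, plus the split.
# Arcs (i, j] (0 <= i < j <= n) are compared against their complement with a
# pooled-variance two-sample t; i = 0 or j = n reduce to a single change
# point. For a fixed arc length L the t statistic is monotone in
# |Z_{i+L} - Z_i| with Z_k = S_k - k * mean(x), so the scan is one cheap
# vector operation per L. Returns list(stat, i, j).
.cbs_max_t <- function(x, min_seg) {
  n <- length(x)
  sigma2 <- stats::var(x)
  if (!is.finite(sigma2) || sigma2 == 0) return(list(stat = 0, i = 0L, j = n))
  S <- c(0, cumsum(x))
  Z <- S - (0:n) * (S[n + 1] / n)
  best_stat <- -Inf
  best_i <- 0L
  best_j <- n
  for (L in min_seg:(n - min_seg)) {
    d <- abs(Z[(1 + L):(n + 1)] - Z[1:(n + 1 - L)])
    k <- which.max(d)
    tL <- d[k] * sqrt(n / (sigma2 * L * (n - L)))
    if (tL > best_stat) {
      best_stat <- tL
      best_i <- k - 1L
      best_j <- k - 1L + L
    }
  }
  list(stat = best_stat, i = as.integer(best_i), j = as.integer(best_j))
}

# permutation p-value with early stopping: once the exceedance count
# guarantees p > alpha the remaining permutations are skipped
.cbs_perm_p <- function(x, obs_stat, n_perm, alpha, min_seg) {
  exceed <- 0L
  limit <- floor(alpha * (n_perm + 1))   # p > alpha once exceed >= limit
  for (b in seq_len(n_perm)) {
    stat_b <- .cbs_max_t(sample(x), min_seg)$stat
    if (stat_b >= obs_stat) {
      exceed <- exceed + 1L
      if (exceed >= limit) return(list(p = 1, early = TRUE))
    }
  }
  list(p = (1 + exceed) / (1 + n_perm), early = FALSE)
}

#' Circular binary segmentation of a log2-ratio track
#'
#' Recursive change-point detection: within each segment the circular split
#' (arc vs. complement) maximizing the two-sample t-statistic is accepted
#' when its permutation p-value is below `alpha`, and the resulting
#' sub-segments are revisited. Segments are classified by their mean against
#' `loss_threshold`/`gain_threshold`.
#'
#' @param log2_track Numeric vector of per-bin log2 ratios.
#' @param alpha Per-split permutation significance level.
#' @param n_perm Number of permutations per tested split (>= 100).
#' @param min_seg_bins Minimum segment length in bins.
#' @param loss_threshold,gain_threshold Segment-mean thresholds for the
#'   `loss`/`gain` classes.
#' @param seed Integer seed for the permutations.
#' @return Data.frame of segments: `start, end` (0-based half-open bins),
#'   `n_bins`, `mean`, `class`.
#' @export
cbs_segment <- function(log2_track, alpha = 0.01, n_perm = 1000,
                        min_seg_bins = 3, loss_threshold = -0.3,
                        gain_threshold = 0.3, seed = 1L) {
  if (n_perm < 100) .fail("n_perm must be >= 100")
  x <- as.numeric(log2_track)
  if (length(x) < 2 * min_seg_bins)
    .fail("track shorter than 2 * min_seg_bins")
  set.seed(seed)
  breaks <- c(0L, length(x))      # working set of segment edges (0-based)
  segment_once <- function(lo, hi) {     # (lo, hi] 0-based half-open edges
    seg <- x[(lo + 1):hi]
    n <- length(seg)
    if (n < 2 * min_seg_bins) return(integer(0))
    best <- .cbs_max_t(seg, min_seg_bins)
    if (!is.finite(best$stat) || best$stat <= 0) return(integer(0))
    pp <- .cbs_perm_p(seg, best$stat, n_perm, alpha, min_seg_bins)
    if (pp$p >= alpha) return(integer(0))
    cuts <- c(best$i, best$j)
    cuts <- cuts[cuts > 0 & cuts < n]
    lo + cuts
  }
  # iterate to convergence: keep splitting any segment that admits a split
  repeat {
    added <- integer(0)
    edges <- sort(unique(breaks))
    for (k in seq_len(length(edges) - 1)) {
      added <- c(added, segment_once(edges[k], edges[k + 1]))
    }
    if (!length(added)) break
    breaks <- c(breaks, added)
  }
  edges <- sort(unique(breaks))
  out <- data.frame(start = edges[-length(edges)], end = edges[-1])
  out$n_bins <- out$end - out$start
  out$mean <- vapply(seq_len(nrow(out)), function(k)
    mean(x[(out$start[k] + 1):out$end[k]]), numeric(1))
  out$class <- ifelse(out$mean <= loss_threshold, "loss",
                      ifelse(out$mean >= gain_threshold, "gain", "neutral"))
  out
}

# does call a match call b? same type, both breakpoints within the
# type-specific window
.sv_match <- function(a, b, window_tra, window_other) {
  if (a$type != b$type) return(FALSE)
  if (a$chrom1 != b$chrom1 || a$chrom2 != b$chrom2) return(FALSE)
  w <- if (a$type == "TRA") window_tra else window_other
  abs(a$pos1 - b$pos1) <= w && abs(a$pos2 - b$pos2) <= w
}

#' Multi-caller structural-variant consensus
#'
#' Calls are support-filtered (`support >= min_support`), pooled in genomic
#' order, and clustered greedily: a call joins the first existing cluster of
#' the same type whose founding call has both breakpoints within the
#' type-specific window (1 kb for translocations, 500 bp otherwise by
#' default). Clusters with calls from at least `min_callers` distinct callers
#' are emitted with median breakpoint coordinates.
#'
#' @param callsets List (>= 2) of per-caller data.frames with columns
#'   `chrom1, pos1, chrom2, pos2, type, support, caller`.
#' @param min_support Minimum paired-end read support.
#' @param window_tra Breakpoint window (bp) for type `TRA`.
#' @param window_other Breakpoint window (bp) for all other types.
#' @param min_callers Minimum number of distinct supporting callers.
#' @return Data.frame of consensus calls: `chrom1, pos1, chrom2, pos2, type,
#'   n_callers, callers, support_max`.
#' @export
consensus_sv <- function(callsets, min_support = 5, window_tra = 1000,
                         window_other = 500, min_callers = 2) {
  if (length(callsets) < 2) .fail("need call sets from at least 2 callers")
  all_calls <- do.call(rbind, callsets)
  all_calls <- all_calls[all_calls$support >= min_support, , drop = FALSE]
  empty <- data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      type = character(), n_callers = integer(),
                      callers = character(), support_max = numeric())
  if (!nrow(all_calls)) return(empty)
  all_calls <- all_calls[order(all_calls$chrom1, all_calls$pos1,
                               all_calls$pos2), , drop = FALSE]
  clusters <- list()
  for (r in seq_len(nrow(all_calls))) {
    call <- all_calls[r, ]
    joined <- FALSE
    for (c in seq_along(clusters)) {
      if (.sv_match(call, clusters[[c]]$founder, window_tra, window_other)) {
        clusters[[c]]$members <- rbind(clusters[[c]]$members, call)
        joined <- TRUE
        break
      }
    }
    if (!joined) clusters[[length(clusters) + 1L]] <-
        list(founder = call, members = call)
  }
  rows <- lapply(clusters, function(cl) {
    m <- cl$members
    if (length(unique(m$caller)) < min_callers) return(NULL)
    data.frame(chrom1 = m$chrom1[1], pos1 = stats::median(m$pos1),
               chrom2 = m$chrom2[1], pos2 = stats::median(m$pos2),
               type = m$type[1], n_callers = length(unique(m$caller)),
               callers = paste(sort(unique(m$caller)), collapse = ","),
               support_max = max(m$support))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom1, out$pos1, out$pos2), ]
  rownames(out) <- NULL
  out
}

#' Condition-specific structural variants
#'
#' Consensus lists from the two conditions are matched with the same
#' type-specific window rules (greedy one-to-one in order); unmatched calls
#' are condition-specific, so the partition reconciles with each input total.
#'
#' @param consensus_pr,consensus_cr Consensus tables from [consensus_sv()].
#' @param window_tra,window_other Breakpoint windows (bp).
#' @return List `shared` (matched index pairs), `pr_specific`, `cr_specific`
#'   (data.frames), `counts`.
#' @export
condition_specific_sv <- function(consensus_pr, consensus_cr,
                                  window_tra = 1000, window_other = 500) {
  matched_cr <- rep(FALSE, nrow(consensus_cr))
  pairs <- NULL
  for (a in seq_len(nrow(consensus_pr))) {
    for (b in seq_len(nrow(consensus_cr))) {
      if (matched_cr[b]) next
      if (.sv_match(consensus_pr[a, ], consensus_cr[b, ],
                    window_tra, window_other)) {
        matched_cr[b] <- TRUE
        pairs <- rbind(pairs, data.frame(pr_idx = a, cr_idx = b))
        break
      }
    }
  }
  if (is.null(pairs)) pairs <- data.frame(pr_idx = integer(),
                                          cr_idx = integer())
  pr_specific <- consensus_pr[setdiff(seq_len(nrow(consensus_pr)),
                                      pairs$pr_idx), , drop = FALSE]
  cr_specific <- consensus_cr[!matched_cr, , drop = FALSE]
  list(shared = pairs, pr_specific = pr_specific, cr_specific = cr_specific,
       counts = c(shared = nrow(pairs), pr_specific = nrow(pr_specific),
                  cr_specific = nrow(cr_specific),
                  pr_total = nrow(consensus_pr),
                  cr_total = nrow(consensus_cr)))
}

#' Annotate genes with copy-number class and summarize CNV extent
#'
#' Each gene receives the class of the segment with maximal overlap. Totals
#' are the summed lengths of loss/gain segments, with genome percentages.
#'
#' @param gene_bed Data.frame `chrom, start, end, gene` (bp, half-open).
#' @param segments Data.frame `chrom, start, end, class` in bp (e.g.
#'   [cbs_segment()] output scaled by the bin size), classes
#'   `loss`/`neutral`/`gain`.
#' @param genome_size Total genome size in bp.
#' @return List with `genes` (per-gene class), `deleted_mb`, `duplicated_mb`,
#'   `deleted_pct`, `duplicated_pct`, `gene_fractions` (share of
#'   CNV-overlapping genes in loss vs gain).
#' @export
annotate_genes_cnv <- function(gene_bed, segments, genome_size) {
  .check_number(genome_size, "genome_size", lower = 0, strict_lower = TRUE)
  cls <- rep("neutral", nrow(gene_bed))
  if (nrow(gene_bed) && nrow(segments)) {
    g <- .df_to_gr(gene_bed)
    s <- .df_to_gr(segments)
    hits <- GenomicRanges::findOverlaps(g, s)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(g)[S4Vectors::queryHits(hits)],
        IRanges::ranges(s)[S4Vectors::subjectHits(hits)]))
      best <- tapply(seq_along(ov), S4Vectors::queryHits(hits), function(ix)
        ix[which.max(ov[ix])])
      qh <- as.integer(names(best))
      cls[qh] <- segments$class[S4Vectors::subjectHits(hits)[unlist(best)]]
    }
  }
  seg_len <- segments$end - segments$start
  del_bp <- sum(seg_len[segments$class == "loss"])
  dup_bp <- sum(seg_len[segments$class == "gain"])
  in_cnv <- cls != "neutral"
  gene_fractions <- if (any(in_cnv))
    c(loss = mean(cls[in_cnv] == "loss"), gain = mean(cls[in_cnv] == "gain"))
  else c(loss = NA_real_, gain = NA_real_)
  list(genes = data.frame(gene = gene_bed$gene, class = cls),
       deleted_mb = del_bp / 1e6, duplicated_mb = dup_bp / 1e6,
       deleted_pct = del_bp / genome_size * 100,
       duplicated_pct = dup_bp / genome_size * 100,
       gene_fractions = gene_fractions)
}
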