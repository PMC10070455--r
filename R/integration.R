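#' Build a signed gene ranking metric
#'
#' Three metrics are supported: `de_signed_logp` =
#' `sign(log2FC) * -log10(p)`; `coverage_weighted` = log2 coverage difference
#' multiplied by the mean coverage; `eigen_delta` = rewired-condition score
#' minus reference score at the gene's maximal-overlap bin.
#'
#' @param inputs Data.frame. For `de_signed_logp`: columns `gene, log2FC, p`.
#'   For `coverage_weighted`: `gene, log2_diff, mean_coverage`. For
#'   `eigen_delta`: `gene, score_pr, score_cr`.
#' @param kind Metric kind.
#' @return Data.frame `gene, metric`, sorted decreasing with ties kept in
#'   input order (a `ranked_gene_list`).
#' @export
build_gene_ranking <- function(inputs,
                               kind = c("de_signed_logp", "coverage_weighted",
                                        "eigen_delta")) {
  kind <- match.arg(kind)
  need <- switch(kind,
    de_signed_logp = c("gene", "log2FC", "p"),
    coverage_weighted = c("gene", "log2_diff", "mean_coverage"),
    eigen_delta = c("gene", "score_pr", "score_cr"))
  miss <- setdiff(need, names(inputs))
  if (length(miss)) .fail("missing columns for %s: %s", kind,
                          paste(miss, collapse = ", "))
  if (anyDuplicated(inputs$gene)) .fail("genes must be unique")
  metric <- switch(kind,
    de_signed_logp = sign(inputs$log2FC) * -log10(pmax(inputs$p, 1e-300)),
    coverage_weighted = inputs$log2_diff * inputs$mean_coverage,
    eigen_delta = inputs$score_cr - inputs$score_pr)
  metric[inputs$p == 1 & kind == "de_signed_logp"] <- 0
  out <- data.frame(gene = inputs$gene, metric = metric)
  out <- out[order(-out$metric), ]
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Pearson correlation after a 1-SD change filter
#'
#' Genes with `|x| < sd_filter * SD(x)` or `|y| < sd_filter * SD(y)` are
#' removed before computing the Pearson correlation (two-sided test).
#'
#' @param x_changes,y_changes Paired numeric change vectors.
#' @param sd_filter Multiplier of each vector's SD used as the cutoff.
#' @return List `r, p, n_retained`.
#' @export
filtered_correlation <- function(x_changes, y_changes, sd_filter = 1.0) {
  if (length(x_changes) != length(y_changes)) .fail("vectors must be paired")
  ok <- stats::complete.cases(x_changes, y_changes)
  x <- x_changes[ok]; y <- y_changes[ok]
  keep <- abs(x) >= sd_filter * stats::sd(x) &
    abs(y) >= sd_filter * stats::sd(y)
  if (sum(keep) < 3)
    .fail("fewer than 3 genes survive the %.2g-SD change filter", sd_filter)
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_retained = sum(keep))
}

# weighted Kolmogorov-Smirnov running-sum enrichment score for indicator
# vector `inset` over metric sorted decreasing
.gsea_es <- function(metric_sorted, inset, weight_exponent) {
  w <- abs(metric_sorted)^weight_exponent
  win <- w * inset
  denom_in <- sum(win)
  n <- length(metric_sorted)
  n_out <- n - sum(inset)
  if (denom_in == 0 || n_out == 0) return(0)
  running <- cumsum(win / denom_in - (!inset) / n_out)
  running[which.max(abs(running))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment scores with
#' gene-label permutations: the null redraws random sets of the same size
#' from the ranked list. NES normalizes each ES by the mean absolute
#' permutation ES of the matching sign, the p-value is the sign-matched
#' permutation tail, and FDR is the permutation-based ratio over sets.
#'
#' @param ranked A `ranked_gene_list` (or data.frame `gene, metric`).
#' @param gene_sets Named list of gene identifier vectors (e.g. [read_gmt()]).
#' @param n_perm Number of gene-label permutations.
#' @param weight_exponent Weight on `|metric|` in the running sum.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked genes; sets outside the bounds are dropped.
#' @param seed Integer seed.
#' @return Data.frame per retained set: `set, size, es, nes, p, fdr`.
#' @export
preranked_gsea <- function(ranked, gene_sets, n_perm = 1000,
                           weight_exponent = 1, min_size = 5, max_size = 500,
                           seed = 1L) {
  ord <- order(-ranked$metric)
  genes <- ranked$gene[ord]
  metric <- ranked$metric[ord]
  sizes <- vapply(gene_sets, function(s) sum(genes %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < length(genes)
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]
  if (!length(gene_sets)) .fail("no gene set within the size bounds")
  es <- vapply(seq_along(gene_sets), function(k)
    .gsea_es(metric, genes %in% gene_sets[[k]], weight_exponent), numeric(1))
  set.seed(seed)
  usize <- sort(unique(sizes))
  perm <- matrix(NA_real_, n_perm, length(usize),
                 dimnames = list(NULL, as.character(usize)))
  n <- length(genes)
  for (b in seq_len(n_perm)) {
    for (u in seq_along(usize)) {
      inset <- logical(n)
      inset[sample.int(n, usize[u])] <- TRUE
      perm[b, u] <- .gsea_es(metric, inset, weight_exponent)
    }
  }
  nes <- p <- numeric(length(es))
  nes_perm_all <- NULL
  for (k in seq_along(es)) {
    pb <- perm[, as.character(sizes[k])]
    same <- if (es[k] >= 0) pb[pb >= 0] else pb[pb < 0]
    mu <- mean(abs(same))
    nes[k] <- if (is.finite(mu) && mu > 0) es[k] / mu else 0
    p[k] <- (1 + sum(abs(same) >= abs(es[k]))) / (1 + length(same))
    nes_perm_all <- c(nes_perm_all,
                      if (is.finite(mu) && mu > 0) same / mu else numeric(0))
  }
  # permutation-based FDR: share of null NES at least as extreme vs. share of
  # observed NES at least as extreme, capped at 1
  fdr <- vapply(seq_along(nes), function(k) {
    null_frac <- mean(abs(nes_perm_all) >= abs(nes[k]))
    obs_frac <- mean(abs(nes) >= abs(nes[k]))
    min(1, null_frac / max(obs_frac, 1e-12))
  }, numeric(1))
  data.frame(set = names(gene_sets), size = sizes, es = es, nes = nes,
             p = p, fdr = fdr, row.names = NULL)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value of the query/set overlap within a gene
#' universe, with Benjamini-Hochberg FDR across sets. `P[X >= 0] = 1` by the
#' survival-function convention.
#'
#' @param query_genes Character vector (must be a subset of the universe).
#' @param gene_sets Named list of gene sets (intersected with the universe).
#' @param universe_genes Character vector of all eligible genes.
#' @return Data.frame per set: `set, overlap, set_size, fold_enrichment, p,
#'   fdr`.
#' @export
hypergeometric_enrichment <- function(query_genes, gene_sets,
                                      universe_genes) {
  query_genes <- unique(query_genes)
  universe_genes <- unique(universe_genes)
  if (!all(query_genes %in% universe_genes))
    .fail("query genes must be a subset of the universe")
  N <- length(universe_genes)
  k <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe_genes)
    m <- length(set)
    ov <- length(intersect(query_genes, set))
    p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    expected <- k * m / N
    data.frame(set = nm, overlap = ov, set_size = m,
               fold_enrichment = if (expected > 0) ov / expected else NA_real_,
               p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- .bh(out$p)
  out
}

#' Multi-evidence gene importance score
#'
#' Per gene, five binary evidence flags are summed: differential expression
#' in the focal direction, copy-number evidence, significant compartment
#' switch toward the matching state, condition-specific loop-anchor overlap,
#' and condition-specific TAD-boundary overlap. The CR score uses
#' CR-direction evidence (up, gain, switch to active = significant AA/BA,
#' CR-specific anchors/boundaries); the PR score mirrors every direction.
#'
#' @param genes Character vector: the harmonized gene universe.
#' @param de Data.frame `gene, log2FC, FDR`.
#' @param cnv Data.frame `gene, class` with classes `loss/neutral/gain`
#'   (from [annotate_genes_cnv()] or CR-specific consensus SV overlap).
#' @param switch_genes Per-class gene lists as returned by
#'   [genes_in_switch_categories()] (its `genes` element).
#' @param anchor_genes List with `pr`, `cr`: genes overlapping
#'   condition-specific loop anchors.
#' @param boundary_genes List with `pr`, `cr`: genes overlapping
#'   condition-specific TAD boundaries.
#' @param de_fdr DE significance threshold.
#' @param min_evidence Selection threshold on the importance score.
#' @return List with `evidence` (data.frame of per-gene flags and both
#'   scores) and `selected_cr`, `selected_pr` (genes with score >=
#'   `min_evidence`).
#' @export
importance_score <- function(genes, de, cnv, switch_genes, anchor_genes,
                             boundary_genes, de_fdr = 0.1, min_evidence = 4) {
  g <- unique(genes)
  de_up <- g %in% de$gene[de$log2FC > 0 & de$FDR < de_fdr]
  de_dn <- g %in% de$gene[de$log2FC < 0 & de$FDR < de_fdr]
  cnv_gain <- g %in% cnv$gene[cnv$class == "gain"]
  cnv_loss <- g %in% cnv$gene[cnv$class == "loss"]
  to_active <- g %in% unique(c(switch_genes$AA, switch_genes$BA))
  to_inactive <- g %in% unique(c(switch_genes$AB, switch_genes$BB))
  anchor_cr <- g %in% anchor_genes$cr
  anchor_pr <- g %in% anchor_genes$pr
  tad_cr <- g %in% boundary_genes$cr
  tad_pr <- g %in% boundary_genes$pr
  score_cr <- de_up + cnv_gain + to_active + anchor_cr + tad_cr
  score_pr <- de_dn + cnv_loss + to_inactive + anchor_pr + tad_pr
  ev <- data.frame(gene = g,
                   de_up = de_up, cnv_gain = cnv_gain,
                   to_active = to_active, anchor_cr = anchor_cr,
                   tad_cr = tad_cr, score_cr = score_cr,
                   de_down = de_dn, cnv_loss = cnv_loss,
                   to_inactive = to_inactive, anchor_pr = anchor_pr,
                   tad_pr = tad_pr, score_pr = score_pr)
  list(evidence = ev,
       selected_cr = g[score_cr >= min_evidence],
       selected_pr = g[score_pr >= min_evidence])
}

#' Optical-density statistics for stain intensities
#'
#' Per-measurement `OD = log10(255 / mean intensity)` and a Welch two-sided
#' t-test between the two groups. Identical groups report `t = 0, p = 1`.
#'
#' @param mean_intensities_group_a,mean_intensities_group_b Mean stain
#'   intensities in `(0, 255]`.
#' @return List `od_a, od_b, t, p`.
#' @export
optical_density_stats <- function(mean_intensities_group_a,
                                  mean_intensities_group_b) {
  check <- function(x, nm) {
    if (any(x <= 0 | x > 255)) .fail("intensities in '%s' must be in (0, 255]",
                                     nm)
  }
  check(mean_intensities_group_a, "group_a")
  check(mean_intensities_group_b, "group_b")
  od_a <- log10(255 / mean_intensities_group_a)
  od_b <- log10(255 / mean_intensities_group_b)
  # t.test() errors on constant data; a zero mean difference is t = 0, p = 1
  tt <- tryCatch(stats::t.test(od_a, od_b, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    if (mean(od_a) == mean(od_b))
      return(list(od_a = od_a, od_b = od_b, t = 0, p = 1))
    return(list(od_a = od_a, od_b = od_b, t = Inf, p = 0))
  }
  list(od_a = od_a, od_b = od_b, t = unname(tt$statistic), p = tt$p.value)
}
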