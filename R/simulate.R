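#' Simulation specification for one chromosome
#'
#' Describes the baseline (primary-condition) contact architecture: power-law
#' distance decay, a blockwise A/B checkerboard, nested TAD boosts, focal
#' loops, and sequencing depth.
#'
#' @param chrom Chromosome label.
#' @param n_bins Number of bins (>= 10).
#' @param resolution Bin size in bp.
#' @param decay_exponent Power-law exponent alpha > 0 of the distance decay
#'   `(1 + d)^(-alpha)`.
#' @param compartment_block_len Length (bins) of the alternating A/B blocks.
#' @param compartment_effect Checkerboard strength epsilon >= 0; contacts are
#'   multiplied by `exp(epsilon * s_i * s_j)` with `s` the per-bin sign.
#' @param tad_list Optional data.frame `start`, `end` (0-based half-open bin
#'   intervals), `boost` (>= 1): within-TAD contacts multiplied by `boost`.
#' @param loop_list Optional data.frame `bin1`, `bin2`, `boost` (>= 1): the
#'   focal pixel at (bin1, bin2) multiplied by `boost`.
#' @param depth Expected total contact count (upper triangle incl. diagonal).
#' @param seed Integer seed for count sampling.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(chrom = "chrS", n_bins = 500, resolution = 50000,
                            decay_exponent = 1.0, compartment_block_len = 20,
                            compartment_effect = 0.4, tad_list = NULL,
                            loop_list = NULL, depth = 1e6, seed = 1L) {
  .check_number(n_bins, "n_bins", lower = 10)
  .check_number(decay_exponent, "decay_exponent", lower = 0,
                strict_lower = TRUE)
  .check_number(compartment_block_len, "compartment_block_len", lower = 1)
  .check_number(compartment_effect, "compartment_effect", lower = 0)
  .check_number(depth, "depth", lower = 0, strict_lower = TRUE)
  .check_intervals <- function(df, what) {
    if (is.null(df)) return(invisible())
    if (any(df$start < 0 | df$end > n_bins | df$start >= df$end))
      .fail("%s intervals must lie within [0, n_bins)", what)
    if (any(df$boost < 1)) .fail("%s boost factors must be >= 1", what)
  }
  .check_intervals(tad_list, "tad_list")
  if (!is.null(loop_list)) {
    if (any(loop_list$bin1 < 0 | loop_list$bin2 < 0 |
              loop_list$bin1 >= n_bins | loop_list$bin2 >= n_bins))
      .fail("loop_list bins must lie within [0, n_bins)")
    if (any(loop_list$boost < 1)) .fail("loop boost factors must be >= 1")
  }
  structure(list(chrom = chrom, n_bins = as.integer(n_bins),
                 resolution = as.integer(resolution),
                 decay_exponent = decay_exponent,
                 compartment_block_len = as.integer(compartment_block_len),
                 compartment_effect = compartment_effect,
                 tad_list = tad_list, loop_list = loop_list,
                 depth = depth, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Rewiring specification (condition B relative to condition A)
#'
#' @param flip_block_fraction Fraction of compartment blocks whose sign flips
#'   in the rewired condition (in `[0, 1]`).
#' @param loops_added,loops_removed Optional data.frames `bin1`, `bin2`
#'   (`loops_added` also `boost`) of focal loops gained/lost.
#' @param tad_splits Integer vector of bin positions at which existing TADs
#'   are split into sub-TADs.
#' @param cnv_list Optional data.frame `start`, `end` (0-based half-open bin
#'   intervals), `copy_ratio` (> 0). Overlapping intervals with conflicting
#'   ratios are rejected.
#' @param expression_coupling Effect size linking compartment/CNV truth to
#'   simulated expression log2 fold changes.
#' @param seed Integer seed for the rewiring choices (block flips etc.).
#' @return A `rewiring_spec` list.
#' @export
rewiring_spec <- function(flip_block_fraction = 0, loops_added = NULL,
                          loops_removed = NULL, tad_splits = integer(),
                          cnv_list = NULL, expression_coupling = 1,
                          seed = 2L) {
  .check_number(flip_block_fraction, "flip_block_fraction", lower = 0,
                upper = 1)
  if (!is.null(cnv_list)) {
    if (any(cnv_list$copy_ratio <= 0)) .fail("copy ratios must be > 0")
    if (nrow(cnv_list) > 1) {
      for (a in seq_len(nrow(cnv_list) - 1L)) for (b in (a + 1):nrow(cnv_list)) {
        overlap <- cnv_list$start[a] < cnv_list$end[b] &&
          cnv_list$start[b] < cnv_list$end[a]
        if (overlap && cnv_list$copy_ratio[a] != cnv_list$copy_ratio[b])
          .fail("overlapping CNVs with contradictory copy ratios")
      }
    }
  }
  structure(list(flip_block_fraction = flip_block_fraction,
                 loops_added = loops_added, loops_removed = loops_removed,
                 tad_splits = as.integer(tad_splits), cnv_list = cnv_list,
                 expression_coupling = expression_coupling,
                 seed = as.integer(seed)),
            class = "rewiring_spec")
}

# expected-intensity matrix lambda(i,j) before depth scaling
.lambda_matrix <- function(n, alpha, eps, s, tads, loops, copy) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- (1 + d)^(-alpha)
  if (eps > 0) lam <- lam * exp(eps * outer(s, s))
  if (!is.null(tads)) {
    for (r in seq_len(nrow(tads))) {
      idx <- (tads$start[r] + 1L):tads$end[r]
      lam[idx, idx] <- lam[idx, idx] * tads$boost[r]
    }
  }
  if (!is.null(loops) && nrow(loops)) {
    i <- pmin(loops$bin1, loops$bin2) + 1L
    j <- pmax(loops$bin1, loops$bin2) + 1L
    lam[cbind(i, j)] <- lam[cbind(i, j)] * loops$boost
    lam[cbind(j, i)] <- lam[cbind(i, j)]
  }
  if (!all(copy == 1)) lam <- lam * outer(copy, copy)
  lam
}

.sample_map <- function(lam, depth, resolution, chrom) {
  n <- nrow(lam)
  ut <- upper.tri(lam, diag = TRUE)
  scale <- depth / sum(lam[ut])
  counts <- matrix(0, n, n)
  counts[ut] <- stats::rpois(sum(ut), lam[ut] * scale)
  counts <- counts + t(counts) - diag(diag(counts))
  contact_map(counts, resolution, chrom)
}

# split TAD intervals at the given boundary bins (each part keeps the boost)
.split_tads <- function(tads, splits) {
  if (is.null(tads) || !length(splits)) return(tads)
  out <- list()
  for (r in seq_len(nrow(tads))) {
    cuts <- sort(splits[splits > tads$start[r] & splits < tads$end[r]])
    edges <- c(tads$start[r], cuts, tads$end[r])
    out[[r]] <- data.frame(start = edges[-length(edges)], end = edges[-1],
                           boost = tads$boost[r])
  }
  do.call(rbind, out)
}

#' Simulate a paired-condition contact map with recorded ground truth
#'
#' Expected counts follow
#' `depth-scaled (1+|i-j|)^(-alpha) * exp(eps * s_i * s_j) * tad_boost *
#' loop_boost * c_i * c_j`, Poisson-sampled independently per condition on the
#' upper triangle and mirrored. Condition A ("PR") uses the baseline spec;
#' condition B ("CR") applies the rewiring (block sign flips, loop gains and
#' losses, TAD splits, CNV copy ratios).
#'
#' @param spec A [simulation_spec()].
#' @param rewiring A [rewiring_spec()].
#' @return List with elements `pr`, `cr` (two [contact_map()]s) and `truth`
#'   (per-bin compartment signs per condition, planted TADs/loops per
#'   condition, planted CNV/SV intervals, copy-ratio vector, flipped blocks).
#' @export
simulate_condition_pair <- function(spec, rewiring = rewiring_spec()) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(rewiring, "rewiring_spec"))
  n <- spec$n_bins
  block_id <- (seq_len(n) - 1L) %/% spec$compartment_block_len
  s_pr <- ifelse(block_id %% 2L == 0L, 1, -1)
  n_blocks <- max(block_id) + 1L
  set.seed(rewiring$seed)
  n_flip <- round(rewiring$flip_block_fraction * n_blocks)
  flipped_blocks <- sort(sample.int(n_blocks, n_flip)) - 1L
  s_cr <- s_pr
  s_cr[block_id %in% flipped_blocks] <- -s_cr[block_id %in% flipped_blocks]

  loops_pr <- spec$loop_list
  loops_cr <- loops_pr
  if (!is.null(rewiring$loops_removed) && !is.null(loops_cr) && nrow(loops_cr)) {
    keep <- !(paste(loops_cr$bin1, loops_cr$bin2) %in%
                paste(rewiring$loops_removed$bin1, rewiring$loops_removed$bin2))
    loops_cr <- loops_cr[keep, , drop = FALSE]
  }
  if (!is.null(rewiring$loops_added))
    loops_cr <- rbind(loops_cr, rewiring$loops_added)

  tads_pr <- spec$tad_list
  tads_cr <- .split_tads(tads_pr, rewiring$tad_splits)

  copy_pr <- rep(1, n)
  copy_cr <- rep(1, n)
  if (!is.null(rewiring$cnv_list)) {
    for (r in seq_len(nrow(rewiring$cnv_list))) {
      idx <- (rewiring$cnv_list$start[r] + 1L):rewiring$cnv_list$end[r]
      copy_cr[idx] <- rewiring$cnv_list$copy_ratio[r]
    }
  }

  lam_pr <- .lambda_matrix(n, spec$decay_exponent, spec$compartment_effect,
                           s_pr, tads_pr, loops_pr, copy_pr)
  lam_cr <- .lambda_matrix(n, spec$decay_exponent, spec$compartment_effect,
                           s_cr, tads_cr, loops_cr, copy_cr)
  set.seed(spec$seed)
  pr <- .sample_map(lam_pr, spec$depth, spec$resolution, spec$chrom)
  cr <- .sample_map(lam_cr, spec$depth, spec$resolution, spec$chrom)

  cnv <- rewiring$cnv_list
  svs <- NULL
  if (!is.null(cnv)) {
    svs <- data.frame(
      chrom = spec$chrom,
      start = cnv$start * spec$resolution,
      end = cnv$end * spec$resolution,
      type = ifelse(cnv$copy_ratio > 1, "DUP", "DEL"),
      copy_ratio = cnv$copy_ratio,
      log2_ratio = log2(cnv$copy_ratio)
    )
  }
  truth <- structure(list(
    chrom = spec$chrom, n_bins = n, resolution = spec$resolution,
    compartments = data.frame(bin = seq_len(n) - 1L, block = block_id,
                              s_pr = s_pr, s_cr = s_cr,
                              flipped = s_pr != s_cr),
    flipped_blocks = flipped_blocks,
    tads_pr = tads_pr, tads_cr = tads_cr,
    loops_pr = loops_pr, loops_cr = loops_cr,
    svs = svs, copy_cr = copy_cr,
    decay_exponent = spec$decay_exponent,
    compartment_effect = spec$compartment_effect
  ), class = "rewire_truth")
  list(pr = pr, cr = cr, truth = truth)
}

#' Simulate per-caller structural-variant call tables
#'
#' Each true SV is emitted by each caller with probability `sensitivity`,
#' with Gaussian breakpoint jitter and Poisson read support; Poisson-many
#' false positives per Mb are appended at uniform positions.
#'
#' @param truth_svs Data.frame with `chrom`, `start`, `end`, `type` (true
#'   breakpoint pairs; for non-TRA, `start` < `end` on one chromosome).
#' @param sensitivity Per-caller emission probability of a true SV.
#' @param fp_rate False positives per Mb of genome per caller (>= 0).
#' @param breakpoint_jitter_sd SD (bp) of breakpoint jitter (>= 0).
#' @param support_mean Mean Poisson paired-end read support.
#' @param n_callers Number of callers.
#' @param genome_size Genome size in bp (for the false-positive count).
#' @param condition Condition label carried on every call.
#' @param seed Integer seed.
#' @return List of `n_callers` data.frames with columns
#'   `chrom1, pos1, chrom2, pos2, type, support, caller, condition`.
#' @export
simulate_sv_callsets <- function(truth_svs, sensitivity = 0.9, fp_rate = 0.5,
                                 breakpoint_jitter_sd = 100, support_mean = 10,
                                 n_callers = 3, genome_size = NULL,
                                 condition = "CR", seed = 3L) {
  .check_number(sensitivity, "sensitivity", lower = 0, upper = 1)
  .check_number(fp_rate, "fp_rate", lower = 0)
  .check_number(breakpoint_jitter_sd, "breakpoint_jitter_sd", lower = 0)
  .check_number(support_mean, "support_mean", lower = 0)
  if (!is.null(truth_svs) && any(truth_svs$start < 0))
    .fail("truth SV positions must be >= 0")
  if (is.null(genome_size))
    genome_size <- if (is.null(truth_svs)) 1e6 else max(truth_svs$end) * 1.1
  set.seed(seed)
  sv_types <- c("DEL", "DUP", "INV")
  lapply(seq_len(n_callers), function(k) {
    caller <- paste0("caller", k)
    out <- NULL
    if (!is.null(truth_svs) && nrow(truth_svs)) {
      keep <- stats::runif(nrow(truth_svs)) <= sensitivity
      tv <- truth_svs[keep, , drop = FALSE]
      if (nrow(tv)) {
        jit <- function(p) pmax(0, round(p + stats::rnorm(length(p), 0,
                                                          breakpoint_jitter_sd)))
        out <- data.frame(chrom1 = tv$chrom, pos1 = jit(tv$start),
                          chrom2 = tv$chrom, pos2 = jit(tv$end),
                          type = tv$type,
                          support = stats::rpois(nrow(tv), support_mean),
                          caller = caller, condition = condition)
      }
    }
    n_fp <- stats::rpois(1, fp_rate * genome_size / 1e6)
    if (n_fp > 0) {
      p1 <- round(stats::runif(n_fp, 0, genome_size * 0.98))
      len <- round(stats::runif(n_fp, 1e3, 1e5))
      fp <- data.frame(chrom1 = if (is.null(truth_svs)) "chrS" else
                         truth_svs$chrom[1],
                       pos1 = p1, chrom2 = if (is.null(truth_svs)) "chrS" else
                         truth_svs$chrom[1],
                       pos2 = p1 + len,
                       type = sample(sv_types, n_fp, replace = TRUE),
                       support = stats::rpois(n_fp, support_mean),
                       caller = caller, condition = condition)
      out <- rbind(out, fp)
    }
    if (is.null(out))
      out <- data.frame(chrom1 = character(), pos1 = numeric(),
                        chrom2 = character(), pos2 = numeric(),
                        type = character(), support = numeric(),
                        caller = character(), condition = character())
    rownames(out) <- NULL
    out
  })
}

#' Simulate a differential-expression table coupled to planted truth
#'
#' Per gene, `log2FC = coupling * (compartment sign delta) +
#' coupling * (CNV log2 copy ratio) + N(0, noise_sd)`; the p-value is a
#' two-sided z-test of the observed log2FC against `noise_sd`, and FDR is
#' Benjamini-Hochberg.
#'
#' @param genes Data.frame `chrom`, `start`, `end`, `gene` (bp, 0-based
#'   half-open); gene midpoints are mapped to bins.
#' @param truth Ground truth from [simulate_condition_pair()].
#' @param coupling Effect size of compartment delta and CNV on log2FC.
#' @param noise_sd Gaussian noise SD (> 0).
#' @param seed Integer seed.
#' @return Data.frame `gene, log2FC, p, FDR, true_log2FC, comp_delta,
#'   cnv_log2`.
#' @export
simulate_expression_table <- function(genes, truth, coupling = 1,
                                      noise_sd = 0.5, seed = 4L) {
  .check_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  mid_bin <- pmin(truth$n_bins - 1L,
                  floor((genes$start + genes$end) / 2 / truth$resolution))
  comp <- truth$compartments
  delta <- comp$s_cr[mid_bin + 1L] - comp$s_pr[mid_bin + 1L]
  cnv_log2 <- log2(truth$copy_cr[mid_bin + 1L])
  true_lfc <- coupling * delta + coupling * cnv_log2
  set.seed(seed)
  lfc <- true_lfc + stats::rnorm(nrow(genes), 0, noise_sd)
  z <- lfc / noise_sd
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene = genes$gene, log2FC = lfc, p = p, FDR = .bh(p),
             true_log2FC = true_lfc, comp_delta = delta, cnv_log2 = cnv_log2)
}

#' Simulate binned WGS coverage for the two conditions
#'
#' Per-bin Poisson read depth; the rewired condition's mean is multiplied by
#' the planted copy ratio, so CNVs distort coverage additively in log space
#' (a copy ratio of 2 shifts the log2 coverage ratio by +1).
#'
#' @param truth Ground truth from [simulate_condition_pair()].
#' @param mean_depth Expected reads per bin on the diploid background.
#' @param seed Integer seed.
#' @return List with `pr`, `cr`: bedGraph-like data.frames
#'   (`chrom, start, end, value`).
#' @export
simulate_coverage_tracks <- function(truth, mean_depth = 100, seed = 6L) {
  .check_number(mean_depth, "mean_depth", lower = 0, strict_lower = TRUE)
  set.seed(seed)
  n <- truth$n_bins
  res <- truth$resolution
  frame <- function(v) data.frame(chrom = truth$chrom,
                                  start = (seq_len(n) - 1) * res,
                                  end = seq_len(n) * res, value = v)
  list(pr = frame(stats::rpois(n, mean_depth)),
       cr = frame(stats::rpois(n, mean_depth * truth$copy_cr)))
}

#' Simulate gene, CTCF-motif and GC annotation tracks
#'
#' Genes are placed preferentially in A (positive-sign) bins with relative
#' weight `a_bias`; motifs are uniform with balanced strands; the GC track is
#' built by a Gaussian copula so its correlation with the planted compartment
#' sign approximates `gc_rho`.
#'
#' @param spec A [simulation_spec()].
#' @param truth Ground truth from [simulate_condition_pair()] (provides the
#'   baseline compartment signs).
#' @param gene_density_per_Mb,motif_density_per_Mb Expected feature densities
#'   (>= 0).
#' @param a_bias Relative placement weight of A bins for genes (>= 1).
#' @param gc_rho Target correlation of the GC track with compartment sign.
#' @param seed Integer seed.
#' @return List with `genes` (BED-like data.frame), `motifs` (BED6-like with
#'   strand), `gc` (per-bin bedGraph-like), `gene_density` (per-bin counts).
#' @export
simulate_annotation_tracks <- function(spec, truth, gene_density_per_Mb = 10,
                                       motif_density_per_Mb = 5, a_bias = 3,
                                       gc_rho = 0.5, seed = 5L) {
  .check_number(gene_density_per_Mb, "gene_density_per_Mb", lower = 0)
  .check_number(motif_density_per_Mb, "motif_density_per_Mb", lower = 0)
  .check_number(a_bias, "a_bias", lower = 1)
  .check_number(gc_rho, "gc_rho", lower = -1, upper = 1)
  set.seed(seed)
  n <- spec$n_bins
  res <- spec$resolution
  glen <- as.numeric(n) * res
  s <- truth$compartments$s_pr
  empty_bed <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), gene = character())

  n_genes <- stats::rpois(1, gene_density_per_Mb * glen / 1e6)
  if (n_genes > 0) {
    wbin <- ifelse(s > 0, a_bias, 1)
    bins <- sample.int(n, n_genes, replace = TRUE, prob = wbin)
    start <- (bins - 1) * res + round(stats::runif(n_genes, 0, res * 0.5))
    len <- round(stats::runif(n_genes, 5e3, min(5e4, res)))
    genes <- data.frame(chrom = spec$chrom, start = start,
                        end = pmin(start + len, glen),
                        gene = sprintf("gene%04d", seq_len(n_genes)))
    genes <- genes[order(genes$start), ]
    genes$gene <- sprintf("gene%04d", seq_len(n_genes))
    rownames(genes) <- NULL
  } else genes <- empty_bed

  n_motifs <- stats::rpois(1, motif_density_per_Mb * glen / 1e6)
  if (n_motifs > 0) {
    mstart <- sort(round(stats::runif(n_motifs, 0, glen - 19)))
    motifs <- data.frame(chrom = spec$chrom, start = mstart,
                         end = mstart + 19,
                         name = sprintf("ctcf%04d", seq_len(n_motifs)),
                         score = round(stats::runif(n_motifs, 200, 1000)),
                         strand = sample(c("+", "-"), n_motifs, replace = TRUE))
  } else {
    motifs <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), name = character(),
                         score = numeric(), strand = character())
  }

  z <- stats::rnorm(n)
  s_std <- (s - mean(s)) / stats::sd(s)
  gc_lat <- gc_rho * s_std + sqrt(1 - gc_rho^2) * z
  gc <- data.frame(chrom = spec$chrom, start = (seq_len(n) - 1) * res,
                   end = seq_len(n) * res, value = 0.41 + 0.05 * gc_lat)

  dens <- tabulate(pmin(n, floor((genes$start + genes$end) / 2 / res) + 1L),
                   nbins = n)
  gene_density <- data.frame(chrom = spec$chrom,
                             start = (seq_len(n) - 1) * res,
                             end = seq_len(n) * res, value = dens)
  list(genes = genes, motifs = motifs, gc = gc, gene_density = gene_density)
}
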