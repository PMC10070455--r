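test_that("coverage log2 ratio matches closed forms and planted gains", {
  x <- c(10, 20, 30)
  expect_equal(coverage_log2_ratio(x, x), rep(0, 3))
  expect_equal(coverage_log2_ratio(2 * x, x, pseudocount = 0,
                                   scale_to_equal_totals = FALSE),
               rep(1, 3))
  # a 2-copy gain on diploid background sits near +1 after segmentation
  set.seed(14)
  pr <- rpois(400, 100)
  cr <- rpois(400, 100 * c(rep(1, 150), rep(2, 100), rep(1, 150)))
  lr <- coverage_log2_ratio(cr, pr, scale_to_equal_totals = FALSE)
  expect_equal(mean(lr[151:250]), 1, tolerance = 0.1)
  expect_error(coverage_log2_ratio(1:3, 1:4), "binning")
})

test_that("simulated coverage carries the planted CNV signal", {
  sh <- shared_sim()
  cov <- simulate_coverage_tracks(sh$sim$truth, mean_depth = 200, seed = 33)
  lr <- coverage_log2_ratio(cov$cr, cov$pr, scale_to_equal_totals = FALSE)
  cnv <- sh$sim$truth$svs     # bins 40-70 ratio 0.5, 200-240 ratio 2
  gain_bins <- (cnv$start[2] / 5e4 + 1):(cnv$end[2] / 5e4)
  loss_bins <- (cnv$start[1] / 5e4 + 1):(cnv$end[1] / 5e4)
  expect_equal(mean(lr[gain_bins]), 1, tolerance = 0.15)
  expect_equal(mean(lr[loss_bins]), -1, tolerance = 0.15)
})

test_that("CBS recovers planted breakpoints and stays quiet on noise", {
  set.seed(15)
  x <- c(rnorm(80, 0, 0.2), rnorm(70, 1, 0.2), rnorm(80, -1, 0.2))
  seg <- cbs_segment(x, alpha = 0.01, n_perm = 300, seed = 16)
  expect_equal(nrow(seg), 3)
  expect_lte(max(abs(sort(seg$end[-3]) - c(80, 150))), 2)
  expect_equal(seg$class, c("neutral", "gain", "loss"))
  # conservation: length-weighted mean of segment means equals track mean
  expect_equal(sum(seg$mean * seg$n_bins) / sum(seg$n_bins), mean(x))
  # a strong step splits exactly at the step
  y <- c(rnorm(60, 0, 0.2), rnorm(60, 1, 0.2))
  seg2 <- cbs_segment(y, alpha = 0.01, n_perm = 300, seed = 17)
  expect_equal(nrow(seg2), 2)
  expect_lte(abs(seg2$end[1] - 60), 1)
  # flat noise: one segment in nearly all seeds
  flat <- vapply(1:40, function(k) {
    set.seed(300 + k)
    nrow(cbs_segment(rnorm(80), alpha = 0.01, n_perm = 200, seed = 400 + k))
  }, numeric(1))
  expect_gte(mean(flat == 1), 0.95)
  expect_error(cbs_segment(rnorm(50), n_perm = 50), "n_perm")
  expect_error(cbs_segment(rnorm(4), min_seg_bins = 3), "shorter")
})

test_that("consensus SV applies support, window and caller rules", {
  mk <- function(p1, p2, type, support, caller)
    data.frame(chrom1 = "chr1", pos1 = p1, chrom2 = "chr1", pos2 = p2,
               type = type, support = support, caller = caller)
  a <- mk(10000, 20000, "DEL", 8, "callerA")
  b <- mk(10300, 20400, "DEL", 6, "callerB")
  cempty <- data.frame(chrom1 = character(0), pos1 = numeric(0),
                       chrom2 = character(0), pos2 = numeric(0),
                       type = character(0), support = numeric(0),
                       caller = character(0))
  out <- consensus_sv(list(a, b, cempty))
  expect_equal(nrow(out), 1)
  expect_equal(out$type, "DEL")
  expect_equal(out$n_callers, 2)
  expect_equal(out$pos1, median(c(10000, 10300)))
  # caller B below the support filter: no consensus
  b4 <- b; b4$support <- 4
  expect_equal(nrow(consensus_sv(list(a, b4, cempty))), 0)
  # type-specific windows: 900 bp apart merges TRA but not DEL
  t1 <- mk(5e5, 8e5, "TRA", 9, "callerA")
  t2 <- mk(5e5 + 900, 8e5 + 900, "TRA", 9, "callerB")
  expect_equal(nrow(consensus_sv(list(t1, t2))), 1)
  d1 <- mk(5e5, 8e5, "DEL", 9, "callerA")
  d2 <- mk(5e5 + 900, 8e5 + 900, "DEL", 9, "callerB")
  expect_equal(nrow(consensus_sv(list(d1, d2))), 0)
  # mixed types never merge
  i1 <- mk(5e5, 8e5, "INV", 9, "callerA")
  expect_equal(nrow(consensus_sv(list(d1, i1))), 0)
  expect_error(consensus_sv(list(a)), "2 callers")
})

test_that("consensus equals truth when jitter is far below the window", {
  truth <- data.frame(chrom = "chr1",
                      start = seq(1e5, 4e6, length.out = 12),
                      end = seq(1e5, 4e6, length.out = 12) + 5e4,
                      type = rep(c("DEL", "DUP", "INV"), 4))
  sets <- simulate_sv_callsets(truth, sensitivity = 1, fp_rate = 0,
                               breakpoint_jitter_sd = 30, support_mean = 12,
                               seed = 19)
  cons <- consensus_sv(sets, min_support = 5)
  expect_equal(nrow(cons), nrow(truth))
  expect_true(all(abs(cons$pos1 - truth$start) <= 150))
  # precision/recall monotone in min_callers
  noisy <- simulate_sv_callsets(truth, sensitivity = 0.7, fp_rate = 1,
                                breakpoint_jitter_sd = 50, support_mean = 12,
                                genome_size = 5e6, seed = 20)
  stats_at <- function(mc) {
    cons <- consensus_sv(noisy, min_support = 5, min_callers = mc)
    if (!nrow(cons)) return(c(prec = 1, rec = 0))
    tp <- sum(vapply(seq_len(nrow(truth)), function(k)
      any(cons$type == truth$type[k] &
            abs(cons$pos1 - truth$start[k]) <= 500 &
            abs(cons$pos2 - truth$end[k]) <= 500), logical(1)))
    matched <- vapply(seq_len(nrow(cons)), function(r)
      any(truth$type == cons$type[r] &
            abs(cons$pos1[r] - truth$start) <= 500 &
            abs(cons$pos2[r] - truth$end) <= 500), logical(1))
    c(prec = mean(matched), rec = tp / nrow(truth))
  }
  s1 <- stats_at(1); s2 <- stats_at(2); s3 <- stats_at(3)
  expect_true(s1["prec"] <= s2["prec"] && s2["prec"] <= s3["prec"])
  expect_true(s1["rec"] >= s2["rec"] && s2["rec"] >= s3["rec"])
})

test_that("greedy consensus clustering matches a brute-force matcher", {
  # random jittered two-caller sets; compare against an exhaustive
  # first-match clustering written independently
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    base <- sort(runif(n, 0, 5e6))
    mkset <- function(caller) {
      keep <- runif(n) < 0.8
      data.frame(chrom1 = "chr1",
                 pos1 = round(base[keep] + rnorm(sum(keep), 0, 120)),
                 chrom2 = "chr1",
                 pos2 = round(base[keep] + 2e4 + rnorm(sum(keep), 0, 120)),
                 type = "DEL", support = 9, caller = caller)
    }
    sets <- list(mkset("A"), mkset("B"))
    cons <- consensus_sv(sets, min_support = 5)
    # brute force
    pool <- do.call(rbind, sets)
    pool <- pool[order(pool$chrom1, pool$pos1, pool$pos2), ]
    assigned <- rep(0L, nrow(pool))
    cid <- 0L
    for (r in seq_len(nrow(pool))) {
      hit <- 0L
      for (c0 in seq_len(cid)) {
        f <- which(assigned == c0)[1]
        if (abs(pool$pos1[r] - pool$pos1[f]) <= 500 &&
            abs(pool$pos2[r] - pool$pos2[f]) <= 500) { hit <- c0; break }
      }
      if (hit == 0L) { cid <- cid + 1L; hit <- cid }
      assigned[r] <- hit
    }
    nc <- sum(vapply(seq_len(cid), function(c0)
      length(unique(pool$caller[assigned == c0])) >= 2, logical(1)))
    expect_equal(nrow(cons), nc)
  }
})

test_that("condition-specific SV partition reconciles and matches cases", {
  mkcons <- function(p1, types = "DEL")
    data.frame(chrom1 = "chr1", pos1 = p1, chrom2 = "chr1", pos2 = p1 + 2e4,
               type = types, n_callers = 2, callers = "A,B", support_max = 9)
  a <- mkcons(c(1e5, 5e5, 9e5))
  out <- condition_specific_sv(a, a)
  expect_equal(unname(out$counts["shared"]), 3)
  expect_equal(unname(out$counts["pr_specific"]), 0)
  b <- mkcons(c(2e6, 3e6))
  out2 <- condition_specific_sv(a, b)
  expect_equal(unname(out2$counts["shared"]), 0)
  expect_equal(unname(out2$counts["pr_specific"]), 3)
  expect_equal(unname(out2$counts["cr_specific"]), 2)
  # partition property under jittered overlap
  set.seed(23)
  base <- sort(runif(30, 0, 5e6))
  pr <- mkcons(round(base + rnorm(30, 0, 150)))
  cr <- mkcons(round(sample(c(base[1:20], runif(10, 6e6, 9e6))) +
                       rnorm(30, 0, 150)))
  out3 <- condition_specific_sv(pr, cr)
  expect_equal(unname(out3$counts["pr_total"]),
               unname(out3$counts["shared"] + out3$counts["pr_specific"]))
  expect_equal(unname(out3$counts["cr_total"]),
               unname(out3$counts["shared"] + out3$counts["cr_specific"]))
})

test_that("gene CNV annotation reports worked percentages and classes", {
  genome <- 3099.75e6                      # sum of chromosome lengths
  segments <- data.frame(chrom = "chr1",
                         start = c(0, 202.11e6, 300e6, 414.60e6),
                         end = c(202.11e6, 300e6, 414.60e6, 650e6),
                         class = c("loss", "neutral", "gain", "neutral"))
  g <- data.frame(chrom = "chr1",
                  start = c(1e6, 310e6, 610e6), end = c(2e6, 311e6, 612e6),
                  gene = c("gL", "gG", "gN"))
  out <- annotate_genes_cnv(g, segments, genome_size = genome)
  expect_equal(round(out$deleted_pct, 2), 6.52)
  expect_equal(round(out$duplicated_pct, 2), 3.70)
  expect_equal(out$deleted_mb, 202.11)
  expect_equal(out$duplicated_mb, 114.60)
  expect_equal(out$genes$class, c("loss", "gain", "neutral"))
  # a gene spanning a boundary takes the maximal-overlap segment
  g2 <- data.frame(chrom = "chr1", start = 202.11e6 - 3e5,
                   end = 202.11e6 + 7e5, gene = "edge")
  out2 <- annotate_genes_cnv(g2, segments, genome_size = genome)
  expect_equal(out2$genes$class, "neutral")
})
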