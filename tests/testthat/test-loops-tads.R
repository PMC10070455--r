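test_that("planted loops are recovered with accurate localization", {
  sh <- shared_sim()
  loops <- call_loops(sh$pr_vc, donut_radius_bins = 5,
                      min_distance_bins = 4, max_distance_bins = 100)
  truth <- sh$sim$truth$loops_pr
  hit <- vapply(seq_len(nrow(truth)), function(k)
    any(abs(loops$bin1 - truth$bin1[k]) <= 1 &
          abs(loops$bin2 - truth$bin2[k]) <= 1), logical(1))
  expect_true(all(hit))                      # full recall, +-1 bin
  # planted loops rank far above any residual background call
  planted <- loops$fdr[paste(loops$bin1, loops$bin2) %in%
                         paste(truth$bin1, truth$bin2)]
  expect_true(all(planted < 1e-10))
})

test_that("a decay-only map yields no loop calls", {
  nulls <- vapply(c(201, 202, 203, 204, 205), function(sd) {
    spec <- simulation_spec(n_bins = 250, resolution = 5e4,
                            compartment_effect = 0, depth = 8e5, seed = sd)
    sim <- simulate_condition_pair(spec, rewiring_spec())
    nrow(call_loops(balance(sim$pr, "VC"), donut_radius_bins = 5,
                    min_distance_bins = 4, max_distance_bins = 100))
  }, numeric(1))
  expect_lte(sum(nulls > 0), 1)
  expect_error(call_loops(balance(tiny_map(5), "VC"),
                          donut_radius_bins = 5), "donut")
})

test_that("loop set partition follows the flank rule and the oracle", {
  res <- 1e4
  mk <- function(b1, b2) data.frame(start1 = b1 * res, end1 = (b1 + 1) * res,
                                    start2 = b2 * res, end2 = (b2 + 1) * res)
  # (100,150) vs (101,150): common within one-bin flank
  out <- classify_loop_sets(mk(100, 150), mk(101, 150), flank_bins = 1,
                            resolution = res)
  expect_equal(unname(out$counts["common"]), 1)
  # (100,150) vs (102,150): beyond the flank, both specific
  out2 <- classify_loop_sets(mk(100, 150), mk(102, 150), flank_bins = 1,
                             resolution = res)
  expect_equal(unname(out2$counts["common"]), 0)
  expect_equal(unname(out2$counts["pr_specific"]), 1)
  expect_equal(unname(out2$counts["cr_specific"]), 1)
  # oracle equivalence on random instances + partition arithmetic
  for (seed in 1:10) {
    lp <- random_loops(100, seed)
    lc <- random_loops(100, seed + 500)
    out3 <- classify_loop_sets(lp, lc, flank_bins = 1, resolution = res)
    bf <- bruteforce_loop_partition(lp, lc, 1, res)
    expect_equal(unname(out3$counts["common"]), bf$n_common)
    expect_equal(out3$pr_specific, bf$pr_specific)
    expect_equal(out3$cr_specific, bf$cr_specific)
    expect_equal(unname(out3$counts["pr_total"]),
                 unname(out3$counts["common"] + out3$counts["pr_specific"]))
    expect_equal(unname(out3$counts["cr_total"]),
                 unname(out3$counts["common"] + out3$counts["cr_specific"]))
  }
})

test_that("anchor partition merges, classifies and matches brute force", {
  res <- 1e4
  # a CR-specific loop sharing one anchor with a common loop:
  # shared anchor -> common, the other -> CR-specific
  common_loop <- data.frame(start1 = 1e5, end1 = 1.1e5,
                            start2 = 5e5, end2 = 5.1e5)
  cr_only <- data.frame(start1 = 5e5, end1 = 5.1e5,
                        start2 = 9e5, end2 = 9.1e5)
  anch <- classify_anchor_sets(common_loop, rbind(common_loop, cr_only),
                               flank_bins = 1, resolution = res)
  expect_equal(anch$category[anch$start == 5e5], "common")
  expect_equal(anch$category[anch$start == 9e5], "CR-specific")
  # abutting same-condition anchors merge into one region
  two <- data.frame(start1 = c(1e5, 1.1e5), end1 = c(1.1e5, 1.2e5),
                    start2 = c(7e5, 9e5), end2 = c(7.1e5, 9.1e5))
  anch2 <- classify_anchor_sets(two, two[0, ], flank_bins = 1,
                                resolution = res)
  expect_equal(sum(anch2$start == 1e5), 1)
  expect_equal(anch2$end[anch2$start == 1e5], 1.2e5)
  # within-category anchors tile without overlap
  sh_ov <- function(df) {
    by_cat <- split(df, df$category)
    all(vapply(by_cat, function(d) {
      if (nrow(d) < 2) return(TRUE)
      d <- d[order(d$start), ]
      all(d$start[-1] >= d$end[-nrow(d)])
    }, logical(1)))
  }
  # excluded regions are removed before merging
  anch3 <- classify_anchor_sets(two, two[0, ], flank_bins = 1,
                                resolution = res,
                                exclude = data.frame(chrom = "chr1",
                                                     start = 0, end = 2e5))
  expect_false(any(anch3$start < 2e5))
  # brute-force category counts on random loop sets
  for (seed in 1:5) {
    lp <- random_loops(60, seed)
    lc <- random_loops(60, seed + 900)
    anch4 <- classify_anchor_sets(lp, lc, flank_bins = 1, resolution = res)
    expect_true(sh_ov(anch4))
    # brute force: merge pooled anchors, then scan membership
    pool <- rbind(data.frame(s = c(lp$start1, lp$start2),
                             e = c(lp$end1, lp$end2), cond = "PR"),
                  data.frame(s = c(lc$start1, lc$start2),
                             e = c(lc$end1, lc$end2), cond = "CR"))
    pool <- pool[order(pool$s), ]
    merged <- list()
    for (r in seq_len(nrow(pool))) {
      lastk <- length(merged)
      if (lastk > 0 && pool$s[r] <= merged[[lastk]]$e) {
        merged[[lastk]]$e <- max(merged[[lastk]]$e, pool$e[r])
      } else merged[[lastk + 1]] <- list(s = pool$s[r], e = pool$e[r])
    }
    flank <- res
    cats <- vapply(merged, function(mr) {
      inr <- pool$s < (mr$e + flank) & mr$s < (pool$e + flank)
      has_pr <- any(inr & pool$cond == "PR")
      has_cr <- any(inr & pool$cond == "CR")
      if (has_pr && has_cr) "common" else if (has_pr) "PR-specific" else
        "CR-specific"
    }, character(1))
    expect_equal(unname(as.vector(attr(anch4, "counts"))),
                 unname(as.vector(table(factor(cats,
                   c("common", "PR-specific", "CR-specific"))))))
  }
})

test_that("APA quantifies planted loop strength and is null at background", {
  # uniform 3x boost over a compartment-free background
  spec <- simulation_spec(n_bins = 300, resolution = 5e4,
                          compartment_effect = 0,
                          loop_list = data.frame(
                            bin1 = c(40, 90, 150, 200, 250),
                            bin2 = c(60, 115, 172, 228, 272), boost = 3),
                          depth = 1e6, seed = 76)
  sim <- simulate_condition_pair(spec, rewiring_spec())
  bal <- balance(sim$pr, "VC")
  truth <- sim$truth$loops_pr
  res <- apa(bal, truth, window_bins = 5, corner_size = 2)
  expect_equal(res$n_used, nrow(truth))
  expect_equal(res$ratio, 3, tolerance = 0.3 / 3)
  # non-loop pixels give a ratio near 1
  set.seed(12)
  bg <- data.frame(bin1 = sample(50:150, 30), bin2 = 0)
  bg$bin2 <- bg$bin1 + sample(20:60, 30, replace = TRUE)
  res0 <- apa(bal, bg, window_bins = 5, corner_size = 2)
  expect_equal(res0$ratio, 1, tolerance = 0.25)
  # window 1 with corner 1: ratio is exactly center / corner pixel
  res1 <- apa(bal, truth[1, , drop = FALSE], window_bins = 1,
              corner_size = 1)
  expect_equal(res1$ratio, res1$matrix[2, 2] / res1$matrix[3, 1])
})

test_that("APA ratio is monotone in planted boost", {
  ratios <- vapply(c(1.5, 3, 6), function(bo) {
    spec <- simulation_spec(n_bins = 200, resolution = 5e4,
                            compartment_effect = 0,
                            loop_list = data.frame(bin1 = c(40, 90, 140),
                                                   bin2 = c(50, 102, 148),
                                                   boost = bo),
                            depth = 8e5, seed = 77)
    sim <- simulate_condition_pair(spec, rewiring_spec())
    apa(balance(sim$pr, "VC"), spec$loop_list, window_bins = 4,
        corner_size = 2)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("insulation boundaries localize planted TAD joints", {
  spec <- simulation_spec(n_bins = 120, resolution = 5e4,
                          compartment_effect = 0,
                          tad_list = data.frame(start = c(20, 60),
                                                end = c(60, 100), boost = 4),
                          depth = 2e6, seed = 84)
  sim <- simulate_condition_pair(spec, rewiring_spec())
  b <- balance(sim$pr, "ICE")
  it <- insulation_track(b, window_bins = 5)
  tb <- call_tad_boundaries(it, delta_threshold = 0.2,
                            min_separation_bins = 5)
  # the shared internal joint at bin 60 is found within +-1 bin
  internal <- tb$boundaries$bin[tb$boundaries$bin > 30 &
                                  tb$boundaries$bin < 90]
  expect_equal(length(internal), 1)
  expect_lte(abs(internal - 60), 1)
  # a uniform map yields no boundaries
  u <- contact_map(matrix(50, 80, 80), 5e4)
  itu <- insulation_track(u, window_bins = 5)
  tbu <- call_tad_boundaries(itu, delta_threshold = 0.1,
                             min_separation_bins = 5)
  expect_equal(nrow(tbu$boundaries), 0)
})

test_that("boundary prominence is monotone in planted boundary strength", {
  prom <- vapply(c(2, 4, 8), function(bo) {
    spec <- simulation_spec(n_bins = 120, resolution = 5e4,
                            compartment_effect = 0,
                            tad_list = data.frame(start = c(20, 60),
                                                  end = c(60, 100),
                                                  boost = bo),
                            depth = 2e6, seed = 85)
    sim <- simulate_condition_pair(spec, rewiring_spec())
    it <- insulation_track(balance(sim$pr, "ICE"), window_bins = 5)
    tb <- call_tad_boundaries(it, delta_threshold = 0.05,
                              min_separation_bins = 5)
    idx <- which(abs(tb$boundaries$bin - 60) <= 2)
    if (length(idx)) max(tb$boundaries$prominence[idx]) else 0
  }, numeric(1))
  expect_true(all(diff(prom) > 0))
})

test_that("CTCF anchor categories and convergence classes follow definitions", {
  res <- 1e4
  anchors <- data.frame(chrom = "chr1",
                        start = c(0, 2e4, 4e4, 6e4),
                        end = c(1e4, 3e4, 5e4, 7e4))
  motifs <- data.frame(chrom = "chr1",
                       start = c(1000, 2000, 21000, 31000),
                       end = c(1019, 2019, 21019, 31019),
                       name = "m", score = 500,
                       strand = c("+", "-", "+", "-"))
  ann <- annotate_ctcf(anchors, motifs, resolution = res)
  expect_equal(ann$ctcf_category,
               c("multiple", "single", "adjacent-only", "none"))
  # anchor 3 (40-50kb) has no motif inside; motif at 31kb is 1 bin left
  expect_equal(ann$n_motifs, c(2L, 1L, 0L, 0L))
  # convergence classes
  loops <- data.frame(start1 = c(0, 0, 2e4, 0, 4e4),
                      end1 = c(1e4, 1e4, 3e4, 1e4, 5e4),
                      start2 = c(2e4, 6e4, 6e4, 4e4, 6e4),
                      end2 = c(3e4, 7e4, 7e4, 5e4, 7e4))
  mo2 <- data.frame(chrom = "chr1", start = c(1000, 21000),
                    end = c(1019, 21019), name = "m", score = 1,
                    strand = c("+", "-"))
  expect_equal(loop_convergence(loops[1, ], mo2), "convergent")
  mo3 <- mo2
  mo3$strand <- c("-", "+")
  expect_equal(loop_convergence(loops[1, ], mo3), "divergent")
  mo4 <- mo2
  mo4$strand <- c("+", "+")
  expect_equal(loop_convergence(loops[1, ], mo4), "tandem")
  expect_equal(loop_convergence(loops[4, ], mo2), "one-sided")
  expect_equal(loop_convergence(loops[5, ], mo2), "none")
})

test_that("permutation enrichment hits boundaries and calibrates under the null", {
  uni <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  set.seed(29)
  qs <- sort(round(runif(40, 0, 1e6 - 5e3)))
  q <- data.frame(chrom = "chr1", start = qs, end = qs + 5e3)
  # query == reference: maximal overlap, p at the bottom of the null scale
  # (circular shifts with near-zero offset can reproduce full overlap, so
  # the floor is approached rather than exactly attained)
  out <- permutation_enrichment(q, q, uni, n_perm = 200, seed = 4)
  expect_equal(out$observed, nrow(q))
  expect_lte(out$p_enriched, 5 / 201)
  expect_equal(out$direction, "enriched")
  # empty reference: overlap 0, depleted, not an error
  out0 <- permutation_enrichment(q, q[0, ], uni, n_perm = 100, seed = 4)
  expect_equal(out0$observed, 0)
  expect_equal(out0$direction, "depleted")
  # independent query/reference: p roughly uniform (coarse bin check)
  set.seed(31)
  ps <- replicate(60, {
    qs <- sort(round(runif(40, 0, 1e6 - 5e3)))
    rs <- sort(round(runif(40, 0, 1e6 - 5e3)))
    permutation_enrichment(data.frame(chrom = "chr1", start = qs,
                                      end = qs + 5000),
                           data.frame(chrom = "chr1", start = rs,
                                      end = rs + 5000),
                           uni, n_perm = 120,
                           seed = sample.int(1e6, 1))$p_enriched
  })
  expect_gt(mean(ps < 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("loop size stats report medians, tests, and ranges", {
  expect_equal(loop_size_stats(list(a = c(100, 200, 300) * 1e3))$medians[["a"]],
               200e3)
  same <- loop_size_stats(list(a = c(1, 2, 3) * 1e5, b = c(1, 2, 3) * 1e5))
  expect_equal(same$wilcoxon$p, 1)
  # power on shifted distributions
  set.seed(41)
  hits <- replicate(20, {
    a <- rnorm(500, 250e3, 5e4)
    b <- rnorm(500, 300e3, 5e4)
    loop_size_stats(list(a = a, b = b))$wilcoxon$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
  rg <- loop_size_stats(list(a = c(5e4, 5e5, 2e6, 3e6)))$size_ranges
  expect_equal(unname(rg["a", ]), c(1, 1, 2))
  expect_error(loop_size_stats(list(a = numeric(0))), "at least one")
})
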