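# Shared fixtures, built in code. The medium simulation is computed once per
# test run and reused by several files.

tiny_map <- function(n = 5, seed = 1, resolution = 1e4) {
  set.seed(seed)
  m <- matrix(rpois(n * n, 10), n, n)
  m <- m + t(m)
  contact_map(m, resolution)
}

# deterministic map whose counts depend only on |i - j|
distance_map <- function(n = 30, f = function(d) 100 / (1 + d),
                         resolution = 1e4) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  contact_map(matrix(f(d), n, n), resolution)
}

default_spec <- function(seed = 11, ...) {
  simulation_spec(n_bins = 400, resolution = 50000, decay_exponent = 1,
                  compartment_block_len = 20, compartment_effect = 0.4,
                  loop_list = data.frame(bin1 = c(50, 120, 300),
                                         bin2 = c(58, 130, 308), boost = 3),
                  depth = 1e6, seed = seed, ...)
}

default_rewiring <- function(...) {
  rewiring_spec(flip_block_fraction = 0.2,
                cnv_list = data.frame(start = c(40, 200, 330),
                                      end = c(70, 240, 360),
                                      copy_ratio = c(0.5, 2, 1.5)),
                seed = 12, ...)
}

# memoized medium-sized paired simulation + annotation + balanced maps
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- default_spec()
      sim <- simulate_condition_pair(spec, default_rewiring())
      ann <- simulate_annotation_tracks(spec, sim$truth, seed = 13)
      cache <<- list(spec = spec, sim = sim, ann = ann,
                     pr_ice = balance(sim$pr, "ICE"),
                     cr_ice = balance(sim$cr, "ICE"),
                     pr_vc = balance(sim$pr, "VC"),
                     cr_vc = balance(sim$cr, "VC"))
    }
    cache
  }
})

# brute-force loop-set partition oracle: same greedy one-to-one semantics,
# written as explicit nested loops over all pairs
bruteforce_loop_partition <- function(loops_pr, loops_cr, flank_bins,
                                      resolution) {
  flank <- flank_bins * resolution
  ov <- function(s1, e1, s2, e2) s1 < (e2 + flank) && s2 < (e1 + flank)
  used_cr <- rep(FALSE, nrow(loops_cr))
  pairs <- list()
  for (a in seq_len(nrow(loops_pr))) {
    for (b in seq_len(nrow(loops_cr))) {
      if (used_cr[b]) next
      if (ov(loops_pr$start1[a], loops_pr$end1[a],
             loops_cr$start1[b], loops_cr$end1[b]) &&
          ov(loops_pr$start2[a], loops_pr$end2[a],
             loops_cr$start2[b], loops_cr$end2[b])) {
        used_cr[b] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(a, b)
        break
      }
    }
  }
  list(n_common = length(pairs),
       pr_specific = setdiff(seq_len(nrow(loops_pr)),
                             vapply(pairs, `[`, numeric(1), 1)),
       cr_specific = which(!used_cr))
}

random_loops <- function(n, seed, span = 1e7, res = 1e4) {
  set.seed(seed)
  a1 <- sort(round(runif(n, 0, span)))
  gap <- round(runif(n, 5 * res, 50 * res))
  data.frame(start1 = a1, end1 = a1 + res,
             start2 = a1 + gap, end2 = a1 + gap + res)
}
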