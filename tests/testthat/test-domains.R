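# CENP-A domain characterization.

# a track over one 600-bp sequence, bin 100: values per bin
track1 <- function(v, L = 600, bs = 100, sid = "c") {
  signal_track(stats::setNames(list(v), sid), bs, stats::setNames(L, sid))
}

test_that("the run caller detects, merges and filters threshold runs", {
  d <- call_domains(track1(c(0, 0, 1, 1, 1, 0)), threshold = 0.5,
                    merge_gap = 0, min_width = 100)
  expect_equal(d$start, 200)
  expect_equal(d$end, 500)
  expect_equal(d$mean_signal, 1)
  # all-zero track: empty set
  expect_equal(nrow(call_domains(track1(rep(0, 6)), 0.5, min_width = 100)), 0)
  # two runs separated by one low bin merge when merge_gap >= bin
  d2 <- call_domains(track1(c(1, 1, 0, 1, 1, 0)), 0.5, merge_gap = 100,
                     min_width = 100)
  expect_equal(nrow(d2), 1)
  expect_equal(c(d2$start, d2$end), c(0, 500))
  d3 <- call_domains(track1(c(1, 1, 0, 1, 1, 0)), 0.5, merge_gap = 0,
                     min_width = 100)
  expect_equal(nrow(d3), 2)
  # min_width drops narrow runs; NA bins are below threshold
  d4 <- call_domains(track1(c(1, NA, 0, 0, 1, 1)), 0.5, min_width = 150)
  expect_equal(c(d4$start, d4$end), c(400, 600))
  expect_error(call_domains(track1(rep(1, 6)), 0.5, min_width = 0),
               "positive")
})

test_that("domain stats report widths, AT%, and merged occupancy", {
  gen <- c(c = paste0(strrep("AT", 150), strrep("GC", 150)))
  ds <- domain_set(intervals("c", 0, 10), source = "truth")
  st <- domain_stats(ds, gen)
  expect_equal(st$occupancy, 10 / 600)
  expect_equal(st$at_per_domain, 1)     # falls in the AT half
  # overlapping domains are counted once
  ds2 <- domain_set(intervals(c("c", "c"), c(0, 5), c(10, 15)))
  expect_equal(domain_stats(ds2, gen)$covered_bases, 15)
  # occupancy is invariant under splitting a domain into adjacent halves
  ds3 <- domain_set(intervals(c("c", "c"), c(0, 5), c(5, 10)))
  expect_equal(domain_stats(ds3, gen)$occupancy, st$occupancy)
})

test_that("domain-free sequences are excluded from the denominator on request", {
  gen <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 50))
  ds <- domain_set(intervals("a", 0, 10))
  on <- domain_stats(ds, gen, exclude_zero_domain_seqs = TRUE)
  off <- domain_stats(ds, gen, exclude_zero_domain_seqs = FALSE)
  expect_equal(on$analyzed_length, 100)
  expect_equal(off$analyzed_length, 300)
  expect_equal(on$occupancy, 0.1)
  expect_equal(off$occupancy, 10 / 300)
  expect_equal(on$occupancy_pct, 10)
})

test_that("width-AT correlation returns exact r for linear data", {
  st <- list(widths = c(100, 200, 300, 400),
             at_per_domain = c(0.5, 0.6, 0.7, 0.8))
  wc <- suppressWarnings(width_at_correlation(st))  # perfect fit intended
  expect_equal(wc$pearson_r, 1)
  expect_equal(wc$slope, 1000)
  # permuted AT is uncorrelated
  set.seed(61)
  stp <- list(widths = rnorm(1000, 500, 100),
              at_per_domain = runif(1000, 0.4, 0.8))
  expect_lt(abs(width_at_correlation(stp)$pearson_r), 0.1)
  expect_error(width_at_correlation(list(widths = c(1, 2),
                                         at_per_domain = c(0.5, 0.6))),
               "at least 3")
  expect_error(width_at_correlation(list(widths = c(1, 2, 3),
                                         at_per_domain = rep(0.5, 3))),
               "constant")
})

test_that("gap ECDF pools gaps and reports the tail fraction", {
  ds <- domain_set(intervals(rep("c", 3), c(0, 20, 100), c(10, 30, 110)))
  g <- gap_ecdf(ds, cutoff = 20)
  expect_equal(g$gaps, c(10, 70))
  expect_equal(g$fraction_gt_cutoff, 0.5)
  expect_true(g$defined)
  # ECDF is a proper CDF: non-decreasing 0 -> 1
  ev <- g$ecdf(sort(g$gaps))
  expect_true(all(diff(ev) >= 0))
  expect_equal(max(ev), 1)
  # all gaps under the cutoff
  expect_equal(gap_ecdf(ds, cutoff = 1000)$fraction_gt_cutoff, 0)
  # fewer than 2 domains everywhere: flagged undefined
  single <- domain_set(intervals(c("a", "b"), c(0, 0), c(10, 10)))
  expect_false(gap_ecdf(single)$defined)
})

test_that("gap tail fraction equals a brute-force count on random sets", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    st <- sort(sample(seq(0, 5e5, 100), n))
    ds <- domain_set(merge_intervals(intervals(rep("c", n), st, st + 99)))
    g <- gap_ecdf(ds, cutoff = 20000)
    brute_gaps <- diff(st) - 99  # brute: recompute from sorted starts
    brute_gaps <- brute_gaps[brute_gaps > 0]
    expect_equal(g$fraction_gt_cutoff, mean(brute_gaps > 20000))
  }
})

test_that("profile matrix centers rows on domain midpoints", {
  # symmetric bump around the midpoint of a planted domain
  v <- rep(0, 40)
  v[19:22] <- c(1, 2, 2, 1)
  tr <- signal_track(list(c = v), 50, c(c = 2000))
  ds <- domain_set(intervals("c", 900, 1100))  # midpoint 1000, bins 19-22
  pm <- profile_matrix(tr, ds, flank = 500, bin = 50)
  expect_equal(ncol(pm), 20)
  row <- as.numeric(pm[1, ])
  expect_equal(row, rev(row))  # symmetric about the center
  # row mean equals a brute-force average of the plotted profile
  pm2 <- profile_matrix(tr, ds, flank = 200, bin = 100)
  expect_equal(ncol(pm2), 4)
  # domain at the sequence start: left flank missing
  ds_edge <- domain_set(intervals("c", 0, 100))
  pme <- profile_matrix(tr, ds_edge, flank = 500, bin = 50)
  expect_true(all(is.na(pme[1, 1:9])))
  expect_false(anyNA(pme[1, 11:20]))
})

test_that("the mean profile equals a brute-force average over rows", {
  set.seed(83)
  v <- rnorm(200)
  tr <- signal_track(list(c = v), 50, c(c = 10000))
  st <- seq(1000, 8000, 1000)
  ds <- domain_set(intervals(rep("c", length(st)), st, st + 200))
  pm <- profile_matrix(tr, ds, flank = 500, bin = 50)
  brute <- sapply(seq_len(20), function(j) {
    vals <- vapply(seq_along(st), function(i) {
      mid <- (st[i] + st[i] + 200) %/% 2
      p0 <- mid - 500 + (j - 1) * 50
      v[p0 %/% 50 + 1]
    }, 0)
    mean(vals)
  })
  expect_equal(unname(colMeans(pm)), brute)
})

test_that("profile clustering is deterministic and separates planted groups", {
  set.seed(91)
  a <- matrix(rep(c(rep(0, 10), rep(3, 10)), 15), nrow = 15, byrow = TRUE)
  b <- matrix(rep(c(rep(3, 10), rep(0, 10)), 15), nrow = 15, byrow = TRUE)
  m <- structure(rbind(a + rnorm(150, 0, 0.01), b + rnorm(150, 0, 0.01)),
                 class = c("profile_matrix", "matrix", "array"))
  cl <- cluster_profiles(m, k = 2, seed = 7)
  expect_equal(length(unique(cl$assignment[1:15])), 1)
  expect_equal(length(unique(cl$assignment[16:30])), 1)
  expect_true(cl$assignment[1] != cl$assignment[16])
  cl2 <- cluster_profiles(m, k = 2, seed = 7)
  expect_identical(cl$assignment, cl2$assignment)
  # cluster 1 is the strongest by peak height
  expect_gte(max(cl$cluster_means[1, ]), max(cl$cluster_means[2, ]))
})

test_that("degenerate clustering puts identical rows in one cluster", {
  m <- structure(matrix(1, nrow = 6, ncol = 8),
                 class = c("profile_matrix", "matrix", "array"))
  cl <- cluster_profiles(m, k = 2, seed = 1)
  expect_true(cl$degenerate)
  expect_equal(cl$assignment, rep(1L, 6))
  expect_equal(cl$sizes, c(6, 0))
  expect_error(cluster_profiles(m, k = 10, seed = 1), "fewer rows")
})

test_that("marker enrichment averages copies with strand-aware projection", {
  # two + copies with constant signals 1 and 3 average to 2
  v <- c(rep(1, 4), rep(3, 4), rep(9, 2))
  tr <- signal_track(list(c = v), 10, c(c = 100))
  cp <- intervals(c("c", "c"), c(0, 40), c(20, 60), strand = c("+", "+"))
  me <- marker_enrichment(tr, cp)
  expect_equal(me$profile, rep(2, 20))
  expect_equal(me$n_copies, 2)
  # a minus-strand copy contributes its signal flipped
  v2 <- c(rep(1, 10), rep(2, 10))
  tr2 <- signal_track(list(c = v2), 10, c(c = 200))
  cpm <- intervals("c", 0, 200, strand = "-")
  me2 <- marker_enrichment(tr2, cpm)
  expect_equal(me2$profile, c(rep(2, 100), rep(1, 100)))
  # masked positions are excluded; all-copies-masked positions are gaps
  mask <- intervals("c", 0, 5)
  me3 <- marker_enrichment(tr, cp[1, ], mask = mask)
  expect_true(all(is.na(me3$profile[1:5])))
  expect_equal(me3$profile[6:20], rep(1, 15))
  expect_equal(me3$coverage[1:5], rep(0L, 5))
  expect_error(marker_enrichment(tr, cp[0, ]), "one copy")
})

test_that("marker enrichment is linear in the signal", {
  set.seed(3)
  v <- rnorm(20)
  tr <- signal_track(list(c = v), 10, c(c = 200))
  tr3 <- signal_track(list(c = 3 * v), 10, c(c = 200))
  cp <- intervals(c("c", "c"), c(0, 100), c(50, 150),
                  strand = c("+", "-"))
  expect_equal(marker_enrichment(tr3, cp)$profile,
               3 * marker_enrichment(tr, cp)$profile)
})

test_that("max_domain_at returns the AT ceiling of the domain set", {
  expect_equal(max_domain_at(list(at_per_domain = c(0.55, 0.72))), 0.72)
  expect_equal(max_domain_at(list(at_per_domain = 0.61)), 0.61)
  expect_error(max_domain_at(list(at_per_domain = numeric(0))), "empty")
})
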