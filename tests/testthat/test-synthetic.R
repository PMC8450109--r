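# Synthetic-data generator.

test_that("synthetic chromosomes hit their target AT composition", {
  g <- synth_genome(data.frame(length = 10000, at = 0.5), seed = 15)
  expect_equal(nchar(g$genome[["chr1"]]), 10000)
  expect_lt(abs(at_content(g$genome[["chr1"]]) - 0.5), 0.02)
  g2 <- synth_genome(data.frame(length = c(10000, 10000), at = c(0.3, 0.74)),
                     seed = 16)
  expect_lt(abs(at_content(g2$genome[["chr1"]]) - 0.30), 0.02)
  expect_lt(abs(at_content(g2$genome[["chr2"]]) - 0.74), 0.02)
  expect_error(synth_genome(data.frame(length = 100, at = 1.2)), "AT targets")
})

test_that("high-AT islands overwrite the background at their positions", {
  isl <- data.frame(chrom = "chr1", start = 2000, length = 3000, at = 0.85)
  g <- synth_genome(data.frame(length = 20000, at = 0.5), islands = isl,
                    seed = 17)
  island_seq <- substring(g$genome[["chr1"]], 2001, 5000)
  expect_gte(at_content(island_seq), 0.83)
  expect_equal(g$features$type, "island")
  expect_equal(g$features$start, 2000)
  expect_error(synth_genome(data.frame(length = 1000, at = 0.5),
                            islands = data.frame(chrom = "chr1", start = 0,
                                                 length = 100, at = 0.5)),
               ">= 0.83")
})

test_that("the generator is byte-deterministic given its seed", {
  spec <- data.frame(length = c(5000, 3000), at = c(0.62, 0.5))
  a <- synth_genome(spec, seed = 99)
  b <- synth_genome(spec, seed = 99)
  expect_identical(a$genome, b$genome)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a$genome, f1)
  write_fasta(b$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(a$genome, synth_genome(spec, seed = 100)$genome))
})

test_that("cassette insertions are recorded and overlap is rejected", {
  cass <- ngm_cassette()
  g <- synth_genome(data.frame(length = 20000, at = 0.5),
                    cassettes = list(list(cassette = cass, chrom = "chr1",
                                          pos = 1000)),
                    seed = 18)
  expect_identical(substring(g$genome[["chr1"]], 1001, 1000 + cass$length),
                   cass$sequence)
  genes <- g$features[g$features$type == "gene", ]
  expect_setequal(genes$expression, c("ubiquitous", "germline", "somatic"))
  expect_error(
    synth_genome(data.frame(length = 20000, at = 0.5),
                 cassettes = list(list(cassette = cass, chrom = "chr1",
                                       pos = 1000),
                                  list(cassette = cass, chrom = "chr1",
                                       pos = 1500)),
                 seed = 18),
    "overlap")
})

test_that("order-1 mode keeps the stationary AT target", {
  g <- synth_genome(data.frame(length = 20000, at = 0.6), seed = 19,
                    order = 1, rho = 0.5)
  expect_lt(abs(at_content(g$genome[["chr1"]]) - 0.6), 0.02)
})

test_that("noise-free synthetic signal round-trips through the caller", {
  g <- synth_genome(data.frame(length = 3e5, at = 0.62), seed = 20)
  chip <- synth_chip_signal(g$genome, occupancy = 0.2, noise_sd = 0,
                            amplitude = 2, seed = 21)
  called <- call_domains(chip$track, threshold = 1, min_width = 100)
  expect_equal(as.data.frame(called)[, c("seq_id", "start", "end")],
               as.data.frame(chip$truth)[, c("seq_id", "start", "end")])
  st <- domain_stats(chip$truth, g$genome)
  expect_lt(abs(st$occupancy - 0.2), 0.02)
  # determinism
  chip2 <- synth_chip_signal(g$genome, occupancy = 0.2, noise_sd = 0,
                             amplitude = 2, seed = 21)
  expect_identical(chip$truth, chip2$truth)
  expect_identical(chip$track$values, chip2$track$values)
})

test_that("planted domains respect the AT cap and exclusion zones", {
  set.seed(22)
  # build a genome with a hot high-AT island that the cap must forbid
  isl <- data.frame(chrom = "chr1", start = 50000, length = 30000, at = 0.9)
  g <- synth_genome(data.frame(length = 3e5, at = 0.62), islands = isl,
                    seed = 23)
  feats <- data.frame(seq_id = "chr1", start = 150000, end = 160000,
                      strand = "+", type = "gene", label = "NeoR",
                      expression = "ubiquitous")
  chip <- synth_chip_signal(g$genome, feats, occupancy = 0.15, noise_sd = 0,
                            at_cap = 0.80, seed = 24)
  tr <- chip$truth
  # no planted domain overlaps the exclusion feature
  expect_false(any(tr$start < 160000 & tr$end > 150000))
  # no planted domain has a 1-kb center window above the cap
  for (i in seq_len(nrow(tr))) {
    mid <- (tr$start[i] + tr$end[i]) %/% 2
    win <- substring(g$genome[["chr1"]], max(1, mid - 499), mid + 500)
    expect_lte(at_content(win), 0.80 + 0.03)  # sampling wiggle only
  }
  # fully excluded genome errors out
  expect_error(
    synth_chip_signal(c(chr1 = strrep("AT", 5000)), occupancy = 0.1,
                      at_cap = 0.8, seed = 1),
    "no placeable")
})

test_that("AT-coupled widths induce a positive width-AT correlation", {
  # AT-heterogeneous chromosomes give the coupling something to act on
  # (an i.i.d. single-AT background has almost no window-AT variation)
  spec <- data.frame(length = rep(1e5, 4), at = c(0.45, 0.55, 0.65, 0.72))
  wins <- 0L
  reps <- 20
  for (r in seq_len(reps)) {
    g <- synth_genome(spec, seed = 300 + r)
    chip <- synth_chip_signal(g$genome, occupancy = 0.15, noise_sd = 0,
                              width_at_coupling = 1.5, seed = 400 + r)
    st <- domain_stats(chip$truth, g$genome, exclude_zero_domain_seqs = FALSE)
    if (width_at_correlation(st)$pearson_r > 0) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.95 - 1e-9)
})

test_that("the end-to-end fixture chains all stages coherently", {
  fx <- build_fixture(donor_chromosomes = data.frame(length = c(2e5, 1e5),
                                                     at = 0.62),
                      target_length = 1e5, seed = 33)
  # truth round-trip
  expect_identical(reconstruct_ac(fx$sim$truth, fx$pool),
                   unname(fx$sim$ac))
  # classification agrees with the simulator truth on the filtered pool
  rec <- classify_fragments(fx$pool_catalogue, fx$sim$ac)
  truth_ids <- unique(fx$sim$truth$segment_id[fx$sim$truth$source ==
                                                "fragment"])
  expect_setequal(rec$fragment_id[rec$label == "incorporated"], truth_ids)
  # manifest seed rebuild is byte-identical
  fx2 <- build_fixture(donor_chromosomes = data.frame(length = c(2e5, 1e5),
                                                      at = 0.62),
                       target_length = 1e5, seed = 33)
  expect_identical(fx$sim$ac, fx2$sim$ac)
  expect_identical(fx$chip$track$values, fx2$chip$track$values)
  # on-disk outputs are written when a directory is given
  d <- withr::local_tempdir()
  build_fixture(donor_chromosomes = data.frame(length = 5e4, at = 0.62),
                target_length = 2e4, seed = 34, dir = d)
  expect_true(all(file.exists(file.path(d, c("donor.fasta", "catalogue.tsv",
                                             "ac.fasta", "ac_truth.tsv",
                                             "chip_signal.bedgraph",
                                             "domains_truth.bed",
                                             "manifest.json")))))
})
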