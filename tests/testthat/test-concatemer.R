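# End-joining concatemer simulator.

test_that("molar weights convert mass ratios to draw probabilities", {
  m1 <- marker_cassette("m1", rand_dna_fixed(100))
  m2 <- marker_cassette("m2", rand_dna_fixed(200))
  # equal mass, lengths 100 and 200 -> weights 2:1
  p <- pool_spec(m1, m2, mass_fractions = c(1, 1))
  w <- molar_weights(p)
  expect_equal(w[1] / w[2], 2)
  expect_equal(sum(w), 1)
  # mass ratio 300:1 at equal length -> 300:1
  m3 <- marker_cassette("m3", rand_dna_fixed(100))
  p2 <- pool_spec(m1, m3, mass_fractions = c(300, 1))
  w2 <- molar_weights(p2)
  expect_equal(w2[1] / w2[2], 300)
  # one species of equal-length molecules -> uniform
  ct <- digest(c(x = "AAGTACAAGTACAAGTACAA"), ac_donor_enzymes())
  expect_true(all(ct$length[2:3] == ct$length[2]))
})

test_that("incorporation probability is logistic with a hard-step limit", {
  m <- join_model(L0 = 500, s = 100)
  expect_equal(incorporation_prob(500, m), 0.5)
  expect_gt(incorporation_prob(5000, m), 0.999)
  expect_lt(incorporation_prob(50, m), 0.02)
  step <- join_model(L0 = 500, s = 0)
  expect_equal(incorporation_prob(499, step), 0)
  expect_equal(incorporation_prob(500, step), 1)
  expect_error(join_model(L0 = -5), "positive")
  expect_error(join_model(p_hr = 2), "p_hr")
})

test_that("a one-fragment pool with forced orientation builds a perfect array", {
  frag <- marker_cassette("unit", "ACGGT")
  pool <- pool_spec(frag, mass_fractions = 1)
  sim <- simulate_ac(pool, join_model(L0 = 1, s = 0, target_length = 15,
                                      seed = 3),
                     orientation = "forward")
  expect_identical(unname(sim$ac), "ACGGTACGGTACGGT")
  expect_equal(nrow(sim$truth), 3)
  expect_equal(sim$truth$join_type, c("origin", "NHEJ", "NHEJ"))
  expect_equal(sim$truth$ac_start, c(0, 5, 10))
})

test_that("simulation errors out when nothing can be incorporated", {
  short <- marker_cassette("short", rand_dna_fixed(100))
  pool <- pool_spec(short, mass_fractions = 1)
  expect_error(simulate_ac(pool, join_model(L0 = 500, s = 0,
                                            target_length = 1000)),
               "no molecule")
})

test_that("a fixed seed reproduces the simulation bit-exactly", {
  set.seed(77)
  ct <- digest(c(chr = rand_dna(20000, at = 0.6)), ac_donor_enzymes())
  pool <- pool_spec(ct, mass_fractions = 1)
  model <- join_model(L0 = 100, s = 50, target_length = 5000, seed = 99)
  a <- simulate_ac(pool, model)
  b <- simulate_ac(pool, model)
  expect_identical(a$ac, b$ac)
  expect_identical(a$truth, b$truth)
  expect_equal(attr(a$truth, "seed"), 99)
})

test_that("the truth table tiles and reconstructs the AC byte-exactly", {
  set.seed(13)
  ct <- digest(c(chr = rand_dna(30000, at = 0.6)), ac_donor_enzymes())
  pool <- pool_spec(ct, ngm_cassette(), mass_fractions = c(300, 1))
  sim <- simulate_ac(pool, join_model(L0 = 200, s = 100,
                                      target_length = 20000, seed = 5))
  tr <- sim$truth
  expect_equal(tr$ac_start[1], 0)
  expect_true(all(tr$ac_start[-1] == tr$ac_end[-nrow(tr)]))  # exact tiling
  expect_equal(tr$ac_end[nrow(tr)], unname(nchar(sim$ac)))
  expect_identical(reconstruct_ac(tr, pool), unname(sim$ac))
  expect_equal(tr$join_type[1], "origin")
  expect_true(all(tr$join_type[-1] == "NHEJ"))  # p_hr = 0
})

test_that("orientations are balanced over many draws", {
  frag <- marker_cassette("unit", rand_dna_fixed(60, seed = 8))
  pool <- pool_spec(frag, mass_fractions = 1)
  sim <- simulate_ac(pool, join_model(L0 = 1, s = 0,
                                      target_length = 60 * 10000, seed = 21))
  n_plus <- sum(sim$truth$orientation == "+")
  bt <- binom.test(n_plus, nrow(sim$truth), p = 0.5)
  expect_equal(nrow(sim$truth), 10000)
  expect_gt(bt$p.value, 0.001)
})

test_that("length bias raises the mean length of incorporated molecules", {
  set.seed(31)
  ct <- digest(c(chr = rand_dna(50000, at = 0.6)), ac_donor_enzymes())
  pool <- pool_spec(ct, mass_fractions = 1)
  sim <- simulate_ac(pool, join_model(L0 = 400, s = 150,
                                      target_length = 30000, seed = 17))
  inc_len <- sim$truth$ac_end - sim$truth$ac_start
  expect_gt(mean(inc_len), mean(ct$length))
})

test_that("homology-mediated joins merge the shared terminus once", {
  # molecule whose end equals its start over 30 bp forces detectable homology
  core <- rand_dna_fixed(30, seed = 4)
  mol <- marker_cassette("h", paste0(core, rand_dna_fixed(140, seed = 6), core))
  pool <- pool_spec(mol, mass_fractions = 1)
  sim <- simulate_ac(pool, join_model(L0 = 1, s = 0, p_hr = 1, h_min = 20,
                                      target_length = 1500, seed = 2),
                     orientation = "forward")
  hr <- sim$truth$join_type == "HR"
  expect_true(any(hr))
  seg_len <- sim$truth$ac_end - sim$truth$ac_start
  expect_true(all(seg_len[hr] == 200 - 30))
  expect_identical(reconstruct_ac(sim$truth, pool), unname(sim$ac))
})

test_that("marker placement reports intervals and completeness", {
  cass <- ngm_cassette()
  set.seed(9)
  ct <- digest(c(chr = rand_dna(30000, at = 0.6)), ac_donor_enzymes())
  pool <- pool_spec(ct, cass, mass_fractions = c(10, 1))
  sim <- simulate_ac(pool, join_model(L0 = 200, s = 100,
                                      target_length = 60000, seed = 10))
  rep <- spike_markers(sim$truth, pool)
  expect_gt(nrow(rep), 0)
  expect_true(all(rep$completeness == 1))  # no pre-fragmentation configured
  expect_true(all(rep$marker == "NGM"))
  # no markers at all -> empty report
  pool2 <- pool_spec(ct, mass_fractions = 1)
  sim2 <- simulate_ac(pool2, join_model(L0 = 200, s = 100,
                                        target_length = 5000, seed = 1))
  expect_equal(nrow(spike_markers(sim2$truth, pool2)), 0)
})

test_that("pre-fragmentation yields partial marker segments", {
  cass <- ngm_cassette()
  ct <- local({ set.seed(40); digest(c(chr = rand_dna(20000, at = 0.6)),
                                     ac_donor_enzymes()) })
  pool <- pool_spec(ct, cass, mass_fractions = c(1, 5),
                    break_prob = c(0, 0.9))
  sim <- simulate_ac(pool, join_model(L0 = 200, s = 100,
                                      target_length = 80000, seed = 12))
  rep <- spike_markers(sim$truth, pool)
  expect_true(any(rep$completeness < 1))
  expect_true(all(rep$completeness > 0 & rep$completeness <= 1))
  expect_identical(reconstruct_ac(sim$truth, pool), unname(sim$ac))
})

test_that("truth tables round-trip through TSV with their seed", {
  frag <- marker_cassette("unit", "ACGGT")
  pool <- pool_spec(frag, mass_fractions = 1)
  sim <- simulate_ac(pool, join_model(L0 = 1, s = 0, target_length = 20,
                                      seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$segment_id, sim$truth$segment_id)
  expect_equal(attr(back, "seed"), 3)
})
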