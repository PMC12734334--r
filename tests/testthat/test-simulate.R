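test_that("planted genomes are recovered exactly by the miner", {
  spec <- genome_spec(10000, planted = data.frame(
    position = c(1000, 3000, 5000, 7000, 9000),
    motif = c("AG", "T", "CCT", "AAAG", "ACGTC"),
    repeat_count = c(7, 12, 6, 5, 5)), seed = 3)
  g <- simulate_genome(spec)
  found <- find_ssrs(g$sequences, g$rules)
  expect_identical(found$loci, g$truth$loci)
  # brute-force oracle confirms no background tract survives
  oracle <- brute_force_ssrs(g$sequences[[1]], g$rules)
  expect_equal(nrow(oracle), 5L)
  expect_equal(oracle$start, g$truth$loci$start)
})

test_that("zero plantings give a clean background", {
  g <- simulate_genome(genome_spec(5000, seed = 8))
  expect_equal(nrow(find_ssrs(g$sequences, g$rules)$loci), 0L)
  expect_equal(nrow(brute_force_ssrs(g$sequences[[1]], g$rules)), 0L)
})

test_that("genome specs validate bounds, thresholds and overlap", {
  expect_error(genome_spec(100, data.frame(position = 95, motif = "AG",
                                           repeat_count = 7)),
               "outside sequence bounds")
  expect_error(genome_spec(1000, data.frame(position = c(10, 20),
                                            motif = c("A", "T"),
                                            repeat_count = c(12, 12))),
               "overlap")
  expect_error(genome_spec(1000, data.frame(position = 10, motif = "AG",
                                            repeat_count = 5)),
               "below its detection threshold")
})

test_that("generators are seed-deterministic", {
  s1 <- simulate_genome(genome_spec(3000, seed = 5))$sequences
  s2 <- simulate_genome(genome_spec(3000, seed = 5))$sequences
  expect_identical(s1, s2)
  p1 <- simulate_population(population_spec(seed = 5))
  p2 <- simulate_population(population_spec(seed = 5))
  expect_identical(p1$genotypes$calls, p2$genotypes$calls)
  t1 <- simulate_traits(57, groups = p1$truth$groups, seed = 5)
  t2 <- simulate_traits(57, groups = p1$truth$groups, seed = 5)
  expect_identical(t1, t2)
})

test_that("default population matches the emulated collection dimensions", {
  sim <- simulate_population(population_spec(seed = 1))
  expect_equal(length(sim$genotypes$accessions), 57L)
  expect_equal(nrow(sim$genotypes$markers), 15L)
  b <- to_band_matrix(sim$genotypes)
  expect_equal(ncol(b), 115L)
  expect_equal(length(unique(sim$truth$groups)), 5L)
  # every cell carries one or two alleles (complete data by default)
  expect_true(all(vapply(sim$genotypes$calls, length, 1L) %in% 1:2))
})

test_that("realized similarities match the calibration targets", {
  for (seed in c(2, 7)) {
    spec <- population_spec(seed = seed)
    sim <- simulate_population(spec)
    s <- simple_matching(to_band_matrix(sim$genotypes))
    same <- pair_mask(sim$truth$groups) & upper.tri(s)
    diff_ <- !pair_mask(sim$truth$groups) & upper.tri(s)
    expect_lt(abs(mean(s[same]) - spec$within_similarity), 0.03)
    expect_lt(abs(mean(s[diff_]) - spec$between_similarity), 0.03)
  }
})

test_that("closed-form expected similarity matches a direct simulation", {
  # one locus, no group structure: expectation vs many simulated pairs
  spec <- population_spec(n_accessions = 400L, n_groups = 1L,
                          na_per_locus = 5L, locus_names = "L1",
                          within_similarity = 0.9,
                          between_similarity = 0.7, seed = 33)
  sim <- simulate_population(spec)
  s <- simple_matching(to_band_matrix(sim$genotypes))
  exp_s <- expected_matching_similarity(sim$truth$locus_freqs,
                                        sim$truth$theta)
  expect_lt(abs(mean(s[upper.tri(s)]) - exp_s), 0.03)
})

test_that("unattainable similarity targets raise a calibration error", {
  expect_error(simulate_population(population_spec(
    na_per_locus = c(2L, 2L), locus_names = c("L1", "L2"),
    n_groups = 2L, n_accessions = 10L,
    within_similarity = 0.9, between_similarity = 0.05, seed = 1)),
    "calibration error")
})

test_that("cutting at the planted threshold recovers the groups", {
  sim <- simulate_population(population_spec(seed = 16))
  grp <- cut_at_similarity(upgma(simple_matching(
    to_band_matrix(sim$genotypes))), 0.76)
  expect_true(perfect_recovery(grp, sim$truth$groups))
  # single-group population collapses to one cluster at the same cut
  one <- simulate_population(population_spec(n_groups = 1L, seed = 16))
  grp1 <- cut_at_similarity(upgma(simple_matching(
    to_band_matrix(one$genotypes))), 0.76)
  expect_equal(length(unique(grp1)), 1L)
})

test_that("trait tables honor the color split and group correlation", {
  sim <- simulate_population(population_spec(seed = 19))
  meta <- simulate_traits(57, groups = sim$truth$groups, seed = 19)
  expect_equal(sum(meta$color == "brown"), 39L)
  expect_equal(sum(meta$color == "white"), 18L)
  # perfect correlation concentrates white in one group
  meta1 <- simulate_traits(57, groups = sim$truth$groups,
                           correlation = 1, seed = 19)
  # the designated group is entirely white; the surplus spills elsewhere
  per_group_white <- tapply(meta1$color == "white", sim$truth$groups, all)
  expect_true(any(per_group_white))
  # codebook closure: encoding never errors
  ids <- molecular_id_table(to_band_matrix(sim$genotypes), meta)
  expect_equal(length(ids), 57L)
})
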