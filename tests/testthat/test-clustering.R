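band_from_rows <- function(rows) {
  # wrap plain 0/1 rows as a band_matrix over one marker per column pair
  n <- nrow(rows)
  m <- ncol(rows)
  structure(rows,
            marker = paste0("M", seq_len(m)),
            size = rep(150L, m),
            missing = matrix(FALSE, n, length(unique(paste0("M",
                                                            seq_len(m)))),
                             dimnames = list(rownames(rows),
                                             paste0("M", seq_len(m)))),
            class = c("band_matrix", "matrix", "array"))
}

test_that("simple matching counts shared absences and presences", {
  rows <- rbind(x = c(1L, 1L, 0L, 0L), y = c(1L, 0L, 1L, 0L))
  s <- simple_matching(band_from_rows(rows))
  expect_equal(s["x", "y"], 0.5)
  ident <- rbind(x = c(1L, 0L, 1L), y = c(1L, 0L, 1L))
  expect_equal(simple_matching(band_from_rows(ident))["x", "y"], 1)
  comp <- rbind(x = rep(1L, 10), y = rep(0L, 10))
  expect_equal(simple_matching(band_from_rows(comp))["x", "y"], 0)
})

test_that("pairwise-complete handling drops missing markers per pair", {
  man <- marker_manifest(c("M1", "M2"))
  g <- genotype_matrix(c("a1", "a2", "a3"), man,
                       matrix(list(150L, 200L,
                                   150L, integer(0),
                                   152L, 200L),
                              nrow = 3, byrow = TRUE))
  s <- simple_matching(to_band_matrix(g))
  # a1 vs a2 compared on M1 columns only (both carry 150, absent 152)
  expect_equal(s["a1", "a2"], 1)
  # columns: M1:150, M1:152, M2:200 -> a1 = 1,0,1; a3 = 0,1,1 -> 1/3
  expect_equal(s["a1", "a3"], 1 / 3)
})

test_that("three-taxon UPGMA matches the hand computation", {
  d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(as.dist(d))
  expect_equal(tr$height, c(0.2, 0.6))
  expect_equal(tr$merge[1, ], c(-2L, -1L))
  cd <- as.matrix(cophenetic_distances(tr))
  expect_equal(cd["A", "B"], 0.2)
  expect_equal(cd["A", "C"], 0.6)
})

test_that("all-equal distances give equal-height merges under the tie rule", {
  d <- matrix(0.5, 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tr <- upgma(as.dist(d))
  expect_equal(tr$height, rep(0.5, 3))
  expect_equal(tr$merge[1, ], c(-2L, -1L))  # (A,B) first by label order
})

test_that("cophenetic distances agree with average-linkage hclust", {
  set.seed(5)
  for (case in 1:8) {
    n <- sample(5:12, 1)
    x <- matrix(runif(n * 6), n)
    rownames(x) <- paste0("t", seq_len(n))
    d <- dist(x)
    got <- cophenetic_distances(upgma(d))
    want <- cophenetic(hclust(d, method = "average"))
    expect_equal(as.matrix(got)[rownames(x), rownames(x)],
                 as.matrix(want)[rownames(x), rownames(x)],
                 tolerance = 1e-12)
    # ultrametric: max of two sides of any triple equals the third or less
    tr <- upgma(d)
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("tree is invariant under leaf permutation up to isomorphism", {
  set.seed(6)
  n <- 9
  x <- matrix(runif(n * 5), n)
  rownames(x) <- paste0("t", seq_len(n))
  d1 <- dist(x)
  perm <- sample(n)
  d2 <- dist(x[perm, ])
  c1 <- as.matrix(cophenetic_distances(upgma(d1)))
  c2 <- as.matrix(cophenetic_distances(upgma(d2)))
  expect_equal(c2[rownames(x), rownames(x)], c1[rownames(x), rownames(x)],
               tolerance = 1e-12)
})

test_that("similarity cuts behave at the extremes and are monotone", {
  sim <- simulate_population(population_spec(seed = 9))
  s <- simple_matching(to_band_matrix(sim$genotypes))
  tr <- upgma(s)
  expect_equal(length(unique(cut_at_similarity(tr, 0))), 1L)
  g_all <- cut_at_similarity(tr, 1)
  # at threshold 1, only exact duplicates (height-0 merges) share a group
  dup_pairs <- sum(s[upper.tri(s)] == 1)
  expect_equal(length(unique(g_all)), nrow(s) - dup_pairs)
  sizes <- vapply(seq(0, 1, by = 0.05), function(th)
    length(unique(cut_at_similarity(tr, th))), 1L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("newick export preserves heights on the similarity scale", {
  sim <- simulate_population(population_spec(seed = 10))
  tr <- upgma(simple_matching(to_band_matrix(sim$genotypes)))
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  p <- ape::read.tree(tf)
  expect_setequal(p$tip.label, sim$genotypes$accessions)
  expect_true(ape::is.ultrametric(p, tol = 1e-6))
  # path distance between two leaves = 2 x merge height
  cp <- ape::cophenetic.phylo(p)
  cd <- as.matrix(cophenetic_distances(tr))
  labs <- rownames(cd)
  expect_equal(cp[labs, labs], 2 * cd[labs, labs], tolerance = 1e-6)
})
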