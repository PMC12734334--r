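test_that("fingerprints are the band rows in display order", {
  b <- tiny_cover_instance()
  expect_identical(as.character(fingerprint_code(b, "acc2")), "111110")
  expect_identical(as.character(fingerprint_code(b, "acc4")), "101001")
  expect_error(fingerprint_code(b, "accX"), "unknown accession")
  # identical call sets give identical fingerprints
  man <- marker_manifest("M1")
  g <- genotype_matrix(c("a1", "a2"), man,
                       matrix(list(c(150L, 152L), c(150L, 152L)), 2))
  bb <- to_band_matrix(g)
  expect_identical(fingerprint_code(bb, "a1"), fingerprint_code(bb, "a2"))
  # fully missing accession: all-zero, low confidence
  g2 <- genotype_matrix(c("a1", "a2"), man,
                        matrix(list(150L, integer(0)), 2))
  fp <- fingerprint_code(to_band_matrix(g2), "a2")
  expect_identical(as.character(fp), "0")
  expect_true(attr(fp, "low_confidence"))
})

test_that("default collection yields 115-bit fingerprints", {
  sim <- simulate_population(population_spec(seed = 13))
  b <- to_band_matrix(sim$genotypes)
  expect_equal(nchar(fingerprint_code(b, "A01")), 115L)
})

test_that("identity codes concatenate and parse deterministically", {
  cb <- id_codebook(list(
    color = list(levels = c(brown = "B", white = "W"), role = "trait"),
    origin = list(levels = c(China = "CN", Japan = "JP"),
                  role = "supplementary")))
  id <- build_molecular_id("101", list(color = "brown", origin = "China"),
                           cb, accession = "a1")
  expect_identical(id$payload, "101-B-CN")
  id2 <- build_molecular_id("101", list(color = "brown", origin = "Japan"),
                            cb)
  expect_identical(substr(id2$payload, 1, 6), substr(id$payload, 1, 6))
  expect_false(id2$payload == id$payload)
  expect_error(build_molecular_id("101", list(color = "red",
                                              origin = "China"), cb),
               "encoding error.*color")
  expect_error(build_molecular_id("101", list(color = "brown"), cb),
               "encoding error.*origin")
})

test_that("payload round-trips through parse for random ids", {
  set.seed(23)
  cb <- default_codebook()
  for (case in 1:25) {
    fp <- paste(sample(0:1, sample(5:120, 1), replace = TRUE),
                collapse = "")
    meta <- list(color = sample(c("brown", "white"), 1),
                 origin = sample(c("China", "Japan", "Malaysia"), 1),
                 cultivation = sample(c("industrial", "artificial"), 1))
    id <- build_molecular_id(fp, meta, cb)
    back <- parse_molecular_id(id$payload)
    expect_identical(back$fingerprint, id$fingerprint)
    expect_identical(back$trait_code, id$trait_code)
    expect_identical(back$supplementary_code, id$supplementary_code)
  }
  expect_error(parse_molecular_id("101-B"), "malformed")
})

test_that("planted duplicate groups are recovered exactly", {
  sim <- simulate_population(population_spec(seed = 14))
  g <- sim$genotypes
  copy_calls <- function(from, to) {
    i <- match(from, g$accessions)
    for (j in match(to, g$accessions))
      g$calls[j, ] <<- g$calls[i, ]
  }
  # two triples and two pairs of identical strains
  copy_calls("A02", c("A12", "A24"))
  copy_calls("A05", c("A08", "A09"))
  copy_calls("A35", "A53")
  copy_calls("A29", "A49")
  b <- to_band_matrix(g)
  meta <- simulate_traits(length(g$accessions), groups = sim$truth$groups,
                          seed = 14)
  ids <- molecular_id_table(b, meta)
  groups <- detect_duplicates(ids, on = "fingerprint")
  expect_equal(lapply(groups, as.character),
               list(c("A02", "A12", "A24"), c("A05", "A08", "A09"),
                    c("A29", "A49"), c("A35", "A53")))
})

test_that("distinct payloads never merge fingerprint-identical strains", {
  cb <- default_codebook()
  mk <- function(acc, origin)
    build_molecular_id("1100", list(color = "brown", origin = origin,
                                    cultivation = "industrial"), cb,
                       accession = acc)
  ids <- list(mk("a1", "China"), mk("a2", "Japan"), mk("a3", "China"))
  by_fp <- detect_duplicates(ids, on = "fingerprint")
  expect_equal(length(by_fp), 1L)
  expect_true(attr(by_fp[[1]], "metadata_distinct"))
  by_payload <- detect_duplicates(ids, on = "payload")
  expect_equal(as.character(by_payload[[1]]), c("a1", "a3"))
  # payload keys split but never merge fingerprint groups
  expect_gte(length(unique(vapply(ids, `[[`, "", "payload"))),
             length(unique(vapply(ids, `[[`, "", "fingerprint"))))
})

test_that("barcode payload carries a verifiable checksum", {
  cb <- default_codebook()
  id <- build_molecular_id("101", list(color = "brown", origin = "China",
                                       cultivation = "industrial"), cb)
  qp <- qr_payload(id)
  expect_identical(substr(qp, 1, nchar(id$payload)), id$payload)
  expect_identical(substr(qp, nchar(qp) - 1, nchar(qp)),
                   oracle_checksum36(id$payload))
  set.seed(31)
  for (case in 1:20) {
    payload <- paste(sample(c(0:9, LETTERS, "-"), sample(5:60, 1),
                            replace = TRUE), collapse = "")
    expect_identical(substr(qr_payload(payload), nchar(payload) + 1,
                            nchar(payload) + 2),
                     oracle_checksum36(payload))
  }
  expect_error(qr_payload(""), "empty payload")
  expect_error(qr_payload(strrep("1", 300), capacity = 100),
               "capacity")
  # a 115-bit fingerprint payload fits the default capacity
  expect_silent(qr_payload(paste0(strrep("1", 115), "-B-CNI")))
})

test_that("codebooks round-trip through their text schema", {
  cb <- default_codebook()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_codebook(cb, tf)
  cb2 <- read_codebook(tf)
  expect_equal(cb2, cb)
  expect_error(id_codebook(list(x = list(levels = c(a = "A", b = "A"),
                                         role = "trait"))),
               "unambiguous")
})
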