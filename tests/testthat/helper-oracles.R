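# Independent oracles and shared fixtures for the test suite.

# Brute-force SSR scanner: tests every (start, unit length) pair and extends
# character by character. Same reporting convention as the package scanner
# (maximal periodic run, leftmost phase, trailing partial unit trimmed) but
# an entirely separate implementation.
brute_force_ssrs <- function(seq, rules = motif_rules()) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  L <- length(chars)
  out <- list()
  for (start in seq_len(L)) {
    for (u in 1:6) {
      if (start + u - 1 > L) next
      unit_chars <- chars[start:(start + u - 1)]
      if (!all(unit_chars %in% acgt)) next
      unit <- paste(unit_chars, collapse = "")
      prim <- TRUE
      for (d in seq_len(u - 1)) {
        if (u %% d == 0 &&
            unit == strrep(substr(unit, 1, d), u / d)) prim <- FALSE
      }
      if (!prim) next
      # leftmost phase of its periodic run?
      if (start > 1 && chars[start - 1] %in% acgt &&
          chars[start - 1] == chars[start - 1 + u]) next
      pos <- start + u
      while (pos <= L && chars[pos] %in% acgt &&
             chars[pos] == chars[pos - u]) pos <- pos + 1
      count <- (pos - start) %/% u
      if (count < rules[[u]]) next
      out[[length(out) + 1]] <- data.frame(
        start = start - 1L, end = start - 1L + u * count, motif = unit,
        unit_length = u, repeat_count = count, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_length = integer(),
                      repeat_count = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_length), ]
  rownames(res) <- NULL
  res
}

# Published per-locus diversity values for a 57-accession H. marmoreus
# collection typed at 15 SSR loci, used as a regression fixture for the
# internal identities of such tables (He = 1 - 1/Ne, PIC <= He, column
# totals and means).
reference_diversity_table <- function() {
  data.frame(
    locus = c("SSR3", "SSR11", "SSR12", "SSR15", "SSR18", "SSR22", "SSR26",
              "SSR32", "SSR35", "SSR36", "SSR38", "SSR48", "SSR51",
              "SSR61", "SSR65"),
    PIC = c(0.476, 0.725, 0.325, 0.436, 0.132, 0.374, 0.339, 0.171,
            0.592, 0.586, 0.323, 0.523, 0.582, 0.360, 0.327),
    Na = c(5L, 9L, 5L, 6L, 7L, 4L, 9L, 8L, 11L, 10L, 7L, 9L, 17L, 5L, 3L),
    Ne = c(2.283, 4.174, 1.690, 2.109, 1.166, 1.988, 1.563, 1.232, 2.840,
           2.658, 1.590, 2.513, 2.909, 1.757, 1.702),
    He = c(0.562, 0.760, 0.408, 0.526, 0.142, 0.497, 0.360, 0.188, 0.648,
           0.624, 0.371, 0.602, 0.656, 0.431, 0.413),
    I = c(0.916, 1.524, 0.598, 0.846, 0.271, 0.690, 0.734, 0.336, 1.185,
          1.241, 0.639, 0.992, 1.082, 0.701, 0.603),
    stringsAsFactors = FALSE)
}

# Random Dirichlet frequency vector (independent of the package internals).
random_freqs <- function(k, alpha = 1) {
  g <- rgamma(k, alpha)
  g / sum(g)
}

# Exhaustive minimum set cover over accessions of a band matrix.
exhaustive_min_cover <- function(b) {
  accs <- rownames(b)
  for (size in seq_along(accs)) {
    combos <- utils::combn(accs, size, simplify = FALSE)
    for (cc in combos) {
      if (coverage(cc, b) == 1) return(cc)
    }
  }
  stop("no cover found")
}

# Independent mod-36 checksum: base-36 digit values via strtoi, other
# characters via code point arithmetic.
oracle_checksum36 <- function(x) {
  digits <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]
  total <- 0
  for (ch in strsplit(x, "")[[1]]) {
    v <- strtoi(ch, base = 36L)
    if (is.na(v)) v <- utf8ToInt(ch) %% 36
    total <- (total + v) %% 1296
  }
  paste0(digits[total %/% 36 + 1], digits[total %% 36 + 1])
}

# 4-accession, 3-marker instance whose greedy cover is {acc2, acc4} in that
# order and whose minimum cover size is 2 (verified exhaustively in tests).
tiny_cover_instance <- function() {
  man <- marker_manifest(c("M1", "M2", "M3"))
  calls <- list(
    list(150L, 250L, 350L),                     # acc1: 10 10 10
    list(c(150L, 152L), c(250L, 252L), 350L),   # acc2: 11 11 10
    list(152L, 250L, 350L),                     # acc3: 01 10 10
    list(150L, 250L, 352L))                     # acc4: 10 10 01
  g <- genotype_matrix(paste0("acc", 1:4), man,
                       matrix(unlist(calls, recursive = FALSE),
                              nrow = 4, byrow = TRUE))
  to_band_matrix(g)
}

# Same-group / different-group indicator helper.
pair_mask <- function(groups) outer(groups, groups, "==")

perfect_recovery <- function(assignment, truth) {
  length(unique(assignment)) == length(unique(truth)) &&
    all(tapply(assignment, truth, function(x) length(unique(x))) == 1) &&
    all(tapply(truth, assignment, function(x) length(unique(x))) == 1)
}
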