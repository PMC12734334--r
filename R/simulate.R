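#' Specification of a synthetic genome with planted SSR tracts
#'
#' @param length Sequence length in bp.
#' @param planted data.frame with columns \code{position} (1-based start),
#'   \code{motif} (primitive unit) and \code{repeat_count}; tracts must fit
#'   inside the sequence and must not overlap or touch.
#' @param gc Background GC content in [0, 1].
#' @param seed RNG seed.
#' @param rules \code{\link{motif_rules}} the background is kept clean
#'   against.
#' @return Object of class \code{genome_spec}.
#' @export
genome_spec <- function(length, planted = NULL, gc = 0.5, seed = 1,
                        rules = motif_rules()) {
  if (is.null(planted))
    planted <- data.frame(position = integer(), motif = character(),
                          repeat_count = integer())
  stopifnot(all(c("position", "motif", "repeat_count") %in% names(planted)))
  if (nrow(planted)) {
    span_len <- nchar(planted$motif) * planted$repeat_count
    ends <- planted$position + span_len - 1L
    if (any(planted$position < 1L) || any(ends > length))
      stop("spec error: planted tract outside sequence bounds")
    ord <- order(planted$position)
    p <- planted[ord, ]
    e <- ends[ord]
    if (nrow(p) > 1L && any(p$position[-1L] <= e[-nrow(p)] + 1L))
      stop("spec error: planted tracts overlap or touch")
    for (i in seq_len(nrow(planted))) {
      u <- nchar(planted$motif[i])
      if (planted$repeat_count[i] < rules[[u]])
        stop("spec error: planted tract ", i, " below its detection ",
             "threshold (", planted$repeat_count[i], " < ", rules[[u]], ")")
      canonical_motif(planted$motif[i])  # validates unit
    }
  }
  structure(list(length = as.integer(length), planted = planted, gc = gc,
                 seed = as.integer(seed), rules = rules),
            class = "genome_spec")
}

#' Simulate a genome with planted SSR tracts and known truth
#'
#' Draws an i.i.d. background at the requested GC content, writes the
#' planted perfect repeats over it, then repeatedly rescans and point-mutates
#' the background until the only tracts reaching the detection thresholds
#' are exactly the planted ones (accidental background repeats, and any
#' background bases that would extend a planted tract, are broken by
#' substitution outside the planted spans). Mining the returned sequence
#' therefore recovers the truth catalog exactly.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @return List with \code{sequences} (named character vector, one
#'   sequence), \code{truth} (the planted \code{ssr_catalog}) and
#'   \code{rules}.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2,
             (1 - spec$gc) / 2)
  chars <- sample(bases, spec$length, replace = TRUE, prob = probs)

  planted <- spec$planted
  in_planted <- rep(FALSE, spec$length)
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      u <- nchar(planted$motif[i])
      span <- planted$position[i]:(planted$position[i] +
                                   u * planted$repeat_count[i] - 1L)
      chars[span] <- strsplit(planted$motif[i], "")[[1L]][
        (seq_along(span) - 1L) %% u + 1L]
      in_planted[span] <- TRUE
    }
  }

  truth_loci <- if (nrow(planted)) {
    u <- nchar(planted$motif)
    data.frame(seq_id = "chr1",
               start = as.integer(planted$position - 1L),
               end = as.integer(planted$position - 1L +
                                u * planted$repeat_count),
               motif = planted$motif,
               motif_class = unname(vapply(planted$motif, canonical_motif,
                                           character(1))),
               unit_length = as.integer(u),
               repeat_count = as.integer(planted$repeat_count),
               stringsAsFactors = FALSE)
  } else {
    data.frame(seq_id = character(), start = integer(), end = integer(),
               motif = character(), motif_class = character(),
               unit_length = integer(), repeat_count = integer())
  }
  truth_loci <- truth_loci[order(truth_loci$start), , drop = FALSE]
  rownames(truth_loci) <- NULL

  truth_key <- paste(truth_loci$start, truth_loci$end, truth_loci$motif)
  for (iter in 1:100) {
    found <- find_ssrs(c(chr1 = paste(chars, collapse = "")), spec$rules)
    found_key <- paste(found$loci$start, found$loci$end, found$loci$motif)
    extra <- which(!found_key %in% truth_key)
    if (length(extra) == 0L && all(truth_key %in% found_key)) break
    if (length(extra) == 0L)
      stop("spec error: a planted tract was destroyed during cleanup")
    for (e in extra) {
      span <- (found$loci$start[e] + 1L):found$loci$end[e]  # 1-based
      editable <- span[!in_planted[span]]
      if (length(editable) == 0L)
        stop("spec error: accidental tract lies entirely inside planted ",
             "spans; change plantings")
      pos <- editable[ceiling(length(editable) / 2)]
      chars[pos] <- sample(setdiff(bases, chars[pos]), 1L)
    }
    if (iter == 100L) stop("background cleanup did not converge")
  }

  list(sequences = c(chr1 = paste(chars, collapse = "")),
       truth = ssr_catalog(truth_loci, genome_length = spec$length),
       rules = spec$rules)
}

#' Specification of a synthetic structured population
#'
#' Defaults emulate a 57-accession dikaryotic collection typed at 15
#' multi-allelic SSR loci with 5 groups, a within-group simple-matching
#' similarity of 0.90 and a between-group similarity of 0.72, so that a cut
#' at similarity 0.76 separates the groups and pairwise similarities span
#' roughly 0.70--1.00.
#'
#' @param n_accessions Number of accessions.
#' @param na_per_locus Integer vector of allele counts per locus; the
#'   default is a 15-locus profile totalling 115 alleles.
#' @param locus_names Marker names, same length as \code{na_per_locus}.
#' @param n_groups Number of groups.
#' @param within_similarity,between_similarity Target expected
#'   simple-matching similarities.
#' @param concentration Dirichlet concentration for locus allele-frequency
#'   vectors.
#' @param missing_rate Fraction of cells blanked as missing data (never a
#'   cell carrying the only copy of an allele).
#' @param seed RNG seed.
#' @return Object of class \code{population_spec}.
#' @export
population_spec <- function(n_accessions = 57L,
                            na_per_locus = c(5L, 9L, 5L, 6L, 7L, 4L, 9L,
                                             8L, 11L, 10L, 7L, 9L, 17L,
                                             5L, 3L),
                            locus_names = c("SSR3", "SSR11", "SSR12",
                                            "SSR15", "SSR18", "SSR22",
                                            "SSR26", "SSR32", "SSR35",
                                            "SSR36", "SSR38", "SSR48",
                                            "SSR51", "SSR61", "SSR65")[
                                              seq_along(na_per_locus)],
                            n_groups = 5L,
                            within_similarity = 0.90,
                            between_similarity = 0.72,
                            concentration = 3,
                            missing_rate = 0,
                            seed = 1L) {
  stopifnot(n_accessions >= n_groups, all(na_per_locus >= 1L),
            max(na_per_locus) <= n_accessions,
            length(locus_names) == length(na_per_locus),
            between_similarity < within_similarity,
            within_similarity <= 1, between_similarity >= 0)
  structure(list(n_accessions = as.integer(n_accessions),
                 na_per_locus = as.integer(na_per_locus),
                 locus_names = locus_names,
                 n_groups = as.integer(n_groups),
                 within_similarity = within_similarity,
                 between_similarity = between_similarity,
                 concentration = concentration,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "population_spec")
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

#' Expected simple-matching similarity under the population model
#'
#' Exact expectation of the simple-matching coefficient on the band matrix
#' for a pair of accessions, given the per-locus allele frequency vectors
#' and the slot-resampling rates. A band column disagrees iff its allele
#' lies in exactly one of the two accessions' band sets, so
#' \eqn{E[S] = 1 - \sum_l E|B_x \Delta B_y|_l / N}. Within a group the two
#' accessions share a realized prototype pair; between groups the
#' prototypes are independently derived from a shared ancestral pair. Both
#' expectations are enumerated exactly over prototype allele pairs.
#'
#' @param p List of per-locus allele-frequency vectors.
#' @param theta Accession-level slot resampling probability.
#' @param phi Group-level slot resampling probability (between-group only).
#' @param between If \code{TRUE}, expectation for an accession pair from
#'   two different groups; otherwise from the same group.
#' @return Expected similarity in [0, 1].
#' @export
expected_matching_similarity <- function(p, theta, phi = 0,
                                         between = FALSE) {
  N <- sum(lengths(p))
  e_delta <- vapply(p, function(pl) {
    na <- length(pl)
    # q[a, j]: P(one slot reads allele j | prototype slot allele is a)
    q <- matrix(theta * rep(pl, each = na), na, na)
    diag(q) <- diag(q) + (1 - theta)
    if (between) {
      # r[A, j]: slot-read prob marginalized over the phi-resampled proto
      q <- (1 - phi) * q + phi * matrix(rep(pl, each = na), na, na)
    }
    tot <- 0
    for (j in seq_len(na)) {
      carry <- outer(q[, j], q[, j], function(x, y) x + y - x * y)
      tot <- tot + as.numeric(t(pl) %*% (2 * carry * (1 - carry)) %*% pl)
    }
    tot
  }, numeric(1))
  1 - sum(e_delta) / N
}

# Expected simple-matching similarity for one accession pair conditional on
# realized prototype pairs (lists of length-2 allele-index vectors per
# locus). shared = TRUE: both accessions descend from the same prototype.
cond_similarity <- function(proto_x, proto_y, p, theta, shared) {
  N <- sum(lengths(p))
  e_delta <- 0
  for (j in seq_along(p)) {
    pl <- p[[j]]
    qx <- lapply(proto_x[[j]], function(a) {
      q <- theta * pl; q[a] <- q[a] + (1 - theta); q
    })
    px <- qx[[1L]] + qx[[2L]] - qx[[1L]] * qx[[2L]]
    if (shared) {
      e_delta <- e_delta + sum(2 * px * (1 - px))
    } else {
      qy <- lapply(proto_y[[j]], function(a) {
        q <- theta * pl; q[a] <- q[a] + (1 - theta); q
      })
      py <- qy[[1L]] + qy[[2L]] - qy[[1L]] * qy[[2L]]
      e_delta <- e_delta + sum(px + py - 2 * px * py)
    }
  }
  1 - e_delta / N
}

#' Simulate a structured multi-allelic population with known truth
#'
#' Generative model per locus: an allele-frequency vector is drawn from a
#' symmetric Dirichlet; an ancestral pair of alleles is drawn from it; each
#' group derives a prototype pair by resampling each allele with probability
#' \eqn{\phi}; each dikaryotic accession derives its call by resampling each
#' prototype allele with probability \eqn{\theta}. \eqn{\theta} and
#' \eqn{\phi} are calibrated by root-finding on the exact expected
#' simple-matching similarity of the band matrix
#' (\code{\link{expected_matching_similarity}}), so that within- and
#' between-group pairs hit their similarity targets in expectation. After
#' sampling, any allele class that no accession carries is patched into a
#' randomly chosen accession so the band matrix has exactly
#' \code{sum(na_per_locus)} columns.
#'
#' @param spec A \code{\link{population_spec}}.
#' @return List with \code{genotypes} (a \code{\link{genotype_matrix}}) and
#'   \code{truth}: group labels, per-locus allele sizes and frequency
#'   vectors, per-group slot-level and band-level frequency vectors,
#'   calibrated \code{theta} and \code{phi}, and the expected within/between
#'   similarities.
#' @export
simulate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_accessions
  L <- length(spec$na_per_locus)
  N <- sum(spec$na_per_locus)
  acc <- sprintf("A%02d", seq_len(n))

  sizes <- lapply(seq_len(L), function(j)
    100L + 10L * j + 2L * (seq_len(spec$na_per_locus[j]) - 1L))
  p <- lapply(spec$na_per_locus, rdirichlet1, alpha = spec$concentration)

  s_floor <- expected_matching_similarity(p, theta = 1)
  if (spec$within_similarity < s_floor ||
      spec$between_similarity < s_floor)
    stop("calibration error: similarity targets unattainable for this ",
         "allele-frequency profile (minimum expected similarity ",
         round(s_floor, 3), ")")
  theta <- if (spec$within_similarity >= 1) 0 else
    stats::uniroot(function(th)
      expected_matching_similarity(p, th) - spec$within_similarity,
      c(0, 1), tol = 1e-8)$root
  s_between_floor <- expected_matching_similarity(p, theta, phi = 1,
                                                  between = TRUE)
  if (spec$n_groups > 1L && spec$between_similarity < s_between_floor)
    stop("calibration error: between-group target ",
         spec$between_similarity, " below the attainable floor ",
         round(s_between_floor, 3), " at the calibrated theta")
  phi <- if (spec$n_groups == 1L) 0 else
    stats::uniroot(function(ph)
      expected_matching_similarity(p, theta, ph, between = TRUE) -
        spec$between_similarity,
      c(0, 1), tol = 1e-8)$root

  groups <- sort(rep_len(seq_len(spec$n_groups), n))
  names(groups) <- acc

  draw <- function(j) sample(spec$na_per_locus[j], 1L, prob = p[[j]])
  mutate_slots <- function(base, rate) {
    # exact-count mutation: resample round-balanced rate * 2L slots,
    # reducing the variance of realized pairwise similarity
    m <- rate * 2L * L
    m <- floor(m) + (stats::runif(1) < m - floor(m))
    if (m > 0) {
      for (sl in sample(2L * L, min(m, 2L * L))) {
        j <- (sl - 1L) %/% 2L + 1L
        base[[j]][(sl - 1L) %% 2L + 1L] <- draw(j)
      }
    }
    base
  }

  # draw an ancestral pair per locus and group prototypes from it,
  # rejecting sets whose conditional expected within/between similarities
  # stray from the targets (the empirical calibration contract:
  # expectations within +/- 0.03 of spec)
  draw_protos <- function() {
    ancestor <- lapply(seq_len(L), function(j) c(draw(j), draw(j)))
    lapply(seq_len(spec$n_groups), function(g) mutate_slots(ancestor, phi))
  }
  proto <- draw_protos()
  if (spec$n_groups > 1L) {
    best_dev <- Inf
    for (try in seq_len(200L)) {
      cand <- draw_protos()
      devs <- c(
        vapply(seq_len(spec$n_groups), function(g)
          cond_similarity(cand[[g]], cand[[g]], p, theta, shared = TRUE) -
            spec$within_similarity, numeric(1)),
        unlist(lapply(seq_len(spec$n_groups - 1L), function(g)
          vapply((g + 1L):spec$n_groups, function(h)
            cond_similarity(cand[[g]], cand[[h]], p, theta,
                            shared = FALSE) - spec$between_similarity,
            numeric(1)))))
      dev <- max(abs(devs))
      if (dev < best_dev) { best_dev <- dev; proto <- cand }
      if (dev <= 0.02) break
    }
    if (best_dev > 0.03)
      stop("calibration error: could not realize group prototypes with ",
           "expected similarities within 0.03 of the targets (best ",
           round(best_dev, 3), ")")
  }

  slots <- array(0L, dim = c(n, L, 2L))
  for (i in seq_len(n)) {
    s_i <- mutate_slots(proto[[groups[i]]], theta)
    for (j in seq_len(L)) slots[i, j, ] <- s_i[[j]]
  }

  # patch alleles that were never drawn so every class appears once
  for (j in seq_len(L)) {
    present <- unique(as.vector(slots[, j, ]))
    absent <- setdiff(seq_len(spec$na_per_locus[j]), present)
    if (length(absent)) {
      hosts <- sample(n, length(absent))
      slots[cbind(hosts, j, 2L)] <- absent
    }
  }

  calls <- matrix(vector("list", n * L), nrow = n, ncol = L)
  for (i in seq_len(n))
    for (j in seq_len(L))
      calls[[i, j]] <- sizes[[j]][sort(unique(slots[i, j, ]))]

  if (spec$missing_rate > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(L)) {
        if (stats::runif(1) >= spec$missing_rate) next
        others <- unlist(calls[-i, j])
        if (all(calls[[i, j]] %in% others)) calls[[i, j]] <- integer(0)
      }
    }
  }

  manifest <- marker_manifest(spec$locus_names)
  g <- genotype_matrix(acc, manifest, calls)

  # truth frequencies: slot-level and band-level (what the estimator sees)
  group_sizes <- tabulate(groups, spec$n_groups)
  slot_freqs <- lapply(seq_len(spec$n_groups), function(gr) {
    lapply(seq_len(L), function(j) {
      f <- theta * p[[j]]
      for (s in proto[[gr]][[j]])
        f[s] <- f[s] + (1 - theta) / 2
      f
    })
  })
  band_freqs <- lapply(seq_len(L), function(j) {
    carry <- rep(0, spec$na_per_locus[j])
    for (gr in seq_len(spec$n_groups)) {
      pr <- proto[[gr]][[j]]
      p_slot <- lapply(1:2, function(s) {
        f <- theta * p[[j]]
        f[pr[s]] <- f[pr[s]] + (1 - theta)
        f
      })
      carry <- carry + group_sizes[gr] / n *
        (1 - (1 - p_slot[[1L]]) * (1 - p_slot[[2L]]))
    }
    carry / sum(carry)
  })

  list(genotypes = g,
       truth = list(groups = groups,
                    sizes = stats::setNames(sizes, spec$locus_names),
                    locus_freqs = stats::setNames(p, spec$locus_names),
                    slot_freqs = slot_freqs,
                    band_freqs = stats::setNames(band_freqs,
                                                 spec$locus_names),
                    theta = theta, phi = phi,
                    expected_within = spec$within_similarity,
                    expected_between = spec$between_similarity),
       spec = spec)
}

#' Simulate qualitative trait metadata for a collection
#'
#' Every accession receives one level per codebook field. If the codebook
#' has a \code{color} field with \code{brown}/\code{white} levels, white is
#' assigned to a fixed proportion of accessions (default 18/57, the
#' brown:white split typical of cultivated crab-flavor/white-jade panels)
#' and is concentrated, at rate \code{correlation}, in the group whose size
#' is closest to the white count — emulating collections where one
#' phenotype clusters in one genetic group. Other fields are drawn
#' uniformly over their levels.
#'
#' @param n Number of accessions.
#' @param codebook An \code{\link{id_codebook}}.
#' @param groups Optional named integer vector of group labels (from
#'   \code{\link{simulate_population}} truth); required for correlated
#'   color assignment.
#' @param correlation Probability that each white slot is filled from the
#'   designated group rather than from the whole collection.
#' @param white_fraction Fraction of white accessions.
#' @param seed RNG seed.
#' @return data.frame with column \code{accession} plus one column per
#'   codebook field.
#' @export
simulate_traits <- function(n, codebook = default_codebook(),
                            groups = NULL, correlation = 0.9,
                            white_fraction = 18 / 57, seed = 1L) {
  stopifnot(inherits(codebook, "id_codebook"))
  set.seed(seed)
  acc <- if (!is.null(groups) && !is.null(names(groups))) names(groups)
         else sprintf("A%02d", seq_len(n))
  out <- data.frame(accession = acc, stringsAsFactors = FALSE)
  for (fn in names(codebook$fields)) {
    levels <- names(codebook$fields[[fn]]$levels)
    if (fn == "color" && all(c("brown", "white") %in% levels)) {
      n_white <- round(n * white_fraction)
      color <- rep("brown", n)
      if (!is.null(groups) && n_white > 0L) {
        tab <- table(groups)
        target <- as.integer(names(tab)[which.min(abs(tab - n_white))])
        in_target <- which(groups == target)
        pool_target <- sample(in_target)
        pool_all <- sample(seq_len(n))
        white <- integer(0)
        while (length(white) < n_white) {
          from_target <- stats::runif(1) < correlation &&
            length(setdiff(pool_target, white)) > 0L
          pool <- if (from_target) setdiff(pool_target, white)
                  else setdiff(pool_all, white)
          white <- c(white, pool[1L])
        }
        color[white] <- "white"
      } else if (n_white > 0L) {
        color[sample(n, n_white)] <- "white"
      }
      out[[fn]] <- color
    } else {
      out[[fn]] <- sample(levels, n, replace = TRUE)
    }
  }
  out
}
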