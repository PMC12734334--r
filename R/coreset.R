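#' Allele-class coverage of an accession subset
#'
#' Fraction of the allele classes (band-matrix columns) present anywhere in
#' the full collection that are also carried by at least one accession of
#' the subset.
#'
#' @param core Character vector of accession ids (may be empty).
#' @param b A \code{\link{to_band_matrix}} result.
#' @return Numeric in [0, 1].
#' @export
coverage <- function(core, b) {
  stopifnot(inherits(b, "band_matrix"))
  total <- sum(colSums(unclass(b)) > 0L)
  if (length(core) == 0L) return(0)
  if (!all(core %in% rownames(b)))
    stop("unknown accession(s): ",
         paste(setdiff(core, rownames(b)), collapse = ", "))
  covered <- sum(colSums(unclass(b)[core, , drop = FALSE]) > 0L)
  covered / total
}

#' Select a core collection by greedy allele-coverage maximization
#'
#' The maximization (M) strategy objective: retain every allele class with
#' as few accessions as possible. Implemented as a deterministic greedy set
#' cover: at each step pick the accession covering the most not-yet-covered
#' allele classes, breaking ties first by larger total band count, then by
#' input order; stop when coverage reaches 100\%. If \code{target_size}
#' exceeds the cover size, selection continues by maximizing the running
#' Shannon diversity of band counts within the growing core, so the extra
#' accessions balance allele-class representation rather than add
#' duplicates.
#'
#' Optional quantitative traits are discretized into quartile classes and
#' appended as extra coverage columns, so the core also spans phenotype
#' classes.
#'
#' @param b A \code{\link{to_band_matrix}} result.
#' @param target_size Optional core size; if smaller than the minimum
#'   achievable cover a warning is raised and the full cover returned.
#' @param traits Optional data.frame of numeric traits (rownames or first
#'   column = accession ids) appended as quartile-class columns.
#' @return Object of class \code{core_set}: list with \code{selected}
#'   (accession ids in selection order), \code{coverage_curve} (fraction of
#'   allele classes covered after each pick), \code{retention_rate} and
#'   \code{n_total}.
#' @export
select_core <- function(b, target_size = NULL, traits = NULL) {
  stopifnot(inherits(b, "band_matrix"))
  x <- unclass(b)[, colSums(unclass(b)) > 0L, drop = FALSE]
  n_band_cols <- ncol(x)
  if (!is.null(traits)) x <- cbind(x, trait_class_columns(traits, rownames(b)))
  n <- nrow(x)
  band_total <- rowSums(unclass(b))      # tie rule (a): total band count
  covered <- rep(FALSE, ncol(x))
  selected <- integer(0)
  curve <- numeric(0)

  repeat {
    gain <- x[, !covered, drop = FALSE] %*% rep(1, sum(!covered))
    gain[selected] <- -1
    best_gain <- max(gain)
    if (best_gain <= 0) break
    cand <- which(gain == best_gain)
    cand <- cand[band_total[cand] == max(band_total[cand])]
    pick <- cand[1L]                     # tie rule (b): input order
    selected <- c(selected, pick)
    covered <- covered | x[pick, ] > 0L
    curve <- c(curve, sum(covered[seq_len(n_band_cols)]) / n_band_cols)
  }

  if (!is.null(target_size)) {
    if (target_size < length(selected)) {
      warning("target_size ", target_size,
              " is below the minimum achievable cover (",
              length(selected), "); returning the full cover")
    } else {
      while (length(selected) < min(target_size, n)) {
        pool <- setdiff(seq_len(n), selected)
        div <- vapply(pool, function(i) {
          counts <- colSums(x[c(selected, i), seq_len(n_band_cols),
                              drop = FALSE])
          p <- counts[counts > 0]
          p <- p / sum(p)
          -sum(p * log(p))
        }, numeric(1))
        cand <- pool[div == max(div)]
        selected <- c(selected, cand[1L])
        curve <- c(curve, curve[length(curve)])
      }
    }
  }

  structure(list(selected = rownames(x)[selected],
                 coverage_curve = curve,
                 retention_rate = length(selected) / n,
                 n_total = n),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat("Core collection:", length(x$selected), "of", x$n_total,
      sprintf("accessions (retention %.2f%%), final coverage %.1f%%\n",
              100 * x$retention_rate,
              100 * x$coverage_curve[length(x$coverage_curve)]))
  invisible(x)
}

# quartile-discretized trait columns as one-hot coverage classes
trait_class_columns <- function(traits, accessions) {
  if (!is.data.frame(traits)) traits <- as.data.frame(traits)
  if (!is.null(traits[["accession"]])) {
    rownames(traits) <- traits$accession
    traits$accession <- NULL
  }
  traits <- traits[accessions, , drop = FALSE]
  cols <- list()
  for (v in names(traits)) {
    q <- stats::quantile(traits[[v]], probs = c(0.25, 0.5, 0.75),
                         na.rm = TRUE)
    cls <- findInterval(traits[[v]], unique(q)) + 1L
    for (lev in sort(unique(cls[!is.na(cls)]))) {
      cols[[paste0(v, ":Q", lev)]] <- as.integer(!is.na(cls) & cls == lev)
    }
  }
  do.call(cbind, cols)
}

#' Compare the core against random subsets of the same size
#'
#' Monte-Carlo estimate of the allele-class coverage achieved by uniformly
#' random accession subsets, for contrast with the full coverage of the
#' M-strategy core.
#'
#' @param b A \code{\link{to_band_matrix}} result.
#' @param size Subset size.
#' @param replicates Number of random subsets.
#' @param seed RNG seed.
#' @return List with \code{core_coverage}, \code{random_mean},
#'   \code{random_sd}, \code{size} and \code{replicates}.
#' @export
compare_baselines <- function(b, size, replicates = 1000, seed = 1) {
  stopifnot(inherits(b, "band_matrix"), size <= nrow(b), size >= 1)
  core <- select_core(b)
  set.seed(seed)
  accs <- rownames(b)
  random_cov <- vapply(seq_len(replicates), function(r) {
    coverage(sample(accs, size), b)
  }, numeric(1))
  list(core_size = length(core$selected),
       core_coverage = coverage(core$selected, b),
       random_mean = mean(random_cov),
       random_sd = stats::sd(random_cov),
       size = size, replicates = replicates)
}
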