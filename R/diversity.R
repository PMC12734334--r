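#' Band-based allele frequencies at one locus
#'
#' Each accession contributes one count per distinct band it carries at the
#' locus (a two-band dikaryon contributes two counts, a single-band strain
#' one); missing accessions are excluded from the denominator. This is the
#' band-scoring convention under which the usual diversity statistics are
#' then computed.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param locus Marker name.
#' @return Object of class \code{allele_frequencies}: list with
#'   \code{locus}, \code{sizes} (allele sizes), \code{freqs} (proportions
#'   summing to 1, all positive) and \code{n_observations} (total scored
#'   bands).
#' @export
allele_frequencies <- function(g, locus) {
  stopifnot(inherits(g, "genotype_matrix"))
  j <- match(locus, g$markers$name)
  if (is.na(j)) stop("unknown locus: ", locus)
  bands <- unlist(g$calls[, j])
  if (length(bands) == 0L)
    stop("no data at locus ", locus, ": all calls missing")
  counts <- table(bands)
  structure(list(locus = locus,
                 sizes = as.integer(names(counts)),
                 freqs = as.numeric(counts) / sum(counts),
                 n_observations = sum(counts)),
            class = "allele_frequencies")
}

freqs_of <- function(f) {
  if (inherits(f, "allele_frequencies")) f$freqs else as.numeric(f)
}

check_freqs <- function(p) {
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-9)
    stop("invalid allele frequencies: must be positive and sum to 1")
  p
}

#' Polymorphic information content (PIC)
#'
#' Botstein's multi-allele form:
#' \deqn{PIC = 1 - \sum_j p_j^2 - \sum_{j<k} 2 p_j^2 p_k^2.}
#' Always \code{0 <= PIC <= He < 1}.
#'
#' @param f An \code{\link{allele_frequencies}} object or a bare numeric
#'   frequency vector.
#' @return Numeric scalar.
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(f) {
  p <- check_freqs(freqs_of(f))
  s2 <- sum(p^2)
  # sum_{j<k} 2 p_j^2 p_k^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Effective number of alleles, Nei gene diversity, Shannon index
#'
#' \code{effective_alleles} is \eqn{Ne = 1 / \sum p_j^2}; \code{expected_het}
#' is the plain Nei gene diversity \eqn{He = 1 - \sum p_j^2} (no small-sample
#' correction), so the identity \eqn{He = 1 - 1/Ne} holds exactly;
#' \code{shannon} is \eqn{I = -\sum p_j \ln p_j} in nats.
#'
#' @inheritParams pic
#' @return Numeric scalar.
#' @examples
#' effective_alleles(rep(0.25, 4))  # 4
#' expected_het(rep(0.25, 4))      # 0.75
#' shannon(rep(0.25, 4))           # log(4)
#' @export
effective_alleles <- function(f) {
  p <- check_freqs(freqs_of(f))
  1 / sum(p^2)
}

#' @rdname effective_alleles
#' @export
expected_het <- function(f) {
  p <- check_freqs(freqs_of(f))
  1 - sum(p^2)
}

#' @rdname effective_alleles
#' @export
shannon <- function(f) {
  p <- check_freqs(freqs_of(f))
  -sum(p * log(p))
}

#' Expected heterozygosity implied by an effective allele number
#'
#' Under the plain Nei gene diversity estimator, \eqn{He = 1 - 1/Ne}. Useful
#' for consistency checks between independently reported Ne and He values.
#'
#' @param ne Effective number of alleles (>= 1).
#' @return Numeric He.
#' @export
he_from_ne <- function(ne) {
  stopifnot(all(ne >= 1))
  1 - 1 / ne
}

#' Per-locus diversity table
#'
#' One row per locus with PIC, Na (observed allele count), Ne, He and I,
#' plus a totals row (column sums) and a means row (totals / locus count).
#' Loci with no data are reported with \code{NA} and excluded from totals
#' and means.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @return data.frame of class \code{diversity_table} with columns
#'   \code{locus, PIC, Na, Ne, He, I}; the last two rows are labelled
#'   \code{"Total"} and \code{"Mean"}.
#' @export
diversity_table <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  loci <- g$markers$name[order(g$markers$display_order)]
  rows <- lapply(loci, function(m) {
    f <- tryCatch(allele_frequencies(g, m), error = function(e) NULL)
    if (is.null(f))
      return(data.frame(locus = m, PIC = NA_real_, Na = NA_integer_,
                        Ne = NA_real_, He = NA_real_, I = NA_real_))
    data.frame(locus = m, PIC = pic(f), Na = length(f$freqs),
               Ne = effective_alleles(f), He = expected_het(f),
               I = shannon(f))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$Na)
  if (!any(ok)) stop("no locus with data")
  tot <- colSums(tab[ok, c("PIC", "Na", "Ne", "He", "I")])
  tab <- rbind(tab,
               data.frame(locus = "Total", PIC = tot[["PIC"]],
                          Na = tot[["Na"]], Ne = tot[["Ne"]],
                          He = tot[["He"]], I = tot[["I"]]),
               data.frame(locus = "Mean", PIC = tot[["PIC"]] / sum(ok),
                          Na = tot[["Na"]] / sum(ok),
                          Ne = tot[["Ne"]] / sum(ok),
                          He = tot[["He"]] / sum(ok),
                          I = tot[["I"]] / sum(ok)))
  rownames(tab) <- NULL
  class(tab) <- c("diversity_table", "data.frame")
  tab
}

#' Write a diversity table with conventional rounding
#'
#' Statistics at 3 decimals, mean Na at 2 decimals, as such tables are
#' usually printed.
#'
#' @param tab A \code{\link{diversity_table}}.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_diversity_table <- function(tab, path, sep = "\t") {
  out <- tab
  for (col in c("PIC", "Ne", "He", "I"))
    out[[col]] <- sprintf("%.3f", out[[col]])
  is_mean <- out$locus == "Mean"
  out$Na <- ifelse(is_mean, sprintf("%.2f", tab$Na), sprintf("%g", tab$Na))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
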