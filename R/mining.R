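#' MISA-style repeat-count thresholds for SSR detection
#'
#' Minimum number of tandem repeats a perfect tract must reach, per unit
#' length, to be called an SSR. Defaults follow the common genome-survey
#' convention for fungal assemblies: mononucleotide runs of at least 10,
#' dinucleotide repeats of at least 6, and tri- through hexanucleotide
#' repeats of at least 5.
#'
#' @param mono,di,tri,tetra,penta,hexa Integer minimum repeat counts for unit
#'   lengths 1--6.
#' @return Object of class \code{motif_rules}: a named integer vector with
#'   names \code{"1"} .. \code{"6"}.
#' @export
motif_rules <- function(mono = 10L, di = 6L, tri = 5L, tetra = 5L,
                        penta = 5L, hexa = 5L) {
  r <- as.integer(c(mono, di, tri, tetra, penta, hexa))
  if (anyNA(r) || any(r < 2L))
    stop("all repeat-count thresholds must be integers >= 2")
  names(r) <- as.character(1:6)
  structure(r, class = "motif_rules")
}

#' Detect perfect SSR tracts in DNA sequences
#'
#' Scans each sequence for maximal perfect tandem repeats of a primitive unit
#' of 1--6 bp whose repeat count meets the per-unit-length threshold. A tract
#' is maximal when its periodic run cannot be extended by a single base in
#' either direction; trailing partial units are trimmed so that
#' \code{end - start == unit_length * repeat_count}. A run reportable under
#' several unit lengths (a poly-A tract is periodic at every unit length) is
#' reported only at its shortest, primitive, unit. Soft-masked (lowercase)
#' bases are uppercased before scanning; \code{N} breaks tracts.
#'
#' @param sequences A \code{Biostrings::DNAStringSet}, a named character
#'   vector of sequences, or the path of a (possibly gzipped) FASTA file.
#' @param rules A \code{\link{motif_rules}} object.
#' @return An \code{ssr_catalog}: list with \code{loci} (data.frame with
#'   columns \code{seq_id}, \code{start}, \code{end} (0-based half-open),
#'   \code{motif}, \code{motif_class}, \code{unit_length},
#'   \code{repeat_count}, sorted by sequence then start),
#'   \code{genome_length}, \code{counts_by_unit_length} and
#'   \code{counts_by_motif_class}.
#' @examples
#' find_ssrs(c(chr1 = paste0("G", strrep("AG", 7), "G")), motif_rules())
#' @export
find_ssrs <- function(sequences, rules = motif_rules()) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (inherits(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
  } else if (is.character(sequences)) {
    seqs <- sequences
  } else {
    stop("sequences must be a DNAStringSet, character vector or FASTA path")
  }
  if (length(seqs) == 0L || all(nchar(seqs) == 0L))
    stop("empty input: no sequences to scan")
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  loci <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    loci[[i]] <- scan_one_sequence(names(seqs)[i], toupper(seqs[[i]]), rules)
  }
  loci <- do.call(rbind, loci)
  if (is.null(loci)) {
    loci <- data.frame(seq_id = character(), start = integer(),
                       end = integer(), motif = character(),
                       motif_class = character(), unit_length = integer(),
                       repeat_count = integer(), stringsAsFactors = FALSE)
  }
  loci <- loci[order(match(loci$seq_id, names(seqs)), loci$start), ,
               drop = FALSE]
  rownames(loci) <- NULL
  ssr_catalog(loci, genome_length = sum(nchar(seqs)))
}

# One sequence: break at non-ACGT, then rle over the lag-u equality vector.
scan_one_sequence <- function(seq_id, seq, rules) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- chars %in% c("A", "C", "G", "T")
  if (any(!ok & chars != "N"))
    stop("format error: non-nucleotide character '",
         chars[which(!ok & chars != "N")[1L]], "' in sequence ", seq_id)
  seg <- rle(ok)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1L
  out <- list()
  for (s in which(seg$values)) {
    hits <- scan_segment(chars[seg_start[s]:seg_end[s]], rules)
    if (!is.null(hits)) {
      hits$start <- hits$start + seg_start[s] - 1L  # to 0-based whole-seq
      hits$end <- hits$end + seg_start[s] - 1L
      out[[length(out) + 1L]] <- hits
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res$seq_id <- seq_id
  res[c("seq_id", "start", "end", "motif", "motif_class", "unit_length",
        "repeat_count")]
}

scan_segment <- function(chars, rules) {
  L <- length(chars)
  out <- list()
  for (u in 1:6) {
    if (L < u * rules[[u]]) next
    eq <- chars[seq_len(L - u)] == chars[(u + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      tract_len <- r$lengths[k] + u            # periodic run length in bp
      count <- tract_len %/% u
      if (count < rules[[u]]) next
      i <- starts[k]                           # leftmost phase
      unit <- paste(chars[i:(i + u - 1L)], collapse = "")
      if (!is_primitive_unit(unit)) next       # belongs to a shorter unit
      out[[length(out) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + u * count, motif = unit,
        motif_class = canonical_motif(unit), unit_length = u,
        repeat_count = count, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

#' Construct an SSR catalog from a locus table
#'
#' @param loci data.frame with columns \code{seq_id, start, end, motif,
#'   motif_class, unit_length, repeat_count} (0-based half-open coordinates).
#' @param genome_length Total assembly length in bp.
#' @return An \code{ssr_catalog} object.
#' @export
ssr_catalog <- function(loci, genome_length) {
  stopifnot(is.data.frame(loci), genome_length >= 0)
  structure(list(
    loci = loci,
    genome_length = as.numeric(genome_length),
    counts_by_unit_length = table(factor(loci$unit_length, levels = 1:6)),
    counts_by_motif_class = if (nrow(loci)) sort(table(loci$motif_class),
                                                 decreasing = TRUE)
                            else table(character())
  ), class = "ssr_catalog")
}

#' @export
print.ssr_catalog <- function(x, ...) {
  cat("SSR catalog:", nrow(x$loci), "loci over",
      format(x$genome_length, big.mark = ","), "bp\n")
  cat("By unit length:\n")
  print(x$counts_by_unit_length)
  invisible(x)
}

#' Summarize motif-class composition of an SSR catalog
#'
#' Reports locus counts and percentage shares by unit length and by motif
#' class (the within-unit-length share is the one usually quoted, e.g.
#' "AG/CT accounts for 55 percent of dinucleotide repeats"), and the mean
#' interlocus distance, defined as total assembly length divided by locus
#' count.
#'
#' @param catalog An \code{ssr_catalog}.
#' @return List with \code{n_loci}, \code{by_unit_length} (unit_length, n,
#'   pct), \code{by_motif_class} (motif_class, unit_length, n, pct_total,
#'   pct_within_unit), and \code{mean_interlocus_distance_bp} (\code{NA} and
#'   \code{empty = TRUE} for an empty catalog).
#' @export
summarize_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "ssr_catalog"))
  n <- nrow(catalog$loci)
  if (n == 0L) {
    return(list(n_loci = 0L, empty = TRUE,
                by_unit_length = data.frame(unit_length = integer(),
                                            n = integer(), pct = numeric()),
                by_motif_class = data.frame(motif_class = character(),
                                            unit_length = integer(),
                                            n = integer(),
                                            pct_total = numeric(),
                                            pct_within_unit = numeric()),
                mean_interlocus_distance_bp = NA_real_))
  }
  ul <- as.data.frame(catalog$counts_by_unit_length,
                      stringsAsFactors = FALSE)
  names(ul) <- c("unit_length", "n")
  ul$unit_length <- as.integer(as.character(ul$unit_length))
  ul$pct <- 100 * ul$n / n

  mc <- stats::aggregate(list(n = catalog$loci$start),
                         by = list(motif_class = catalog$loci$motif_class,
                                   unit_length = catalog$loci$unit_length),
                         FUN = length)
  mc$pct_total <- 100 * mc$n / n
  unit_tot <- ul$n[match(mc$unit_length, ul$unit_length)]
  mc$pct_within_unit <- 100 * mc$n / unit_tot
  mc <- mc[order(mc$unit_length, -mc$n, mc$motif_class), ]
  rownames(mc) <- NULL

  list(n_loci = n, empty = FALSE, by_unit_length = ul, by_motif_class = mc,
       mean_interlocus_distance_bp = catalog$genome_length / n)
}

#' Export an SSR catalog
#'
#' \code{write_locus_table} writes a tab-delimited table with 1-based
#' inclusive coordinates (GFF-style for human consumption);
#' \code{write_catalog_gff3} writes a GFF3 track with feature type
#' \code{microsatellite}.
#'
#' @param catalog An \code{ssr_catalog}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_locus_table <- function(catalog, path) {
  stopifnot(inherits(catalog, "ssr_catalog"))
  tab <- catalog$loci
  tab$start_1based <- tab$start + 1L
  tab <- tab[c("seq_id", "start_1based", "end", "motif", "motif_class",
               "unit_length", "repeat_count")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_table
#' @export
write_catalog_gff3 <- function(catalog, path) {
  stopifnot(inherits(catalog, "ssr_catalog"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  l <- catalog$loci
  if (nrow(l)) {
    attrs <- sprintf("ID=ssr%05d;motif=%s;class=%s;repeats=%d",
                     seq_len(nrow(l)), l$motif, l$motif_class,
                     l$repeat_count)
    writeLines(paste(l$seq_id, "ssrcore", "microsatellite", l$start + 1L,
                     l$end, ".", "+", ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}
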