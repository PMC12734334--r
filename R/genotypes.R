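#' Marker manifest
#'
#' A table of SSR markers: name, primer pair and display order. Display order
#' fixes the column order of band matrices and the bit order of fingerprint
#' codes, mirroring the consistent primer order used when concatenating band
#' data into molecular IDs.
#'
#' @param name Character vector of unique marker names (e.g. \code{"SSR3"}).
#' @param forward_primer,reverse_primer Character vectors of primer
#'   sequences; may be \code{NA} when unknown.
#' @param display_order Integer permutation of \code{1..M}; defaults to input
#'   order.
#' @return data.frame of class \code{marker_manifest}.
#' @export
marker_manifest <- function(name, forward_primer = NA_character_,
                            reverse_primer = NA_character_,
                            display_order = seq_along(name)) {
  if (anyDuplicated(name))
    stop("marker names must be unique")
  if (!setequal(display_order, seq_along(name)))
    stop("display_order must be a permutation of 1..", length(name))
  structure(data.frame(name = as.character(name),
                       forward_primer = forward_primer,
                       reverse_primer = reverse_primer,
                       display_order = as.integer(display_order),
                       stringsAsFactors = FALSE),
            class = c("marker_manifest", "data.frame"))
}

#' @rdname marker_manifest
#' @param path Delimited text file with columns \code{name},
#'   \code{forward_primer}, \code{reverse_primer}, \code{display_order}.
#' @param sep Field separator.
#' @export
read_marker_manifest <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("name", "forward_primer", "reverse_primer", "display_order")
  missing_cols <- setdiff("name", names(tab))
  if (length(missing_cols))
    stop("marker manifest lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(need, names(tab)))
    tab[[col]] <- if (col == "display_order") seq_len(nrow(tab)) else NA
  marker_manifest(tab$name, tab$forward_primer, tab$reverse_primer,
                  tab$display_order)
}

#' @rdname marker_manifest
#' @param manifest A \code{marker_manifest}.
#' @export
write_marker_manifest <- function(manifest, path, sep = ",") {
  utils::write.table(manifest, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genotype matrix of allele sizes
#'
#' Accessions by markers, each cell an unordered set of 0--2 allele sizes in
#' bp. Dikaryotic strains carry up to two alleles per locus; a single size
#' means one band (homozygous-like), an empty set means missing data.
#'
#' @param accessions Character vector of accession ids.
#' @param markers A \code{\link{marker_manifest}}.
#' @param calls List-matrix (accessions x markers) of integer vectors; or a
#'   list of lists in the same layout.
#' @return Object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(accessions, markers, calls) {
  stopifnot(inherits(markers, "marker_manifest"))
  accessions <- as.character(accessions)
  if (anyDuplicated(accessions)) stop("accession ids must be unique")
  if (!is.matrix(calls))
    calls <- matrix(calls, nrow = length(accessions),
                    ncol = nrow(markers), byrow = TRUE)
  dimnames(calls) <- list(accessions, markers$name)
  for (i in seq_along(accessions)) {
    for (j in seq_len(nrow(markers))) {
      v <- sort(unique(as.integer(calls[[i, j]])))
      if (length(v) > 2L)
        stop("ploidy error: >2 alleles at (", accessions[i], ", ",
             markers$name[j], ")")
      if (length(v) && any(v <= 0L))
        stop("allele sizes must be positive at (", accessions[i], ", ",
             markers$name[j], ")")
      calls[[i, j]] <- v
    }
  }
  structure(list(accessions = accessions, markers = markers, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_missing <- sum(vapply(x$calls, length, 1L) == 0L)
  cat("Genotype matrix:", length(x$accessions), "accessions x",
      nrow(x$markers), "markers;", n_missing, "missing cells\n")
  invisible(x)
}

#' Read a genotype table
#'
#' Reads a delimited GeneMapper-style export with one accession-id column and
#' one or two allele-size columns per marker, named \code{<marker>_a} and
#' \code{<marker>_b} (or the bare marker name for single-column markers).
#' Empty cells are missing data.
#'
#' @param path Delimited text file.
#' @param manifest A \code{\link{marker_manifest}}; every size column must
#'   belong to a manifest marker.
#' @param sep Field separator.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, manifest, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (!"accession" %in% names(tab))
    stop("genotype table must have an 'accession' column")
  size_cols <- setdiff(names(tab), "accession")
  col_marker <- sub("_[ab]$", "", size_cols)
  unknown <- setdiff(unique(col_marker), manifest$name)
  if (length(unknown))
    stop("manifest error: unknown marker(s) in genotype table: ",
         paste(unknown, collapse = ", "))
  acc <- tab$accession
  calls <- matrix(vector("list", length(acc) * nrow(manifest)),
                  nrow = length(acc), ncol = nrow(manifest))
  for (j in seq_len(nrow(manifest))) {
    cols <- size_cols[col_marker == manifest$name[j]]
    if (length(cols) > 2L)
      stop("ploidy error: marker ", manifest$name[j], " has ",
           length(cols), " size columns")
    for (i in seq_along(acc)) {
      v <- unlist(tab[i, cols, drop = FALSE], use.names = FALSE)
      v <- v[!is.na(v) & nzchar(trimws(v))]
      calls[[i, j]] <- as.integer(v)
    }
  }
  genotype_matrix(acc, manifest, calls)
}

#' Write a genotype table
#'
#' Inverse of \code{\link{read_genotypes}}: two size columns per marker,
#' second column empty for single-band calls, both empty for missing data.
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_genotypes <- function(g, path, sep = ",") {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- data.frame(accession = g$accessions, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in seq_len(nrow(g$markers))) {
    a <- b <- character(length(g$accessions))
    for (i in seq_along(g$accessions)) {
      v <- g$calls[[i, j]]
      if (length(v) >= 1L) a[i] <- as.character(v[1L])
      if (length(v) == 2L) b[i] <- as.character(v[2L])
    }
    out[[paste0(g$markers$name[j], "_a")]] <- a
    out[[paste0(g$markers$name[j], "_b")]] <- b
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand a genotype matrix into a binary band matrix
#'
#' One column per observed (marker, allele size) pair: the band scoring used
#' for fingerprints, similarity and core selection, where presence of a band
#' is 1 and absence 0. Columns are ordered by marker display order, then
#' ascending allele size; a column exists iff at least one accession carries
#' that allele, so the column count equals the total observed allele number
#' (sum of per-marker Na).
#'
#' @param g A \code{\link{genotype_matrix}}.
#' @return Integer 0/1 matrix of class \code{band_matrix} with accession
#'   rownames, \code{"marker:size"} colnames, and attributes \code{marker}
#'   and \code{size} (per column) and \code{missing} (accessions x markers
#'   logical matrix flagging missing cells, whose columns read 0 but carry no
#'   information).
#' @export
to_band_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  ord <- order(g$markers$display_order)
  col_marker <- character(0)
  col_size <- integer(0)
  for (j in ord) {
    sizes <- sort(unique(unlist(g$calls[, j])))
    col_marker <- c(col_marker, rep(g$markers$name[j], length(sizes)))
    col_size <- c(col_size, sizes)
  }
  b <- matrix(0L, nrow = length(g$accessions), ncol = length(col_size),
              dimnames = list(g$accessions,
                              paste(col_marker, col_size, sep = ":")))
  miss <- matrix(FALSE, nrow = length(g$accessions), ncol = nrow(g$markers),
                 dimnames = list(g$accessions, g$markers$name))
  for (i in seq_along(g$accessions)) {
    for (j in seq_len(nrow(g$markers))) {
      v <- g$calls[[i, j]]
      if (length(v) == 0L) {
        miss[i, g$markers$name[j]] <- TRUE
      } else {
        b[i, col_marker == g$markers$name[j] & col_size %in% v] <- 1L
      }
    }
  }
  structure(b, marker = col_marker, size = col_size, missing = miss,
            class = c("band_matrix", class(b)))
}

#' Collapse a band matrix back to allele-call sets
#'
#' Inverse of \code{\link{to_band_matrix}} on non-missing data; used to check
#' that the binary expansion is lossless.
#'
#' @param b A \code{band_matrix}.
#' @return Named list (per accession) of named lists (per marker) of integer
#'   allele-size vectors; missing cells are \code{NULL}.
#' @export
band_matrix_calls <- function(b) {
  stopifnot(inherits(b, "band_matrix"))
  marker <- attr(b, "marker")
  size <- attr(b, "size")
  miss <- attr(b, "missing")
  lapply(stats::setNames(rownames(b), rownames(b)), function(acc) {
    out <- lapply(stats::setNames(unique(marker), unique(marker)),
                  function(m) {
      if (miss[acc, m]) NULL else sort(size[marker == m & b[acc, ] == 1L])
    })
    out
  })
}

#' Write a band matrix as delimited 0/1 text
#'
#' @param b A \code{band_matrix}.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_band_matrix <- function(b, path, sep = "\t") {
  out <- data.frame(accession = rownames(b), unclass(b)[, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
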