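#' Identity-code codebook
#'
#' Maps categorical metadata levels to short codes for the trait and
#' supplementary components of a molecular identity code. Each field carries
#' a role: \code{"trait"} fields feed the trait code, \code{"supplementary"}
#' fields the supplementary code; within both roles the codes are
#' concatenated in field order.
#'
#' @param fields Named list; each element a list with \code{levels} (named
#'   character vector, level -> code) and \code{role} ("trait" or
#'   "supplementary").
#' @return Object of class \code{id_codebook}.
#' @export
id_codebook <- function(fields) {
  for (fn in names(fields)) {
    f <- fields[[fn]]
    if (!f$role %in% c("trait", "supplementary"))
      stop("field '", fn, "': role must be 'trait' or 'supplementary'")
    if (anyDuplicated(f$levels))
      stop("field '", fn, "': codes must be unambiguous")
    if (any(grepl("-", f$levels, fixed = TRUE)))
      stop("field '", fn, "': codes must not contain the '-' separator")
  }
  structure(list(fields = fields), class = "id_codebook")
}

#' Default codebook: fruiting-body color, origin region, cultivation type
#'
#' A reproducible stand-in for collection-specific encoding rules: color
#' (trait), geographic origin and cultivation type (supplementary).
#'
#' @return An \code{\link{id_codebook}}.
#' @export
default_codebook <- function() {
  id_codebook(list(
    color = list(levels = c(brown = "B", white = "W"), role = "trait"),
    origin = list(levels = c(China = "CN", Japan = "JP", Malaysia = "MY",
                             SoutheastAsia = "SE"),
                  role = "supplementary"),
    cultivation = list(levels = c(industrial = "I", artificial = "A"),
                       role = "supplementary")
  ))
}

#' Read / write a codebook as delimited text
#'
#' Schema: columns \code{field}, \code{role}, \code{level}, \code{code};
#' one row per level, fields in first-occurrence order.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return An \code{\link{id_codebook}} (read) or \code{path} (write).
#' @export
read_codebook <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("field", "role", "level", "code") %in% names(tab)))
  fields <- list()
  for (fn in unique(tab$field)) {
    rows <- tab[tab$field == fn, ]
    fields[[fn]] <- list(levels = stats::setNames(rows$code, rows$level),
                         role = rows$role[1L])
  }
  id_codebook(fields)
}

#' @rdname read_codebook
#' @param codebook An \code{\link{id_codebook}}.
#' @export
write_codebook <- function(codebook, path, sep = ",") {
  rows <- do.call(rbind, lapply(names(codebook$fields), function(fn) {
    f <- codebook$fields[[fn]]
    data.frame(field = fn, role = f$role, level = names(f$levels),
               code = unname(f$levels), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fingerprint code of one accession
#'
#' The accession's band-matrix row as a "0"/"1" string, bits ordered by
#' marker display order then ascending allele size; its length equals the
#' total allele-class count and is identical for every accession of a
#' collection. An accession with fully missing data yields an all-zero
#' string flagged \code{low_confidence}.
#'
#' @param b A \code{\link{to_band_matrix}} result.
#' @param accession Accession id.
#' @return Character scalar with attribute \code{low_confidence} (logical).
#' @export
fingerprint_code <- function(b, accession) {
  stopifnot(inherits(b, "band_matrix"))
  if (!accession %in% rownames(b))
    stop("unknown accession: ", accession)
  fp <- paste(unclass(b)[accession, ], collapse = "")
  structure(fp, low_confidence = all(attr(b, "missing")[accession, ]))
}

#' Assemble a molecular identity code
#'
#' Payload layout: \code{fingerprint-traitcode-supplementarycode}, with
#' \code{"-"} separators; deterministic given fingerprint, metadata and
#' codebook.
#'
#' @param fingerprint "0"/"1" string from \code{\link{fingerprint_code}}.
#' @param metadata Named list or one-row data.frame with one level per
#'   codebook field.
#' @param codebook An \code{\link{id_codebook}}.
#' @param accession Optional accession id carried along.
#' @return Object of class \code{molecular_id}: list with \code{accession},
#'   \code{fingerprint}, \code{trait_code}, \code{supplementary_code},
#'   \code{payload}.
#' @export
build_molecular_id <- function(fingerprint, metadata, codebook,
                               accession = NA_character_) {
  stopifnot(inherits(codebook, "id_codebook"))
  if (is.data.frame(metadata)) metadata <- as.list(metadata[1L, ])
  codes <- c(trait = "", supplementary = "")
  for (fn in names(codebook$fields)) {
    f <- codebook$fields[[fn]]
    if (is.null(metadata[[fn]]))
      stop("encoding error: metadata lacks field '", fn, "'")
    lev <- as.character(metadata[[fn]])
    if (!lev %in% names(f$levels))
      stop("encoding error: level '", lev, "' not in codebook field '",
           fn, "'")
    codes[[f$role]] <- paste0(codes[[f$role]], f$levels[[lev]])
  }
  structure(list(accession = accession,
                 fingerprint = as.character(fingerprint),
                 trait_code = codes[["trait"]],
                 supplementary_code = codes[["supplementary"]],
                 payload = paste(fingerprint, codes[["trait"]],
                                 codes[["supplementary"]], sep = "-")),
            class = "molecular_id")
}

#' Parse a payload back into its three components
#'
#' @param payload \code{fingerprint-trait-supplementary} string.
#' @return List with \code{fingerprint}, \code{trait_code},
#'   \code{supplementary_code}.
#' @export
parse_molecular_id <- function(payload) {
  parts <- strsplit(payload, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("malformed payload: expected 3 '-'-separated components, got ",
         length(parts))
  list(fingerprint = parts[1L], trait_code = parts[2L],
       supplementary_code = parts[3L])
}

#' Detect accessions sharing an identical identity key
#'
#' Partitions accessions into maximal groups with an identical fingerprint
#' (or full payload); singletons are omitted and groups are ordered by the
#' first occurrence of a member. When keyed on the fingerprint, each group
#' is flagged \code{metadata_distinct} if its members' payloads differ, i.e.
#' strains indistinguishable by bands but separable through metadata.
#'
#' @param ids List of \code{\link{build_molecular_id}} results.
#' @param on \code{"fingerprint"} or \code{"payload"}.
#' @return List of duplicate groups; each a character vector of accession
#'   ids with attribute \code{metadata_distinct} (fingerprint keying only).
#' @export
detect_duplicates <- function(ids, on = c("fingerprint", "payload")) {
  on <- match.arg(on)
  stopifnot(length(ids) >= 2L)
  keys <- vapply(ids, function(x) x[[if (on == "fingerprint")
                                       "fingerprint" else "payload"]],
                 character(1))
  accs <- vapply(ids, function(x) x$accession, character(1))
  payloads <- vapply(ids, function(x) x$payload, character(1))
  groups <- list()
  for (key in unique(keys)) {
    members <- which(keys == key)
    if (length(members) < 2L) next
    grp <- accs[members]
    if (on == "fingerprint")
      attr(grp, "metadata_distinct") <-
        length(unique(payloads[members])) > 1L
    groups[[length(groups) + 1L]] <- grp
  }
  groups
}

#' 2D-barcode payload with self-validating checksum
#'
#' Returns the identity payload verbatim plus a 2-character mod-36 checksum
#' (characters mapped to 0--35 via their base-36 digit value, other
#' characters via their Unicode code point mod 36; the character-value sum
#' mod 36^2 is written as two base-36 digits). The raw payload is
#' recoverable by dropping the final two characters. Payloads beyond the
#' barcode byte capacity raise an error suggesting base-36 compaction of
#' the fingerprint.
#'
#' @param id A \code{\link{build_molecular_id}} result or a payload string.
#' @param capacity Maximum payload length in characters; default 2953, the
#'   byte capacity of the largest standard 2D barcode symbol at low error
#'   correction.
#' @return Character scalar: payload plus checksum.
#' @export
qr_payload <- function(id, capacity = 2953L) {
  payload <- if (inherits(id, "molecular_id")) id$payload else
    as.character(id)
  if (!nzchar(payload)) stop("empty payload")
  if (nchar(payload) + 2L > capacity)
    stop("payload of ", nchar(payload), " characters exceeds capacity ",
         capacity, "; consider base-36 compression of the fingerprint")
  paste0(payload, checksum36(payload))
}

checksum36 <- function(x) {
  alphabet <- c(0:9, LETTERS)
  vals <- vapply(strsplit(x, "")[[1L]], function(ch) {
    i <- match(toupper(ch), alphabet)
    if (is.na(i)) utf8ToInt(ch) %% 36L else i - 1L
  }, integer(1))
  total <- sum(vals) %% 1296L
  paste0(alphabet[total %/% 36L + 1L], alphabet[total %% 36L + 1L])
}

#' Build the identity-code table for a whole collection
#'
#' @param b A \code{\link{to_band_matrix}} result.
#' @param metadata data.frame with an \code{accession} column plus one
#'   column per codebook field.
#' @param codebook An \code{\link{id_codebook}}.
#' @return List of \code{molecular_id} objects (one per accession, in band
#'   matrix row order).
#' @export
molecular_id_table <- function(b, metadata, codebook = default_codebook()) {
  stopifnot(inherits(b, "band_matrix"), "accession" %in% names(metadata))
  lapply(rownames(b), function(acc) {
    row <- metadata[metadata$accession == acc, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("metadata must have exactly one row for accession ", acc)
    build_molecular_id(fingerprint_code(b, acc), row, codebook,
                       accession = acc)
  })
}

#' Write molecular identity codes as delimited text
#'
#' @param ids List of \code{molecular_id} objects.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_molecular_ids <- function(ids, path, sep = "\t") {
  tab <- do.call(rbind, lapply(ids, function(x) {
    data.frame(accession = x$accession, fingerprint = x$fingerprint,
               trait_code = x$trait_code,
               supplementary_code = x$supplementary_code,
               payload = x$payload, qr_payload = qr_payload(x),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
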