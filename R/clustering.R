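#' Simple-matching similarity between accessions
#'
#' For two binary band profiles, the fraction of comparable columns on which
#' they agree, counting both shared presences (1-1) and shared absences
#' (0-0). Columns belonging to a marker that is missing in either accession
#' of a pair are excluded pairwise (pairwise-complete handling), so one
#' failed amplification does not drop a whole accession.
#'
#' @param b A \code{\link{to_band_matrix}} result.
#' @return Object of class \code{similarity_matrix}: symmetric numeric
#'   matrix in [0,1] with unit diagonal and accession dimnames.
#' @export
simple_matching <- function(b) {
  stopifnot(inherits(b, "band_matrix"))
  n <- nrow(b)
  if (n < 2L) stop("need at least 2 accessions")
  miss <- attr(b, "missing")
  marker <- attr(b, "marker")
  x <- unclass(b)
  S <- matrix(1, n, n, dimnames = list(rownames(b), rownames(b)))
  if (!any(miss)) {
    m <- ncol(x)
    agree <- tcrossprod(x) + tcrossprod(1 - x)
    S <- agree / m
  } else {
    col_ok <- !miss[, marker, drop = FALSE]   # accession x column usability
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        use <- col_ok[i, ] & col_ok[j, ]
        if (!any(use))
          stop("undefined pair: no comparable columns between ",
               rownames(b)[i], " and ", rownames(b)[j])
        S[i, j] <- S[j, i] <- mean(x[i, use] == x[j, use])
      }
    }
  }
  diag(S) <- 1
  structure(S, class = c("similarity_matrix", class(S)))
}

#' @rdname simple_matching
#' @param s A \code{similarity_matrix}.
#' @return \code{similarity_to_dist} returns a \code{stats::dist} of
#'   \code{1 - S}.
#' @export
similarity_to_dist <- function(s) {
  stats::as.dist(1 - unclass(s))
}

#' UPGMA dendrogram
#'
#' Unweighted pair-group average-linkage clustering. At each step the
#' closest pair of clusters is merged at a node whose height is the current
#' (size-weighted average) distance between them, so on a similarity-derived
#' distance a node at height h joins clusters at similarity 1 - h, matching
#' dendrograms read on a similarity scale. Ties are resolved
#' deterministically: among equally close pairs, the pair whose (smaller
#' label, larger label) — labels compared as the lexicographically smallest
#' leaf label in each cluster — is lexicographically smallest merges first.
#'
#' @param d A \code{stats::dist}, a symmetric distance matrix, or a
#'   \code{similarity_matrix} (converted via \code{1 - S}).
#' @return Object of class \code{c("upgma_tree", "hclust")}: standard
#'   \code{hclust} fields (\code{merge}, \code{height}, \code{order},
#'   \code{labels}) with merge heights in distance units.
#' @export
upgma <- function(d) {
  if (inherits(d, "similarity_matrix")) d <- similarity_to_dist(d)
  if (inherits(d, "dist")) {
    labels <- attr(d, "Labels")
    D <- as.matrix(d)
  } else {
    D <- as.matrix(d)
    labels <- rownames(D)
  }
  n <- nrow(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2L) stop("need at least 2 leaves")
  if (any(!is.finite(D))) stop("non-finite distances in input")

  # active clusters: id < 0 -> leaf -id; id > 0 -> merge row id
  active <- as.list(-seq_len(n))
  sizes <- rep(1L, n)
  reps <- labels                       # smallest leaf label per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  idx <- seq_len(n)                    # row/col of each active cluster in D

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        dv <- D[a, b]
        lab <- sort(c(reps[a], reps[b]))
        if (is.null(best) || dv < best$d - 1e-12 ||
            (abs(dv - best$d) <= 1e-12 &&
             (lab[1L] < best$lab[1L] ||
              (lab[1L] == best$lab[1L] && lab[2L] < best$lab[2L])))) {
          best <- list(a = a, b = b, d = dv, lab = lab)
        }
      }
    }
    a <- best$a; b <- best$b
    merge[step, ] <- sort(c(active[[a]], active[[b]]))
    height[step] <- best$d
    new_size <- sizes[a] + sizes[b]
    keep <- setdiff(seq_len(k), c(a, b))
    new_d <- (sizes[a] * D[a, keep] + sizes[b] * D[b, keep]) / new_size
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d),
               c(new_d, 0))
    active <- c(active[keep], step)
    sizes <- c(sizes[keep], new_size)
    reps <- c(reps[keep], min(best$lab))
  }

  res <- structure(list(merge = merge, height = height,
                        order = hclust_order(merge), labels = labels,
                        method = "upgma",
                        call = match.call(),
                        dist.method = "1 - simple matching"),
                   class = c("upgma_tree", "hclust"))
  res
}

# leaf order for plotting, by recursive traversal of the merge matrix
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Cut a dendrogram at a similarity threshold
#'
#' Groups are the connected leaf sets joined by merges at height at most
#' \code{1 - threshold}; at threshold 1 only exact duplicates (height-0
#' merges) share a group, at threshold 0 all accessions form one group.
#' Groups are numbered by the input order of their first accession.
#'
#' @param tree An \code{\link{upgma}} tree.
#' @param threshold Similarity in [0, 1].
#' @return Named integer vector of group ids, in input accession order.
#' @export
cut_at_similarity <- function(tree, threshold) {
  stopifnot(inherits(tree, "hclust"), threshold >= 0, threshold <= 1)
  h <- 1 - threshold
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_leaf <- integer(nrow(tree$merge))  # a representative leaf per node
  leaf_of <- function(node) if (node < 0L) -node else node_leaf[node]
  for (step in seq_len(nrow(tree$merge))) {
    a <- leaf_of(tree$merge[step, 1L])
    b <- leaf_of(tree$merge[step, 2L])
    # union only when the merge sits at or under the cut height
    if (tree$height[step] <= h + 1e-9) parent[find(b)] <- find(a)
    node_leaf[step] <- a
  }
  roots <- vapply(seq_len(n), find, 1L)
  ids <- match(roots, unique(roots))
  stats::setNames(ids, tree$labels)
}

#' Cophenetic distances of a UPGMA tree
#'
#' The merge height at which each leaf pair first joins; equals
#' \code{stats::cophenetic} on the underlying \code{hclust} structure.
#'
#' @param tree An \code{\link{upgma}} tree.
#' @return A \code{stats::dist}.
#' @export
cophenetic_distances <- function(tree) {
  stats::cophenetic(structure(unclass(tree), class = "hclust"))
}

#' Convert a UPGMA tree to ape phylo / Newick
#'
#' Branch lengths are parent height minus child height in merge-distance
#' units, so leaf-to-root depth equals the root merge distance and the tree
#' is ultrametric on the 1 - similarity scale.
#'
#' @param tree An \code{\link{upgma}} tree.
#' @return \code{as_phylo} returns an \code{ape::phylo};
#'   \code{write_newick} writes a Newick file and returns the path.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  p <- ape::as.phylo(structure(unclass(tree), class = "hclust"))
  # as.phylo.hclust halves heights (cophenetic = 2 x depth); undo
  p$edge.length <- p$edge.length * 2
  p
}

#' @rdname as_phylo
#' @param path Output file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

#' Write a similarity matrix as delimited text
#'
#' @param s A \code{similarity_matrix}.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_similarity <- function(s, path, sep = "\t") {
  out <- data.frame(accession = rownames(s), unclass(s),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
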