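#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via \pkg{ape}), exact on additive
#' distance matrices; negative branch lengths are clamped to 0 afterwards.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and row/column
#'   labels, at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining requires at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix must carry labels")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  if (any(dm < 0)) stop("distances must be nonnegative")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Pairwise distances from a family alignment
#'
#' Pairwise-deletion distances: for each pair of rows only columns ungapped
#' in both are compared; `d = 1 - fraction identical`, optionally Poisson
#' corrected (`-ln(1 - p)`).
#'
#' @param msa An `MSA` from [align_family()].
#' @param correction `"none"` (default) or `"poisson"`.
#' @return Symmetric labeled distance matrix.
#' @export
msa_distances <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stop("no shared ungapped columns between ", msa$ids[i],
                       " and ", msa$ids[j])
    p <- 1 - mean(m[i, ok] == m[j, ok])
    if (correction == "poisson") {
      if (p >= 1) stop("Poisson correction undefined at p = 1")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' (unrooted) trees; both trees must have identical leaf label sets.
#'
#' @param t1,t2 `phylo` trees.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label))
    stop("trees must share the same leaf label set")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Read a Newick tree string or file
#' @param text A Newick string (or `file` argument to read from a path).
#' @param file Optional path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch({
    if (!is.null(file)) ape::read.tree(file)
    else ape::read.tree(text = text)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error")
  tr
}

#' Serialize a tree to Newick
#' @param tree A `phylo` tree.
#' @param file Optional path; when given, writes the file and returns the
#'   path invisibly.
#' @return The Newick string (or the path, invisibly).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(file)
}
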