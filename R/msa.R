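#' Progressive multiple alignment of a homolog family
#'
#' Deterministic guide-tree progressive alignment: pairwise global alignments
#' give identity distances (`d = 1 - identity/100`), a UPGMA guide tree is
#' built with lexicographic tie-breaking (so the result does not depend on
#' input order), and profiles are merged bottom-up by affine-gap
#' profile-profile alignment with sum-of-pairs BLOSUM62 scoring ("once a gap,
#' always a gap").
#'
#' @param sequences Named character vector of >= 2 protein sequences; names
#'   are the gene labels.
#' @param matrix,gap_open,gap_extend Scoring scheme (defaults BLOSUM62,
#'   10/0.5).
#' @return An `MSA`: list with `ids` and `aln`, a named character vector of
#'   equal-length aligned strings in the input order. No column is all-gap
#'   and removing gaps from any row recovers its input sequence.
#' @export
align_family <- function(sequences, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5) {
  if (length(sequences) < 2) stop("alignment requires at least 2 sequences")
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("sequences must carry unique non-empty names")
  sequences <- toupper(sequences)

  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- global_align(sequences[[i]], sequences[[j]], matrix,
                      gap_open, gap_extend)
    d[i, j] <- d[j, i] <- 1 - a$n_identical / a$alignment_length
  }

  merges <- upgma_merge_order(d)
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(sequences[[i]], "", fixed = TRUE)[[1]], nrow = 1)
    rownames(m) <- ids[i]
    m
  })
  for (mg in merges) {
    merged <- profile_align(profiles[[mg[1]]], profiles[[mg[2]]],
                            matrix, gap_open, gap_extend)
    profiles[[mg[1]]] <- merged
    profiles[[mg[2]]] <- NULL_profile
  }
  final <- profiles[[merges[[length(merges)]][1]]]
  aln <- apply(final, 1, paste, collapse = "")
  aln <- aln[ids] # restore input order
  structure(list(ids = ids, aln = aln), class = "MSA")
}

NULL_profile <- matrix(character(0), 0, 0)

# UPGMA merge schedule over a distance matrix; returns a list of index pairs
# (into the evolving profile list; the merged profile replaces the first
# index). Ties on distance are broken by the lexicographically smallest
# (cluster label) pair, labels being each cluster's smallest member id, so
# the schedule is invariant to input order.
upgma_merge_order <- function(d) {
  n <- nrow(d)
  ids <- rownames(d)
  active <- seq_len(n)
  size <- rep(1, n)
  label <- ids
  D <- d
  merges <- list()
  while (length(active) > 1) {
    best <- NULL
    for (ai in seq_along(active)) for (aj in seq_along(active)) {
      if (aj <= ai) next
      i <- active[ai]; j <- active[aj]
      li <- label[i]; lj <- label[j]
      key <- sort(c(li, lj))
      cand <- list(dist = D[i, j], key = key, i = i, j = j)
      if (is.null(best) || cand$dist < best$dist - 1e-12 ||
          (abs(cand$dist - best$dist) <= 1e-12 &&
           (cand$key[1] < best$key[1] ||
            (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    # order the pair so the profile with the smaller label is kept first
    if (label[j] < label[i]) { tmp <- i; i <- j; j <- tmp }
    merges[[length(merges) + 1L]] <- c(i, j)
    for (k in setdiff(active, c(i, j))) {
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    label[i] <- min(label[i], label[j])
    active <- setdiff(active, j)
  }
  merges
}

# Affine-gap Needleman-Wunsch over profile columns with mean sum-of-pairs
# scoring; existing gaps contribute 0. Deterministic traceback
# (diagonal > up > left). Returns the merged character matrix.
profile_align <- function(A, B, matrix, gap_open, gap_extend) {
  alpha <- rownames(matrix)
  counts <- function(P) {
    nc <- ncol(P)
    C <- base::matrix(0, nrow = length(alpha), ncol = nc)
    for (j in seq_len(nc)) {
      idx <- match(P[, j][P[, j] != "-"], alpha)
      idx[is.na(idx)] <- match("X", alpha)
      for (ix in idx) C[ix, j] <- C[ix, j] + 1
    }
    C
  }
  CA <- counts(A); CB <- counts(B)
  nA <- nrow(A); nB <- nrow(B)
  S <- t(CA) %*% matrix %*% CB / (nA * nB) # column-pair scores
  n <- ncol(A); m <- ncol(B)
  gi <- gap_open + gap_extend
  NEG <- -Inf
  M <- base::matrix(NEG, n + 1, m + 1)
  X <- base::matrix(NEG, n + 1, m + 1) # gap in B (consume A column; "up")
  Y <- base::matrix(NEG, n + 1, m + 1) # gap in A ("left")
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + gap_extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + gap_extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + S[i, j]
      X[i + 1, j + 1] <- max(M[i, j + 1] - gi, X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gi, Y[i + 1, j] - gap_extend)
    }
  }
  # traceback
  i <- n; j <- m
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- c("M", "X", "Y")[which.max(fin)]
  colsA <- integer(0); colsB <- integer(0) # 0 = gap column
  while (i > 0 || j > 0) {
    if (i == 0) { colsA <- c(0L, colsA); colsB <- c(j, colsB); j <- j - 1; next }
    if (j == 0) { colsA <- c(i, colsA); colsB <- c(0L, colsB); i <- i - 1; next }
    if (state == "M") {
      prev <- M[i + 1, j + 1] - S[i, j]
      colsA <- c(i, colsA); colsB <- c(j, colsB)
      i <- i - 1; j <- j - 1
      state <- if (isTRUE(all.equal(M[i + 1, j + 1], prev))) "M"
               else if (isTRUE(all.equal(X[i + 1, j + 1], prev))) "X" else "Y"
    } else if (state == "X") {
      cur <- X[i + 1, j + 1]
      colsA <- c(i, colsA); colsB <- c(0L, colsB)
      i <- i - 1
      state <- if (isTRUE(all.equal(M[i + 1, j + 1] - gi, cur))) "M" else "X"
    } else {
      cur <- Y[i + 1, j + 1]
      colsA <- c(0L, colsA); colsB <- c(j, colsB)
      j <- j - 1
      state <- if (isTRUE(all.equal(M[i + 1, j + 1] - gi, cur))) "M" else "Y"
    }
  }
  L <- length(colsA)
  out <- base::matrix("-", nA + nB, L)
  rownames(out) <- c(rownames(A), rownames(B))
  out[seq_len(nA), colsA != 0L] <- A[, colsA[colsA != 0L], drop = FALSE]
  out[nA + seq_len(nB), colsB != 0L] <- B[, colsB[colsB != 0L], drop = FALSE]
  out
}

#' @export
print.MSA <- function(x, ...) {
  cat(sprintf("MSA: %d sequences, %d columns\n", length(x$aln),
              nchar(x$aln[1])))
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa$aln), "", fixed = TRUE)) ->
    m
  rownames(m) <- msa$ids
  m
}

# per-row map: column index -> ungapped residue number (NA at gaps)
msa_col_to_res <- function(msa, row) {
  ch <- strsplit(msa$aln[[row]], "", fixed = TRUE)[[1]]
  out <- rep(NA_integer_, length(ch))
  out[ch != "-"] <- seq_len(sum(ch != "-"))
  out
}

#' Column conservation classes of a family alignment
#'
#' Classifies every alignment column by the strictest satisfied class:
#' `identical-in-all` (one residue in every row), `equivalent-in-all` (all
#' residues fall in one equivalence set, by default the structurally similar
#' trio I/L/V), `identical-in-group` / `equivalent-in-group` (the condition
#' holds within every taxon group separately but not across groups), else
#' `not-conserved`. A gap anywhere in a column vetoes conservation.
#'
#' @param msa An `MSA` from [align_family()].
#' @param groups Named character vector mapping row id -> taxon group; rows
#'   missing from it are `unassigned`.
#' @param equivalence List of character vectors, each an equivalence set
#'   (default `list(c("I","L","V"))`).
#' @param reference Row id whose ungapped residue numbers annotate the
#'   columns (default the first row).
#' @return Data frame with one row per column: `column`, `ref_residue`
#'   (NA where the reference row is gapped), `class`, and one
#'   `class_<group>` column per taxon group present.
#' @export
conserved_columns <- function(msa, groups = NULL,
                              equivalence = list(c("I", "L", "V")),
                              reference = NULL) {
  stopifnot(inherits(msa, "MSA"))
  if (is.null(reference)) reference <- msa$ids[1]
  if (!(reference %in% msa$ids)) stop("reference row not in the alignment")
  m <- msa_matrix(msa)
  if (is.null(groups)) groups <- stats::setNames(rep("unassigned",
                                                     length(msa$ids)),
                                                 msa$ids)
  grp <- groups[msa$ids]
  grp[is.na(grp)] <- "unassigned"
  ref_map <- msa_col_to_res(msa, reference)
  gset <- sort(unique(grp))

  one_set <- function(res) {
    if (length(unique(res)) == 1) return(TRUE)
    any(vapply(equivalence, function(s) all(res %in% s), TRUE))
  }
  cls <- character(ncol(m))
  percls <- base::matrix("not-conserved", ncol(m), length(gset),
                         dimnames = list(NULL, gset))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) { cls[j] <- "not-conserved"; next }
    ident_all <- length(unique(col)) == 1
    equiv_all <- one_set(col)
    ident_grp <- all(vapply(gset, function(g)
      length(unique(col[grp == g])) == 1, TRUE))
    equiv_grp <- all(vapply(gset, function(g) one_set(col[grp == g]), TRUE))
    cls[j] <- if (ident_all) "identical-in-all"
      else if (equiv_all) "equivalent-in-all"
      else if (ident_grp) "identical-in-group"
      else if (equiv_grp) "equivalent-in-group"
      else "not-conserved"
    for (g in gset) {
      cg <- col[grp == g]
      percls[j, g] <- if (length(cg) == 0) NA_character_
        else if (length(unique(cg)) == 1) "identical-in-group"
        else if (one_set(cg)) "equivalent-in-group"
        else "not-conserved"
    }
  }
  out <- data.frame(column = seq_len(ncol(m)), ref_residue = ref_map,
                    class = cls, stringsAsFactors = FALSE)
  for (g in gset) out[[paste0("class_", g)]] <- percls[, g]
  out
}

#' Map a residue number between two family members through the alignment
#'
#' @param msa An `MSA`.
#' @param from,to Row ids.
#' @param residue 1-based ungapped residue number in `from`.
#' @return The corresponding ungapped residue number in `to`, or
#'   `NA_integer_` when `to` has a gap in that column.
#' @export
map_residue <- function(msa, from, residue, to) {
  stopifnot(inherits(msa, "MSA"), from %in% msa$ids, to %in% msa$ids)
  fmap <- msa_col_to_res(msa, from)
  if (residue < 1 || residue > max(fmap, na.rm = TRUE))
    stop("residue ", residue, " out of range for ", from)
  col <- which(fmap == residue)
  tmap <- msa_col_to_res(msa, to)
  tmap[col]
}

#' Write an MSA as aligned FASTA
#' @param msa An `MSA`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  write_protein_fasta(msa$aln, path)
}
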