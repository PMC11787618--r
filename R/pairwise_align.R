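#' BLOSUM62 substitution matrix with neutral unknowns
#'
#' Returns the standard NCBI BLOSUM62 protein substitution matrix (as shipped
#' with Biostrings) with one modification: the unknown residue `X` (and the
#' stop symbol `*`) scores 0 against every residue, so masked or ambiguous
#' positions neither reward nor penalize an alignment.
#'
#' @return A numeric matrix with identical row and column names covering the
#'   20 amino acids plus `B`, `Z`, `X` and `*`.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  for (sym in c("X", "*")) {
    S[sym, ] <- 0
    S[, sym] <- 0
  }
  S
}

# Integer-encode a protein string against the matrix alphabet; any residue
# not in the alphabet is normalized to X.
encode_protein <- function(x, alphabet) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx
}

new_alignment_result <- function(query_id, subject_id, mode, score,
                                 aligned_query, aligned_subject,
                                 query_span, subject_span) {
  qa <- strsplit(aligned_query, "", fixed = TRUE)[[1]]
  sa <- strsplit(aligned_subject, "", fixed = TRUE)[[1]]
  stopifnot(length(qa) == length(sa))
  n_id <- sum(qa == sa & qa != "-" & qa != "X")
  len <- length(qa)
  structure(list(
    query_id = query_id, subject_id = subject_id, mode = mode,
    score = score,
    aligned_query = aligned_query, aligned_subject = aligned_subject,
    query_span = query_span, subject_span = subject_span,
    n_identical = n_id, alignment_length = len,
    percent_identity = if (len > 0) round(100 * n_id / len, 1) else NA_real_
  ), class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("%s alignment: %s vs %s\n", x$mode, x$query_id, x$subject_id))
  cat(sprintf("  score %.1f, length %d, identity %s%%\n",
              x$score, x$alignment_length,
              ifelse(is.na(x$percent_identity), "NA",
                     format(x$percent_identity))))
  if (x$alignment_length > 0) {
    cat("  ", x$aligned_query, "\n  ", x$aligned_subject, "\n", sep = "")
  }
  invisible(x)
}

align_impl <- function(a, b, matrix, gap_open, gap_extend, local,
                       end_gap_free, query_id, subject_id) {
  if (!nzchar(a) || !nzchar(b)) stop("alignment requires non-empty sequences")
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("require gap_open >= gap_extend >= 0")
  alpha <- rownames(matrix)
  ea <- encode_protein(a, alpha)
  eb <- encode_protein(b, alpha)
  r <- .gotoh_align_cpp(ea, eb, matrix, gap_open, gap_extend, local,
                        end_gap_free)
  tochar <- function(v) {
    ch <- rep("-", length(v))
    ch[v != 0L] <- alpha[v[v != 0L]]
    paste(ch, collapse = "")
  }
  new_alignment_result(
    query_id, subject_id, if (local) "local" else "global",
    score = r$score,
    aligned_query = tochar(r$ali_a), aligned_subject = tochar(r$ali_b),
    query_span = c(r$a_start, r$a_end), subject_span = c(r$b_start, r$b_end)
  )
}

#' Exact Smith-Waterman local alignment with affine gaps
#'
#' Optimal local protein alignment under an affine gap model: the first
#' residue of a gap costs `gap_open + gap_extend` and each further residue
#' `gap_extend`. Defaults mirror common BLASTP scoring (BLOSUM62, 11/1).
#' The traceback is deterministic (diagonal > up > left; the end cell is the
#' maximal-scoring cell with smallest `(end_i, end_j)`), and two sequences
#' with no positive-scoring residue pair yield the empty alignment with
#' score 0.
#'
#' @param a,b Protein strings (non-empty). Residues outside the matrix
#'   alphabet are treated as `X`, which scores 0 against everything.
#' @param matrix Substitution matrix; default [blosum62()].
#' @param gap_open,gap_extend Positive gap penalties, `gap_open >=
#'   gap_extend >= 0`.
#' @param query_id,subject_id Labels carried into the result.
#' @return An `AlignmentResult` with score, aligned strings, 1-based spans,
#'   identity counts and percent identity over the full alignment length.
#' @seealso [global_align()], [percent_identity()]
#' @export
local_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1, query_id = "query",
                        subject_id = "subject") {
  align_impl(a, b, matrix, gap_open, gap_extend, local = TRUE,
             end_gap_free = FALSE, query_id, subject_id)
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Optimal global alignment; by default terminal gaps are penalized exactly
#' like internal ones. Defaults follow the EMBOSS Needle web defaults
#' (BLOSUM62, gap open 10, gap extend 0.5). Percent identity follows the
#' Needle convention: identical columns divided by the full alignment length
#' including gap columns, reported to one decimal.
#'
#' @inheritParams local_align
#' @param end_gap_free If `TRUE`, terminal gaps are free (overlap-style
#'   global alignment).
#' @return An `AlignmentResult`.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5, query_id = "query",
                         subject_id = "subject", end_gap_free = FALSE) {
  align_impl(a, b, matrix, gap_open, gap_extend, local = FALSE,
             end_gap_free = end_gap_free, query_id, subject_id)
}

#' Percent identity of an alignment
#'
#' `100 * n_identical / alignment_length` where the length counts every
#' column including gap columns; `X` aligned to `X` is not counted as
#' identical. Errors on a zero-length (empty local) alignment, for which
#' identity is undefined.
#'
#' @param r An `AlignmentResult`.
#' @return Percentage rounded to one decimal.
#' @export
percent_identity <- function(r) {
  stopifnot(inherits(r, "AlignmentResult"))
  if (r$alignment_length == 0)
    stop("percent identity is undefined for a zero-length alignment")
  round(100 * r$n_identical / r$alignment_length, 1)
}

# Fast score-only local alignment of one query against many subjects.
local_scores <- function(query, subjects, matrix = blosum62(),
                         gap_open = 11, gap_extend = 1) {
  alpha <- rownames(matrix)
  eq <- encode_protein(query, alpha)
  es <- lapply(subjects, encode_protein, alphabet = alpha)
  .sw_score_multi_cpp(eq, es, matrix, gap_open, gap_extend)
}
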