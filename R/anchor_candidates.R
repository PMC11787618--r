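#' Locate an anchor gene in a genome
#'
#' Scores a reference anchor protein (e.g. egt or Bm9) against every protein
#' of a genome by local alignment and returns the best accepted hit, or an
#' absent hit when nothing passes the thresholds. Ties are broken by higher
#' score, then longer alignment, then lexicographically smaller `gene_id`.
#'
#' @param genome A [genome_record()].
#' @param anchor_ref Reference anchor protein sequence.
#' @param anchor_name Label (`"egt"` or `"Bm9"`).
#' @param min_score Minimum accepted local alignment score (default 80).
#' @param min_coverage Minimum fraction of the reference anchor covered by
#'   the alignment (default 0.5).
#' @param matrix,gap_open,gap_extend Scoring scheme (BLASTP-style defaults).
#' @return An `AnchorHit`: list with `genome_id`, `anchor_name`, `gene_id`
#'   (`NA` when absent), `score`, `identity`, `coverage`, `absent`.
#' @export
find_anchor <- function(genome, anchor_ref, anchor_name,
                        min_score = 80, min_coverage = 0.5,
                        matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(genome, "GenomeRecord"), nrow(genome$genes) >= 1)
  sc <- local_scores(anchor_ref, genome$genes$protein, matrix,
                     gap_open, gap_extend)
  hit <- pick_best_hit(anchor_ref, genome$genes, sc, min_score, min_coverage,
                       coverage_ref = "query", matrix, gap_open, gap_extend)
  absent <- is.null(hit)
  structure(list(genome_id = genome$genome_id, anchor_name = anchor_name,
                 gene_id = if (absent) NA_character_ else hit$gene_id,
                 score = if (absent) NA_real_ else hit$score,
                 identity = if (absent) NA_real_ else hit$identity,
                 coverage = if (absent) NA_real_ else hit$coverage,
                 absent = absent),
            class = "AnchorHit")
}

# Shared hit selection: walk candidate genes in (score desc) order, resolve
# ties by alignment length then gene_id, accept the first passing thresholds.
# coverage_ref: "query" = fraction of the query aligned; "shorter" = fraction
# of the shorter of the two sequences aligned.
pick_best_hit <- function(query, genes, scores, min_score, min_coverage,
                          coverage_ref, matrix, gap_open, gap_extend) {
  ok <- which(scores >= min_score)
  if (length(ok) == 0) return(NULL)
  for (s in sort(unique(scores[ok]), decreasing = TRUE)) {
    idx <- ok[scores[ok] == s]
    alns <- lapply(idx, function(i)
      local_align(query, genes$protein[i], matrix, gap_open, gap_extend,
                  subject_id = genes$gene_id[i]))
    len <- vapply(alns, function(a) a$alignment_length, 0L)
    ord <- order(-len, genes$gene_id[idx])
    for (k in ord) {
      i <- idx[k]
      a <- alns[[k]]
      denom <- switch(coverage_ref,
                      query = nchar(query),
                      shorter = min(nchar(query), nchar(genes$protein[i])))
      span <- if (coverage_ref == "query" ||
                  nchar(query) <= nchar(genes$protein[i]))
        a$query_span else a$subject_span
      cov <- (span[2] - span[1] + 1) / denom
      if (a$alignment_length == 0) cov <- 0
      if (cov >= min_coverage)
        return(list(gene_id = genes$gene_id[i], score = a$score,
                    identity = a$percent_identity, coverage = cov,
                    alignment = a))
    }
  }
  NULL
}

# ranks strictly between `from` and `to` walking forward (increasing rank
# mod n) from `from`; excludes both endpoints
arc_between <- function(from, to, n) {
  if (from == to) return(integer(0))
  r <- (from + 1L) %% n
  out <- integer(0)
  while (r != to) {
    out <- c(out, r)
    r <- (r + 1L) %% n
  }
  out
}

#' Extract candidate genes between the two anchors
#'
#' Implements the synteny step: the genes strictly between the egt and Bm9
#' anchors are the candidates for the seeded homology search. On circular
#' genomes the shorter of the two arcs between the anchors is used (the
#' longer arc would span most of the genome); on a tie the arc leaving egt in
#' the forward direction is taken. When the Bm9 anchor is absent, up to
#' `fallback_window` genes on each side of egt are taken instead and the
#' interval is flagged; genomes without an egt hit are skipped with a
#' warning and yield `NULL`.
#'
#' @param genome A [genome_record()].
#' @param egt_hit,bm9_hit `AnchorHit`s from [find_anchor()].
#' @param fallback_window Genes taken on each side of egt when Bm9 is absent
#'   (default 10).
#' @return A `CandidateInterval` (list with `genome_id`, `egt_hit`,
#'   `bm9_hit`, `candidates`, `candidate_ranks`, `bm9_absent_fallback`), or
#'   `NULL` when egt is absent.
#' @export
extract_candidates <- function(genome, egt_hit, bm9_hit,
                               fallback_window = 10) {
  stopifnot(inherits(genome, "GenomeRecord"))
  if (egt_hit$absent) {
    warning("genome ", genome$genome_id,
            " has no egt anchor; skipped from candidate generation",
            call. = FALSE)
    return(NULL)
  }
  n <- nrow(genome$genes)
  ranks <- genome$genes$rank
  r_egt <- genome$genes$rank[genome$genes$gene_id == egt_hit$gene_id]
  circular <- genome$topology == "circular"

  if (!bm9_hit$absent) {
    r_bm9 <- genome$genes$rank[genome$genes$gene_id == bm9_hit$gene_id]
    if (circular) {
      fwd <- arc_between(r_egt, r_bm9, n)   # egt -> bm9 forward
      bwd <- arc_between(r_bm9, r_egt, n)   # bm9 -> egt forward
      cand <- if (length(fwd) <= length(bwd)) fwd else bwd
    } else {
      lo <- min(r_egt, r_bm9); hi <- max(r_egt, r_bm9)
      cand <- if (hi - lo > 1) seq(lo + 1L, hi - 1L) else integer(0)
    }
    fallback <- FALSE
  } else {
    w <- fallback_window
    if (circular) {
      offs <- setdiff(seq(-w, w), 0L)
      cand <- unique((r_egt + offs) %% n)
      cand <- cand[cand != r_egt]
      # traversal order starting w genes before egt, wrapping forward
      start <- (r_egt - w) %% n
      ord <- (match(cand, (start + seq_len(2L * w + 1L) - 1L) %% n))
      cand <- cand[order(ord)]
    } else {
      cand <- setdiff(seq(max(0L, r_egt - w), min(n - 1L, r_egt + w)), r_egt)
    }
    fallback <- TRUE
  }
  cand_ids <- genome$genes$gene_id[match(cand, ranks)]
  structure(list(genome_id = genome$genome_id, egt_hit = egt_hit,
                 bm9_hit = bm9_hit, candidates = cand_ids,
                 candidate_ranks = as.integer(cand),
                 bm9_absent_fallback = fallback),
            class = "CandidateInterval")
}
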