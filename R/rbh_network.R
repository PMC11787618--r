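#' Best local-alignment hit of a gene in another genome
#'
#' The directed half of the reciprocal-best-hit criterion: the query protein
#' is scored against the full proteome of a *different* genome and the
#' highest-scoring hit passing the score and coverage thresholds is
#' returned. Coverage is measured on the shorter of the two sequences. Ties:
#' higher score, then longer alignment, then lexicographic `gene_id`.
#'
#' @param query List with `genome_id`, `gene_id` and `protein` (a gene
#'   feature), e.g. one row of `genome$genes` plus the genome id.
#' @param target A [genome_record()] from a different genome.
#' @param min_hit_score Minimum accepted score (default 50).
#' @param min_coverage Minimum aligned fraction of the shorter sequence
#'   (default 0.25).
#' @param matrix,gap_open,gap_extend Scoring scheme.
#' @return List with `genome_id`, `gene_id`, `score`, `identity`,
#'   `coverage`, or `NULL` when no hit is accepted.
#' @export
best_hit <- function(query, target, min_hit_score = 50, min_coverage = 0.25,
                     matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(target, "GenomeRecord"))
  if (identical(query$genome_id, target$genome_id))
    stop("best_hit target must be a different genome than the query's")
  sc <- local_scores(query$protein, target$genes$protein, matrix,
                     gap_open, gap_extend)
  hit <- pick_best_hit(query$protein, target$genes, sc, min_hit_score,
                       min_coverage, coverage_ref = "shorter",
                       matrix, gap_open, gap_extend)
  if (is.null(hit)) return(NULL)
  list(genome_id = target$genome_id, gene_id = hit$gene_id,
       score = hit$score, identity = hit$identity, coverage = hit$coverage)
}

node_key <- function(genome_id, gene_id) paste(genome_id, gene_id, sep = "\r")

#' Build the reciprocal-best-hit homology graph
#'
#' Every candidate gene is searched against the full proteome of every other
#' genome; an undirected edge joins gene `g` and its best hit `h` iff `g` is
#' in turn `h`'s best hit back in `g`'s genome (reciprocity), both directions
#' passing the thresholds. Nodes are all candidate genes plus every gene that
#' appears in a reciprocal pair. The result is independent of the order in
#' which genomes are supplied.
#'
#' @param candidate_intervals List of `CandidateInterval`s (NULLs allowed and
#'   ignored) from [extract_candidates()].
#' @param genomes List of [genome_record()]s (all searched genomes,
#'   including those that contributed no candidates).
#' @inheritParams best_hit
#' @return A `HomologyGraph`: list with `nodes` (data frame `genome_id`,
#'   `gene_id`) and `edges` (data frame `genome_a`, `gene_a`, `genome_b`,
#'   `gene_b`, `score_ab`, `score_ba`, `identity_ab`).
#' @export
build_graph <- function(candidate_intervals, genomes,
                        min_hit_score = 50, min_coverage = 0.25,
                        matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  genomes <- genomes[!vapply(genomes, is.null, TRUE)]
  if (length(genomes) < 2) stop("need at least 2 genomes")
  names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  candidate_intervals <- Filter(Negate(is.null), candidate_intervals)

  cache <- new.env(parent = emptyenv())
  bh <- function(qg, qid, tg) {
    key <- paste(qg, qid, tg, sep = "\r")
    if (!is.null(cache[[key]])) {
      h <- cache[[key]]
      return(if (identical(h, "none")) NULL else h)
    }
    q <- list(genome_id = qg, gene_id = qid,
              protein = genomes[[qg]]$genes$protein[
                genomes[[qg]]$genes$gene_id == qid])
    h <- best_hit(q, genomes[[tg]], min_hit_score, min_coverage,
                  matrix, gap_open, gap_extend)
    cache[[key]] <- if (is.null(h)) "none" else h
    h
  }

  nodes <- data.frame(genome_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  edges <- list()
  for (ci in candidate_intervals) {
    for (gid in ci$candidates) {
      nodes <- rbind(nodes, data.frame(genome_id = ci$genome_id,
                                       gene_id = gid,
                                       stringsAsFactors = FALSE))
      for (tg in setdiff(names(genomes), ci$genome_id)) {
        h <- bh(ci$genome_id, gid, tg)
        if (is.null(h)) next
        back <- bh(tg, h$gene_id, ci$genome_id)
        if (is.null(back) || !identical(back$gene_id, gid)) next
        a <- c(ci$genome_id, gid); b <- c(tg, h$gene_id)
        # canonical (unordered) orientation
        if (paste(b, collapse = "\r") < paste(a, collapse = "\r")) {
          edges[[length(edges) + 1L]] <- data.frame(
            genome_a = b[1], gene_a = b[2], genome_b = a[1], gene_b = a[2],
            score_ab = back$score, score_ba = h$score,
            identity_ab = back$identity, stringsAsFactors = FALSE)
        } else {
          edges[[length(edges) + 1L]] <- data.frame(
            genome_a = a[1], gene_a = a[2], genome_b = b[1], gene_b = b[2],
            score_ab = h$score, score_ba = back$score,
            identity_ab = h$identity, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges) > 0) unique(do.call(rbind, edges)) else
    data.frame(genome_a = character(0), gene_a = character(0),
               genome_b = character(0), gene_b = character(0),
               score_ab = numeric(0), score_ba = numeric(0),
               identity_ab = numeric(0), stringsAsFactors = FALSE)
  nodes <- unique(rbind(nodes,
                        data.frame(genome_id = edges$genome_a,
                                   gene_id = edges$gene_a,
                                   stringsAsFactors = FALSE),
                        data.frame(genome_id = edges$genome_b,
                                   gene_id = edges$gene_b,
                                   stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$genome_id, nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "HomologyGraph")
}

#' @export
print.HomologyGraph <- function(x, ...) {
  cat(sprintf("HomologyGraph: %d nodes, %d reciprocal-best-hit edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Extract the seed-connected homolog family
#'
#' The family is the connected component of the reciprocal-best-hit graph
#' containing the seed gene: connectivity, not cliques, so a homolog with no
#' direct edge to the seed still joins through intermediates (this is what
#' lets very distant relatives enter the family). When a genome contributes
#' more than one gene to the component, the gene scoring highest against the
#' seed protein becomes that genome's member and the rest are reported as
#' orphans.
#'
#' @param graph A `HomologyGraph` from [build_graph()].
#' @param seed Character vector `c(genome_id, gene_id)`; must be a node.
#' @param genomes Optional named list of [genome_record()]s, used to score
#'   same-genome extras against the seed.
#' @param matrix,gap_open,gap_extend Scoring scheme used for that tie-break.
#' @param exclude_genes Optional data frame (`genome_id`, `gene_id`) of
#'   genes barred from family membership; their nodes and edges are removed
#'   before the component is taken (the seed itself is never removed). The
#'   census pipeline passes the identified anchor genes here: the anchors
#'   define the search neighborhood and play distinct roles in the census,
#'   so they cannot double as family members - without this, a genome whose
#'   member was deleted and a genome whose anchor was deleted can pair
#'   their two widowed genes through a marginal reciprocal hit.
#' @return A `HomologFamily`: list with `seed`, `members` (named character
#'   vector, genome_id -> gene_id) and `orphans` (data frame).
#' @export
seed_component <- function(graph, seed, genomes = NULL,
                           matrix = blosum62(), gap_open = 11,
                           gap_extend = 1, exclude_genes = NULL) {
  stopifnot(inherits(graph, "HomologyGraph"), length(seed) == 2)
  skey <- node_key(seed[1], seed[2])
  if (!is.null(exclude_genes) && nrow(exclude_genes) > 0) {
    ex <- setdiff(node_key(exclude_genes$genome_id, exclude_genes$gene_id),
                  skey)
    nk <- node_key(graph$nodes$genome_id, graph$nodes$gene_id)
    graph$nodes <- graph$nodes[!(nk %in% ex), , drop = FALSE]
    if (nrow(graph$edges) > 0) {
      ea <- node_key(graph$edges$genome_a, graph$edges$gene_a)
      eb <- node_key(graph$edges$genome_b, graph$edges$gene_b)
      graph$edges <- graph$edges[!(ea %in% ex | eb %in% ex), , drop = FALSE]
    }
  }
  keys <- node_key(graph$nodes$genome_id, graph$nodes$gene_id)
  if (!(skey %in% keys)) stop("seed gene is not a node of the graph")

  if (nrow(graph$edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = node_key(graph$edges$genome_a, graph$edges$gene_a),
                 to = node_key(graph$edges$genome_b, graph$edges$gene_b),
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = keys, stringsAsFactors = FALSE))
    comp <- igraph::components(g)
    member_keys <- names(comp$membership)[comp$membership ==
                                            comp$membership[skey]]
  } else {
    member_keys <- skey
  }
  parts <- strsplit(member_keys, "\r", fixed = TRUE)
  df <- data.frame(genome_id = vapply(parts, `[`, "", 1),
                   gene_id = vapply(parts, `[`, "", 2),
                   stringsAsFactors = FALSE)
  df <- df[order(df$genome_id, df$gene_id), , drop = FALSE]

  members <- character(0)
  orphans <- df[0, ]
  seed_prot <- if (!is.null(genomes)) {
    gg <- genomes[[seed[1]]]
    gg$genes$protein[gg$genes$gene_id == seed[2]]
  } else NULL
  for (gm in unique(df$genome_id)) {
    rows <- df[df$genome_id == gm, , drop = FALSE]
    if (nrow(rows) == 1) {
      members[gm] <- rows$gene_id
    } else if (gm == seed[1] && seed[2] %in% rows$gene_id) {
      members[gm] <- seed[2]
      orphans <- rbind(orphans, rows[rows$gene_id != seed[2], ])
    } else if (!is.null(seed_prot) && !is.null(genomes[[gm]])) {
      prots <- genomes[[gm]]$genes$protein[match(rows$gene_id,
                                                 genomes[[gm]]$genes$gene_id)]
      sc <- local_scores(seed_prot, prots, matrix, gap_open, gap_extend)
      best <- order(-sc, rows$gene_id)[1]
      members[gm] <- rows$gene_id[best]
      orphans <- rbind(orphans, rows[-best, ])
    } else {
      members[gm] <- rows$gene_id[1]
      orphans <- rbind(orphans, rows[-1, ])
    }
  }
  rownames(orphans) <- NULL
  structure(list(seed = stats::setNames(as.character(seed),
                                        c("genome_id", "gene_id")),
                 members = members[order(names(members))],
                 orphans = orphans),
            class = "HomologFamily")
}

#' @export
print.HomologFamily <- function(x, ...) {
  cat(sprintf("HomologFamily seeded at %s/%s: %d members, %d orphans\n",
              x$seed[["genome_id"]], x$seed[["gene_id"]],
              length(x$members), nrow(x$orphans)))
  invisible(x)
}

#' Per-genome presence/absence census
#'
#' One row per input genome recording the egt and Bm9 anchor hits, the
#' family member (or `ABSENT`), and whether the member lies inside the
#' candidate interval — the tabular analog of a gene-distribution figure.
#'
#' @param family A `HomologFamily` from [seed_component()].
#' @param genomes List of [genome_record()]s.
#' @param intervals List of `CandidateInterval`s (or `NULL` for skipped
#'   genomes), matched by genome id.
#' @param anchors Optional named list (by genome id) of `list(egt =, bm9 =)`
#'   `AnchorHit`s, used to report anchor presence for genomes that produced
#'   no candidate interval.
#' @return Data frame with columns `genome_id`, `taxon_group`, `egt`,
#'   `family_member`, `bm9`, `family_in_interval`.
#' @export
census <- function(family, genomes, intervals, anchors = NULL) {
  intervals <- Filter(Negate(is.null), intervals)
  by_gm <- stats::setNames(intervals,
                           vapply(intervals, `[[`, "", "genome_id"))
  rows <- lapply(genomes, function(g) {
    ci <- by_gm[[g$genome_id]]
    eh <- if (!is.null(ci)) ci$egt_hit else anchors[[g$genome_id]]$egt
    bh <- if (!is.null(ci)) ci$bm9_hit else anchors[[g$genome_id]]$bm9
    egt <- if (!is.null(eh) && !eh$absent) eh$gene_id else "ABSENT"
    bm9 <- if (!is.null(bh) && !bh$absent) bh$gene_id else "ABSENT"
    mem <- if (g$genome_id %in% names(family$members))
      family$members[[g$genome_id]] else "ABSENT"
    inint <- if (mem == "ABSENT" || is.null(ci)) NA else mem %in% ci$candidates
    data.frame(genome_id = g$genome_id, taxon_group = g$taxon_group,
               egt = egt, family_member = mem, bm9 = bm9,
               family_in_interval = inint, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genome_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
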