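AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
HYDROPHOBIC6 <- c("I", "L", "V", "M", "F", "A")
# alphabet used for the planted family member outside its coil core: free of
# every hydrophobic-set residue so the planted coil and its constrained
# columns are unambiguously identifiable in the emitted genomes
NONHYD14 <- setdiff(AA20, HYDROPHOBIC6)

#' Configuration of the synthetic-genome generator
#'
#' Describes a set of small circular viral genomes emulating the study
#' design: every genome carries an egt-like anchor (~500 aa) and a Bm9-like
#' anchor (~100 aa); a divergent single-copy ortholog family (~230 aa,
#' carrying a planted coiled coil whose a/d core positions are constrained to
#' I/L/V) sits between the anchors; the remaining genes are shared decoy
#' families, orthologous across the genomes. By default the family member is
#' deleted in the last genome (the one-genome-without-a-homolog analog) and
#' the Bm9 anchor in the two genomes before it, matching the observed census
#' structure (most genomes have the member between both anchors; a few lack
#' Bm9; exactly one lacks the member).
#'
#' @param n_genomes Number of genomes (default 10).
#' @param genes_per_genome Genes per genome (default 40; real genomes carry
#'   roughly 30-150 single-exon CDS).
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @param tree `"star"` (default: each genome evolves independently from the
#'   ancestor along a branch of `branch_length`) or an \pkg{ape} `phylo`
#'   tree whose tip labels are the genome ids.
#' @param branch_length Branch length per genome under the star tree.
#' @param divergence Substitutions per site per unit branch length
#'   (default 0.2).
#' @param coil_length Planted coil length, a multiple of 7 (default 35).
#' @param coil_start First residue of the planted coil in the family
#'   ancestor (default 85).
#' @param member_length,egt_length,bm9_length Ancestor protein lengths.
#' @param decoy_count Shared decoy families (one gene per genome each);
#'   defaults to `genes_per_genome - 3` and must equal it. Decoys are
#'   orthologous across genomes, like the core genes that make up most of a
#'   real viral genome: every gene of every genome has true homologs
#'   elsewhere, so reciprocal-best-hit decisions are always competitive.
#' @param core_constraint If `TRUE` (default) substitutions at the coil's
#'   a/d positions stay within I/L/V.
#' @param delete_member_in,delete_bm9_in,delete_egt_in Genome ids receiving
#'   deletions; `NULL` (default) applies the census-structure defaults
#'   described above; use `character(0)` for no deletions.
#' @param indel_rate Per-site indel probability for stress tests only
#'   (default 0; indels invalidate the ancestral-coordinate ground truth).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genomes = 10, genes_per_genome = 40,
                              seed = 1, tree = "star", branch_length = 1,
                              divergence = 0.2, coil_length = 35,
                              coil_start = 85, member_length = 230,
                              egt_length = 500, bm9_length = 100,
                              decoy_count = NULL, core_constraint = TRUE,
                              delete_member_in = NULL,
                              delete_bm9_in = NULL,
                              delete_egt_in = character(0),
                              indel_rate = 0) {
  if (is.null(decoy_count)) decoy_count <- genes_per_genome - 3L
  if (genes_per_genome != 3 + decoy_count)
    stop("genes_per_genome must equal 3 + decoy_count ",
         "(anchors and member plus shared decoy families)")
  stopifnot(n_genomes >= 2, coil_length %% 7 == 0, coil_length >= 14,
            divergence >= 0, decoy_count >= 1,
            coil_start >= 1, coil_start + coil_length - 1 <= member_length,
            indel_rate >= 0, indel_rate < 1)
  genome_ids <- sprintf("SG%02d", seq_len(n_genomes))
  if (is.null(delete_member_in))
    delete_member_in <- genome_ids[n_genomes]
  if (is.null(delete_bm9_in))
    delete_bm9_in <- if (n_genomes >= 4)
      genome_ids[c(n_genomes - 2, n_genomes - 1)] else character(0)
  for (del in list(delete_member_in, delete_bm9_in, delete_egt_in))
    if (!all(del %in% genome_ids))
      stop("deletion refers to an unknown genome id")
  if (inherits(tree, "phylo") && !setequal(tree$tip.label, genome_ids))
    stop("tree tip labels must equal the genome ids")
  structure(list(
    n_genomes = n_genomes, genome_ids = genome_ids,
    genes_per_genome = genes_per_genome, seed = as.integer(seed),
    tree = tree, branch_length = branch_length, divergence = divergence,
    coil_length = coil_length, coil_start = coil_start,
    member_length = member_length, egt_length = egt_length,
    bm9_length = bm9_length, decoy_count = decoy_count,
    core_constraint = core_constraint,
    delete_member_in = delete_member_in, delete_bm9_in = delete_bm9_in,
    delete_egt_in = delete_egt_in, indel_rate = indel_rate),
    class = "SimulationConfig")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# substitute each site independently with probability p; the replacement is
# uniform over `pool[[class]]` minus the current residue
mutate_protein <- function(chars, p, site_pool) {
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    pool <- setdiff(site_pool[[i]], chars[i])
    if (length(pool) == 0) next
    chars[i] <- if (length(pool) == 1) pool else sample(pool, 1)
  }
  chars
}

apply_indels <- function(chars, rate, alphabet) {
  if (rate <= 0) return(chars)
  out <- character(0)
  for (ch in chars) {
    u <- stats::runif(1)
    if (u < rate / 2) next                       # deletion
    out <- c(out, ch)
    if (u >= rate / 2 && u < rate)               # insertion after the site
      out <- c(out, sample(alphabet, 1))
  }
  if (length(out) == 0) chars else out
}

#' Generate synthetic genomes with ground truth
#'
#' Builds an ancestral proteome from the seeded RNG, evolves it along the
#' configured tree by i.i.d. per-site substitution (substitution probability
#' = `divergence` x branch length; replacements uniform over the allowed
#' residues, with a/d coil positions restricted to I/L/V under
#' `core_constraint`), lays the genes on circular genomes with the family
#' member between the two anchors and a random rotation per genome, applies
#' the configured deletions, and returns the records together with a
#' machine-checkable `SyntheticTruth`.
#'
#' The family member's non-core positions are drawn from (and substitute
#' within) the 14 residues outside the default hydrophobic set, so the
#' planted coil interval and its constrained columns are exactly
#' identifiable in the output - the property the conservation-recovery tests
#' rely on. The first half of the genomes is labeled `group-I`, the second
#' half `group-II`.
#'
#' @param config A [simulation_config()].
#' @return List with `genomes` (named list of [genome_record()]s) and
#'   `truth` (a `SyntheticTruth` list).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    cl <- config$coil_length
    cs <- config$coil_start
    core_off <- sort(c(seq(0, cl - 1, by = 7), seq(3, cl - 1, by = 7)))
    core_pos <- cs + core_off

    # ancestral proteome
    member <- strsplit(random_protein(config$member_length, NONHYD14), "")[[1]]
    member[core_pos] <- sample(c("I", "L", "V"), length(core_pos),
                               replace = TRUE)
    egt <- strsplit(random_protein(config$egt_length), "")[[1]]
    bm9 <- strsplit(random_protein(config$bm9_length), "")[[1]]
    decoys <- lapply(seq_len(config$decoy_count), function(i)
      strsplit(random_protein(sample(80:400, 1)), "")[[1]])

    member_pool <- rep(list(NONHYD14), config$member_length)
    for (i in core_pos)
      member_pool[[i]] <- if (config$core_constraint) c("I", "L", "V") else AA20
    full_pool <- function(len) rep(list(AA20), len)

    # branch substitution probabilities per genome
    ids <- config$genome_ids
    n <- config$n_genomes
    evolve_to_tips <- function(anc_chars, pool) {
      if (identical(config$tree, "star")) {
        p <- config$divergence * config$branch_length
        out <- lapply(ids, function(g)
          apply_indels(mutate_protein(anc_chars, p, pool),
                       config$indel_rate, AA20))
        names(out) <- ids
        return(out)
      }
      tr <- ape::reorder.phylo(config$tree, "cladewise")
      nt <- length(tr$tip.label)
      seqs <- vector("list", nt + tr$Nnode)
      seqs[[nt + 1L]] <- anc_chars # root
      for (e in seq_len(nrow(tr$edge))) {
        from <- tr$edge[e, 1]; to <- tr$edge[e, 2]
        p <- config$divergence * tr$edge.length[e]
        seqs[[to]] <- apply_indels(mutate_protein(seqs[[from]], p, pool),
                                   config$indel_rate, AA20)
      }
      out <- seqs[seq_len(nt)]
      names(out) <- tr$tip.label
      out[ids]
    }

    member_tips <- evolve_to_tips(member, member_pool)
    egt_tips <- evolve_to_tips(egt, full_pool(config$egt_length))
    bm9_tips <- evolve_to_tips(bm9, full_pool(config$bm9_length))
    decoy_tips <- lapply(decoys, function(dc)
      evolve_to_tips(dc, full_pool(length(dc))))

    genomes <- list()
    truth_rows <- list()
    for (gi in seq_len(n)) {
      g <- ids[gi]
      group <- if (gi <= ceiling(n / 2)) "group-I" else "group-II"
      has_member <- !(g %in% config$delete_member_in)
      has_bm9 <- !(g %in% config$delete_bm9_in)
      has_egt <- !(g %in% config$delete_egt_in)

      pool_prots <- lapply(decoy_tips, `[[`, g)
      pool_roles <- sprintf("decoy%02d", seq_len(config$decoy_count))
      perm <- sample(length(pool_prots))
      pool_prots <- pool_prots[perm]
      pool_roles <- pool_roles[perm]

      n_between <- sample(0:2, 1) # decoys sharing the anchor interval
      order_prots <- list()
      order_roles <- character(0)
      if (has_egt) { order_prots <- c(order_prots, list(egt_tips[[g]]))
                     order_roles <- c(order_roles, "egt") }
      between <- if (n_between > 0) seq_len(n_between) else integer(0)
      mid_prots <- c(if (has_member) list(member_tips[[g]]) else list(),
                     pool_prots[between])
      mid_roles <- c(if (has_member) "member" else character(0),
                     pool_roles[between])
      if (length(mid_roles) > 1) {
        mp <- sample(length(mid_roles))
        mid_prots <- mid_prots[mp]; mid_roles <- mid_roles[mp]
      }
      order_prots <- c(order_prots, mid_prots)
      order_roles <- c(order_roles, mid_roles)
      if (has_bm9) { order_prots <- c(order_prots, list(bm9_tips[[g]]))
                     order_roles <- c(order_roles, "bm9") }
      rest <- setdiff(seq_along(pool_prots), between)
      order_prots <- c(order_prots, pool_prots[rest])
      order_roles <- c(order_roles, pool_roles[rest])

      # random rotation of the circular gene order
      rot <- sample(length(order_roles), 1)
      idx <- c(seq(rot, length(order_roles)),
               if (rot > 1) seq_len(rot - 1) else integer(0))
      order_prots <- order_prots[idx]
      order_roles <- order_roles[idx]

      # coordinates: sequential layout with random intergenic spacers
      starts <- integer(0); ends <- integer(0)
      pos <- 1L
      strands <- character(0)
      for (k in seq_along(order_prots)) {
        gap <- sample(20:120, 1)
        s <- pos + gap
        e <- s + 3L * (length(order_prots[[k]]) + 1L) - 1L
        starts <- c(starts, s); ends <- c(ends, e)
        strands <- c(strands, sample(c("+", "-"), 1))
        pos <- e
      }
      glen <- pos + sample(20:120, 1)
      gene_ids <- sprintf("%s_orf%03d", g, seq_along(order_roles))
      genes <- data.frame(
        gene_id = gene_ids,
        locus_tag = sprintf("%s_%03d", g, seq_along(order_roles)),
        product_name = paste0("hypothetical protein (", order_roles, ")"),
        start = starts, end = ends, strand = strands,
        protein = vapply(order_prots, paste, "", collapse = ""),
        stringsAsFactors = FALSE)
      genomes[[g]] <- genome_record(g, genes, glen, accession = "",
                                    taxon_group = group,
                                    topology = "circular")
      role_of <- stats::setNames(order_roles, gene_ids)
      truth_rows[[g]] <- data.frame(
        genome_id = g, taxon_group = group,
        egt_gene = if (has_egt) names(role_of)[role_of == "egt"] else NA,
        bm9_gene = if (has_bm9) names(role_of)[role_of == "bm9"] else NA,
        member_gene = if (has_member) names(role_of)[role_of == "member"]
                      else NA,
        stringsAsFactors = FALSE)
    }

    truth <- structure(list(
      table = do.call(rbind, truth_rows),
      coil_interval = c(cs, cs + cl - 1L),
      coil_register_offset = 0L,
      constrained_columns = core_pos,
      egt_ref = paste(egt, collapse = ""),
      bm9_ref = paste(bm9, collapse = ""),
      member_ref = paste(member, collapse = ""),
      tree = config$tree,
      config = config), class = "SyntheticTruth")
    rownames(truth$table) <- NULL
    list(genomes = genomes, truth = truth)
  })
}

#' Expected pairwise identity between two leaves of the generator
#'
#' Closed form under the generator's i.i.d. substitution model for the family
#' member: a site substituted with probability `p` on each of two independent
#' branches, replacements uniform over `k` alternatives, agrees with
#' probability `(1-p)^2 + p^2/k`. The member mixes core sites (`k = 2` under
#' the I/L/V constraint) and non-core sites (`k = 13`).
#'
#' @param config A [simulation_config()] with a star tree.
#' @return Expected fraction identity between two genomes' family members.
#' @export
expected_member_identity <- function(config) {
  stopifnot(identical(config$tree, "star"))
  p <- config$divergence * config$branch_length
  n_core <- length(seq(0, config$coil_length - 1, by = 7)) * 2
  n_rest <- config$member_length - n_core
  k_core <- if (config$core_constraint) 2 else 19
  id_core <- (1 - p)^2 + p^2 / k_core
  id_rest <- (1 - p)^2 + p^2 / 13
  (n_core * id_core + n_rest * id_rest) / config$member_length
}

#' Verify a synthetic fixture against its ground truth
#'
#' Re-checks every `SyntheticTruth` assertion directly on the emitted
#' genomes: recorded anchor/member genes exist exactly when not deleted, the
#' member lies on the forward arc from egt to Bm9 when both anchors survive,
#' and (under the core constraint) every constrained coil column carries only
#' I/L/V across all members.
#'
#' @param genomes Named list of [genome_record()]s.
#' @param truth The matching `SyntheticTruth`.
#' @return List with `pass` (logical) and `failures` (character vector).
#' @export
truth_check <- function(genomes, truth) {
  fails <- character(0)
  note <- function(...) fails <<- c(fails, sprintf(...))
  tb <- truth$table
  for (i in seq_len(nrow(tb))) {
    g <- tb$genome_id[i]
    rec <- genomes[[g]]
    if (is.null(rec)) { note("genome %s missing", g); next }
    ids <- rec$genes$gene_id
    if (anyDuplicated(ids) > 0) note("%s: duplicate gene ids", g)
    if (!identical(rec$genes$rank, seq_len(nrow(rec$genes)) - 1L))
      note("%s: ranks not consecutive", g)
    for (col in c("egt_gene", "bm9_gene", "member_gene")) {
      v <- tb[[col]][i]
      if (!is.na(v) && !(v %in% ids))
        note("%s: recorded %s '%s' not in genome", g, col, v)
    }
    if (!is.na(tb$member_gene[i]) && tb$member_gene[i] %in% ids) {
      prot <- rec$genes$protein[ids == tb$member_gene[i]]
      if (isTRUE(truth$config$core_constraint) &&
          truth$config$indel_rate == 0) {
        res <- strsplit(prot, "")[[1]][truth$constrained_columns]
        if (!all(res %in% c("I", "L", "V")))
          note("%s: constrained coil columns not within I/L/V", g)
      }
      if (!is.na(tb$egt_gene[i]) && !is.na(tb$bm9_gene[i])) {
        n <- nrow(rec$genes)
        r_e <- rec$genes$rank[ids == tb$egt_gene[i]]
        r_b <- rec$genes$rank[ids == tb$bm9_gene[i]]
        r_m <- rec$genes$rank[ids == tb$member_gene[i]]
        if (!(r_m %in% arc_between(r_e, r_b, n)))
          note("%s: member not on the egt->Bm9 arc", g)
      }
    }
  }
  missing <- setdiff(tb$genome_id, names(genomes))
  extra <- setdiff(names(genomes), tb$genome_id)
  if (length(extra) > 0) note("unexpected genomes: %s",
                              paste(extra, collapse = ","))
  list(pass = length(fails) == 0, failures = fails)
}
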