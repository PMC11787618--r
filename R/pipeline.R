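#' Pipeline configuration with documented defaults
#'
#' Bundles every tunable threshold of the census pipeline. Unknown keys are
#' rejected (calling this with a misspelled argument is an error), so a
#' key=value config file validated through this constructor cannot silently
#' ignore a setting.
#'
#' @param min_anchor_score,min_anchor_coverage Anchor acceptance: minimum
#'   local score (80) and minimum fraction of the reference anchor aligned
#'   (0.5).
#' @param min_hit_score,min_hit_coverage Homology-hit acceptance: minimum
#'   local score (50) and minimum aligned fraction of the shorter sequence
#'   (0.25).
#' @param fallback_window Genes on each side of egt searched when Bm9 is
#'   absent (10).
#' @param gap_open_local,gap_extend_local Local (BLASTP-style) gap penalties
#'   (11, 1).
#' @param gap_open_global,gap_extend_global Global (Needle-style) gap
#'   penalties (10, 0.5).
#' @param coil_window,coil_threshold Coiled-coil scanner window (21) and
#'   core-hydrophobicity threshold (0.7).
#' @param hydrophobic Hydrophobic residue set for the scanner.
#' @param equivalence Equivalence sets for column conservation (I/L/V).
#' @param distance_correction `"none"` or `"poisson"` for tree distances.
#' @param align_full_length Align full member proteins instead of their
#'   coiled-coil fragments (FALSE).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(min_anchor_score = 80, min_anchor_coverage = 0.5,
                            min_hit_score = 50, min_hit_coverage = 0.25,
                            fallback_window = 10,
                            gap_open_local = 11, gap_extend_local = 1,
                            gap_open_global = 10, gap_extend_global = 0.5,
                            coil_window = 21, coil_threshold = 0.7,
                            hydrophobic = c("I", "L", "V", "M", "F", "A"),
                            equivalence = list(c("I", "L", "V")),
                            distance_correction = "none",
                            align_full_length = FALSE) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full anchored-ortholog census pipeline
#'
#' End-to-end workflow: anchor search in every genome, candidate extraction
#' between the anchors, reciprocal-best-hit graph over full proteomes, the
#' seed gene's connected component as the homolog family, the per-genome
#' presence/absence census, coiled-coil scan of the members, progressive
#' alignment of the coil fragments, column conservation report, and a
#' neighbor-joining family tree (compared to a reference topology when one
#' is supplied). All artifacts are written to `out_dir` as TSV / FASTA /
#' Newick plus a run log recording every threshold and every skipped genome;
#' outputs are deterministic for fixed inputs and configuration.
#'
#' @param genomes List of [genome_record()]s, or paths to GenBank files.
#' @param egt_ref,bm9_ref Reference anchor protein sequences.
#' @param seed_gene Character vector `c(genome_id, gene_id)` of the seed.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param reference_tree Optional `phylo` tree or Newick path for the
#'   Robinson-Foulds comparison (leaf labels: genome ids).
#' @return Invisibly, a list with the in-memory artifacts (`anchors`,
#'   `intervals`, `graph`, `family`, `census`, `coils`, `msa`,
#'   `conservation`, `tree`, `rf`, `out_dir`).
#' @export
run_census_pipeline <- function(genomes, egt_ref, bm9_ref, seed_gene,
                                out_dir, config = pipeline_config(),
                                reference_tree = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.character(genomes)) genomes <- lapply(genomes, read_genbank)
  if (length(genomes) < 2) stop("the pipeline requires at least 2 genomes")
  names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  if (length(seed_gene) != 2 || !(seed_gene[1] %in% names(genomes)) ||
      !(seed_gene[2] %in% genomes[[seed_gene[1]]]$genes$gene_id))
    stop("seed gene not resolvable: need c(genome_id, gene_id) present in ",
         "the input genomes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("synortho census pipeline run log",
                 sprintf("genomes: %s", paste(names(genomes), collapse = ", ")),
                 sprintf("seed: %s/%s", seed_gene[1], seed_gene[2]),
                 "configuration:",
                 vapply(names(config)[!vapply(config, is.list, TRUE)],
                        function(k) sprintf("  %s = %s", k,
                                            paste(config[[k]], collapse = ",")),
                        ""),
                 sprintf("  equivalence = %s",
                         paste(vapply(config$equivalence, paste, "",
                                      collapse = ""), collapse = " | ")))

  # anchors and candidate intervals
  anchors <- list(); intervals <- list()
  for (g in names(genomes)) {
    egt_hit <- find_anchor(genomes[[g]], egt_ref, "egt",
                           config$min_anchor_score, config$min_anchor_coverage,
                           gap_open = config$gap_open_local,
                           gap_extend = config$gap_extend_local)
    bm9_hit <- find_anchor(genomes[[g]], bm9_ref, "Bm9",
                           config$min_anchor_score, config$min_anchor_coverage,
                           gap_open = config$gap_open_local,
                           gap_extend = config$gap_extend_local)
    anchors[[g]] <- list(egt = egt_hit, bm9 = bm9_hit)
    ci <- withCallingHandlers(
      extract_candidates(genomes[[g]], egt_hit, bm9_hit,
                         config$fallback_window),
      warning = function(w) {
        log_lines <<- c(log_lines, paste("skip:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    intervals[[g]] <- ci
  }

  # the seed must enter the graph even if it fell outside its interval
  ci <- intervals[[seed_gene[1]]]
  if (is.null(ci)) {
    intervals[[seed_gene[1]]] <- structure(
      list(genome_id = seed_gene[1],
           egt_hit = anchors[[seed_gene[1]]]$egt,
           bm9_hit = anchors[[seed_gene[1]]]$bm9,
           candidates = seed_gene[2], candidate_ranks = NA_integer_,
           bm9_absent_fallback = FALSE), class = "CandidateInterval")
    log_lines <- c(log_lines, "note: seed genome had no candidate interval; seeded directly")
  } else if (!(seed_gene[2] %in% ci$candidates)) {
    intervals[[seed_gene[1]]]$candidates <- c(ci$candidates, seed_gene[2])
    log_lines <- c(log_lines, "note: seed gene appended to its genome's candidates")
  }

  anchor_tab <- do.call(rbind, lapply(names(anchors), function(g) {
    do.call(rbind, lapply(anchors[[g]], function(h)
      data.frame(genome_id = g, anchor = h$anchor_name,
                 gene_id = ifelse(h$absent, "ABSENT", h$gene_id),
                 score = ifelse(h$absent, NA, h$score),
                 identity = ifelse(h$absent, NA, h$identity),
                 coverage = ifelse(h$absent, NA, round(h$coverage, 4)),
                 stringsAsFactors = FALSE)))
  }))
  write_tsv_file(anchor_tab, file.path(out_dir, "anchors.tsv"))
  cand_tab <- do.call(rbind, lapply(Filter(Negate(is.null), intervals),
    function(ci) data.frame(
      genome_id = ci$genome_id,
      egt = ifelse(ci$egt_hit$absent, "ABSENT", ci$egt_hit$gene_id),
      bm9 = ifelse(ci$bm9_hit$absent, "ABSENT", ci$bm9_hit$gene_id),
      candidates = paste(ci$candidates, collapse = ","),
      bm9_absent_fallback = ci$bm9_absent_fallback,
      stringsAsFactors = FALSE)))
  write_tsv_file(cand_tab, file.path(out_dir, "candidates.tsv"))

  graph <- build_graph(intervals, genomes,
                       min_hit_score = config$min_hit_score,
                       min_coverage = config$min_hit_coverage,
                       gap_open = config$gap_open_local,
                       gap_extend = config$gap_extend_local)
  write_tsv_file(graph$edges, file.path(out_dir, "edges.tsv"))
  # anchors play a distinct role in the census and are barred from family
  # membership (they are likewise excluded from candidate intervals)
  anchor_ex <- do.call(rbind, lapply(names(anchors), function(g) {
    hits <- Filter(function(h) !h$absent, anchors[[g]])
    if (length(hits) == 0) return(NULL)
    data.frame(genome_id = g,
               gene_id = vapply(hits, `[[`, "", "gene_id"),
               stringsAsFactors = FALSE)
  }))
  family <- seed_component(graph, seed_gene, genomes,
                           gap_open = config$gap_open_local,
                           gap_extend = config$gap_extend_local,
                           exclude_genes = anchor_ex)
  cen <- census(family, genomes, intervals, anchors)
  write_tsv_file(cen, file.path(out_dir, "census.tsv"))

  member_label <- function(g) paste0(g, ":", family$members[[g]])
  member_prots <- vapply(names(family$members), function(g) {
    rec <- genomes[[g]]
    rec$genes$protein[rec$genes$gene_id == family$members[[g]]]
  }, "")
  names(member_prots) <- vapply(names(family$members), member_label, "")
  write_protein_fasta(member_prots, file.path(out_dir, "family.fasta"))

  coils <- list(); frag <- character(0)
  for (lab in names(member_prots)) {
    ann <- scan_coiled_coil(member_prots[[lab]], config$coil_window,
                            config$coil_threshold, config$hydrophobic,
                            id = lab)
    coils[[lab]] <- ann
    if (config$align_full_length || length(ann) == 0) {
      if (length(ann) == 0)
        log_lines <- c(log_lines,
                       sprintf("note: no coiled coil detected in %s; full-length sequence aligned", lab))
      frag[lab] <- member_prots[[lab]]
    } else {
      best <- ann[[which.max(vapply(ann, `[[`, 0, "score"))]]
      frag[lab] <- substr(member_prots[[lab]], best$interval[1],
                          best$interval[2])
    }
  }
  write_tsv_file(coil_table(do.call(c, unname(coils))),
                 file.path(out_dir, "coils.tsv"))

  msa <- NULL; conservation <- NULL; tree <- NULL; rf <- NULL
  if (length(frag) >= 2) {
    msa <- align_family(frag, gap_open = config$gap_open_global,
                        gap_extend = config$gap_extend_global)
    write_msa_fasta(msa, file.path(out_dir, "family_aln.fasta"))
    groups <- stats::setNames(
      vapply(names(family$members), function(g) genomes[[g]]$taxon_group, ""),
      vapply(names(family$members), member_label, ""))
    ref_row <- member_label(seed_gene[1])
    conservation <- conserved_columns(msa, groups, config$equivalence,
                                      reference = ref_row)
    write_tsv_file(conservation, file.path(out_dir, "conservation.tsv"))
  }
  if (length(frag) >= 3) {
    dm <- msa_distances(msa, correction = config$distance_correction)
    # leaves named by genome for comparison against genome-level references
    rownames(dm) <- colnames(dm) <-
      vapply(strsplit(rownames(dm), ":", fixed = TRUE), `[`, "", 1)
    tree <- nj_tree(dm)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    if (!is.null(reference_tree)) {
      if (is.character(reference_tree))
        reference_tree <- read_newick(file = reference_tree)
      keep <- intersect(reference_tree$tip.label, tree$tip.label)
      rt <- ape::keep.tip(reference_tree, keep)
      ft <- ape::keep.tip(tree, keep)
      rf <- rf_distance(ft, rt)
      writeLines(sprintf("rf_distance\t%d", rf),
                 file.path(out_dir, "rf.txt"))
      log_lines <- c(log_lines,
                     sprintf("RF distance to reference topology: %d", rf))
    }
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(anchors = anchors, intervals = intervals, graph = graph,
                 family = family, census = cen, coils = coils, msa = msa,
                 conservation = conservation, tree = tree, rf = rf,
                 out_dir = out_dir))
}

#' Rotate a circular genome to a new origin
#'
#' Re-chooses the origin of a circular genome just upstream of the gene with
#' the given rank; gene order, lengths and strand are preserved while
#' coordinates and ranks rotate. Useful for checking that candidate
#' extraction and the homology network do not depend on where the sequence
#' record happens to start.
#'
#' @param record A circular [genome_record()].
#' @param new_first_rank Rank (0-based) of the gene that becomes the first
#'   gene of the rotated record.
#' @return A rotated [genome_record()].
#' @export
rotate_genome <- function(record, new_first_rank) {
  stopifnot(inherits(record, "GenomeRecord"),
            record$topology == "circular",
            new_first_rank %in% record$genes$rank)
  off <- record$genes$start[record$genes$rank == new_first_rank] - 1L
  g <- record$genes
  g$start <- ((g$start - 1L - off) %% record$length) + 1L
  g$end <- ((g$end - 1L - off) %% record$length) + 1L
  if (any(g$end < g$start))
    stop("rotation origin falls inside a gene; pick another gene boundary")
  genome_record(record$genome_id, g, record$length, record$accession,
                record$taxon_group, record$topology)
}

#' Load the accessioned reference proteins for the printed-identity checks
#'
#' The three proteins behind the published identity figures (Bm8 from BmNPV
#' T3, its close relative Ac16 from AcMNPV C6 and its distant relative Ld127
#' from LdMNPV A21) are distributed by NCBI and are not bundled with this
#' package. To run the accession-backed checks, fetch them and save a FASTA
#' file with ids `Bm8`, `Ac16` and `Ld127` at the given path (default
#' `reference/bv_odv_e26_reference.fasta` under the package's extdata).
#'
#' @param path Path to the user-supplied reference FASTA.
#' @return Named character vector with elements `Bm8`, `Ac16`, `Ld127`.
#' @export
load_reference_proteins <- function(path = system.file(
  "extdata", "reference", "bv_odv_e26_reference.fasta",
  package = "synortho")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("accessioned reference proteins (Bm8/Ac16/Ld127) are not bundled; ",
         "fetch them from GenBank and save them as ",
         "inst/extdata/reference/bv_odv_e26_reference.fasta ",
         "(ids: Bm8, Ac16, Ld127)")
  seqs <- read_protein_fasta(path)
  need <- c("Bm8", "Ac16", "Ld127")
  if (!all(need %in% names(seqs)))
    stop("reference FASTA must contain ids: ", paste(need, collapse = ", "))
  seqs[need]
}
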