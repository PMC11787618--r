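test_that("identical sequences align gap-free", {
  s <- rand_protein(40)
  msa <- align_family(c(x = s, y = s))
  expect_equal(unname(msa$aln), c(s, s))
})

test_that("a pairwise progressive alignment attains the enumerated optimum", {
  msa <- align_family(c(r1 = "ACDE", r2 = "ACE"))
  expect_equal(nchar(msa$aln[["r1"]]), 4)
  expect_equal(sum(strsplit(msa$aln[["r2"]], "")[[1]] == "-"), 1)
  expect_equal(score_alignment(msa$aln[["r1"]], msa$aln[["r2"]],
                               blosum62(), 10, 0.5),
               bf_global_score("ACDE", "ACE", blosum62(), 10, 0.5))
  expect_equal(gsub("-", "", msa$aln[["r1"]]), "ACDE")
  expect_equal(gsub("-", "", msa$aln[["r2"]]), "ACE")
})

test_that("rows always reconstruct their inputs and no column is all-gap", {
  set.seed(88)
  for (k in 1:5) {
    n <- sample(3:6, 1)
    seqs <- vapply(seq_len(n), function(i) rand_protein(sample(20:40, 1)), "")
    names(seqs) <- paste0("s", seq_len(n))
    msa <- align_family(seqs)
    expect_equal(length(unique(nchar(msa$aln))), 1)
    for (id in names(seqs))
      expect_equal(gsub("-", "", msa$aln[[id]]), unname(seqs[[id]]))
    m <- do.call(rbind, strsplit(unname(msa$aln), ""))
    expect_true(all(colSums(m != "-") > 0))
    expect_gte(ncol(m), max(nchar(seqs)))
    expect_lte(ncol(m), sum(nchar(seqs)))
  }
})

test_that("an indel-free generator family aligns gap-free onto ancestral columns", {
  sim <- simulate_genomes(simulation_config(n_genomes = 6,
                                            genes_per_genome = 16,
                                            seed = 14,
                                            divergence = 0.25,
                                            delete_member_in = character(0)))
  tb <- sim$truth$table
  seqs <- vapply(seq_len(nrow(tb)), function(i) {
    g <- sim$genomes[[tb$genome_id[i]]]
    g$genes$protein[g$genes$gene_id == tb$member_gene[i]]
  }, "")
  names(seqs) <- tb$genome_id
  msa <- align_family(seqs)
  expect_equal(nchar(msa$aln[[1]]), sim$truth$config$member_length)
  expect_false(any(grepl("-", msa$aln, fixed = TRUE)))
})

test_that("alignment output does not depend on sequence input order", {
  set.seed(99)
  seqs <- c(a = rand_protein(30), b = rand_protein(34),
            c = rand_protein(28), d = rand_protein(31))
  m1 <- align_family(seqs)
  m2 <- align_family(seqs[c(3, 1, 4, 2)])
  expect_equal(m1$aln[sort(names(seqs))], m2$aln[sort(names(seqs))])
})

test_that("column classes follow the strictest satisfied conservation level", {
  aln <- c(g1 = "IAIKQ", g2 = "IAVKQ", g3 = "IALRQ", g4 = "IALR-")
  msa <- structure(list(ids = names(aln), aln = aln), class = "MSA")
  groups <- c(g1 = "group-I", g2 = "group-I", g3 = "group-II",
              g4 = "group-II")
  rep <- conserved_columns(msa, groups, reference = "g1")
  # col1 all I -> identical; col2 all A -> identical
  expect_equal(rep$class[1], "identical-in-all")
  # col3 {I,V,L,L} -> within the I/L/V set
  expect_equal(rep$class[3], "equivalent-in-all")
  # col4 {K,K,R,R} -> identical within each group only
  expect_equal(rep$class[4], "identical-in-group")
  # col5 has a gap -> vetoed
  expect_equal(rep$class[5], "not-conserved")
  expect_equal(rep$ref_residue, 1:5)
  # the class hierarchy: identical-in-all implies set-equivalence holds too
  expect_equal(rep$`class_group-I`[3], "equivalent-in-group")
})

test_that("per-group equivalence without cross-group equivalence is detected", {
  aln <- c(g1 = "IK", g2 = "VK", g3 = "FR", g4 = "MR")
  msa <- structure(list(ids = names(aln), aln = aln), class = "MSA")
  groups <- c(g1 = "A", g2 = "A", g3 = "B", g4 = "B")
  rep <- conserved_columns(msa, groups,
                           equivalence = list(c("I", "L", "V"),
                                              c("F", "M")),
                           reference = "g1")
  expect_equal(rep$class[1], "equivalent-in-group")
  expect_equal(rep$class[2], "identical-in-group")
})

test_that("conserved columns recover exactly the planted constrained set", {
  sim <- simulate_genomes(simulation_config(n_genomes = 6,
                                            genes_per_genome = 16,
                                            seed = 23,
                                            divergence = 0.3,
                                            delete_member_in = character(0)))
  tr <- sim$truth
  tb <- tr$table
  ci <- tr$coil_interval
  seqs <- vapply(seq_len(nrow(tb)), function(i) {
    g <- sim$genomes[[tb$genome_id[i]]]
    substr(g$genes$protein[g$genes$gene_id == tb$member_gene[i]],
           ci[1], ci[2])
  }, "")
  names(seqs) <- tb$genome_id
  msa <- align_family(seqs)
  rep <- conserved_columns(msa, reference = "SG01")
  flagged <- rep$column[rep$class %in% c("identical-in-all",
                                         "equivalent-in-all")]
  m <- do.call(rbind, strsplit(unname(msa$aln), ""))
  ilv <- flagged[vapply(flagged, function(j)
    all(m[, j] %in% c("I", "L", "V")), TRUE)]
  expect_equal(ilv + ci[1] - 1L, tr$constrained_columns)
})

test_that("residue mapping is consistent, invertible, and gap-aware", {
  msa <- align_family(c(r1 = "ACDE", r2 = "ACE"))
  expect_equal(map_residue(msa, "r1", 1, "r2"), 1L)
  expect_true(is.na(map_residue(msa, "r1", 3, "r2"))) # D sits over the gap
  expect_equal(map_residue(msa, "r1", 4, "r2"), 3L)
  expect_error(map_residue(msa, "r2", 4, "r1"), "out of range")
  # identity on identical sequences
  s <- rand_protein(25)
  m2 <- align_family(c(x = s, y = s))
  for (r in c(1, 10, 25)) expect_equal(map_residue(m2, "x", r, "y"), r)
  # round trip wherever neither direction hits a gap
  set.seed(3)
  seqs <- c(p = rand_protein(30), q = rand_protein(33), r = rand_protein(27))
  m3 <- align_family(seqs)
  for (res in seq_len(30)) {
    fwd <- map_residue(m3, "p", res, "q")
    if (!is.na(fwd)) expect_equal(map_residue(m3, "q", fwd, "p"), res)
  }
})

test_that("alignment requires two named sequences and a known reference", {
  expect_error(align_family(c(solo = "ACDE")), "at least 2")
  expect_error(align_family(c("ACDE", "ACE")), "names")
  msa <- align_family(c(r1 = "ACDE", r2 = "ACE"))
  expect_error(conserved_columns(msa, reference = "nope"), "reference")
})
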