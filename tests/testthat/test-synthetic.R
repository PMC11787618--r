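test_that("the same seed produces byte-identical fixtures", {
  cfg <- simulation_config(n_genomes = 4, genes_per_genome = 16,
                           seed = 42)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth$table, s2$truth$table)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (g in s1$genomes) write_genbank(g, file.path(d1, paste0(g$genome_id, ".gb")))
  for (g in s2$genomes) write_genbank(g, file.path(d2, paste0(g$genome_id, ".gb")))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # a different seed changes the output
  s3 <- simulate_genomes(simulation_config(n_genomes = 4,
                                           genes_per_genome = 16,
                                           seed = 43))
  expect_false(identical(s1$genomes, s3$genomes))
})

test_that("zero divergence reproduces the ancestral proteins in every genome", {
  cfg <- simulation_config(n_genomes = 3, genes_per_genome = 14,
                           seed = 8, divergence = 0,
                           delete_member_in = character(0),
                           delete_bm9_in = character(0))
  sim <- simulate_genomes(cfg)
  tb <- sim$truth$table
  for (i in seq_len(nrow(tb))) {
    g <- sim$genomes[[tb$genome_id[i]]]
    prot <- function(id) g$genes$protein[g$genes$gene_id == id]
    expect_equal(prot(tb$member_gene[i]), sim$truth$member_ref)
    expect_equal(prot(tb$egt_gene[i]), sim$truth$egt_ref)
    expect_equal(prot(tb$bm9_gene[i]), sim$truth$bm9_ref)
  }
})

test_that("mean family identity matches the closed-form expectation", {
  cfg0 <- simulation_config(n_genomes = 4, genes_per_genome = 14,
                            seed = 1, divergence = 0.3,
                            delete_member_in = character(0),
                            delete_bm9_in = character(0))
  expected <- expected_member_identity(cfg0)
  obs <- c()
  for (seed in 1:20) {
    cfg <- simulation_config(n_genomes = 4, genes_per_genome = 14,
                             seed = seed, divergence = 0.3,
                             delete_member_in = character(0),
                             delete_bm9_in = character(0))
    sim <- simulate_genomes(cfg)
    tb <- sim$truth$table
    prots <- vapply(seq_len(nrow(tb)), function(i) {
      g <- sim$genomes[[tb$genome_id[i]]]
      g$genes$protein[g$genes$gene_id == tb$member_gene[i]]
    }, "")
    chars <- strsplit(prots, "")
    for (i in 1:3) for (j in (i + 1):4)
      obs <- c(obs, mean(chars[[i]] == chars[[j]]))
  }
  expect_equal(mean(obs), expected, tolerance = 0.02 / expected)
})

test_that("deletions are applied exactly where configured", {
  cfg <- simulation_config(n_genomes = 6, genes_per_genome = 14,
                           seed = 4,
                           delete_member_in = "SG03",
                           delete_bm9_in = c("SG01", "SG05"),
                           delete_egt_in = "SG02")
  sim <- simulate_genomes(cfg)
  tb <- sim$truth$table
  expect_equal(tb$genome_id[is.na(tb$member_gene)], "SG03")
  expect_equal(tb$genome_id[is.na(tb$bm9_gene)], c("SG01", "SG05"))
  expect_equal(tb$genome_id[is.na(tb$egt_gene)], "SG02")
  counts <- vapply(sim$genomes, function(g) nrow(g$genes), 0)
  expect_equal(unname(counts[c("SG03", "SG01", "SG02")]), rep(13, 3))
  expect_equal(unname(counts["SG04"]), 14)
  expect_true(truth_check(sim$genomes, sim$truth)$pass)
})

test_that("truth_check verifies fixtures and detects corruption", {
  sim <- simulate_genomes(simulation_config(n_genomes = 4,
                                            genes_per_genome = 14,
                                            seed = 10))
  expect_true(truth_check(sim$genomes, sim$truth)$pass)
  # corrupt a recorded gene id
  bad <- sim$truth
  bad$table$member_gene[1] <- "SG01_orf999"
  r <- truth_check(sim$genomes, bad)
  expect_false(r$pass)
  expect_match(r$failures, "member_gene", all = FALSE)
  # drop a whole genome
  r2 <- truth_check(sim$genomes[-2], sim$truth)
  expect_false(r2$pass)
  # violate the core constraint in a member protein
  mut <- sim$genomes
  g1 <- mut[["SG01"]]
  mid <- sim$truth$table$member_gene[1]
  p <- g1$genes$protein[g1$genes$gene_id == mid]
  substr(p, sim$truth$constrained_columns[1],
         sim$truth$constrained_columns[1]) <- "Q"
  g1$genes$protein[g1$genes$gene_id == mid] <- p
  mut[["SG01"]] <- g1
  expect_false(truth_check(mut, sim$truth)$pass)
})

test_that("contradictory or invalid configurations are rejected", {
  expect_error(simulation_config(n_genomes = 4, delete_member_in = "SG09"),
               "unknown genome")
  expect_error(simulation_config(coil_length = 20), "coil_length")
  expect_error(simulation_config(genes_per_genome = 10, decoy_count = 15))
  bad_tree <- read_newick("((A,B),(C,D));")
  expect_error(simulation_config(n_genomes = 4, tree = bad_tree),
               "tip labels")
})

test_that("constrained coil columns stay within I/L/V across all genomes", {
  sim <- simulate_genomes(simulation_config(n_genomes = 6,
                                            genes_per_genome = 14,
                                            seed = 19,
                                            divergence = 0.3,
                                            delete_member_in = character(0)))
  tb <- sim$truth$table
  for (i in seq_len(nrow(tb))) {
    g <- sim$genomes[[tb$genome_id[i]]]
    p <- strsplit(g$genes$protein[g$genes$gene_id == tb$member_gene[i]],
                  "")[[1]]
    expect_true(all(p[sim$truth$constrained_columns] %in% c("I", "L", "V")))
  }
})
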