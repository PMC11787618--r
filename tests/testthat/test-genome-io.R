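test_that("GenBank round-trip preserves generator output", {
  sim <- simulate_genomes(simulation_config(n_genomes = 2,
                                            genes_per_genome = 8,
                                            seed = 3,
                                            delete_member_in = character(0),
                                            delete_bm9_in = character(0)))
  for (g in sim$genomes) {
    path <- withr::local_tempfile(fileext = ".gb")
    write_genbank(g, path)
    back <- read_genbank(path)
    expect_equal(back$genome_id, g$genome_id)
    expect_equal(back$topology, g$topology)
    expect_equal(back$taxon_group, g$taxon_group)
    expect_equal(back$length, g$length)
    expect_equal(back$genes, g$genes)
  }
})

test_that("multi-interval (join) CDS are skipped with a warning", {
  gb <- c(
    "LOCUS       TOY              5000 bp    DNA     circular VRL 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "     CDS             100..129",
    "                     /gene=\"gA\"",
    "                     /translation=\"MKLVNNEAA\"",
    "     CDS             join(200..229,300..329)",
    "                     /gene=\"gJ\"",
    "                     /translation=\"MKLVNNEAAMKLVNNEAA\"",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  expect_warning(rec <- read_genbank(path), "multi-interval")
  expect_equal(rec$genes$gene_id, "gA")
  expect_equal(rec$genes$rank, 0L)
})

test_that("CDS without a translation qualifier are translated from ORIGIN", {
  prot <- "MKLV"
  dna_f <- "ATGAAACTGGTTTAA" # MKLV*
  dna_r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna_f)))
  genome_seq <- paste0(strrep("A", 10), dna_f, strrep("C", 10), dna_r,
                       strrep("G", 10))
  rows <- function(x, w) paste(substring(x, seq(1, nchar(x), w),
                                         pmin(seq(1, nchar(x), w) + w - 1,
                                              nchar(x))), collapse = " ")
  gb <- c(
    sprintf("LOCUS       TOY2             %d bp    DNA     linear VRL 01-JAN-2024",
            nchar(genome_seq)),
    "FEATURES             Location/Qualifiers",
    "     CDS             11..25",
    "                     /gene=\"fwd\"",
    "     CDS             complement(36..50)",
    "                     /gene=\"rev\"",
    "ORIGIN",
    paste("        1", rows(tolower(genome_seq), 10)),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- read_genbank(path)
  expect_equal(rec$topology, "linear")
  expect_equal(rec$genes$protein, c(prot, prot))
  expect_equal(rec$genes$strand, c("+", "-"))
})

test_that("gene ranks are consecutive and ordered by start regardless of input order", {
  genes <- data.frame(
    gene_id = c("g3", "g1", "g2"), locus_tag = "", product_name = "",
    start = c(500, 100, 300), end = c(590, 190, 390),
    strand = "+", protein = c("MCC", "MAA", "MBB"),
    stringsAsFactors = FALSE)
  rec <- genome_record("TOY", genes, 1000)
  expect_equal(rec$genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(rec$genes$rank, 0:2)
  expect_true(all(diff(rec$genes$start) > 0))
})

test_that("genome records reject malformed gene tables", {
  base <- data.frame(gene_id = "g1", locus_tag = "", product_name = "",
                     start = 10, end = 40, strand = "+", protein = "MAA",
                     stringsAsFactors = FALSE)
  expect_error(genome_record("T", rbind(base, base), 100), "unique")
  bad <- base; bad$protein <- ""
  expect_error(genome_record("T", bad, 100), "non-empty")
  bad <- base; bad$end <- 5
  expect_error(genome_record("T", bad, 100), "coordinates")
  expect_error(genome_record("T", base[0, ], 100), "empty genome")
})

test_that("protein FASTA round-trips and rejects malformed input", {
  recs <- c(p1 = "MKLVNN", p2 = "MAACDEFGHIKLMNPQRSTVWY")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(recs, path)
  back <- read_protein_fasta(path)
  expect_identical(back, recs)
  # ids are the first whitespace token, in file order
  writeLines(c(">idA some description", "MKL", ">idB", "MAA"), path)
  expect_equal(names(read_protein_fasta(path)), c("idA", "idB"))
  writeLines(c(">dup", "MKL", ">dup", "MAA"), path)
  expect_error(read_protein_fasta(path), "duplicate")
  writeLines(c(">a", "MKL", ">empty", "", ">b", "MAA"), path)
  expect_error(read_protein_fasta(path), "empty")
  # long sequences wrap at 60 columns
  long <- c(x = strrep("MKLV", 40))
  write_protein_fasta(long, path)
  expect_true(all(nchar(readLines(path)[-1]) <= 60))
  expect_identical(read_protein_fasta(path), long)
})

test_that("TSV writer round-trips a census-like table", {
  df <- data.frame(genome_id = c("A", "B"), egt = c("g1", "ABSENT"),
                   family_in_interval = c(TRUE, NA),
                   score = c(12.5, 80), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_file(df, path)
  expect_equal(read_tsv_file(path), df)
})

test_that("unreadable or CDS-free files raise input errors", {
  expect_error(read_genbank(file.path(tempdir(), "does-not-exist.gb")),
               "cannot read")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X  100 bp DNA circular", "FEATURES", "//"), path)
  expect_error(read_genbank(path), "no usable CDS")
})
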