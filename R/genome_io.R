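#' Construct an annotated genome record
#'
#' The central container of the package: an ordered set of protein-coding
#' gene features on one (usually circular) viral genome. Genes are sorted by
#' start coordinate and given consecutive 0-based ranks; coordinates are
#' 1-based inclusive, GenBank style.
#'
#' @param genome_id Short genome label (e.g. an abbreviation like `BmNPV`).
#' @param genes A data frame with columns `gene_id`, `locus_tag`,
#'   `product_name`, `start`, `end`, `strand` (`+`/`-`) and `protein`
#'   (stop-trimmed amino-acid string).
#' @param length Genome length in bp.
#' @param accession GenBank accession.version, or `""`.
#' @param taxon_group One of `group-I`, `group-II`, `unassigned`.
#' @param topology `circular` (default) or `linear`.
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(genome_id, genes, length,
                          accession = "", taxon_group = "unassigned",
                          topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  taxon_group <- match.arg(taxon_group, c("unassigned", "group-I", "group-II"))
  need <- c("gene_id", "locus_tag", "product_name", "start", "end",
            "strand", "protein")
  if (!all(need %in% names(genes)))
    stop("genes must have columns: ", paste(need, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)[, need]
  if (nrow(genes) == 0) stop("empty genome: no gene features")
  if (anyDuplicated(genes$gene_id))
    stop("gene_id values must be unique within a genome")
  if (any(!nzchar(genes$protein)))
    stop("every gene must carry a non-empty protein")
  if (any(grepl("*", genes$protein, fixed = TRUE)))
    stop("proteins must be stop-trimmed (no internal '*')")
  if (any(genes$start < 1 | genes$end < genes$start | genes$end > length))
    stop("gene coordinates must satisfy 1 <= start <= end <= genome length")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  genes <- genes[order(genes$start, genes$end, genes$gene_id), , drop = FALSE]
  genes$rank <- seq_len(nrow(genes)) - 1L
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, accession = accession,
                 taxon_group = taxon_group, topology = topology,
                 length = as.integer(length), genes = genes),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s (%s, %s, %d bp): %d genes\n",
              x$genome_id,
              if (nzchar(x$accession)) x$accession else "no accession",
              x$topology, x$length, nrow(x$genes)))
  invisible(x)
}

normalize_protein <- function(p) {
  p <- toupper(gsub("[[:space:]]", "", p))
  gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", p)
}

# --- GenBank flat file -----------------------------------------------------

parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[[:space:]]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|complement", loc)) return(NULL) # multi-interval
  m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
  if (length(m) == 0) {
    m1 <- regmatches(loc, regexec("^<?([0-9]+)>?$", loc))[[1]]
    if (length(m1) == 0) return(NULL)
    return(list(start = as.integer(m1[2]), end = as.integer(m1[2]),
                strand = strand))
  }
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

#' Read a GenBank flat file into a `GenomeRecord`
#'
#' Consumes only what downstream analysis needs: the LOCUS line (length and
#' topology; topology defaults to circular when the LOCUS line does not state
#' one), the accession (VERSION preferred over ACCESSION) and every
#' single-interval CDS feature. Proteins are taken from the `/translation`
#' qualifier when present and otherwise translated from the ORIGIN sequence
#' with the standard genetic code. CDS with `join(...)`/`order(...)`
#' locations are skipped with a warning: spliced CDS are essentially absent
#' from these genomes and mistranslating a join silently would be worse than
#' excluding it.
#'
#' @param path Path to a GenBank flat file with at least one usable CDS.
#' @param genome_id Genome label; defaults to the LOCUS name.
#' @return A [genome_record()].
#' @export
read_genbank <- function(path, genome_id = NULL) {
  lines <- tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
                    error = function(e) stop("cannot read GenBank file: ",
                                             conditionMessage(e)))
  if (length(lines) == 0) stop("cannot read GenBank file: empty file")

  locus <- grep("^LOCUS", lines, value = TRUE)
  locus_name <- ""
  glen <- NA_integer_
  topology <- "circular"
  if (length(locus) > 0) {
    tok <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
    if (length(tok) >= 2) locus_name <- tok[2]
    bp <- which(tok == "bp")
    if (length(bp) == 1 && bp > 1) glen <- suppressWarnings(as.integer(tok[bp - 1]))
    if (any(tolower(tok) == "linear")) topology <- "linear"
  }
  accession <- ""
  ver <- grep("^VERSION", lines, value = TRUE)
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(ver) > 0) {
    accession <- strsplit(trimws(sub("^VERSION", "", ver[1])), "[[:space:]]+")[[1]][1]
  } else if (length(acc) > 0) {
    accession <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "[[:space:]]+")[[1]][1]
  }
  if (is.na(accession)) accession <- ""
  taxon_group <- "unassigned"
  def <- grep("^DEFINITION", lines, value = TRUE)
  if (length(def) > 0) {
    m <- regmatches(def[1], regexec("taxon_group=([A-Za-z-]+)", def[1]))[[1]]
    if (length(m) == 2 && m[2] %in% c("group-I", "group-II", "unassigned"))
      taxon_group <- m[2]
  }

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  end_rec <- grep("^//", lines)
  last <- min(c(origin_start, end_rec, length(lines) + 1L))

  dna <- NULL
  if (length(origin_start) > 0) {
    o_end <- if (length(end_rec) > 0) min(end_rec[end_rec > origin_start[1]]) - 1L
             else length(lines)
    dna <- paste(gsub("[^A-Za-z]", "", lines[(origin_start[1] + 1L):o_end]),
                 collapse = "")
    dna <- toupper(dna)
  }
  if (is.na(glen)) glen <- if (!is.null(dna)) nchar(dna) else NA_integer_

  genes <- list()
  n_skipped <- 0L
  if (length(feat_start) > 0 && feat_start[1] + 1L <= last - 1L) {
    flines <- lines[(feat_start[1] + 1L):(last - 1L)]
    # split the feature table into features (key at column 6)
    key_idx <- grep("^ {5}\\S", flines)
    if (length(key_idx) > 0) {
      bounds <- c(key_idx, length(flines) + 1L)
      for (k in seq_along(key_idx)) {
        block <- flines[key_idx[k]:(bounds[k + 1L] - 1L)]
        hdr <- block[1]
        key <- sub("^ {5}(\\S+).*$", "\\1", hdr)
        if (key != "CDS") next
        # location may continue over lines until the first qualifier
        rest <- sub("^ {5}\\S+\\s+", "", hdr)
        body <- if (length(block) > 1) trimws(block[-1]) else character(0)
        qstart <- which(startsWith(body, "/"))
        loc <- paste(c(rest, if (length(qstart) > 0 && qstart[1] > 1)
                               body[seq_len(qstart[1] - 1)] else
                             if (length(qstart) == 0) body else character(0)),
                     collapse = "")
        quals <- list()
        if (length(qstart) > 0) {
          qb <- c(qstart, length(body) + 1L)
          for (q in seq_along(qstart)) {
            qtxt <- paste(body[qstart[q]:(qb[q + 1L] - 1L)], collapse = "")
            qm <- regmatches(qtxt, regexec("^/([A-Za-z_]+)(=\"?(.*?)\"?)?$", qtxt))[[1]]
            if (length(qm) >= 2) quals[[qm[2]]] <- if (length(qm) >= 4) qm[4] else ""
          }
        }
        pl <- parse_location(loc)
        if (is.null(pl)) {
          warning("skipping multi-interval CDS at '", loc, "' in ", path,
                  call. = FALSE)
          n_skipped <- n_skipped + 1L
          next
        }
        prot <- quals[["translation"]]
        if (is.null(prot) || !nzchar(prot)) {
          if (is.null(dna)) {
            warning("CDS without /translation and no ORIGIN sequence; skipped",
                    call. = FALSE)
            n_skipped <- n_skipped + 1L
            next
          }
          cds <- substr(dna, pl$start, pl$end)
          d <- Biostrings::DNAString(cds)
          if (pl$strand == "-") d <- Biostrings::reverseComplement(d)
          prot <- as.character(Biostrings::translate(d, if.fuzzy.codon = "X"))
          prot <- sub("\\*$", "", prot)
        }
        prot <- normalize_protein(prot)
        gid <- quals[["gene"]]
        if (is.null(gid) || !nzchar(gid)) gid <- quals[["locus_tag"]]
        if (is.null(gid) || !nzchar(gid)) gid <- quals[["protein_id"]]
        if (is.null(gid) || !nzchar(gid)) gid <- sprintf("cds_%03d", length(genes) + 1L)
        lt <- quals[["locus_tag"]]; if (is.null(lt)) lt <- ""
        pn <- quals[["product"]]; if (is.null(pn)) pn <- ""
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, locus_tag = lt, product_name = pn,
          start = pl$start, end = pl$end, strand = pl$strand,
          protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(genes) == 0)
    stop("no usable CDS feature in ", path)
  genes <- do.call(rbind, genes)
  genes$gene_id <- make.unique(genes$gene_id, sep = "_")
  if (is.na(glen)) glen <- max(genes$end)
  genome_record(genome_id = if (is.null(genome_id)) locus_name else genome_id,
                genes = genes, length = glen, accession = accession,
                taxon_group = taxon_group, topology = topology)
}

#' Write a `GenomeRecord` as a GenBank flat file
#'
#' Emits LOCUS/DEFINITION/ACCESSION/VERSION lines, a `source` feature and one
#' CDS feature per gene with `gene`, `locus_tag`, `product` and `translation`
#' qualifiers. The taxon group is recorded on the DEFINITION line
#' (`taxon_group=...`) so that [read_genbank()] round-trips it. No ORIGIN
#' sequence is written; readers take proteins from the translation
#' qualifiers.
#'
#' @param record A [genome_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "GenomeRecord"))
  wrap_qual <- function(txt) {
    out <- character(0)
    while (nchar(txt) > 58) {
      out <- c(out, substr(txt, 1, 58))
      txt <- substr(txt, 59, nchar(txt))
    }
    c(out, txt)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s VRL 01-JAN-2024",
                     record$genome_id, record$length, record$topology), con)
  writeLines(sprintf("DEFINITION  %s synthetic genome; taxon_group=%s.",
                     record$genome_id, record$taxon_group), con)
  if (nzchar(record$accession)) {
    writeLines(sprintf("ACCESSION   %s", sub("\\..*$", "", record$accession)), con)
    writeLines(sprintf("VERSION     %s", record$accession), con)
  }
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", record$length), con)
  for (i in seq_len(nrow(record$genes))) {
    g <- record$genes[i, ]
    loc <- sprintf("%d..%d", g$start, g$end)
    if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", g$gene_id), con)
    if (nzchar(g$locus_tag))
      writeLines(sprintf("                     /locus_tag=\"%s\"", g$locus_tag), con)
    if (nzchar(g$product_name))
      writeLines(sprintf("                     /product=\"%s\"", g$product_name), con)
    tr <- wrap_qual(sprintf("/translation=\"%s\"", g$protein))
    writeLines(paste0("                     ", tr), con)
  }
  writeLines("//", con)
  invisible(path)
}

# --- FASTA / TSV -----------------------------------------------------------

#' Read a protein FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-cased sequences; names are the
#'   first whitespace-delimited token of each header. Duplicate ids or empty
#'   sequences are errors.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(x), "[[:space:]]+"), `[`, "", 1)
  seqs <- toupper(as.character(x))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  names(seqs) <- ids
  seqs
}

#' Write protein sequences as FASTA (60-column wrap)
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  stopifnot(!is.null(names(records)), all(nzchar(names(records))))
  x <- Biostrings::AAStringSet(unname(records))
  names(x) <- names(records)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Write a data frame as TSV with a header row
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_file()]
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
}
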