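# Independent brute-force oracles used across the suite. These deliberately
# avoid dynamic programming tables: plain recursion enumerates every gapped
# alignment, so agreement with the package's DP kernels is a real check.

AA_SAMPLE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(len) paste(sample(AA_SAMPLE, len, replace = TRUE),
                                    collapse = "")

# best global affine-gap score of a[i..] vs b[j..] by exhaustive recursion;
# first gap residue costs go + ge, further residues ge; end gaps penalized
bf_global_score <- function(a, b, S, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, S[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (i <= n)
      best <- max(best, -(if (prev == "X") ge else go + ge) +
                    rec(i + 1, j, "X"))
    if (j <= m)
      best <- max(best, -(if (prev == "Y") ge else go + ge) +
                    rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "start")
}

# best local score: maximum over all substring pairs of the exhaustive
# global score (plus the empty alignment at 0)
bf_local_score <- function(a, b, S, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      sub_a <- paste(av[i1:i2], collapse = "")
      sub_b <- paste(bv[j1:j2], collapse = "")
      best <- max(best, bf_global_score(sub_a, sub_b, S, go, ge))
    }
  best
}

# score an alignment given as two equal-length gapped strings
score_alignment <- function(qa, sa, S, go, ge) {
  q <- strsplit(qa, "")[[1]]; s <- strsplit(sa, "")[[1]]
  stopifnot(length(q) == length(s))
  total <- 0
  in_gap <- ""
  for (k in seq_along(q)) {
    if (q[k] != "-" && s[k] != "-") {
      total <- total + S[q[k], s[k]]
      in_gap <- ""
    } else {
      side <- if (q[k] == "-") "q" else "s"
      total <- total - ge - (if (identical(in_gap, side)) 0 else go)
      in_gap <- side
    }
  }
  total
}

# direct reimplementation of the coiled-coil scan contract: per-window
# winning-register scores, threshold, same-register merging; returns a data
# frame of intervals before cross-register overlap resolution
bf_coil_windows <- function(protein, window, threshold, hydrophobic) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  if (n < window) return(data.frame())
  rows <- list()
  for (s in seq_len(n - window + 1)) {
    sc <- numeric(7)
    for (q in 0:6) {
      core <- integer(0)
      for (r in s:(s + window - 1))
        if (((r - 1 + q) %% 7) %in% c(0, 3)) core <- c(core, r)
      sc[q + 1] <- mean(res[core] %in% hydrophobic)
    }
    q_win <- which.max(sc) - 1
    rows[[s]] <- data.frame(start = s, q = q_win, score = sc[q_win + 1])
  }
  do.call(rbind, rows)
}

# all non-trivial bipartitions of an unrooted tree, as canonical strings
bf_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next # trivial split
    below <- ape::extract.clade(tree, child)$tip.label
    side <- sort(below)
    other <- sort(setdiff(tips, side))
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (tips[1] %in% side) other else side
    out <- c(out, paste(canon, collapse = "|"))
  }
  unique(out)
}

bf_rf <- function(t1, t2) {
  s1 <- bf_splits(t1); s2 <- bf_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# small named-genome fixture used by several module tests
toy_genome <- function(genome_id, proteins, taxon_group = "unassigned") {
  n <- length(proteins)
  starts <- cumsum(c(100, head(nchar(proteins) * 3 + 150, -1)))
  ends <- starts + nchar(proteins) * 3 + 2
  genes <- data.frame(
    gene_id = names(proteins),
    locus_tag = paste0(genome_id, "_", seq_len(n)),
    product_name = "hypothetical protein",
    start = starts, end = ends,
    strand = rep("+", n), protein = unname(proteins),
    stringsAsFactors = FALSE)
  genome_record(genome_id, genes, max(ends) + 100,
                taxon_group = taxon_group)
}
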