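#' Scan a protein for coiled-coil regions by heptad-register scoring
#'
#' A transparent heptad-hydrophobicity scanner: a coiled coil repeats every 7
#' residues (letters a-g) and packs hydrophobic residues at the core `a` and
#' `d` positions (the "1st and 4th" of each heptad). For every window of
#' `window` residues and every one of the 7 possible registers, the score is
#' the fraction of a/d positions occupied by a hydrophobic residue; windows
#' whose best register reaches `threshold` are merged (same register) into
#' maximal intervals. Where intervals of different registers overlap, the
#' higher-scoring one wins at the overlap and the other is trimmed (and
#' dropped if it falls below one window).
#'
#' @param protein Amino-acid string.
#' @param window Window size in residues, a multiple of 7, at least 14
#'   (default 21).
#' @param threshold Minimum fraction of hydrophobic a/d positions in a
#'   window, in (0, 1] (default 0.7).
#' @param hydrophobic Residues counted as hydrophobic (default
#'   `I, L, V, M, F, A`).
#' @param id Optional sequence label carried into the annotations.
#' @return List of `CoiledCoilAnnotation`s sorted by start; each has
#'   `interval` (1-based inclusive), `register_offset` (0-6: the register
#'   letter index of the interval's first residue, 0 = `a`), `score` (mean
#'   core hydrophobicity over the interval) and `protein_length`. Proteins
#'   shorter than `window` yield an empty list.
#' @export
scan_coiled_coil <- function(protein, window = 21, threshold = 0.7,
                             hydrophobic = c("I", "L", "V", "M", "F", "A"),
                             id = NA_character_) {
  stopifnot(window >= 14, window %% 7 == 0, threshold > 0, threshold <= 1)
  res <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < window) return(list())
  hyd <- res %in% toupper(hydrophobic)

  # score of interval [s, e] under absolute register phase q
  # (letter index of residue r is (r - 1 + q) mod 7; a = 0, d = 3)
  core_score <- function(s, e, q) {
    r <- s:e
    core <- ((r - 1 + q) %% 7) %in% c(0, 3)
    if (!any(core)) return(0)
    mean(hyd[r][core])
  }

  # each window qualifies under its winning register only (ties: smallest q)
  starts <- seq_len(n - window + 1L)
  scores <- vapply(0:6, function(q)
    vapply(starts, function(s) core_score(s, s + window - 1L, q), 0),
    numeric(length(starts)))
  scores <- matrix(scores, nrow = length(starts))
  win_q <- max.col(scores, ties.method = "first") - 1L
  win_sc <- scores[cbind(seq_along(starts), win_q + 1L)]

  per_phase <- list()
  for (q in 0:6) {
    hit <- starts[win_q == q & win_sc >= threshold]
    if (length(hit) == 0) next
    # merge overlapping/adjacent windows into maximal intervals
    brk <- c(0L, which(diff(hit) > window), length(hit))
    for (k in seq_len(length(brk) - 1L)) {
      hs <- hit[(brk[k] + 1L):brk[k + 1L]]
      s <- min(hs); e <- max(hs) + window - 1L
      per_phase[[length(per_phase) + 1L]] <-
        list(start = s, end = e, q = q, score = core_score(s, e, q))
    }
  }
  if (length(per_phase) == 0) return(list())

  # cross-register overlap resolution: higher score wins at the overlap
  ord <- order(-vapply(per_phase, `[[`, 0, "score"),
               vapply(per_phase, `[[`, 0, "start"),
               vapply(per_phase, `[[`, 0, "q"))
  taken <- logical(n)
  out <- list()
  for (iv in per_phase[ord]) {
    free <- !taken[iv$start:iv$end]
    if (!any(free)) next
    runs <- rle(free)
    pos <- cumsum(c(0, runs$lengths[-length(runs$lengths)])) + iv$start
    best_len <- 0L; best_s <- NA_integer_
    for (k in seq_along(runs$lengths))
      if (runs$values[k] && runs$lengths[k] > best_len) {
        best_len <- runs$lengths[k]; best_s <- pos[k]
      }
    if (best_len < window) next
    s <- best_s; e <- best_s + best_len - 1L
    taken[s:e] <- TRUE
    out[[length(out) + 1L]] <- structure(
      list(id = id, interval = c(s, e),
           register_offset = (s - 1L + iv$q) %% 7L,
           score = core_score(s, e, iv$q),
           protein_length = n),
      class = "CoiledCoilAnnotation")
  }
  out[order(vapply(out, function(a) a$interval[1], 0))]
}

#' Register letter of a residue within a coiled-coil annotation
#'
#' Returns `"a"` or `"d"` for core positions, `"other"` for non-core letters
#' (b, c, e, f, g) inside the interval, and `"outside"` for residues outside
#' it. The a and d positions of one heptad are exactly 3 residues apart.
#'
#' @param annotation A `CoiledCoilAnnotation` from [scan_coiled_coil()].
#' @param residue_number 1-based residue number in the protein.
#' @return One of `"a"`, `"d"`, `"other"`, `"outside"`.
#' @export
is_core_position <- function(annotation, residue_number) {
  stopifnot(inherits(annotation, "CoiledCoilAnnotation"))
  if (residue_number < 1 || residue_number > annotation$protein_length)
    stop("residue number ", residue_number, " outside the protein (length ",
         annotation$protein_length, ")")
  iv <- annotation$interval
  if (residue_number < iv[1] || residue_number > iv[2]) return("outside")
  idx <- (residue_number - iv[1] + annotation$register_offset) %% 7
  if (idx == 0) "a" else if (idx == 3) "d" else "other"
}

#' Register letter (a-g) of a residue inside a coiled-coil interval
#' @inheritParams is_core_position
#' @return One of `"a"` .. `"g"`, or `"outside"`.
#' @export
register_letter <- function(annotation, residue_number) {
  iv <- annotation$interval
  if (residue_number < iv[1] || residue_number > iv[2]) return("outside")
  letters[((residue_number - iv[1] + annotation$register_offset) %% 7) + 1]
}

# flat table of annotations, for TSV output
coil_table <- function(annotations) {
  if (length(annotations) == 0)
    return(data.frame(id = character(0), start = integer(0),
                      end = integer(0), register_offset = integer(0),
                      score = numeric(0), core_positions = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(annotations, function(a) {
    r <- a$interval[1]:a$interval[2]
    core <- r[((r - a$interval[1] + a$register_offset) %% 7) %in% c(0, 3)]
    data.frame(id = a$id, start = a$interval[1], end = a$interval[2],
               register_offset = a$register_offset, score = a$score,
               core_positions = paste(core, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
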