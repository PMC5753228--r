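#' Find all exact motif occurrences in a protein set
#'
#' Exact substring matching of literal motif sequences — deliberately not
#' regular expressions, so that every reported motif carries its full
#' specificity guarantee. All occurrences are reported, including
#' overlapping and repeated ones. Ambiguity codes (X, B, Z, U, O, J) in
#' protein sequences match nothing. Matching runs on the raw (unmasked)
#' sequence.
#'
#' The production matcher delegates to the C-level multi-pattern scanner of
#' Biostrings; [find_matches_naive()] is an independent pure-R reference
#' implementation with identical output, kept for verification.
#'
#' @param motifs A motif tibble or character vector of motif sequences.
#' @param proteins A protein tibble.
#' @return A hit tibble with columns `protein_id`, `start`, `end` (1-based,
#'   inclusive; `substr(sequence, start, end)` equals `motif`), `motif`,
#'   ordered by (`protein_id`, `start`, `motif`).
#' @examples
#' p <- protein_tbl("p1", "AAKRKRAA")
#' find_matches("KRKR", p)
#' @export
find_matches <- function(motifs, proteins) {
  motifs <- motif_sequences(motifs)
  validate_proteins(proteins)
  if (length(motifs) == 0 || nrow(proteins) == 0) return(empty_hit_tbl())
  subject <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$id))
  hits <- map(motifs, function(m) {
    mi <- Biostrings::vmatchPattern(m, subject)
    st <- Biostrings::startIndex(mi)
    keep <- lengths(st) > 0
    if (!any(keep)) return(NULL)
    tibble(
      protein_id = rep(proteins$id[keep], lengths(st[keep])),
      start = unlist(st[keep], use.names = FALSE),
      motif = m
    )
  })
  assemble_hits(hits)
}

#' @rdname find_matches
#' @export
find_matches_naive <- function(motifs, proteins) {
  motifs <- motif_sequences(motifs)
  validate_proteins(proteins)
  if (length(motifs) == 0 || nrow(proteins) == 0) return(empty_hit_tbl())
  hits <- map(motifs, function(m) {
    L <- nchar(m)
    per_protein <- map2(proteins$id, proteins$sequence, function(id, s) {
      n <- nchar(s)
      if (n < L) return(NULL)
      starts <- seq_len(n - L + 1)
      at <- starts[substring(s, starts, starts + L - 1) == m]
      if (length(at) == 0) return(NULL)
      tibble(protein_id = id, start = at, motif = m)
    })
    list_rbind(per_protein)
  })
  assemble_hits(hits)
}

assemble_hits <- function(hits) {
  out <- list_rbind(hits)
  if (is.null(out) || nrow(out) == 0) return(empty_hit_tbl())
  out |>
    mutate(end = .data$start + nchar(.data$motif) - 1L,
           start = as.integer(.data$start), end = as.integer(.data$end)) |>
    select("protein_id", "start", "end", "motif") |>
    arrange(.data$protein_id, .data$start, .data$motif)
}

empty_hit_tbl <- function() {
  tibble(protein_id = character(), start = integer(), end = integer(),
         motif = character())
}

motif_sequences <- function(motifs) {
  seqs <- if (is.data.frame(motifs)) {
    validate_motifs(motifs)
    motifs$sequence
  } else {
    as.character(motifs)
  }
  seqs <- unique(seqs)
  if (length(seqs) > 0) {
    bad <- !vapply(seqs, is_standard_seq, logical(1))
    if (any(bad)) {
      abort(paste0("motif sequences must use the 20 standard letters; offending: ",
                   paste(seqs[bad], collapse = ", ")))
    }
  }
  seqs
}

#' Per-motif match statistics over the nuclear and non-nuclear sets
#'
#' For each motif, counts the distinct nuclear proteins, distinct
#' non-nuclear proteins, and distinct nuclear families it matches (a
#' protein with several hits counts once). These are the confidence scores
#' attached to every reported hit and catalogue entry.
#'
#' @param motifs A motif tibble or character vector.
#' @param nuclear Nuclear protein tibble; every record must carry a
#'   `family_id` (see [cluster_families()]).
#' @param non_nuclear Non-nuclear protein tibble (may be empty).
#' @return A tibble `sequence`, `n_nuclear`, `n_non_nuclear`, `n_families`,
#'   one row per distinct motif sequence, in input order.
#' @export
match_stats <- function(motifs, nuclear, non_nuclear = empty_protein_tbl()) {
  seqs <- motif_sequences(motifs)
  validate_proteins(nuclear)
  validate_proteins(non_nuclear)
  if (nrow(nuclear) > 0 && any(is.na(nuclear$family_id))) {
    abort(paste0("match_stats: nuclear protein(s) without family_id: ",
                 paste(nuclear$id[is.na(nuclear$family_id)], collapse = ", ")))
  }
  if (length(seqs) == 0) {
    return(tibble(sequence = character(), n_nuclear = integer(),
                  n_non_nuclear = integer(), n_families = integer()))
  }
  # presence/absence per protein is all that is needed here, so plain
  # fixed-string matching (C level, no per-call dispatch) carries the
  # counting; positional hits stay with find_matches()
  nuc_seq <- nuclear$sequence
  nn_seq <- non_nuclear$sequence
  fam <- nuclear$family_id
  res <- map(seqs, function(m) {
    in_nuc <- grepl(m, nuc_seq, fixed = TRUE)
    c(
      n_nuclear = sum(in_nuc),
      n_non_nuclear = sum(grepl(m, nn_seq, fixed = TRUE)),
      n_families = length(unique(fam[in_nuc]))
    )
  })
  m <- do.call(rbind, res)
  tibble(
    sequence = seqs,
    n_nuclear = as.integer(m[, "n_nuclear"]),
    n_non_nuclear = as.integer(m[, "n_non_nuclear"]),
    n_families = as.integer(m[, "n_families"])
  )
}

#' Locate PY-NLS patterns in a sequence
#'
#' Finds every span matching the PY-NLS pattern: one of R/K/H, then 2-5
#' arbitrary standard residues, then Pro-Tyr. Overlapping spans and
#' different linker lengths at the same anchor are all reported. Ambiguity
#' codes never participate in a match.
#'
#' @param sequence A single amino-acid sequence.
#' @return A tibble `start`, `end` (1-based inclusive) of all matching
#'   spans.
#' @examples
#' find_py_nls("RAAPY")
#' @export
find_py_nls <- function(sequence) {
  stopifnot(length(sequence) == 1)
  ch <- seq_chars(sequence)
  n <- length(ch)
  standard <- ch %in% AA_STANDARD
  out_start <- integer(0)
  out_end <- integer(0)
  anchors <- which(ch %in% c("R", "K", "H"))
  for (i in anchors) {
    for (g in 2:5) {
      j <- i + g + 2L  # position of Y
      if (j > n) break
      if (ch[j] != "Y" || ch[j - 1L] != "P") next
      if (!all(standard[(i + 1L):(i + g)])) next
      out_start <- c(out_start, i)
      out_end <- c(out_end, j)
    }
  }
  tibble(start = as.integer(out_start), end = as.integer(out_end))
}

#' Locate classical monopartite NLS consensus hits
#'
#' Diagnostic matcher for the classical basic consensus K-K/R-X-K/R (X any
#' standard residue). This pattern is reported for context only; it is
#' never used as a filter, because consensus generalization is exactly what
#' the catalogue construction avoids.
#'
#' @param sequence A single amino-acid sequence.
#' @return A tibble `start`, `end` (1-based inclusive) of all 4-residue
#'   matching spans.
#' @export
classical_consensus_hits <- function(sequence) {
  stopifnot(length(sequence) == 1)
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 4) return(tibble(start = integer(), end = integer()))
  i <- seq_len(n - 3L)
  ok <- ch[i] == "K" &
    ch[i + 1L] %in% c("K", "R") &
    ch[i + 2L] %in% AA_STANDARD &
    ch[i + 3L] %in% c("K", "R")
  tibble(start = as.integer(i[ok]), end = as.integer(i[ok] + 3L))
}
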