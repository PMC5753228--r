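#' Physicochemical plausibility filter for NLS motifs
#'
#' An NLS candidate passes when it looks like a basic import signal:
#'
#' * it contains at least `nls_min_positive` positively charged residues
#'   (H, K, R), relaxed to `nls_min_positive_with_py` when the motif itself
#'   contains a PY-NLS pattern (see [find_py_nls()]); and
#' * at least one charge region has an overall positive charge — two
#'   regions for motifs of `nls_long_threshold` or more residues. A charge
#'   region is a maximal run of charged residues (H, K, R, D, E; any other
#'   residue breaks the run) and its net charge is +1 per H/K/R minus 1 per
#'   D/E, so positives cancelled by immediately adjacent negatives do not
#'   count.
#'
#' @param motifs A motif tibble or character vector of motif sequences.
#' @param config A [refinement_config()].
#' @return A tibble `sequence`, `pass`, `reason` (`NA` when passing), one
#'   row per input sequence.
#' @examples
#' nls_charge_filter(c("KRKRK", "KAAARAAPY", "KDKDAA"))
#' @export
nls_charge_filter <- function(motifs, config = refinement_config()) {
  config <- as_refinement_config(config)
  seqs <- if (is.data.frame(motifs)) motifs$sequence else as.character(motifs)
  res <- map(seqs, function(s) {
    ch <- seq_chars(s)
    n_pos <- sum(ch %in% config$positive_set)
    has_py <- nrow(find_py_nls(s)) > 0
    need <- if (has_py) config$nls_min_positive_with_py else config$nls_min_positive
    if (n_pos < need) {
      return(list(pass = FALSE, reason = "too_few_positive_residues"))
    }
    runs_needed <- if (nchar(s) >= config$nls_long_threshold) {
      config$nls_min_positive_regions_long
    } else {
      1L
    }
    if (positive_region_count(ch, config) < runs_needed) {
      return(list(pass = FALSE, reason = "no_net_positive_region"))
    }
    list(pass = TRUE, reason = NA_character_)
  })
  tibble(
    sequence = seqs,
    pass = map_lgl(res, "pass"),
    reason = map_chr(res, "reason")
  )
}

# number of maximal charged runs with net charge > 0
positive_region_count <- function(ch, config) {
  charged <- ch %in% c(config$positive_set, config$negative_set)
  if (!any(charged)) return(0L)
  r <- rle(charged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  n_ok <- 0L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    run <- ch[starts[k]:ends[k]]
    net <- sum(run %in% config$positive_set) - sum(run %in% config$negative_set)
    if (net > 0) n_ok <- n_ok + 1L
  }
  n_ok
}

#' Physicochemical plausibility filter for NES motifs
#'
#' An NES candidate passes when it contains at least `nes_min_hydrophobic`
#' hydrophobic residues (A, F, I, L, M, V) *and* at least
#' `nes_min_hydrophobic_fraction` of its residues are hydrophobic. The
#' removal condition is strictly below the fraction, so a motif at exactly
#' 30% hydrophobic passes at the default.
#'
#' @inheritParams nls_charge_filter
#' @return A tibble `sequence`, `pass`, `reason`.
#' @examples
#' nes_hydrophobicity_filter(c("LALKLL", "LLKKKKKKKK", "LLLKKKKKKK"))
#' @export
nes_hydrophobicity_filter <- function(motifs, config = refinement_config()) {
  config <- as_refinement_config(config)
  seqs <- if (is.data.frame(motifs)) motifs$sequence else as.character(motifs)
  n_hyd <- map_int(seqs, function(s) sum(seq_chars(s) %in% config$hydrophobic_set))
  frac <- n_hyd / nchar(seqs)
  pass <- n_hyd >= config$nes_min_hydrophobic &
    frac >= config$nes_min_hydrophobic_fraction
  reason <- dplyr::case_when(
    n_hyd < config$nes_min_hydrophobic ~ "too_few_hydrophobic_residues",
    frac < config$nes_min_hydrophobic_fraction ~ "hydrophobic_fraction_below_threshold",
    .default = NA_character_
  )
  tibble(sequence = seqs, pass = pass, reason = reason)
}

#' Keep motifs matching at least a minimum number of families
#'
#' Generalization filter for in-silico motifs: a refined motif must match
#' proteins from at least `min_families` distinct nuclear families,
#' otherwise it is likely an over-specific fragment of one homologous
#' group.
#'
#' @param motifs A motif tibble.
#' @param nuclear Nuclear protein tibble with `family_id` set.
#' @param min_families Minimum distinct families matched (default 2).
#' @return The retained subset of `motifs`.
#' @export
family_filter <- function(motifs, nuclear, min_families = 2L) {
  validate_motifs(motifs)
  if (nrow(motifs) == 0) return(motifs)
  st <- match_stats(motifs$sequence, nuclear)
  nf <- st$n_families[match(motifs$sequence, st$sequence)]
  motifs[nf >= min_families, , drop = FALSE]
}

#' Remove redundant motifs
#'
#' Collapses exact duplicate sequences (keeping the entry with the
#' strongest evidence: experimental over expert over potential), then
#' enforces substring minimality: whenever one motif is a proper substring
#' of another, only the shorter is kept. The shorter motif matches
#' everything the longer one matches, so nothing is lost. The result is
#' independent of input order and idempotent.
#'
#' @param motifs A motif tibble.
#' @return The substring-minimal motif tibble, ordered by length then
#'   sequence.
#' @examples
#' m <- motif_tbl(c("KRK", "AKRKA"), "NLS")
#' redundancy_removal(m)$sequence
#' @export
redundancy_removal <- function(motifs) {
  validate_motifs(motifs)
  if (nrow(motifs) == 0) return(motifs)
  ev_rank <- match(motifs$evidence, EVIDENCE_LEVELS)
  ord <- order(motifs$sequence, ev_rank, motifs$source, motifs$seed,
               method = "radix", na.last = TRUE)
  dedup <- motifs[ord, , drop = FALSE]
  dedup <- dedup[!duplicated(dedup$sequence), , drop = FALSE]
  seqs <- dedup$sequence
  # a motif is removed iff some *other* retained motif is a proper substring;
  # since substring-minimal elements are never removed, checking against all
  # shorter motifs is equivalent
  keep <- vapply(seq_along(seqs), function(i) {
    others <- seqs[nchar(seqs) < nchar(seqs[i])]
    !any(vapply(others, function(o) grepl(o, seqs[i], fixed = TRUE), logical(1)))
  }, logical(1))
  out <- dedup[keep, , drop = FALSE]
  out[order(nchar(out$sequence), out$sequence, method = "radix"), , drop = FALSE]
}
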