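#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and trailing `*` stop/terminator symbols are
#' stripped. The record id is the first whitespace-delimited token of the
#' header line. Records start unlabeled; attach localization labels with
#' [join_labels()].
#'
#' @param path Path to a FASTA file.
#' @return A protein tibble with columns `id`, `sequence`, `label`
#'   (`"unlabeled"`), `organism`, `family_id`, `masked_sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some protein", "mkkrkv"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("read_fasta: no such file: ", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    warn(paste0("read_fasta: no records in ", path))
    return(empty_protein_tbl())
  }
  ids <- vapply(strsplit(names(raw), "[ \t]"), `[[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("read_fasta: duplicate record id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*+$", "", seqs)
  if (any(nchar(seqs) == 0)) {
    abort(paste0("read_fasta: empty sequence for id(s): ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  bad <- map(seqs, offending_chars, allowed = AA_ALLOWED)
  has_bad <- lengths(bad) > 0
  if (any(has_bad)) {
    msg <- paste0(ids[has_bad], " [", map_chr(bad[has_bad], paste, collapse = ""), "]")
    abort(paste0("read_fasta: invalid characters outside the amino-acid alphabet: ",
                 paste(msg, collapse = "; ")))
  }
  protein_tbl(id = ids, sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A protein tibble (columns `id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a protein tibble
#'
#' The common currency of the package: one row per protein with its
#' localization label, optional organism, family assignment and masked
#' sequence.
#'
#' @param id Character vector of unique protein ids.
#' @param sequence Uppercase amino-acid sequences (20 standard letters plus
#'   ambiguity codes X, B, Z, U, O, J).
#' @param label One of `"nuclear"`, `"non_nuclear"`, `"unlabeled"`.
#' @param organism Optional organism name.
#' @param family_id Optional non-negative integer family assignment
#'   (nuclear records only, after clustering).
#' @param masked_sequence Optional same-length sequence with low-complexity
#'   positions replaced by `"x"`.
#' @return A tibble with the six columns above.
#' @export
protein_tbl <- function(id, sequence, label = "unlabeled", organism = NA_character_,
                        family_id = NA_integer_, masked_sequence = NA_character_) {
  out <- tibble(
    id = as.character(id),
    sequence = as.character(sequence),
    label = as.character(label),
    organism = as.character(organism),
    family_id = as.integer(family_id),
    masked_sequence = as.character(masked_sequence)
  )
  validate_proteins(out)
}

empty_protein_tbl <- function() {
  tibble(
    id = character(), sequence = character(), label = character(),
    organism = character(), family_id = integer(), masked_sequence = character()
  )
}

validate_proteins <- function(proteins) {
  stopifnot(is.data.frame(proteins))
  req <- c("id", "sequence", "label")
  missing_cols <- setdiff(req, names(proteins))
  if (length(missing_cols) > 0) {
    abort(paste0("protein table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(proteins$id)) {
    abort(paste0("duplicate protein id(s): ",
                 paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", ")))
  }
  if (nrow(proteins) > 0 && any(nchar(proteins$sequence) < 1)) {
    abort("protein sequences must have length >= 1")
  }
  bad_label <- setdiff(unique(proteins$label), LABEL_LEVELS)
  if (length(bad_label) > 0) {
    abort(paste0("unknown label(s): ", paste(bad_label, collapse = ", ")))
  }
  masked <- !is.na(proteins$masked_sequence)
  if (any(masked)) {
    same_len <- nchar(proteins$masked_sequence[masked]) == nchar(proteins$sequence[masked])
    if (!all(same_len)) abort("masked_sequence must have the same length as sequence")
  }
  proteins
}

#' Read a localization label table
#'
#' Reads a tab-separated table with columns `id`, `label` and optionally
#' `organism`. Labels must be `"nuclear"` or `"non_nuclear"`; anything else
#' is an error (the vocabulary is closed on purpose — upstream curation must
#' resolve its evidence into one of the two classes).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `id`, `label`, `organism`.
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("id", "label")
  if (!all(req %in% names(tab))) {
    abort("read_labels: the table must have columns `id` and `label`")
  }
  if (!"organism" %in% names(tab)) tab$organism <- NA_character_
  bad <- setdiff(unique(tab$label), c("nuclear", "non_nuclear"))
  if (length(bad) > 0) {
    abort(paste0("read_labels: unknown label(s): ", paste(bad, collapse = ", "),
                 " (allowed: nuclear, non_nuclear)"))
  }
  if (anyDuplicated(tab$id)) {
    abort(paste0("read_labels: duplicate id(s): ",
                 paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")))
  }
  tab |>
    mutate(id = as.character(.data$id), organism = as.character(.data$organism)) |>
    select("id", "label", "organism")
}

#' Attach localization labels to a protein table
#'
#' Joins a label table (see [read_labels()]) onto a protein tibble. Label
#' rows whose id is absent from the protein table are reported with a
#' warning; proteins without a label row stay `"unlabeled"`.
#'
#' @param proteins A protein tibble.
#' @param labels A tibble with columns `id`, `label` and optionally
#'   `organism`.
#' @return The protein tibble with `label` (and `organism`) filled in.
#' @export
join_labels <- function(proteins, labels) {
  validate_proteins(proteins)
  orphan <- setdiff(labels$id, proteins$id)
  if (length(orphan) > 0) {
    warn(paste0("join_labels: label ids absent from the protein table: ",
                paste(orphan, collapse = ", ")))
  }
  idx <- match(proteins$id, labels$id)
  hit <- !is.na(idx)
  proteins$label[hit] <- labels$label[idx[hit]]
  if ("organism" %in% names(labels)) {
    org <- labels$organism[idx[hit]]
    keep <- !is.na(org)
    proteins$organism[hit][keep] <- org[keep]
  }
  proteins
}

#' Construct a signal motif tibble
#'
#' @param sequence Uppercase motif sequences over the 20 standard amino
#'   acids (no ambiguity codes).
#' @param signal_type `"NLS"` or `"NES"`.
#' @param evidence `"experimental"`, `"expert"` or `"potential"`.
#' @param source One of `"uniprot"`, `"nesbase"`, `"validness"`,
#'   `"seqnls"`, `"in_silico"`, `"user"`. `evidence == "potential"` if and
#'   only if `source == "in_silico"`.
#' @param seed,substitution,n_deletions Edit provenance for in-silico
#'   motifs: the seed motif it descends from, the single substitution
#'   applied (as `"p<pos><letter>"`, or `NA` for none) and the number of
#'   single-residue deletions applied.
#' @return A motif tibble with the seven columns above.
#' @export
motif_tbl <- function(sequence, signal_type, evidence = "experimental",
                      source = "user", seed = NA_character_,
                      substitution = NA_character_, n_deletions = NA_integer_) {
  out <- tibble(
    sequence = as.character(sequence),
    signal_type = as.character(signal_type),
    evidence = as.character(evidence),
    source = as.character(source),
    seed = as.character(seed),
    substitution = as.character(substitution),
    n_deletions = as.integer(n_deletions)
  )
  validate_motifs(out)
}

empty_motif_tbl <- function() {
  tibble(
    sequence = character(), signal_type = character(), evidence = character(),
    source = character(), seed = character(), substitution = character(),
    n_deletions = integer()
  )
}

validate_motifs <- function(motifs) {
  req <- c("sequence", "signal_type", "evidence", "source")
  missing_cols <- setdiff(req, names(motifs))
  if (length(missing_cols) > 0) {
    abort(paste0("motif table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(motifs) == 0) return(motifs)
  if (any(is.na(motifs$sequence)) || any(nchar(motifs$sequence) == 0)) {
    abort("motif sequences must be non-empty")
  }
  bad <- !vapply(motifs$sequence, is_standard_seq, logical(1))
  if (any(bad)) {
    abort(paste0(
      "motif sequences must use only the 20 standard uppercase amino-acid letters; ",
      "offending: ", paste(unique(motifs$sequence[bad]), collapse = ", ")
    ))
  }
  bad_type <- setdiff(unique(motifs$signal_type), SIGNAL_TYPES)
  if (length(bad_type) > 0) {
    abort(paste0("unknown signal_type: ", paste(bad_type, collapse = ", ")))
  }
  bad_ev <- setdiff(unique(motifs$evidence), EVIDENCE_LEVELS)
  if (length(bad_ev) > 0) {
    abort(paste0("unknown evidence: ", paste(bad_ev, collapse = ", ")))
  }
  bad_src <- setdiff(unique(motifs$source), SOURCE_LEVELS)
  if (length(bad_src) > 0) {
    abort(paste0("unknown source: ", paste(bad_src, collapse = ", ")))
  }
  mism <- xor(motifs$evidence == "potential", motifs$source == "in_silico")
  if (any(mism)) {
    abort("evidence must be 'potential' exactly for source 'in_silico' motifs")
  }
  motifs
}

#' Read or write a motif table
#'
#' Motif catalogues are exchanged as comma- or tab-separated files (decided
#' by the file extension: `.tsv`/`.tab` for tabs, anything else commas) with
#' columns `sequence`, `signal_type`, `evidence`, `source` and optional
#' provenance columns `seed`, `substitution`, `n_deletions`. Writing then
#' reading reproduces the table exactly, in order.
#'
#' @param path File path.
#' @return For `read_motifs()`, a motif tibble.
#' @export
read_motifs <- function(path) {
  reader <- if (grepl("\\.(tsv|tab)$", path)) readr::read_tsv else readr::read_csv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0) return(empty_motif_tbl())
  for (col in c("seed", "substitution")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  if (!"n_deletions" %in% names(tab)) tab$n_deletions <- NA_character_
  tab$n_deletions <- as.integer(tab$n_deletions)
  validate_motifs(as_tibble(tab)[names(empty_motif_tbl())])
}

#' @rdname read_motifs
#' @param motifs A motif tibble.
#' @export
write_motifs <- function(motifs, path) {
  validate_motifs(motifs)
  out <- motifs[intersect(names(empty_motif_tbl()), names(motifs))]
  writer <- if (grepl("\\.(tsv|tab)$", path)) readr::write_tsv else readr::write_csv
  writer(out, path, progress = FALSE)
  invisible(path)
}
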