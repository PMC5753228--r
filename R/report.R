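#' Coverage of a proteome by a motif catalogue
#'
#' For each organism (and overall), counts the proteins and the number and
#' percentage containing at least one NLS and at least one NES match. A
#' protein with many hits counts once per column; a protein with both an
#' NLS and an NES counts once in each column.
#'
#' @param proteins A protein tibble; `organism` is used for grouping when
#'   present (records with `NA` organism group as `"unknown"`).
#' @param motifs A motif tibble (may mix NLS and NES rows), a
#'   `motif_catalogue`, or a list of `motif_catalogue` objects.
#' @return A tibble with one row per organism plus an `"(all)"` row:
#'   `organism`, `n_proteins`, `n_with_nls`, `pct_nls`, `n_with_nes`,
#'   `pct_nes`. Percentages are rounded to one decimal.
#' @export
coverage_report <- function(proteins, motifs) {
  motifs <- as_motif_table(motifs)
  validate_proteins(proteins)
  org <- dplyr::coalesce(proteins$organism, "unknown")
  carriers <- function(type) {
    m <- motifs[motifs$signal_type == type, , drop = FALSE]
    if (nrow(m) == 0 || nrow(proteins) == 0) return(character(0))
    unique(find_matches(m, proteins)$protein_id)
  }
  nls_ids <- carriers("NLS")
  nes_ids <- carriers("NES")
  per_org <- tibble(organism = org, id = proteins$id) |>
    group_by(.data$organism) |>
    summarise(
      n_proteins = n(),
      n_with_nls = sum(.data$id %in% nls_ids),
      n_with_nes = sum(.data$id %in% nes_ids),
      .groups = "drop"
    )
  overall <- tibble(
    organism = "(all)",
    n_proteins = nrow(proteins),
    n_with_nls = length(nls_ids),
    n_with_nes = length(nes_ids)
  )
  bind_rows(per_org, overall) |>
    mutate(
      pct_nls = round(100 * .data$n_with_nls / pmax(.data$n_proteins, 1L), 1),
      pct_nes = round(100 * .data$n_with_nes / pmax(.data$n_proteins, 1L), 1)
    ) |>
    select("organism", "n_proteins", "n_with_nls", "pct_nls",
           "n_with_nes", "pct_nes")
}

as_motif_table <- function(motifs) {
  if (inherits(motifs, "motif_catalogue")) return(motifs$motifs)
  if (is.list(motifs) && !is.data.frame(motifs) &&
      all(vapply(motifs, inherits, logical(1), "motif_catalogue"))) {
    return(list_rbind(map(motifs, "motifs")))
  }
  validate_motifs(motifs)
  motifs
}

#' Evaluate a candidate signal against the nuclear / non-nuclear datasets
#'
#' Returns every nuclear and non-nuclear protein the query motif matches,
#' with the summary match statistics. This mirrors submitting one's own
#' putative signal for evaluation.
#'
#' @param query A single motif sequence (20 standard letters).
#' @param nuclear,non_nuclear Protein tibbles (`nuclear` with `family_id`
#'   for family counting; without it the family count is omitted).
#' @return A list with `nuclear_ids`, `non_nuclear_ids` and `stats` (a
#'   one-row tibble).
#' @export
evaluate_motif <- function(query, nuclear, non_nuclear) {
  stopifnot(length(query) == 1)
  if (!is_standard_seq(query)) {
    abort("evaluate_motif: the query must use only the 20 standard amino-acid letters")
  }
  nuc_ids <- unique(find_matches(query, nuclear)$protein_id)
  nn_ids <- unique(find_matches(query, non_nuclear)$protein_id)
  stats <- if (all(!is.na(nuclear$family_id))) {
    match_stats(query, nuclear, non_nuclear)
  } else {
    tibble(sequence = query, n_nuclear = length(nuc_ids),
           n_non_nuclear = length(nn_ids), n_families = NA_integer_)
  }
  list(nuclear_ids = nuc_ids, non_nuclear_ids = nn_ids, stats = stats)
}

#' Find catalogue motifs contained in a query signal
#'
#' The converse lookup of [evaluate_motif()]: which catalogue motifs occur
#' as exact substrings *within* the query sequence.
#'
#' @param query A single amino-acid sequence.
#' @param catalogue A `motif_catalogue` or motif tibble.
#' @return The subset of catalogue rows whose sequence is a substring of
#'   the query.
#' @export
evaluate_against_catalogue <- function(query, catalogue) {
  stopifnot(length(query) == 1)
  motifs <- as_motif_table(catalogue)
  hit <- vapply(motifs$sequence, grepl, logical(1), x = query, fixed = TRUE)
  motifs[hit, , drop = FALSE]
}

#' Motif length distribution
#'
#' Counts motifs per integer length; lengths above `max_length` pool into
#' one open-ended bin (default `"26+"`), mirroring how sparse long motifs
#' are reported.
#'
#' @param motifs A motif tibble, `motif_catalogue`, or character vector.
#' @param max_length Last individually counted length (default 25).
#' @return A tibble `length` (factor: `"1"`, ..., `"25"`, `"26+"`), `n`;
#'   only observed bins are returned, in order.
#' @export
length_distribution <- function(motifs, max_length = 25L) {
  seqs <- if (is.data.frame(motifs) || inherits(motifs, "motif_catalogue")) {
    as_motif_table(motifs)$sequence
  } else {
    as.character(motifs)
  }
  if (length(seqs) == 0) {
    return(tibble(length = factor(character()), n = integer()))
  }
  overflow <- paste0(max_length + 1L, "+")
  len <- nchar(seqs)
  bin <- if_else(len > max_length, overflow, as.character(len))
  lev <- c(as.character(seq_len(max_length)), overflow)
  tibble(bin = factor(bin, levels = lev)) |>
    count(.data$bin, name = "n") |>
    rename(length = "bin")
}

#' Cumulative organism-sharing curve of a motif catalogue
#'
#' For each catalogue motif, counts the organisms whose proteome contains
#' at least one protein matching it; reports, for k = 1..n organisms, the
#' percentage of motifs found in at least k organisms. The curve is
#' non-increasing in k.
#'
#' @param motifs A motif tibble or `motif_catalogue`.
#' @param proteomes A protein tibble spanning one or more organisms (the
#'   `organism` column defines the grouping).
#' @return A tibble `k`, `n_motifs`, `pct` (percentage of the catalogue).
#' @export
organism_sharing_curve <- function(motifs, proteomes) {
  motifs <- as_motif_table(motifs)
  validate_proteins(proteomes)
  orgs <- unique(dplyr::coalesce(proteomes$organism, "unknown"))
  if (length(orgs) == 0) abort("organism_sharing_curve: empty proteome set")
  n_motifs <- nrow(motifs)
  hits <- find_matches(motifs, proteomes)
  org_of <- stats::setNames(dplyr::coalesce(proteomes$organism, "unknown"),
                            proteomes$id)
  n_org <- hits |>
    mutate(organism = org_of[.data$protein_id]) |>
    distinct(.data$motif, .data$organism) |>
    count(.data$motif, name = "n_organisms")
  counts <- stats::setNames(rep(0L, n_motifs), motifs$sequence)
  counts[n_org$motif] <- n_org$n_organisms
  tibble(k = seq_along(orgs)) |>
    mutate(
      n_motifs = map_int(.data$k, ~ sum(counts >= .x)),
      pct = round(100 * .data$n_motifs / max(n_motifs, 1L), 1)
    )
}

#' Plot a motif length distribution
#'
#' @param motifs A motif tibble, `motif_catalogue`, or character vector.
#' @param max_length Last individually counted length.
#' @return A ggplot bar chart.
#' @export
plot_length_distribution <- function(motifs, max_length = 25L) {
  dist <- length_distribution(motifs, max_length)
  ggplot(dist, aes(x = .data$length, y = .data$n)) +
    geom_col(fill = "grey25") +
    labs(x = "motif length (residues)", y = "motifs") +
    theme_minimal()
}

#' Plot an organism-sharing curve
#'
#' @param motifs A motif tibble or `motif_catalogue`.
#' @param proteomes A multi-organism protein tibble.
#' @return A ggplot step plot of the cumulative sharing percentage.
#' @export
plot_sharing_curve <- function(motifs, proteomes) {
  curve <- organism_sharing_curve(motifs, proteomes)
  ggplot(curve, aes(x = .data$k, y = .data$pct)) +
    geom_step() +
    geom_point() +
    labs(x = "found in at least k organisms", y = "% of motifs") +
    theme_minimal()
}
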