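#' Assemble the final motif catalogue
#'
#' Combines the collected (original) signals with the refined in-silico
#' signals into the published-catalogue structure:
#'
#' * original signals are included whenever they are specific (match no
#'   non-nuclear protein) and sensitive (match at least one nuclear
#'   protein) — the family and physicochemical rules do not bind them;
#' * in-silico signals must additionally pass their type's physicochemical
#'   filter ([nls_charge_filter()] or [nes_hydrophobicity_filter()]) and
#'   match at least `config$min_families` families;
#' * the union is made substring-minimal with [redundancy_removal()].
#'
#' Every catalogue entry is annotated with its match statistics against the
#' build datasets; by construction every entry has zero non-nuclear
#' matches. One catalogue is built per signal type; mixing NLS and NES in
#' one call is an error.
#'
#' @param originals Motif tibble of collected signals.
#' @param refined Motif tibble from [refine_motifs()] (may be empty).
#' @param nuclear Nuclear protein tibble with `family_id` set.
#' @param non_nuclear Non-nuclear protein tibble.
#' @param config A [refinement_config()].
#' @return A `motif_catalogue` object: list with `motifs` (annotated motif
#'   tibble), `signal_type`, `report` (assembly counts, including the
#'   overlap between refined signals and originals) and `config`.
#' @export
assemble_catalogue <- function(originals, refined, nuclear, non_nuclear,
                               config = refinement_config()) {
  config <- as_refinement_config(config)
  validate_motifs(originals)
  validate_motifs(refined)
  types <- unique(c(originals$signal_type, refined$signal_type))
  if (length(types) > 1) {
    abort("assemble_catalogue: mixed signal types in one run; assemble NLS and NES separately")
  }
  if (length(types) == 0) abort("assemble_catalogue: both motif sets are empty")
  type <- types[[1]]

  phys_filter <- if (type == "NLS") nls_charge_filter else nes_hydrophobicity_filter

  keep_specific <- function(m) {
    if (nrow(m) == 0) return(m)
    st <- match_stats(m$sequence, nuclear, non_nuclear)
    st <- st[match(m$sequence, st$sequence), ]
    m[st$n_non_nuclear == 0 & st$n_nuclear >= 1, , drop = FALSE]
  }

  orig_keep <- keep_specific(distinct(originals, .data$sequence, .keep_all = TRUE))

  insilico <- refined[refined$source == "in_silico", , drop = FALSE]
  # survivors of the refinement loop that are seed signals re-enter through
  # `originals`; only true in-silico variants face the extra filters
  insilico <- keep_specific(insilico)
  if (nrow(insilico) > 0) {
    phys <- phys_filter(insilico$sequence, config)
    insilico <- insilico[phys$pass, , drop = FALSE]
    insilico <- family_filter(insilico, nuclear, min_families = config$min_families)
  }

  n_overlap <- sum(insilico$sequence %in% orig_keep$sequence)
  combined <- bind_rows(orig_keep, insilico)
  final <- redundancy_removal(combined)

  stats <- match_stats(final$sequence, nuclear, non_nuclear)
  motifs <- final |>
    left_join(stats, by = "sequence") |>
    as_tibble()

  report <- tibble(
    step = c("originals_in", "originals_specific_sensitive", "in_silico_in",
             "in_silico_kept", "overlap_refined_vs_original", "final"),
    n = c(nrow(originals), nrow(orig_keep), sum(refined$source == "in_silico"),
          nrow(insilico), n_overlap, nrow(motifs))
  )

  structure(
    list(motifs = motifs, signal_type = type, report = report, config = config),
    class = "motif_catalogue"
  )
}

#' Build a motif catalogue from seeds and prepared datasets
#'
#' Convenience pipeline: [seed_filter()], then [refine_motifs()], then
#' [assemble_catalogue()] with the filtered seeds as the originals.
#'
#' @param seeds Motif tibble of seed signals (one signal type).
#' @param nuclear,non_nuclear Prepared protein tibbles (`nuclear` with
#'   `family_id`).
#' @param config A [refinement_config()].
#' @return A `motif_catalogue` object.
#' @export
build_catalogue <- function(seeds, nuclear, non_nuclear, config = refinement_config()) {
  config <- as_refinement_config(config)
  kept <- seed_filter(seeds, nuclear, non_nuclear, config)
  refined <- refine_motifs(kept, nuclear, non_nuclear, config)
  assemble_catalogue(kept, refined, nuclear, non_nuclear, config)
}

#' @export
print.motif_catalogue <- function(x, ...) {
  cat(sprintf("<motif_catalogue> %d %s motif(s)\n", nrow(x$motifs), x$signal_type))
  if (nrow(x$motifs) > 0) {
    cat(sprintf("  evidence: %s\n",
                paste(sprintf("%s=%d", names(table(x$motifs$evidence)),
                              as.integer(table(x$motifs$evidence))), collapse = ", ")))
    cat(sprintf("  mean nuclear proteins per motif: %.2f\n", mean(x$motifs$n_nuclear)))
  }
  invisible(x)
}

#' Tidy a motif catalogue into its annotated motif table
#'
#' @param x A `motif_catalogue`.
#' @param ... Unused.
#' @return The motif tibble with match statistics.
#' @export
tidy.motif_catalogue <- function(x, ...) {
  x$motifs
}

#' One-row summary of a motif catalogue
#'
#' @param x A `motif_catalogue`.
#' @param ... Unused.
#' @return A one-row tibble: motif counts by origin, matched nuclear
#'   proteins and families, and mean sensitivity per motif.
#' @export
glance.motif_catalogue <- function(x, ...) {
  m <- x$motifs
  tibble(
    signal_type = x$signal_type,
    n_motifs = nrow(m),
    n_original = sum(m$source != "in_silico"),
    n_in_silico = sum(m$source == "in_silico"),
    mean_nuclear_per_motif = if (nrow(m) > 0) mean(m$n_nuclear) else NA_real_,
    max_non_nuclear = if (nrow(m) > 0) max(m$n_non_nuclear) else NA_integer_
  )
}

#' Plot the length distribution of a motif catalogue
#'
#' @param object A `motif_catalogue`.
#' @param ... Unused.
#' @return A ggplot bar chart of motif counts per length (lengths above 25
#'   pooled as `"26+"`).
#' @export
autoplot.motif_catalogue <- function(object, ...) {
  dist <- length_distribution(object$motifs)
  ggplot(dist, aes(x = .data$length, y = .data$n)) +
    geom_col(fill = "grey25") +
    labs(x = "motif length (residues)", y = "motifs",
         title = paste0("Length distribution of ", object$signal_type, " motifs")) +
    theme_minimal()
}
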