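#' Refinement configuration
#'
#' Collects every numeric threshold of the catalogue-construction protocol in
#' one validated object. Defaults are the protocol's published operating
#' point; change them only for sensitivity analyses.
#'
#' @param min_protein_length Proteins shorter than this many residues are
#'   discarded as likely fragments (default 50).
#' @param min_unmasked_run Minimum number of consecutive unmasked residues a
#'   protein must retain after low-complexity masking (default 30).
#' @param cross_label_identity Non-nuclear proteins with global pairwise
#'   sequence identity strictly above this fraction to any nuclear protein
#'   are removed (default 0.80).
#' @param max_seed_length Seed signals longer than this are discarded before
#'   refinement, to limit non-functional linker residues (default 30).
#' @param min_families In-silico motifs must match proteins from at least
#'   this many distinct families (default 2).
#' @param nls_min_positive Minimum count of positively charged residues
#'   (H, K, R) in an NLS (default 3).
#' @param nls_min_positive_with_py Relaxed minimum when the motif contains a
#'   PY-NLS pattern (default 2).
#' @param nls_long_threshold Motif length at or above which two positive
#'   regions are required instead of one (default 20).
#' @param nls_min_positive_regions_long Number of net-positive charge runs
#'   required for long NLS (default 2).
#' @param nes_min_hydrophobic Minimum count of hydrophobic residues
#'   (A, F, I, L, M, V) in an NES (default 3).
#' @param nes_min_hydrophobic_fraction Minimum hydrophobic fraction of an
#'   NES; exactly this fraction passes (default 0.30).
#' @param positive_set,negative_set,hydrophobic_set Residue classes used by
#'   the physicochemical filters.
#' @param seg_window,seg_trigger,seg_extension Low-complexity masking
#'   parameters: window length (residues), trigger entropy and extension
#'   entropy (bits).
#' @param prune_before_delete During refinement, generate deletion variants
#'   only from candidates that already pass the specificity/sensitivity
#'   filter (`TRUE`, the literal protocol) or from every candidate that
#'   matches no non-nuclear protein (`FALSE`, a more generative reading that
#'   lets insensitive candidates shed residues). See the vignette.
#' @param rng_seed Integer seed recorded in run signatures.
#'
#' @return An object of class `refinement_config` (a validated named list).
#' @examples
#' cfg <- refinement_config()
#' cfg$min_protein_length
#' @export
refinement_config <- function(min_protein_length = 50L,
                              min_unmasked_run = 30L,
                              cross_label_identity = 0.80,
                              max_seed_length = 30L,
                              min_families = 2L,
                              nls_min_positive = 3L,
                              nls_min_positive_with_py = 2L,
                              nls_long_threshold = 20L,
                              nls_min_positive_regions_long = 2L,
                              nes_min_hydrophobic = 3L,
                              nes_min_hydrophobic_fraction = 0.30,
                              positive_set = c("H", "K", "R"),
                              negative_set = c("D", "E"),
                              hydrophobic_set = c("A", "F", "I", "L", "M", "V"),
                              seg_window = 12L,
                              seg_trigger = 2.2,
                              seg_extension = 2.5,
                              prune_before_delete = TRUE,
                              rng_seed = 1L) {
  cfg <- list(
    min_protein_length = as.integer(min_protein_length),
    min_unmasked_run = as.integer(min_unmasked_run),
    cross_label_identity = cross_label_identity,
    max_seed_length = as.integer(max_seed_length),
    min_families = as.integer(min_families),
    nls_min_positive = as.integer(nls_min_positive),
    nls_min_positive_with_py = as.integer(nls_min_positive_with_py),
    nls_long_threshold = as.integer(nls_long_threshold),
    nls_min_positive_regions_long = as.integer(nls_min_positive_regions_long),
    nes_min_hydrophobic = as.integer(nes_min_hydrophobic),
    nes_min_hydrophobic_fraction = nes_min_hydrophobic_fraction,
    positive_set = toupper(positive_set),
    negative_set = toupper(negative_set),
    hydrophobic_set = toupper(hydrophobic_set),
    seg_window = as.integer(seg_window),
    seg_trigger = seg_trigger,
    seg_extension = seg_extension,
    prune_before_delete = isTRUE(prune_before_delete),
    rng_seed = as.integer(rng_seed)
  )

  counts <- c(
    "min_protein_length", "min_unmasked_run", "max_seed_length",
    "min_families", "nls_min_positive", "nls_min_positive_with_py",
    "nls_long_threshold", "nls_min_positive_regions_long",
    "nes_min_hydrophobic", "seg_window"
  )
  bad <- counts[vapply(cfg[counts], function(v) is.na(v) || v < 0L, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("refinement_config: negative or missing count(s): ",
                 paste(bad, collapse = ", ")))
  }
  for (f in c("cross_label_identity", "nes_min_hydrophobic_fraction")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("refinement_config: ", f, " must be a fraction in [0, 1]"))
    }
  }
  if (length(intersect(cfg$positive_set, cfg$negative_set)) > 0) {
    abort("refinement_config: positive_set and negative_set must be disjoint")
  }
  if (!all(c(cfg$positive_set, cfg$negative_set, cfg$hydrophobic_set) %in% AA_STANDARD)) {
    abort("refinement_config: residue classes must use the 20 standard letters")
  }
  structure(cfg, class = "refinement_config")
}

#' @export
print.refinement_config <- function(x, ...) {
  cat("<refinement_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-30s %s\n", nm, paste(val, collapse = " ")))
  }
  invisible(x)
}

as_refinement_config <- function(config) {
  if (is.null(config)) return(refinement_config())
  if (!inherits(config, "refinement_config")) {
    abort("`config` must be a refinement_config object (see refinement_config())")
  }
  config
}
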