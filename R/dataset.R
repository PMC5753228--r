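#' Filter proteins on length and unmasked-run criteria
#'
#' Keeps proteins at least `min_protein_length` residues long that retain at
#' least one run of `min_unmasked_run` consecutive unmasked residues after
#' low-complexity masking. Both boundaries are inclusive: a length-50
#' protein and a 30-residue run pass at the defaults. Removal reasons are
#' attached as the `"removed"` attribute (a tibble of `id`, `reason`).
#'
#' @param proteins A protein tibble with `masked_sequence` populated (run
#'   [mask_proteins()] first).
#' @param config A [refinement_config()].
#' @return The retained subset of `proteins`, with attribute `"removed"`.
#' @export
filter_proteins <- function(proteins, config = refinement_config()) {
  config <- as_refinement_config(config)
  validate_proteins(proteins)
  if (nrow(proteins) > 0 && any(is.na(proteins$masked_sequence))) {
    abort("filter_proteins: masked_sequence missing; run mask_proteins() first")
  }
  len_ok <- nchar(proteins$sequence) >= config$min_protein_length
  run_ok <- vapply(proteins$masked_sequence, function(m) {
    longest_unmasked_run(m) >= config$min_unmasked_run
  }, logical(1), USE.NAMES = FALSE)
  if (nrow(proteins) == 0) {
    run_ok <- logical(0)
  }
  keep <- len_ok & run_ok
  removed <- tibble(
    id = proteins$id[!keep],
    reason = if_else(!len_ok[!keep], "length", "unmasked_run")
  )
  out <- proteins[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

longest_unmasked_run <- function(masked) {
  ch <- seq_chars(masked)
  r <- rle(ch != MASK_CHAR)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else max(runs)
}

#' Split labelled proteins into nuclear and non-nuclear sets
#'
#' Applies the label-resolution policy of the dataset build: a protein with
#' experimental nuclear evidence is nuclear even if it also carries
#' experimental non-nuclear evidence; a protein that is experimentally
#' non-nuclear but carries a *less reliable* (non-experimental) nuclear
#' annotation is dropped from both sets as a likely annotation conflict;
#' remaining non-nuclear proteins form the non-nuclear set. Unlabeled
#' records are dropped with a warning.
#'
#' @param proteins A labelled protein tibble.
#' @param extra_nuclear_flags Character vector of protein ids carrying a
#'   less-reliable nuclear annotation on top of their experimental
#'   non-nuclear label.
#' @return A list with elements `nuclear` and `non_nuclear` (protein
#'   tibbles) and `dropped` (character vector of removed ids).
#' @export
resolve_labels <- function(proteins, extra_nuclear_flags = character()) {
  validate_proteins(proteins)
  unl <- proteins$label == "unlabeled"
  if (any(unl)) {
    warn(paste0("resolve_labels: dropping unlabeled protein(s): ",
                paste(proteins$id[unl], collapse = ", ")))
  }
  nuclear <- proteins[proteins$label == "nuclear", , drop = FALSE]
  nn <- proteins[proteins$label == "non_nuclear", , drop = FALSE]
  conflicted <- nn$id %in% extra_nuclear_flags
  dropped <- c(proteins$id[unl], nn$id[conflicted])
  list(
    nuclear = nuclear,
    non_nuclear = nn[!conflicted, , drop = FALSE],
    dropped = dropped
  )
}

#' Global pairwise sequence identity
#'
#' Identity of the best global (Needleman-Wunsch) alignment, defined as the
#' number of identical aligned positions divided by the alignment length
#' (gap columns included). BLOSUM62 scoring with gap opening 10 and gap
#' extension 0.5; the rare letters U, O, J are scored as X.
#'
#' @param a,b Amino-acid sequences. `a` may be a vector; `b` must be a
#'   single sequence.
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(length(b) == 1)
  a2 <- chartr("UOJ", "XXX", a)
  b2 <- chartr("UOJ", "XXX", b)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(a2),
    subject = Biostrings::AAString(b2),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Remove non-nuclear twins of nuclear proteins
#'
#' Drops every non-nuclear protein whose global pairwise sequence identity
#' to any nuclear protein exceeds `identity` (strictly greater). Such pairs
#' are as likely to reflect annotation mistakes as true signal differences,
#' so they are removed from the negative set for safety; the nuclear set is
#' never touched.
#'
#' @param non_nuclear,nuclear Protein tibbles.
#' @param identity Identity threshold as a fraction (default 0.80).
#' @return The cleaned non-nuclear tibble, with attribute `"removed"`
#'   listing the dropped ids.
#' @export
remove_cross_label_twins <- function(non_nuclear, nuclear, identity = 0.80) {
  validate_proteins(non_nuclear)
  validate_proteins(nuclear)
  if (nrow(non_nuclear) == 0 || nrow(nuclear) == 0) {
    attr(non_nuclear, "removed") <- character()
    return(non_nuclear)
  }
  alive <- rep(TRUE, nrow(non_nuclear))
  for (j in seq_len(nrow(nuclear))) {
    if (!any(alive)) break
    ids <- pairwise_identity(non_nuclear$sequence[alive], nuclear$sequence[j])
    drop_now <- ids > identity
    alive[which(alive)[drop_now]] <- FALSE
  }
  out <- non_nuclear[alive, , drop = FALSE]
  attr(out, "removed") <- non_nuclear$id[!alive]
  out
}

# Length-dependent twilight-zone identity threshold (percentage) of the
# HSSP curve, used by the hssp_distance clustering predicate: HVAL =
# percentage identity minus this curve, evaluated at the alignment length.
hssp_curve <- function(len) {
  ifelse(len <= 11, 100,
         ifelse(len > 450, 19.5,
                480 * len^(-0.32 * (1 + exp(-len / 1000)))))
}

#' Cluster nuclear proteins into sequence-similarity families
#'
#' Single-linkage clustering of the nuclear set under a pairwise-similarity
#' predicate; families are the connected components of the similarity
#' graph. Two predicates are built in:
#'
#' * `"identity_threshold"`: global pairwise identity strictly greater than
#'   `identity` (default 0.30).
#' * `"hssp_distance"`: HVAL > 0, where HVAL is the global percentage
#'   identity minus the length-dependent twilight-zone (HSSP) curve at the
#'   alignment length.
#'
#' @param nuclear A nuclear protein tibble.
#' @param method `"identity_threshold"` or `"hssp_distance"`.
#' @param identity Identity threshold for `"identity_threshold"`.
#' @return The nuclear tibble with `family_id` filled with contiguous
#'   integers starting at 0, ordered by first appearance.
#' @export
cluster_families <- function(nuclear, method = c("identity_threshold", "hssp_distance"),
                             identity = 0.30) {
  method <- match.arg(method)
  validate_proteins(nuclear)
  n <- nrow(nuclear)
  if (n == 0) abort("cluster_families: empty nuclear set")
  edges <- integer(0)
  if (n > 1) {
    for (j in seq_len(n - 1)) {
      rest <- (j + 1):n
      if (method == "identity_threshold") {
        ids <- pairwise_identity(nuclear$sequence[rest], nuclear$sequence[j])
        sim <- ids > identity
      } else {
        sim <- hval_positive(nuclear$sequence[rest], nuclear$sequence[j])
      }
      hit <- rest[sim]
      if (length(hit) > 0) edges <- c(edges, rbind(j, hit))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # relabel components 0-based in order of first appearance
  first <- match(unique(comp), comp)
  relabel <- stats::setNames(seq_along(first) - 1L, comp[first])
  nuclear$family_id <- as.integer(relabel[as.character(comp)])
  nuclear
}

hval_positive <- function(a, b) {
  a2 <- chartr("UOJ", "XXX", a)
  b2 <- chartr("UOJ", "XXX", b)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(a2),
    subject = Biostrings::AAString(b2),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  pide <- Biostrings::pid(aln, type = "PID1")
  len <- Biostrings::nchar(aln)
  (pide - hssp_curve(len)) > 0
}

#' Extract the family assignment of a clustered nuclear set
#'
#' @param nuclear A nuclear protein tibble with `family_id` set.
#' @return A tibble `id`, `family_id` covering every nuclear protein.
#' @export
family_assignment <- function(nuclear) {
  if (any(is.na(nuclear$family_id))) {
    abort("family_assignment: family_id missing; run cluster_families() first")
  }
  tibble(id = nuclear$id, family_id = as.integer(nuclear$family_id))
}

#' Prepare nuclear / non-nuclear datasets from labelled proteins
#'
#' Convenience pipeline over the dataset-preparation steps: mask
#' low-complexity regions, apply the length and unmasked-run filters,
#' resolve labels into the two sets, remove non-nuclear twins of nuclear
#' proteins, and cluster the nuclear set into families.
#'
#' @param proteins A labelled protein tibble.
#' @param config A [refinement_config()].
#' @param extra_nuclear_flags See [resolve_labels()].
#' @param cluster_method See [cluster_families()].
#' @return A list with `nuclear` (with `family_id`), `non_nuclear`, and a
#'   `report` tibble of per-step removal counts.
#' @export
prepare_datasets <- function(proteins, config = refinement_config(),
                             extra_nuclear_flags = character(),
                             cluster_method = "identity_threshold") {
  config <- as_refinement_config(config)
  masked <- mask_proteins(proteins, config)
  filtered <- filter_proteins(masked, config)
  n_filtered <- nrow(masked) - nrow(filtered)
  sets <- resolve_labels(filtered, extra_nuclear_flags)
  nn <- remove_cross_label_twins(sets$non_nuclear, sets$nuclear,
                                 identity = config$cross_label_identity)
  n_twins <- length(attr(nn, "removed"))
  nuclear <- cluster_families(sets$nuclear, method = cluster_method)
  report <- tibble(
    step = c("length_or_mask_filter", "label_conflicts", "cross_label_twins",
             "nuclear", "non_nuclear", "families"),
    n = c(n_filtered, length(sets$dropped), n_twins,
          nrow(nuclear), nrow(nn), n_distinct(nuclear$family_id))
  )
  list(nuclear = nuclear, non_nuclear = nn, report = report)
}
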