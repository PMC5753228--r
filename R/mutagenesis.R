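#' Filter seed signals for specificity, sensitivity and length
#'
#' Entry gate of the refinement protocol: a seed survives only if it
#' matches at least one nuclear protein, matches no non-nuclear protein,
#' and is at most `max_seed_length` residues long (longer signals likely
#' drag in non-functional linker residues).
#'
#' @param signals A motif tibble of seed signals.
#' @param nuclear,non_nuclear Prepared protein tibbles. The non-nuclear set
#'   must be non-empty: with no negatives the specificity constraint would
#'   be vacuous.
#' @param config A [refinement_config()].
#' @return The retained subset of `signals`, with attribute `"removed"`
#'   (tibble of `sequence`, `reason`).
#' @export
seed_filter <- function(signals, nuclear, non_nuclear, config = refinement_config()) {
  config <- as_refinement_config(config)
  validate_motifs(signals)
  if (nrow(non_nuclear) == 0) {
    abort("seed_filter: non-nuclear set is empty; the specificity constraint would be vacuous")
  }
  if (nrow(signals) == 0) {
    attr(signals, "removed") <- tibble(sequence = character(), reason = character())
    return(signals)
  }
  stats <- match_stats(signals$sequence, nuclear, non_nuclear)
  st <- stats[match(signals$sequence, stats$sequence), ]
  too_long <- nchar(signals$sequence) > config$max_seed_length
  unspecific <- st$n_non_nuclear > 0
  insensitive <- st$n_nuclear < 1
  keep <- !too_long & !unspecific & !insensitive
  reason <- dplyr::case_when(
    too_long ~ "too_long",
    unspecific ~ "matches_non_nuclear",
    insensitive ~ "no_nuclear_match",
    .default = NA_character_
  )
  removed <- tibble(sequence = signals$sequence[!keep], reason = reason[!keep])
  out <- signals[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Single-residue substitution variants of a signal
#'
#' Enumerates, for each of the L positions, all 20 amino-acid choices —
#' 20 x L candidates including the original at every position. With
#' `dedupe = TRUE` (default) the deduplicated set is returned, which has
#' exactly 19 x L + 1 members.
#'
#' @param signal A single motif sequence over the 20 standard letters.
#' @param dedupe Return unique variants (default) or the full enumeration.
#' @return Character vector of variant sequences.
#' @examples
#' substitution_variants("K")
#' length(substitution_variants("KRKRKR"))          # 19*6 + 1
#' length(substitution_variants("KRKRKR", dedupe = FALSE))  # 20*6
#' @export
substitution_variants <- function(signal, dedupe = TRUE) {
  stopifnot(length(signal) == 1, nchar(signal) >= 1)
  if (!is_standard_seq(signal)) {
    abort("substitution_variants: signal must use the 20 standard letters")
  }
  L <- nchar(signal)
  out <- character(20L * L)
  k <- 0L
  for (pos in seq_len(L)) {
    for (aa in AA_STANDARD) {
      k <- k + 1L
      v <- signal
      substr(v, pos, pos) <- aa
      out[k] <- v
    }
  }
  if (dedupe) unique(out) else out
}

#' Single-residue deletion variants of a signal
#'
#' All distinct strings obtained by deleting exactly one residue. Signals
#' of length 1 produce nothing (empty signals are never emitted).
#'
#' @param signal A single motif sequence.
#' @return Character vector of at most `nchar(signal)` distinct variants.
#' @examples
#' deletion_variants("KRK")
#' @export
deletion_variants <- function(signal) {
  stopifnot(length(signal) == 1)
  L <- nchar(signal)
  if (L < 2) return(character(0))
  unique(vapply(seq_len(L), function(i) {
    paste0(substr(signal, 1L, i - 1L), substr(signal, i + 1L, L))
  }, character(1)))
}

#' Refine seed signals by iterated in silico mutagenesis
#'
#' The core search. The candidate pool is initialised with the seeds and
#' all their single-substitution variants. Then, until no new variant can
#' be generated: (a) candidates matching any non-nuclear protein or no
#' nuclear protein are removed from the pool; (b) single-residue deletion
#' variants of the pool spawn new candidates, skipping any string already
#' proposed. On termination the pool contains only specific (zero
#' non-nuclear matches) and sensitive (at least one nuclear match)
#' signals.
#'
#' With `config$prune_before_delete = TRUE` (default) deletions are
#' generated only from candidates that survived filter (a), reading the
#' protocol literally. With `FALSE`, deletions are generated from every
#' candidate that matches no non-nuclear protein, so a still-insensitive
#' candidate may shed residues until it becomes sensitive; candidates
#' matching the negative set never spawn variants in either mode.
#'
#' @param seeds A motif tibble of seeds (normally the output of
#'   [seed_filter()]).
#' @param nuclear,non_nuclear Prepared protein tibbles.
#' @param config A [refinement_config()].
#' @param trace If `TRUE`, attach a per-iteration tibble of pool sizes as
#'   attribute `"trace"`.
#' @return A motif tibble of surviving signals. Seeds that survive keep
#'   their original evidence and source; new variants carry
#'   `evidence = "potential"`, `source = "in_silico"` and provenance
#'   columns `seed`, `substitution` (`"p<pos><letter>"` or `NA`) and
#'   `n_deletions`.
#' @export
refine_motifs <- function(seeds, nuclear, non_nuclear, config = refinement_config(),
                          trace = FALSE) {
  config <- as_refinement_config(config)
  validate_motifs(seeds)
  if (nrow(non_nuclear) == 0) {
    abort("refine_motifs: non-nuclear set is empty; the specificity constraint would be vacuous")
  }
  if (nrow(seeds) == 0) {
    out <- empty_motif_tbl()
    attr(out, "trace") <- tibble(iteration = integer(), pool = integer(), new = integer())
    return(out)
  }
  if (n_distinct(seeds$signal_type) > 1) {
    abort("refine_motifs: refine one signal type (NLS or NES) per run")
  }
  seed_seqs <- sort(unique(seeds$sequence))

  # provenance: first-wins under a deterministic (sorted) proposal order,
  # so the output is invariant to the input order of the seeds
  prov <- new.env(parent = emptyenv())
  propose <- function(s, seed, substitution, n_del) {
    if (is.null(prov[[s]])) {
      prov[[s]] <- list(seed = seed, substitution = substitution, n_deletions = n_del)
      TRUE
    } else FALSE
  }

  pool <- character(0)
  for (s in seed_seqs) {
    if (propose(s, s, NA_character_, 0L)) pool <- c(pool, s)
    L <- nchar(s)
    for (pos in seq_len(L)) {
      for (aa in AA_STANDARD) {
        v <- s
        substr(v, pos, pos) <- aa
        if (v == s) next
        if (propose(v, s, paste0("p", pos, aa), 0L)) pool <- c(pool, v)
      }
    }
  }

  # cached per-candidate specificity/sensitivity
  stat_cache <- new.env(parent = emptyenv())
  get_stats <- function(cands) {
    todo <- cands[vapply(cands, function(s) is.null(stat_cache[[s]]), logical(1))]
    if (length(todo) > 0) {
      st <- match_stats(todo, nuclear, non_nuclear)
      for (i in seq_len(nrow(st))) {
        stat_cache[[st$sequence[i]]] <- c(st$n_nuclear[i], st$n_non_nuclear[i])
      }
    }
    m <- t(vapply(cands, function(s) stat_cache[[s]], numeric(2)))
    tibble(sequence = cands, n_nuclear = m[, 1], n_non_nuclear = m[, 2])
  }

  tr <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    st <- get_stats(pool)
    ok <- st$n_non_nuclear == 0 & st$n_nuclear >= 1
    survivors <- pool[ok]
    del_source <- if (config$prune_before_delete) {
      survivors
    } else {
      pool[st$n_non_nuclear == 0]
    }
    pool <- survivors
    new <- character(0)
    for (s in sort(del_source)) {
      p <- prov[[s]]
      for (v in deletion_variants(s)) {
        if (propose(v, p$seed, p$substitution, p$n_deletions + 1L)) {
          new <- c(new, v)
        }
      }
    }
    tr[[iter]] <- tibble(iteration = iter, pool = length(pool), new = length(new))
    if (length(new) == 0) break
    pool <- c(pool, new)
    if (iter > 200L) abort("refine_motifs: iteration budget exceeded (internal error)")
  }

  out <- refined_pool_to_motifs(pool, prov, seeds)
  if (trace) attr(out, "trace") <- list_rbind(tr)
  attr(out, "iterations") <- iter
  attr(out, "signature") <- run_signature(seeds, nuclear, non_nuclear, config)
  out
}

refined_pool_to_motifs <- function(pool, prov, seeds) {
  if (length(pool) == 0) {
    out <- empty_motif_tbl()
    return(out)
  }
  pool <- sort(pool)
  type <- seeds$signal_type[1]
  rows <- map(pool, function(s) {
    p <- prov[[s]]
    seed_row <- which(seeds$sequence == s)
    if (length(seed_row) > 0) {
      # a surviving seed keeps its original annotation
      seeds[seed_row[1], , drop = FALSE] |>
        mutate(seed = s, substitution = NA_character_, n_deletions = 0L)
    } else {
      tibble(sequence = s, signal_type = type, evidence = "potential",
             source = "in_silico", seed = p$seed, substitution = p$substitution,
             n_deletions = p$n_deletions)
    }
  })
  validate_motifs(list_rbind(rows))
}

# compact reproducibility fingerprint of a refinement run
run_signature <- function(seeds, nuclear, non_nuclear, config) {
  fields <- c(
    paste(sort(seeds$sequence), collapse = ","),
    paste(sort(nuclear$id), collapse = ","),
    paste(sort(non_nuclear$id), collapse = ","),
    paste(unlist(config[order(names(config))]), collapse = ",")
  )
  sprintf("%08x", sum(utf8ToInt(paste(fields, collapse = "|")) *
                        seq_along(utf8ToInt(paste(fields, collapse = "|")))) %% 0xFFFFFFFF)
}

#' Verify the edit provenance of a refined motif
#'
#' Replays the recorded provenance of an in-silico motif: applies the
#' recorded single substitution (if any) to the seed, then checks that the
#' motif is obtainable from the result by exactly `n_deletions`
#' single-residue deletions — i.e. the motif is a subsequence of the
#' substituted seed and shorter by exactly that count.
#'
#' @param motifs A motif tibble with provenance columns.
#' @return Logical vector, one entry per row: `TRUE` when the provenance
#'   trail reproduces the motif. Rows without provenance (`seed` `NA`)
#'   return `NA`.
#' @export
replay_provenance <- function(motifs) {
  validate_motifs(motifs)
  vapply(seq_len(nrow(motifs)), function(i) {
    seed <- motifs$seed[i]
    if (is.na(seed)) return(NA)
    s <- seed
    subst <- motifs$substitution[i]
    if (!is.na(subst)) {
      m <- regmatches(subst, regexec("^p([0-9]+)([A-Z])$", subst))[[1]]
      if (length(m) != 3) return(FALSE)
      pos <- as.integer(m[2])
      if (pos < 1 || pos > nchar(s)) return(FALSE)
      substr(s, pos, pos) <- m[3]
    }
    nd <- motifs$n_deletions[i]
    target <- motifs$sequence[i]
    if (is.na(nd)) return(FALSE)
    (nchar(s) - nchar(target) == nd) && is_subsequence(target, s)
  }, logical(1))
}

is_subsequence <- function(small, big) {
  a <- seq_chars(small)
  b <- seq_chars(big)
  j <- 1L
  for (i in seq_along(b)) {
    if (j > length(a)) break
    if (b[i] == a[j]) j <- j + 1L
  }
  j > length(a)
}
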