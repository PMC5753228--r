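#' Default planted signal set for synthetic proteomes
#'
#' One NLS and one NES, each planted across two nuclear families. The NLS
#' is built around a basic K/R cluster and the NES around hydrophobic
#' residues, so that the physicochemical plausibility filters cannot veto
#' their recovery by design.
#'
#' @return A planted-motif tibble: `sequence`, `signal_type`,
#'   `carrier_families` (list column of 0-based family ids).
#' @export
default_planted_motifs <- function() {
  tibble(
    sequence = c("KRKKRSA", "LAKFLVL"),
    signal_type = c("NLS", "NES"),
    carrier_families = list(c(0L, 1L), c(2L, 3L))
  )
}

#' Generate a labelled synthetic proteome with planted signals
#'
#' Builds a toy benchmark emulating the statistical structure the catalogue
#' construction assumes: nuclear proteins come in sequence-similarity
#' families (members are point-mutated copies of a family founder), each
#' planted signal is inserted verbatim into every member of its carrier
#' families, and non-nuclear background proteins are rejection-checked to
#' be free of every planted signal. Optional homopolymer stretches exercise
#' low-complexity masking. Fully deterministic for a given `seed`.
#'
#' A planted-motif row may carry a `decorated` string (a corrupted version
#' of the signal, e.g. with one extra or substituted residue). The first
#' member of the first carrier family then receives the decorated string
#' instead of the clean signal, emulating how an experimentally annotated
#' signal is observed inside one real protein with its flanking context.
#'
#' @param n_nuclear,n_non_nuclear Numbers of nuclear and non-nuclear
#'   proteins.
#' @param n_families Number of nuclear families; nuclear proteins are
#'   distributed over them as evenly as possible.
#' @param planted_motifs A planted-motif tibble (see
#'   [default_planted_motifs()]); optional column `decorated`.
#' @param length_range Integer range of background protein lengths.
#' @param background_freqs Named numeric vector of residue frequencies over
#'   the 20 standard letters; `NULL` for uniform.
#' @param low_complexity_rate Probability that a protein receives one
#'   inserted homopolymer stretch (15-25 residues).
#' @param mutation_rate Per-position substitution rate applied to family
#'   founders to create members.
#' @param organism Organism tag attached to every record.
#' @param seed Integer seed; the only source of randomness.
#' @return A list with `proteins` (all records, labelled; nuclear rows
#'   carry their ground-truth `family_id`), `nuclear`, `non_nuclear`,
#'   `truth` (tibble `protein_id`, `motif`, `signal_type`, `start`, `end`),
#'   and `planted` (the planted-motif tibble, with `decorated` filled).
#' @export
generate_proteome <- function(n_nuclear = 24L, n_non_nuclear = 30L,
                              n_families = 6L,
                              planted_motifs = default_planted_motifs(),
                              length_range = c(60L, 120L),
                              background_freqs = NULL,
                              low_complexity_rate = 0.15,
                              mutation_rate = 0.05,
                              organism = "synthetic",
                              seed = 1L) {
  planted <- validate_planted(planted_motifs, n_families, n_nuclear)
  if (n_nuclear < n_families) abort("generate_proteome: n_nuclear < n_families")
  freqs <- normalize_freqs(background_freqs)
  withr::with_seed(as.integer(seed), {
    fam_sizes <- family_sizes(n_nuclear, n_families)
    # reserved vocabulary: nothing may occur anywhere except where planted
    reserved <- unique(c(planted$sequence, stats::na.omit(planted$decorated)))

    founders <- map_chr(fam_sizes, function(sz) {
      random_clean_sequence(length_range, freqs, reserved)
    })

    # plant plan: which strings are spliced into which nuclear protein
    nuc_ids <- sprintf("nuc%03d", seq_len(n_nuclear))
    fam_of <- rep(seq_len(n_families) - 1L, fam_sizes)
    plan <- vector("list", n_nuclear)
    for (r in seq_len(nrow(planted))) {
      fams <- planted$carrier_families[[r]]
      members <- which(fam_of %in% fams)
      dec <- planted$decorated[r]
      for (k in seq_along(members)) {
        ins <- if (k == 1L && !is.na(dec)) dec else planted$sequence[r]
        plan[[members[k]]] <- c(plan[[members[k]]], ins)
      }
    }

    nuclear_seqs <- character(n_nuclear)
    for (i in seq_len(n_nuclear)) {
      nuclear_seqs[i] <- build_nuclear_protein(
        founders[fam_of[i] + 1L], plan[[i]], reserved, planted,
        mutation_rate, low_complexity_rate, freqs
      )
    }

    nn_ids <- sprintf("cyt%03d", seq_len(n_non_nuclear))
    nn_seqs <- map_chr(seq_len(n_non_nuclear), function(i) {
      s <- random_clean_sequence(length_range, freqs, reserved)
      if (stats::runif(1) < low_complexity_rate) {
        s <- insert_homopolymer(s, reserved)
      }
      s
    })

    # generator validity self-check: planted signals never leak into the
    # background set
    for (m in reserved) {
      stopifnot(!any(grepl(m, nn_seqs, fixed = TRUE)))
    }

    nuclear <- protein_tbl(
      id = nuc_ids, sequence = nuclear_seqs, label = "nuclear",
      organism = organism, family_id = fam_of
    )
    non_nuclear <- protein_tbl(
      id = nn_ids, sequence = nn_seqs, label = "non_nuclear",
      organism = organism
    )
    truth <- truth_table(nuclear, planted)
    list(
      proteins = bind_rows(nuclear, non_nuclear),
      nuclear = nuclear,
      non_nuclear = non_nuclear,
      truth = truth,
      planted = planted
    )
  })
}

validate_planted <- function(planted, n_families, n_nuclear) {
  if (!is.data.frame(planted) || nrow(planted) == 0) {
    abort("planted_motifs must be a non-empty data frame")
  }
  req <- c("sequence", "signal_type", "carrier_families")
  if (!all(req %in% names(planted))) {
    abort(paste0("planted_motifs needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(nchar(planted$sequence) < 1)) abort("planted motifs must be non-empty")
  if (!all(vapply(planted$sequence, is_standard_seq, logical(1)))) {
    abort("planted motifs must use the 20 standard letters")
  }
  fams <- unlist(planted$carrier_families)
  if (any(fams < 0) || any(fams >= n_families)) {
    abort("carrier_families must be 0-based family ids below n_families")
  }
  if (!"decorated" %in% names(planted)) planted$decorated <- NA_character_
  as_tibble(planted)
}

normalize_freqs <- function(freqs) {
  if (is.null(freqs)) {
    return(stats::setNames(rep(1 / 20, 20), AA_STANDARD))
  }
  if (!all(AA_STANDARD %in% names(freqs))) {
    abort("background_freqs must name all 20 standard residues")
  }
  freqs <- freqs[AA_STANDARD]
  freqs / sum(freqs)
}

family_sizes <- function(n_nuclear, n_families) {
  base <- rep(n_nuclear %/% n_families, n_families)
  extra <- n_nuclear %% n_families
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

random_background <- function(len, freqs) {
  paste(sample(AA_STANDARD, len, replace = TRUE, prob = freqs), collapse = "")
}

random_clean_sequence <- function(length_range, freqs, reserved, max_tries = 100L) {
  len <- sample(seq(length_range[1], length_range[2]), 1)
  for (t in seq_len(max_tries)) {
    s <- random_background(len, freqs)
    if (!any(vapply(reserved, grepl, logical(1), x = s, fixed = TRUE))) return(s)
  }
  abort("generate_proteome: could not draw a background sequence free of planted signals")
}

insert_homopolymer <- function(s, reserved) {
  # compositionally quiet letters: never part of the basic/hydrophobic motif
  # cores, so repeats cannot collide with planted signals
  letter <- sample(c("S", "Q", "G", "P", "E", "N"), 1)
  run <- strrep(letter, sample(15:25, 1))
  pos <- sample(0:nchar(s), 1)
  out <- paste0(substr(s, 1, pos), run, substr(s, pos + 1, nchar(s)))
  for (m in reserved) {
    if (grepl(m, out, fixed = TRUE)) return(s)  # collision: skip insertion
  }
  out
}

splice_in <- function(s, insert) {
  pos <- sample(0:nchar(s), 1)
  paste0(substr(s, 1, pos), insert, substr(s, pos + 1, nchar(s)))
}

build_nuclear_protein <- function(founder, inserts, reserved, planted,
                                  mutation_rate, low_complexity_rate, freqs,
                                  max_tries = 100L) {
  for (t in seq_len(max_tries)) {
    ch <- seq_chars(founder)
    mut <- stats::runif(length(ch)) < mutation_rate
    if (any(mut)) ch[mut] <- sample(AA_STANDARD, sum(mut), replace = TRUE, prob = freqs)
    s <- paste(ch, collapse = "")
    if (stats::runif(1) < low_complexity_rate) s <- insert_homopolymer(s, reserved)
    for (ins in inserts) s <- splice_in(s, ins)
    # expected reserved content: exactly the spliced strings and their
    # reserved substrings, nothing else
    ok <- TRUE
    for (m in reserved) {
      expected <- any(vapply(inserts %||% character(0), function(ins) {
        grepl(m, ins, fixed = TRUE)
      }, logical(1)))
      if (grepl(m, s, fixed = TRUE) != expected) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(s)
  }
  abort("generate_proteome: could not assemble a nuclear protein respecting the plant plan")
}

truth_table <- function(nuclear, planted) {
  rows <- list()
  for (r in seq_len(nrow(planted))) {
    m <- planted$sequence[r]
    for (i in seq_len(nrow(nuclear))) {
      at <- gregexpr(m, nuclear$sequence[i], fixed = TRUE)[[1]]
      if (at[1] == -1) next
      rows[[length(rows) + 1]] <- tibble(
        protein_id = nuclear$id[i],
        motif = m,
        signal_type = planted$signal_type[r],
        start = as.integer(at),
        end = as.integer(at) + nchar(m) - 1L
      )
    }
  }
  out <- list_rbind(rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(protein_id = character(), motif = character(),
                  signal_type = character(), start = integer(), end = integer()))
  }
  arrange(out, .data$protein_id, .data$start, .data$motif)
}

#' Derive seed motifs (and decoys) from planted signals
#'
#' Emits the "experimentally annotated" seed list a real catalogue build
#' would start from: each planted signal decorated by one extra terminal
#' residue (`"extend"`), one substituted residue (`"substitute"`), or used
#' as-is (`"none"`), plus decoy seeds cut out of non-nuclear proteins.
#' Decorated seeds force the refinement loop to shorten or correct them;
#' decoys match the negative set and must never survive.
#'
#' @param planted A planted-motif tibble (see [default_planted_motifs()]).
#' @param decoration `"extend"`, `"substitute"` or `"none"`.
#' @param n_decoys Number of decoy seeds per signal type.
#' @param non_nuclear Non-nuclear protein tibble decoys are cut from
#'   (required when `n_decoys > 0`).
#' @param seed Integer seed.
#' @return A list with `seeds` (motif tibble, evidence `"experimental"`,
#'   source `"user"`) and `planted` (the input with the `decorated` column
#'   filled; pass this to [generate_proteome()] so each decorated seed is
#'   planted into one carrier).
#' @export
generate_seed_motifs <- function(planted, decoration = c("extend", "substitute", "none"),
                                 n_decoys = 2L, non_nuclear = NULL, seed = 1L) {
  decoration <- match.arg(decoration)
  if (!"decorated" %in% names(planted)) planted$decorated <- NA_character_
  if (n_decoys > 0 && (is.null(non_nuclear) || nrow(non_nuclear) == 0)) {
    abort("generate_seed_motifs: non_nuclear proteins are required to cut decoys from")
  }
  withr::with_seed(as.integer(seed), {
    planted$decorated <- map_chr(seq_len(nrow(planted)), function(r) {
      decorate_motif(planted$sequence[r], decoration)
    })
    seed_rows <- motif_tbl(
      sequence = planted$decorated,
      signal_type = planted$signal_type,
      evidence = "experimental",
      source = "user"
    )
    decoys <- empty_motif_tbl()
    if (n_decoys > 0) {
      for (type in unique(planted$signal_type)) {
        for (k in seq_len(n_decoys)) {
          decoys <- bind_rows(decoys, motif_tbl(
            sequence = cut_decoy(non_nuclear),
            signal_type = type, evidence = "experimental", source = "user"
          ))
        }
      }
    }
    list(seeds = bind_rows(seed_rows, decoys), planted = planted)
  })
}

decorate_motif <- function(m, decoration) {
  if (decoration == "none") return(m)
  if (decoration == "extend") {
    extra <- sample(c("W", "T", "N", "G"), 1)  # neutral flanking residue
    if (stats::runif(1) < 0.5) paste0(extra, m) else paste0(m, extra)
  } else {
    pos <- sample(nchar(m), 1)
    old <- substr(m, pos, pos)
    new <- sample(setdiff(c("W", "T", "N", "G", "S"), old), 1)
    substr(m, pos, pos) <- new
    m
  }
}

cut_decoy <- function(non_nuclear, len = 6L, max_tries = 50L) {
  for (t in seq_len(max_tries)) {
    i <- sample(nrow(non_nuclear), 1)
    s <- non_nuclear$sequence[i]
    if (nchar(s) < len) next
    at <- sample(nchar(s) - len + 1L, 1)
    d <- substr(s, at, at + len - 1L)
    if (is_standard_seq(d)) return(d)
  }
  abort("generate_seed_motifs: could not cut a decoy from the non-nuclear set")
}

#' Generate a complete synthetic benchmark
#'
#' One-call orchestrator for end-to-end runs: decorates the planted signals
#' into seeds, generates the proteome with the decorated seeds planted into
#' one carrier each, and cuts decoy seeds from the generated non-nuclear
#' set.
#'
#' @inheritParams generate_proteome
#' @inheritParams generate_seed_motifs
#' @param signal_type Keep only seeds/planted motifs of this type
#'   (`"NLS"`, `"NES"`, or `NULL` for all).
#' @return A list: `proteins`, `nuclear`, `non_nuclear`, `truth`,
#'   `planted`, `seeds`.
#' @export
generate_benchmark <- function(n_nuclear = 24L, n_non_nuclear = 30L,
                               n_families = 6L,
                               planted_motifs = default_planted_motifs(),
                               decoration = "extend", n_decoys = 2L,
                               signal_type = NULL,
                               length_range = c(60L, 120L),
                               background_freqs = NULL,
                               low_complexity_rate = 0.15,
                               mutation_rate = 0.05,
                               organism = "synthetic",
                               seed = 1L) {
  if (!is.null(signal_type)) {
    planted_motifs <- planted_motifs[planted_motifs$signal_type %in% signal_type, ,
                                     drop = FALSE]
  }
  seed <- as.integer(seed)
  # decorate first (without decoys), then generate with the decorations
  dec <- withr::with_seed(seed, {
    if (!"decorated" %in% names(planted_motifs)) {
      planted_motifs$decorated <- NA_character_
    }
    planted_motifs$decorated <- map_chr(planted_motifs$sequence, decorate_motif,
                                        decoration = decoration)
    planted_motifs
  })
  sim <- generate_proteome(
    n_nuclear = n_nuclear, n_non_nuclear = n_non_nuclear,
    n_families = n_families, planted_motifs = dec,
    length_range = length_range, background_freqs = background_freqs,
    low_complexity_rate = low_complexity_rate, mutation_rate = mutation_rate,
    organism = organism, seed = seed + 1L
  )
  seeds <- generate_seed_motifs(
    sim$planted, decoration = "none", n_decoys = n_decoys,
    non_nuclear = sim$non_nuclear, seed = seed + 2L
  )
  # decoration already applied above; use the recorded decorated strings
  seed_tbl <- motif_tbl(
    sequence = sim$planted$decorated,
    signal_type = sim$planted$signal_type,
    evidence = "experimental", source = "user"
  )
  decoys <- seeds$seeds[!(seeds$seeds$sequence %in%
                            c(sim$planted$sequence, sim$planted$decorated)), ,
                        drop = FALSE]
  sim$seeds <- bind_rows(seed_tbl, decoys)
  sim
}
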