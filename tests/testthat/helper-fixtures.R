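# Shared fixtures and independent oracles for the test suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
  }, character(1))
}

# small labelled protein tables with explicit family ids
nuc_fixture <- function(seqs, families = rep(0L, length(seqs))) {
  protein_tbl(
    id = sprintf("n%02d", seq_along(seqs)), sequence = seqs,
    label = "nuclear", family_id = as.integer(families)
  )
}

nn_fixture <- function(seqs) {
  protein_tbl(
    id = sprintf("c%02d", seq_along(seqs)), sequence = seqs,
    label = "non_nuclear"
  )
}

# brute-force Shannon entropy (bits) of every window, computed directly and
# independently of the package's rolling-count implementation
brute_window_entropy <- function(s, window) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < window) return(numeric(0))
  vapply(seq_len(n - window + 1), function(i) {
    p <- table(ch[i:(i + window - 1)]) / window
    -sum(p * log2(p))
  }, numeric(1))
}

# quadratic reference scan used to cross-check matchers (third, independent
# route: regmatches over fixed patterns)
brute_hits <- function(motifs, proteins) {
  out <- list()
  for (m in unique(motifs)) {
    for (i in seq_len(nrow(proteins))) {
      s <- proteins$sequence[i]
      L <- nchar(m)
      for (st in seq_len(max(nchar(s) - L + 1, 0))) {
        if (substr(s, st, st + L - 1) == m) {
          out[[length(out) + 1]] <- data.frame(
            protein_id = proteins$id[i], start = st, end = st + L - 1,
            motif = m, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), motif = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$protein_id, df$start, df$motif), , drop = FALSE]
}

# independent breadth-first enumeration of the refinement search space:
# follows the written protocol directly with plain set operations
bfs_refine <- function(seed_seqs, nuc_seqs, nn_seqs, prune_before_delete = TRUE,
                       max_iter = 100) {
  subst_all <- function(s) {
    out <- character(0)
    for (p in seq_len(nchar(s))) {
      for (aa in AA20) {
        v <- s
        substr(v, p, p) <- aa
        out <- c(out, v)
      }
    }
    unique(out)
  }
  del_all <- function(s) {
    if (nchar(s) < 2) return(character(0))
    unique(vapply(seq_len(nchar(s)), function(i) {
      paste0(substr(s, 1, i - 1), substr(s, i + 1, nchar(s)))
    }, character(1)))
  }
  occurs <- function(m, seqs) any(grepl(m, seqs, fixed = TRUE))
  good <- function(m) occurs(m, nuc_seqs) && !occurs(m, nn_seqs)

  pool <- unique(c(seed_seqs, unlist(lapply(seed_seqs, subst_all))))
  seen <- pool
  for (it in seq_len(max_iter)) {
    keep <- Filter(good, pool)
    src <- if (prune_before_delete) {
      keep
    } else {
      Filter(function(m) !occurs(m, nn_seqs), pool)
    }
    pool <- keep
    new <- setdiff(unique(unlist(lapply(src, del_all))), seen)
    if (length(new) == 0) return(sort(unlist(pool)))
    pool <- c(pool, new)
    seen <- c(seen, new)
  }
  stop("bfs_refine did not terminate")
}
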