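test_that("substitution variants follow the 20L / 19L+1 counting law", {
  v6 <- substitution_variants("KRKRKR", dedupe = FALSE)
  expect_length(v6, 120)                       # 20 x L enumerated
  expect_length(unique(v6), 19 * 6 + 1)        # deduplicated
  expect_setequal(substitution_variants("K"), AA20)
  withr::local_seed(3)
  for (rep in 1:20) {
    s <- random_aa(1, sample(1:12, 1))
    u <- substitution_variants(s)
    expect_length(u, 19 * nchar(s) + 1)
    expect_true(s %in% u)                      # original always included
  }
})

test_that("deletion variants are the distinct single-residue deletions", {
  expect_setequal(deletion_variants("KRK"), c("RK", "KK", "KR"))
  expect_equal(deletion_variants("AA"), "A")   # duplicates collapse
  expect_length(deletion_variants("K"), 0)     # no empty strings, ever
  withr::local_seed(4)
  for (rep in 1:20) {
    s <- random_aa(1, sample(2:12, 1))
    d <- deletion_variants(s)
    expect_lte(length(d), nchar(s))
    expect_true(all(nchar(d) == nchar(s) - 1))
  }
})

test_that("seed_filter keeps specific, sensitive, short-enough signals", {
  nuclear <- nuc_fixture(c("AAKRKKAA", "CCKRKKCC"), families = c(0L, 1L))
  nn <- nn_fixture("MMLLMMLL")
  seeds <- motif_tbl(
    c("KRKK",                      # 2 nuclear, 0 non-nuclear -> kept
      "LLMM",                      # matches a non-nuclear protein
      "WWWW",                      # matches nothing
      strrep("K", 31)),            # longer than 30 residues
    "NLS"
  )
  kept <- seed_filter(seeds, nuclear, nn)
  expect_equal(kept$sequence, "KRKK")
  removed <- attr(kept, "removed")
  expect_equal(removed$reason[removed$sequence == "LLMM"], "matches_non_nuclear")
  expect_equal(removed$reason[removed$sequence == "WWWW"], "no_nuclear_match")
  expect_equal(removed$reason[removed$sequence == strrep("K", 31)], "too_long")
})

test_that("seed_filter refuses an empty non-nuclear set", {
  nuclear <- nuc_fixture("AAKRKKAA")
  expect_error(seed_filter(motif_tbl("KRKK", "NLS"), nuclear, nn_fixture(character(0))),
               "vacuous|empty")
})

test_that("a seed whose deletion is the planted signal is recovered in generative mode", {
  # the nuclear set carries KKRK in 3 proteins / 2 families; the seed KKRKW
  # matches nothing, so only the generative reading can shorten it
  nuclear <- nuc_fixture(
    c("AAKKRKAA", "CCKKRKCC", "GGKKRKGG", "MMMMMMMM"),
    families = c(0L, 0L, 1L, 2L)
  )
  nn <- nn_fixture(c("LLLLLLLL", "FFFFFFFF"))
  seeds <- motif_tbl("KKRKW", "NLS")
  cfg_gen <- refinement_config(prune_before_delete = FALSE)
  out <- refine_motifs(seeds, nuclear, nn, cfg_gen)
  expect_true("KKRK" %in% out$sequence)
  row <- out[out$sequence == "KKRK", ]
  expect_equal(row$n_deletions, 1L)
  expect_equal(row$seed, "KKRKW")
  # the independent breadth-first oracle agrees with the whole survivor set
  oracle <- bfs_refine("KKRKW", nuclear$sequence, nn$sequence,
                       prune_before_delete = FALSE)
  expect_setequal(out$sequence, oracle)
  # under the literal pruning order the insensitive seed can never shrink
  out_lit <- refine_motifs(seeds, nuclear, nn, refinement_config())
  oracle_lit <- bfs_refine("KKRKW", nuclear$sequence, nn$sequence,
                           prune_before_delete = TRUE)
  expect_setequal(out_lit$sequence, oracle_lit)
})

test_that("a seed poisoned at every shortening yields an empty refinement", {
  nuclear <- nuc_fixture("AAAAAAAAAA")
  nn <- nn_fixture("KKKKKK")   # contains KKK and every shortening of it
  out <- refine_motifs(motif_tbl("KKK", "NLS"), nuclear, nn)
  expect_equal(nrow(out), 0)
})

test_that("an already optimal seed is a fixpoint of the refinement", {
  nuclear <- nuc_fixture("AAKRWAA")
  nn <- nn_fixture("CCRWCCKWCCKRCC")  # every deletion of KRW is non-specific
  seeds <- motif_tbl("KRW", "NLS", evidence = "experimental", source = "uniprot")
  out <- refine_motifs(seeds, nuclear, nn)
  expect_equal(out$sequence, "KRW")
  # the surviving seed keeps its original annotation
  expect_equal(out$evidence, "experimental")
  expect_equal(out$source, "uniprot")
  expect_lte(attr(out, "iterations"), 2L)  # deletions are exhausted immediately
})

test_that("refinement output is invariant to seed order and matches the oracle", {
  withr::local_seed(55)
  nuclear <- nuc_fixture(
    c("AAKRKKAA", "CCKRKKCC", "GGLRLLGG", "TTLRLLTT"),
    families = c(0L, 1L, 2L, 3L)
  )
  nn <- nn_fixture(c("MMMMWWWW", "FFFFYYYY"))
  seeds <- motif_tbl(c("KRKKW", "LRLLW"), "NLS")
  a <- refine_motifs(seeds, nuclear, nn, refinement_config(prune_before_delete = FALSE))
  b <- refine_motifs(seeds[2:1, ], nuclear, nn,
                     refinement_config(prune_before_delete = FALSE))
  expect_equal(a, b, ignore_attr = TRUE)
  oracle <- bfs_refine(seeds$sequence, nuclear$sequence, nn$sequence,
                       prune_before_delete = FALSE)
  expect_setequal(a$sequence, oracle)
})

test_that("every refined motif is specific and sensitive, checked independently", {
  sim <- generate_benchmark(seed = 202, signal_type = "NLS")
  kept <- seed_filter(sim$seeds, sim$nuclear, sim$non_nuclear)
  out <- refine_motifs(kept, sim$nuclear, sim$non_nuclear)
  expect_gt(nrow(out), 0)
  for (m in out$sequence) {
    nuc_hits <- find_matches_naive(m, sim$nuclear)
    nn_hits <- find_matches_naive(m, sim$non_nuclear)
    expect_gte(length(unique(nuc_hits$protein_id)), 1)
    expect_equal(nrow(nn_hits), 0)
  }
})

test_that("provenance replay reproduces every in-silico motif", {
  sim <- generate_benchmark(seed = 203, signal_type = "NLS", decoration = "substitute")
  kept <- seed_filter(sim$seeds, sim$nuclear, sim$non_nuclear)
  out <- refine_motifs(kept, sim$nuclear, sim$non_nuclear)
  insilico <- out[out$source == "in_silico", ]
  expect_gt(nrow(insilico), 0)
  expect_true(all(replay_provenance(insilico)))
  # every output equals some seed after <= 1 substitution and >= 0 deletions
  expect_true(all(insilico$seed %in% kept$sequence))
  expect_true(all(insilico$n_deletions >= 0))
})

test_that("replay_provenance rejects a falsified trail", {
  m <- motif_tbl("KRK", "NLS", evidence = "potential", source = "in_silico",
                 seed = "WWWW", substitution = NA, n_deletions = 1L)
  expect_false(replay_provenance(m))
})
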