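test_that("length and unmasked-run filters apply at their stated boundaries", {
  withr::local_seed(5)
  seqs <- c(
    short = random_aa(1, 49),                  # below the length floor
    atfloor = random_aa(1, 50),                # exactly at it
    run29 = paste0(random_aa(1, 29), strrep("K", 42), random_aa(1, 29)),
    run30 = paste0(random_aa(1, 30), strrep("K", 40), random_aa(1, 30))
  )
  prot <- protein_tbl(names(seqs), unname(seqs))
  # control the mask directly so the run lengths are exact
  prot$masked_sequence <- c(
    seqs[["short"]],
    seqs[["atfloor"]],
    paste0(substr(seqs[["run29"]], 1, 29), strrep("x", 42), substr(seqs[["run29"]], 72, 100)),
    paste0(substr(seqs[["run30"]], 1, 30), strrep("x", 40), substr(seqs[["run30"]], 71, 100))
  )
  out <- filter_proteins(prot)
  expect_setequal(out$id, c("atfloor", "run30"))
  removed <- attr(out, "removed")
  expect_equal(removed$reason[removed$id == "short"], "length")
  expect_equal(removed$reason[removed$id == "run29"], "unmasked_run")
})

test_that("filter_proteins demands masking first and is idempotent", {
  prot <- protein_tbl("p1", random_aa(1, 60, seed = 1))
  expect_error(filter_proteins(prot), "mask_proteins")
  masked <- mask_proteins(prot)
  once <- filter_proteins(masked)
  twice <- filter_proteins(once)
  expect_equal(once$id, twice$id)
  expect_true(all(once$id %in% masked$id))
})

test_that("label resolution follows the nuclear-priority policy", {
  prot <- protein_tbl(
    c("both", "conflict", "plain_nn", "nuc", "nolabel"),
    random_aa(5, 60, seed = 2),
    label = c("nuclear", "non_nuclear", "non_nuclear", "nuclear", "unlabeled")
  )
  expect_warning(
    sets <- resolve_labels(prot, extra_nuclear_flags = "conflict"),
    "nolabel"
  )
  # experimental nuclear evidence wins even with non-nuclear evidence
  expect_true(all(c("both", "nuc") %in% sets$nuclear$id))
  # non-nuclear with a less-reliable nuclear flag is dropped from both sets
  expect_false("conflict" %in% c(sets$nuclear$id, sets$non_nuclear$id))
  expect_true("conflict" %in% sets$dropped)
  expect_equal(sets$non_nuclear$id, "plain_nn")
  expect_length(intersect(sets$nuclear$id, sets$non_nuclear$id), 0)
})

test_that("pairwise identity is identities over alignment length", {
  expect_equal(pairwise_identity("KKKK", "KKKK"), 1)
  # same length, one mismatch: gap-free global alignment dominates
  expect_equal(pairwise_identity("KKKA", "KKKC"), 0.75)
  # unrelated sequences land far below the twin threshold
  withr::local_seed(8)
  a <- random_aa(1, 60)
  b <- random_aa(1, 60)
  expect_lt(pairwise_identity(a, b), 0.4)
})

test_that("cross-label twins above the identity threshold are removed", {
  withr::local_seed(13)
  base <- random_aa(1, 60)
  # 85% identical: mutate 9 of 60 positions
  twin <- base
  for (p in seq(3, 59, by = 7)) substr(twin, p, p) <- setdiff(AA20, substr(twin, p, p))[1]
  unrelated <- random_aa(1, 60)
  nuclear <- nuc_fixture(base)
  nn <- nn_fixture(c(base, twin, unrelated))
  out <- remove_cross_label_twins(nn, nuclear, identity = 0.80)
  expect_equal(out$id, "c03")        # identical and 85%-twin removed
  expect_setequal(attr(out, "removed"), c("c01", "c02"))
  # exhaustive post-condition: nothing retained is a twin of any nuclear
  for (i in seq_len(nrow(out))) {
    expect_true(all(pairwise_identity(out$sequence[i], nuclear$sequence[1]) <= 0.80))
  }
  # and the nuclear set is untouched by construction (function never edits it)
})

test_that("single-linkage families equal connected components of the similarity graph", {
  withr::local_seed(21)
  h1 <- random_aa(1, 30); h2 <- random_aa(1, 30)
  h3 <- random_aa(1, 30); h4 <- random_aa(1, 30)
  chainA <- paste0(h1, h2)   # A~B share h2, B~C share h3, A!~C
  chainB <- paste0(h2, h3)
  chainC <- paste0(h3, h4)
  lone <- random_aa(1, 60)
  dup <- chainA
  nuclear <- protein_tbl(
    c("A", "B", "C", "lone", "dup"),
    c(chainA, chainB, chainC, lone, dup), label = "nuclear"
  )
  got <- cluster_families(nuclear, method = "identity_threshold", identity = 0.30)

  # brute-force oracle: connected components over the same predicate
  n <- nrow(nuclear)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        adj[i, j] <- adj[j, i] <-
          pairwise_identity(nuclear$sequence[i], nuclear$sequence[j]) > 0.30
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    frontier <- i
    comp[i] <- cid
    while (length(frontier) > 0) {
      nxt <- which(adj[frontier[1], ] & is.na(comp))
      comp[nxt] <- cid
      frontier <- c(frontier[-1], nxt)
    }
    cid <- cid + 1L
  }
  # same partition (label-invariant comparison)
  expect_equal(
    split(nuclear$id, got$family_id)[order(vapply(split(nuclear$id, got$family_id), `[[`, "", 1))],
    split(nuclear$id, comp)[order(vapply(split(nuclear$id, comp), `[[`, "", 1))],
    ignore_attr = TRUE
  )
  # chain collapses into one family under single linkage
  expect_length(unique(got$family_id[got$id %in% c("A", "B", "C")]), 1)
  expect_false(got$family_id[got$id == "lone"] %in%
                 got$family_id[got$id %in% c("A", "B", "C")])
  # ids contiguous from zero and total
  expect_setequal(unique(got$family_id), seq_len(length(unique(got$family_id))) - 1L)
  expect_false(any(is.na(got$family_id)))
})

test_that("the HSSP-distance predicate clusters identical sequences together", {
  withr::local_seed(31)
  s <- random_aa(1, 80)
  other <- random_aa(1, 80)
  nuclear <- protein_tbl(c("a", "b", "c"), c(s, s, other), label = "nuclear")
  got <- cluster_families(nuclear, method = "hssp_distance")
  expect_equal(got$family_id[1], got$family_id[2])
  expect_false(got$family_id[3] == got$family_id[1])
  expect_error(cluster_families(nuclear, method = "nope"), "arg")
})

test_that("prepare_datasets chains the preparation steps", {
  withr::local_seed(17)
  fam1 <- random_aa(1, 70)
  prot <- protein_tbl(
    c("n1", "n2", "c1", "c2", "tiny"),
    c(fam1, fam1, random_aa(1, 70), fam1, random_aa(1, 30)),
    label = c("nuclear", "nuclear", "non_nuclear", "non_nuclear", "non_nuclear")
  )
  prep <- prepare_datasets(prot)
  expect_setequal(prep$nuclear$id, c("n1", "n2"))
  expect_equal(prep$non_nuclear$id, "c1")   # c2 is a twin, tiny is short
  expect_false(any(is.na(prep$nuclear$family_id)))
  expect_true(all(c("nuclear", "non_nuclear", "families") %in% prep$report$step))
})
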