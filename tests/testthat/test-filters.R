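test_that("the NLS charge filter applies the positive-count rule", {
  out <- nls_charge_filter(c("KRKRK", "KAAARAAPY", "KDKDAA"))
  expect_equal(out$pass, c(TRUE, TRUE, FALSE))
  # KAAARAAPY has only 2 positives but contains the PY-NLS RAAPY
  expect_equal(out$reason[3], "too_few_positive_residues")
})

test_that("the charge-region rule cancels positives against adjacent negatives", {
  # RKKDDDA: 3 positives, but the single charged run RKKDDD has net 0
  out <- nls_charge_filter("RKKDDDA")
  expect_false(out$pass)
  expect_equal(out$reason, "no_net_positive_region")
  # separating the negatives restores a net-positive run
  expect_true(nls_charge_filter("RKKADDD")$pass)
})

test_that("long NLS need two net-positive regions", {
  one_region <- paste0(strrep("K", 6), strrep("A", 14))   # length 20, 1 run
  two_regions <- paste0("KKK", strrep("A", 14), "KKK")    # length 20, 2 runs
  expect_false(nls_charge_filter(one_region)$pass)
  expect_true(nls_charge_filter(two_regions)$pass)
  # just below the length threshold one region suffices
  expect_true(nls_charge_filter(paste0(strrep("K", 6), strrep("A", 13)))$pass)
})

test_that("the NES hydrophobicity filter applies count and fraction rules", {
  out <- nes_hydrophobicity_filter(c("LALKLL", "LLKKKKKKKK", "LLLKKKKKKK"))
  expect_equal(out$pass, c(TRUE, FALSE, TRUE))   # exactly 30% passes
  expect_equal(out$reason[2], "too_few_hydrophobic_residues")
  expect_false(nes_hydrophobicity_filter("LLLLKKKKKKKKKKKKKK")$pass)  # 4/18 < 30%
})

test_that("family_filter keeps motifs spanning enough families", {
  nuclear <- nuc_fixture(
    c("AKRKA", "CKRKC", "GKRKG", "ALLLA"),
    families = c(0L, 0L, 1L, 2L)
  )
  m <- motif_tbl(c("KRK", "LLL", "WWW"), "NLS")
  kept <- family_filter(m, nuclear, min_families = 2)
  expect_equal(kept$sequence, "KRK")          # LLL: 1 family; WWW: 0 proteins
})

test_that("redundancy removal keeps only substring-minimal motifs", {
  m <- motif_tbl(c("KRK", "AKRKA"), "NLS")
  expect_equal(redundancy_removal(m)$sequence, "KRK")
  both <- motif_tbl(c("KRK", "LML"), "NLS")
  expect_setequal(redundancy_removal(both)$sequence, c("KRK", "LML"))
})

test_that("duplicate motifs collapse to the strongest evidence", {
  m <- dplyr::bind_rows(
    motif_tbl("KRK", "NLS", evidence = "potential", source = "in_silico"),
    motif_tbl("KRK", "NLS", evidence = "experimental", source = "uniprot")
  )
  out <- redundancy_removal(m)
  expect_equal(nrow(out), 1)
  expect_equal(out$evidence, "experimental")
})

test_that("redundancy removal is idempotent and permutation-invariant", {
  withr::local_seed(77)
  pool <- unique(c(random_aa(15, 4), random_aa(10, 6), random_aa(5, 8), "KRK", "AKRKA"))
  m <- motif_tbl(pool, "NLS")
  base <- redundancy_removal(m)
  expect_equal(redundancy_removal(base), base)
  for (rep in 1:50) {
    perm <- m[sample(nrow(m)), ]
    expect_equal(redundancy_removal(perm), base)
  }
  # no retained motif is a proper substring of another retained motif
  s <- base$sequence
  for (i in seq_along(s)) {
    for (j in seq_along(s)) {
      if (i != j) expect_false(grepl(s[i], s[j], fixed = TRUE) && nchar(s[i]) < nchar(s[j]))
    }
  }
})

test_that("catalogue assembly binds filters to in-silico motifs only", {
  nuclear <- nuc_fixture(
    c("AAKRKKAA", "CCKRKKCC", "GGLKLAAGG", "TTWAWAWTT"),
    families = c(0L, 0L, 1L, 2L)
  )
  nn <- nn_fixture(c("MMMMMMM", "FFFFFFF"))
  # original: specific+sensitive but only 1 family, and charge-poor — still kept
  originals <- motif_tbl("WAWAW", "NLS", evidence = "experimental", source = "uniprot")
  refined <- dplyr::bind_rows(
    # in-silico, passes charge, spans 2 proteins of 1 family -> family filter drops it
    motif_tbl("KRKK", "NLS", evidence = "potential", source = "in_silico",
              seed = "KRKKW", n_deletions = 1L),
    # in-silico, hydrophobic not basic -> charge filter drops it
    motif_tbl("LKLAA", "NLS", evidence = "potential", source = "in_silico",
              seed = "LKLAAW", n_deletions = 1L)
  )
  cat <- assemble_catalogue(originals, refined, nuclear, nn)
  expect_equal(tidy(cat)$sequence, "WAWAW")
  expect_equal(cat$report$n[cat$report$step == "in_silico_kept"], 0)
})

test_that("assembly applies redundancy across originals and refined motifs", {
  nuclear <- nuc_fixture(
    c("AAKRKKAA", "CCKRKKCC", "GGKRKKGG"),
    families = c(0L, 1L, 2L)
  )
  nn <- nn_fixture("MMMMMMM")
  originals <- motif_tbl("AKRKK", "NLS", evidence = "experimental", source = "uniprot")
  refined <- motif_tbl("KRKK", "NLS", evidence = "potential", source = "in_silico",
                       seed = "AKRKK", n_deletions = 1L)
  cat <- assemble_catalogue(originals, refined, nuclear, nn)
  # the refined motif is a substring of the original: only the shorter lives
  expect_equal(tidy(cat)$sequence, "KRKK")
})

test_that("assembly refuses mixed signal types", {
  nuclear <- nuc_fixture("AAKRKKAA")
  nn <- nn_fixture("MMMM")
  expect_error(
    assemble_catalogue(
      motif_tbl("KRKK", "NLS"),
      motif_tbl("LLLAL", "NES", evidence = "potential", source = "in_silico"),
      nuclear, nn
    ),
    "mixed"
  )
})

test_that("every catalogue motif is specific and sensitive with full annotation", {
  sim <- generate_benchmark(seed = 301)
  for (ty in c("NLS", "NES")) {
    cat <- build_catalogue(sim$seeds[sim$seeds$signal_type == ty, ],
                           sim$nuclear, sim$non_nuclear)
    m <- tidy(cat)
    expect_gt(nrow(m), 0)
    expect_true(all(m$n_non_nuclear == 0))
    expect_true(all(m$n_nuclear >= 1))
    ins <- m[m$source == "in_silico", ]
    expect_true(all(ins$n_families >= 2))
    phys <- if (ty == "NLS") nls_charge_filter else nes_hydrophobicity_filter
    expect_true(all(phys(ins$sequence)$pass))
    g <- glance(cat)
    expect_equal(g$n_motifs, nrow(m))
  }
})
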