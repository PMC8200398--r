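test_that("compile_sites finds interior P1 sites and honours P1' exclusions", {
  trypsin <- one_rule_panel(c("K", "R"))
  expect_equal(compile_sites("AKA", trypsin), 2L)
  expect_equal(compile_sites("AAAA", trypsin), integer())
  # a P1 residue at the C-terminus produces no site
  expect_equal(compile_sites("AAK", trypsin), integer())
  # P1' exclusion blocks the cut only when the blocking residue follows
  blocked <- one_rule_panel("K", excl = "P")
  expect_equal(compile_sites("AKPA", blocked), integer())
  expect_equal(compile_sites("AKAP", blocked), 2L)
  # a second rule without the exclusion re-enables the cut
  both <- enzyme_panel(
    cleavage_rule("a", NA, "K", "P"),
    cleavage_rule("b", NA, "K"),
    name = "both"
  )
  expect_equal(compile_sites("AKPA", both), 2L)
})

test_that("the lectin digest reproduces the published fragment inventory", {
  d <- digest(lectin_record())
  expect_equal(nrow(d), 88L)
  expect_equal(length(compile_sites(LECTIN_SEQ, gi_panel())), 87L)
  s <- classify_lengths(d)
  expect_equal(c(s$n_free, s$n_2_5, s$n_gt5), c(30L, 45L, 13L))
  expect_equal(s$pct_free, 34.09)
  expect_equal(s$pct_gt5, 14.77)
  # 100 * 45 / 88 rounded half away from zero; the published 51.13 is a
  # truncation of the same quantity
  expect_equal(s$pct_2_5, 51.14)
  # the 2-5 multiset equals the published 45 peptides with multiplicity
  m <- fragment_multiset(d, 2, 5)
  expect_equal(sort(m), sort(PUBLISHED_2_5))
  expect_equal(sum(m == "AF"), 2L)
  expect_equal(sum(m == "SIK"), 2L)
  expect_equal(length(fragment_multiset(d, 1, 1)), 30L)
  expect_equal(length(fragment_multiset(d, 1, nchar(LECTIN_SEQ))), 88L)
})

test_that("digestion partitions the parent and is exhaustive", {
  for (seed in 1:5) {
    prot <- random_protein(1, 120, seed = seed)
    d <- digest(prot)
    # partition: contiguous half-open intervals covering [0, n)
    expect_equal(d$start[1], 0L)
    expect_equal(d$end[nrow(d)], nchar(prot$sequence))
    expect_equal(d$start[-1], d$end[-nrow(d)])
    expect_identical(paste(d$sequence, collapse = ""), prot$sequence)
    expect_identical(substring(prot$sequence, d$start + 1, d$end), d$sequence)
    # completeness: no fragment has a cut-eligible bond before its last residue
    for (frag in d$sequence) {
      interior <- compile_sites(frag, gi_panel())
      expect_length(interior, 0L)
    }
  }
})

test_that("an empty panel releases the whole sequence as one fragment", {
  empty <- enzyme_panel(name = "none")
  d <- digest(lectin_record(), empty)
  expect_equal(nrow(d), 1L)
  expect_identical(d$sequence, LECTIN_SEQ)
})

test_that("engine agrees with the independent per-bond oracle on 1000 seeded 60-mers", {
  prots <- random_protein(1000, 60, seed = 2024)
  d <- digest(prots)
  frag_by_parent <- split(d$sequence, d$parent_id)
  for (i in seq_len(nrow(prots))) {
    expect_identical(
      frag_by_parent[[prots$id[i]]],
      oracle_digest(prots$sequence[i], GI_CUT_SET)
    )
  }
})

test_that("enlarging the cut set never decreases the fragment count", {
  prots <- random_protein(50, 80, seed = 99)
  for (k in seq_len(length(GI_CUT_SET) - 1)) {
    smaller <- one_rule_panel(GI_CUT_SET[seq_len(k)])
    larger <- one_rule_panel(GI_CUT_SET[seq_len(k + 1)])
    n_small <- nrow(digest(prots, smaller))
    n_large <- nrow(digest(prots, larger))
    expect_gte(n_large, n_small)
  }
})

test_that("classify_lengths handles degenerate digests", {
  one <- tibble::tibble(parent_id = "p", start = 0L, end = 7L,
                        length = 7L, sequence = "AAAAAAA")
  s <- classify_lengths(one)
  expect_equal(c(s$n_free, s$n_2_5, s$n_gt5), c(0L, 0L, 1L))
  expect_equal(c(s$pct_free, s$pct_2_5, s$pct_gt5), c(0, 0, 100))
  expect_error(classify_lengths(one[0, ]), "nothing to classify",
               class = "tp_validation")
})

test_that("glance and tidy expose the digest as tibbles; panel config round-trips", {
  d <- digest(lectin_record(), read_panel(tp_file("panel_gi.yaml")))
  expect_equal(nrow(d), 88L)
  g <- glance(d)
  expect_equal(g$panel, "gi_default")
  expect_equal(g$n_total, 88L)
  expect_s3_class(tidy(d), "tbl_df")
  p <- ggplot2::autoplot(d)
  expect_s3_class(p, "ggplot")
})
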