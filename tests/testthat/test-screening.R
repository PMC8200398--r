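fixture_affinity <- function() read_affinity(tp_file("affinity_hpepdock.tsv"))
fixture_docking <- function() read_docking(tp_file("docking_pparg.tsv"))

test_that("the affinity loader preserves order and validates rows", {
  aff <- fixture_affinity()
  expect_equal(nrow(aff), 45L)
  expect_equal(aff$peptide[1], "PEW")
  expect_equal(aff$hpepdock_score[1], -157.801)
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("peptide\thpepdock_score", empty)
  expect_error(read_affinity(empty), "no records", class = "tp_validation")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\thpepdock_score", "AF\t-91.54", "SIK\tnot_a_number"), bad)
  suppressWarnings(
    expect_error(read_affinity(bad), "line 3", class = "tp_validation")
  )
})

test_that("the high-affinity filter keeps scores strictly below the threshold", {
  aff <- fixture_affinity()
  hi <- filter_high_affinity(aff)
  expect_equal(hi$peptide,
               c("PEW", "VSVGF", "PSQK", "TTPW", "ATSF", "ITY", "TSF"))
  expect_equal(nrow(filter_high_affinity(aff, threshold = -160)), 0L)
  expect_equal(nrow(filter_high_affinity(aff, threshold = 0)), 45L)
  # output size is monotone non-increasing as the threshold decreases
  thresholds <- seq(0, -170, by = -5)
  sizes <- vapply(thresholds,
                  function(t) nrow(filter_high_affinity(aff, t)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("hydrophobic fraction counts the stated residue set and is reversal-invariant", {
  expect_equal(hydrophobic_fraction("TTPW"), 0.5)
  expect_equal(hydrophobic_fraction("VSVGF"), 0.6)
  expect_equal(hydrophobic_fraction("AAAA"), 1.0)
  peps <- fragment_multiset(digest(random_protein(5, 60, seed = 11)), 2, 5)
  h <- hydrophobic_fraction(peps)
  expect_true(all(h >= 0 & h <= 1))
  reversed <- vapply(strsplit(peps, ""),
                     function(x) paste(rev(x), collapse = ""), character(1))
  expect_equal(hydrophobic_fraction(reversed), h)
})

test_that("transporter class and proline flags follow the absorbability rules", {
  expect_equal(transporter_class(c("A", "PK", "PEW", "TTPW", "VSVGF", "EAEAAASAN")),
               c("AA_TRANSPORT", "PEPT", "PEPT", "SOPT", "SOPT", "NONE"))
  expect_true(contains_proline("TTPW"))
  expect_false(contains_proline("ITY"))
  expect_true(contains_proline("PPP"))
})

test_that("docking contacts intersect the binding site as published", {
  ann <- annotate_docking(fixture_docking())
  row <- function(p) which(ann$ligand == p)
  expect_equal(ann$site_contacts[[row("TTPW")]], "Cys285")
  expect_true(ann$in_site[row("TTPW")])
  expect_equal(ann$site_contacts[[row("PSQK")]], character())
  expect_false(ann$in_site[row("PSQK")])
  # the four in-site peptides among the seven docked high-affinity ones
  expect_setequal(ann$ligand[ann$in_site], c("ITY", "TSF", "TTPW", "ATSF"))
  # control ligand G3335 touches the site only through Ser289
  ctrl <- annotate_docking(read_controls())
  expect_equal(ctrl$site_contacts[[which(ctrl$name == "G3335")]], "Ser289")
  # residue comparison is case-insensitive
  up <- annotate_docking(fixture_docking(), sites = toupper(pparg_site_set()))
  expect_equal(up$in_site, ann$in_site)
})

test_that("candidate triage on the bundled tables selects TTPW and ITY", {
  scr <- rank_candidates(fixture_affinity(), fixture_docking())
  expect_setequal(scr$peptide[scr$candidate], c("TTPW", "ITY"))
  expect_equal(sum(scr$high_affinity), 7L)
  # candidates are a subset of high-affinity in-site peptides
  expect_true(all(scr$high_affinity[scr$candidate]))
  expect_true(all(scr$in_site[scr$candidate]))
  # sorted by binding energy, most negative first, undocked last
  docked <- scr$binding_energy[!is.na(scr$binding_energy)]
  expect_equal(docked, sort(docked))
  expect_true(all(is.na(scr$binding_energy[(length(docked) + 1):nrow(scr)])))
  # the weakest-control energy clause prunes TSF and ATSF despite site contact
  expect_false(any(scr$candidate[scr$peptide %in% c("TSF", "ATSF")]))
  expect_equal(attr(scr, "energy_cutoff"), -5.64)
})

test_that("candidate triage validates inputs and handles empty docking", {
  aff <- fixture_affinity()
  stray <- tibble::tibble(ligand = "QQQQ", binding_energy = -9,
                          contacts = list("Cys285"))
  expect_error(rank_candidates(aff, stray), "QQQQ", class = "tp_validation")
  none <- fixture_docking()[0, ]
  scr <- rank_candidates(aff, none)
  expect_equal(sum(scr$candidate), 0L)
  expect_equal(nrow(scr), 45L)
})
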