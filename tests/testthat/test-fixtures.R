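test_that("the catalog is deterministic and every fixture parses and triages", {
  expect_identical(fixture_catalog(), fixture_catalog())
  for (nm in fixture_catalog()) {
    fx <- build_fixture(nm)
    entries <- parse_cif(fx$cif)
    expect_equal(length(entries), 1, label = nm)
    expect_s3_class(triage(entries[[1]]), "entry_flags")
    if (!is.na(fx$expected)) {
      expect_silent(parse_smiles(fx$expected))
    }
  }
})

test_that("fixture geometries separate bonds from non-bonds cleanly", {
  for (nm in fixture_catalog()) {
    rep <- fixture_geometry_report(nm)
    expect_equal(nrow(rep), 0, label = nm)
  }
})

test_that("fixture tags collectively cover every pipeline branch", {
  tags <- unlist(lapply(fixture_catalog(), function(nm) build_fixture(nm)$tags))
  needed <- c("aromatic", "coordination", "carbonyl", "borane", "metallocene",
              "ionic", "disorder", "special_position", "zprime2",
              "polymer_1d", "polymer_2d", "racemic", "sohncke", "meso",
              "haloanion", "organometallic", "solvent", "chiral")
  expect_true(all(needed %in% tags))
})

test_that("fixtures materialize to disk with a manifest", {
  dir <- tempfile("fixtures")
  manifest <- write_fixtures(dir)
  expect_equal(nrow(manifest), length(fixture_catalog()))
  expect_true(file.exists(file.path(dir, "ferrocene.cif")))
  expect_true(file.exists(file.path(dir, "expectations.tsv")))
  ref <- parse_cif(file.path(dir, "nacl.cif"), is_file = TRUE)[[1]]
  expect_equal(length(ref$symops), 192)
})
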