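test_that("identical canonical structures classify as identical", {
  for (s in c("CCO", "c1ccccc1", "[Na+].[Cl-]", "C[C@H](N)C(=O)O")) {
    expect_identical(classify_discrepancy(s, s), "identical")
  }
  expect_identical(classify_discrepancy("CCO", "OCC"), "identical")
})

test_that("nitro and related group conventions are recognized", {
  expect_identical(classify_discrepancy("CN(=O)=O", "C[N+](=O)[O-]"),
                   "nitro_representation")
  expect_identical(classify_discrepancy("CCN(=O)=O", "CC[N+](=O)[O-]"),
                   "nitro_representation")
})

test_that("chirality differences report their direction", {
  expect_identical(classify_discrepancy("C[C@H](N)C(=O)O", "CC(N)C(=O)O"),
                   "missing_chirality_in_other")
  expect_identical(classify_discrepancy("CC(N)C(=O)O", "C[C@H](N)C(=O)O"),
                   "missing_chirality_in_ours")
})

test_that("racemate doubling matches a single-molecule representation", {
  s <- "N[C@H](F)[C@@H](Cl)O"
  doubled <- paste(s, invert_stereo_marks(s), sep = ".")
  expect_identical(classify_discrepancy(doubled, s), "racemate_representation")
})

test_that("charge, aromaticity and bond-order differences rank correctly", {
  expect_identical(classify_discrepancy("CC(=O)O", "CC(=O)[O-]"),
                   "charge_settings")
  expect_identical(classify_discrepancy("c1ccccc1", "C1=CC=CC=C1"),
                   "aromaticity_settings")
  expect_identical(classify_discrepancy("CC=CC", "CCC=C"), "bond_orders")
})

test_that("structural categories catch counts and composition", {
  expect_identical(classify_discrepancy("CCO", "CCN"), "chemical_composition")
  expect_identical(classify_discrepancy("CCO.CCO.O", "CCO.O"),
                   "stoichiometry")
  expect_identical(classify_discrepancy("C1CCCCC1", "CCCCCC"), "ring_count")
  expect_identical(classify_discrepancy("CCO.O", "CCO"),
                   "missing_O_moieties_in_other")
  expect_identical(classify_discrepancy("CCO.N", "CCO"),
                   "missing_moieties_in_other")
  expect_identical(classify_discrepancy("CCO", "CCO.N"),
                   "missing_moieties_in_ours")
  expect_identical(classify_discrepancy("CCCO", "CCO"), "missing_C_in_other")
})

test_that("unparseable input maps to other_reason", {
  expect_identical(classify_discrepancy("C1CC", "CCO"), "other_reason")
})

test_that("severity is monotone under injected composition changes", {
  pairs <- list(c("CCO", "OCC"),
                c("CN(=O)=O", "C[N+](=O)[O-]"),
                c("CC(=O)O", "CC(=O)[O-]"))
  sev <- function(cat) match(cat, DISCREPANCY_CATEGORIES)
  for (p in pairs) {
    base <- sev(classify_discrepancy(p[1], p[2]))
    bumped <- sev(classify_discrepancy(paste0(p[1], "CP"), p[2]))
    expect_true(bumped >= base, label = paste(p, collapse = " vs "))
  }
})

test_that("summaries count categories in severity order", {
  s <- summarize_discrepancies(character(0))
  expect_true(all(s$count == 0))
  s <- summarize_discrepancies(c("identical", "identical",
                                 "chemical_composition",
                                 "chemical_composition"))
  expect_equal(s$percent[s$category == "identical"], 50)
  expect_equal(s$percent[s$category == "chemical_composition"], 50)
  s <- summarize_discrepancies(rep("identical", 7))
  expect_equal(s$percent[1], 100)
  expect_identical(s$category, DISCREPANCY_CATEGORIES)
})
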