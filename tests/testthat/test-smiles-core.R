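test_that("parsing handles charges, moieties and positions of errors", {
  g <- parse_smiles("[Na+].[Cl-]")
  expect_equal(max(mg_components(g)), 2)
  expect_equal(sort(g$atoms$charge), c(-1L, 1L))

  expect_error(parse_smiles("C1CC"), "unmatched ring")
  expect_error(parse_smiles("C(C"), "unclosed branch")
  expect_error(parse_smiles("[Zq]"), "position 1")
  expect_error(parse_smiles("C%1C"), "%nn")

  g <- parse_smiles("[13CH4]")   # isotope digits are accepted and ignored
  expect_equal(g$atoms$hcount, 4L)
})

test_that("implicit hydrogens follow the organic-subset valence rules", {
  h <- function(s) parse_smiles(s)$atoms$hcount
  expect_equal(h("C"), 4L)
  expect_equal(h("CC"), c(3L, 3L))
  expect_equal(h("C=O"), c(2L, 0L))
  expect_equal(h("c1ccccc1"), rep(1L, 6))
  expect_equal(h("c1ccncc1")[4], 0L)
  expect_equal(h("CN(=O)=O")[2], 0L)    # pentavalent N
  expect_equal(h("S(=O)(=O)(O)O")[1], 0L)
})

test_that("writing matches the bracket and hydrogen conventions", {
  expect_equal(write_smiles(parse_smiles("C")), "C")
  r <- run_fixture("en_nickel")
  expect_canon_equal(r$smiles, "[Ni]1[NH2]CC[NH2]1")
  r <- run_fixture("ferrocene")
  expect_canon_equal(
    r$smiles,
    "[Fe]12345678([cH]9[cH]1[cH]2[cH]3[cH]49)[cH]1[cH]5[cH]6[cH]7[cH]81")
})

test_that("parse-write round trips preserve structure", {
  cases <- c("CCO", "c1ccc2ccccc2c1", "C[C@H](N)C(=O)O",
             "[Cu]([n]1ccccc1)([n]1ccccc1)(Cl)Cl",
             "O=C1C=CC(=O)C=C1", "[Na+].[Cl-]",
             "[P](F)(F)(F)(F)(F)[F-]", "C#N", "CC(=O)[O-]")
  for (s in cases) {
    c1 <- canon_smiles(s)
    expect_identical(canon_smiles(c1), c1, label = s)
    g1 <- parse_smiles(s); g2 <- parse_smiles(c1)
    expect_equal(sort(table(g1$atoms$element)), sort(table(g2$atoms$element)))
    expect_equal(sum(g1$atoms$hcount), sum(g2$atoms$hcount))
    expect_equal(sort(g1$atoms$charge), sort(g2$atoms$charge))
    expect_equal(nrow(g1$bonds), nrow(g2$bonds))
  }
})

test_that("canonical form is invariant under atom permutations", {
  cases <- c("OCC", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
             "[Fe]12345678([cH]9[cH]1[cH]2[cH]3[cH]49)[cH]1[cH]5[cH]6[cH]7[cH]81",
             "C[C@H](N)C(=O)O", "c1ccc2ccccc2c1")
  set.seed(99)
  for (s in cases) {
    g <- parse_smiles(s)
    ref <- canonicalize(g)
    for (k in 1:25) {
      gp <- mg_permute(g, sample(n_atoms(g)))
      expect_identical(canonicalize(gp), ref, label = s)
    }
  }
  expect_identical(canon_smiles("OCC"), canon_smiles("CCO"))
})

test_that("canonicalization distinguishes charge/H variants of a ring", {
  expect_false(canon_smiles("C1=CC=CC1") == canon_smiles("[cH-]1cccc1"))
})

test_that("ring-closure digits are reused and %nn works beyond nine", {
  r <- run_fixture("carborane")
  g <- parse_smiles(r$smiles)
  expect_equal(n_atoms(g), 12)
  expect_equal(nrow(g$bonds), 30)          # icosahedron edge count
  expect_true(all(atom_needs_bracket(g)))
  expect_true(grepl("%", r$smiles))        # needs two-digit closures
})

test_that("stereo mark inversion is a token-safe involution", {
  expect_identical(invert_stereo_marks("C[C@H](N)C=O"), "C[C@@H](N)C=O")
  expect_identical(invert_stereo_marks("CCO"), "CCO")
  set.seed(3)
  for (k in 1:1000) {
    s <- random_chiral_moiety()
    expect_identical(invert_stereo_marks(invert_stereo_marks(s)), s)
  }
  # inversion produces the enantiomer, not the same molecule
  s <- "C[C@H](N)C(=O)O"
  expect_false(canon_smiles(s) == canon_smiles(invert_stereo_marks(s)))
})

test_that("equivalent stereo writings canonicalize identically", {
  expect_identical(canon_smiles("C[C@H](N)C(=O)O"),
                   canon_smiles("N[C@@H](C)C(=O)O"))
  expect_identical(canon_smiles("F[C@H](Cl)Br"), canon_smiles("[C@@H](F)(Cl)Br"))
})
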