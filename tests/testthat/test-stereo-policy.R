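test_that("Sohncke classification follows rotation determinants", {
  expect_true(is_sohncke(list(symop())))
  expect_false(is_sohncke(lapply(c("x,y,z", "-x,-y,-z"), parse_symop)))
  p212121 <- lapply(c("x,y,z", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2",
                      "-x+1/2,-y,z+1/2"), parse_symop)
  expect_true(is_sohncke(p212121))
  expect_true(all(vapply(p212121,
                         function(op) det(op$rot) == 1, logical(1))))
})

test_that("the 230 space-group types yield exactly 65 Sohncke groups", {
  sg <- spacegroup_operator_sets()
  expect_equal(nrow(sg), 230)
  expect_true(all(lengths(sg$ops) == sg$n_ops))
  got <- vapply(sg$ops, is_sohncke, logical(1))
  # brute-force oracle: numeric determinant of every rotation part
  oracle <- vapply(sg$ops, function(ops) {
    all(vapply(ops, function(op) abs(det(op$rot) - 1) < 1e-9, logical(1)))
  }, logical(1))
  expect_identical(got, oracle)
  expect_equal(sum(got), 65)
})

test_that("tetrahedral perception marks only genuine stereocenters", {
  r <- run_fixture("chiral_sohncke")
  marks <- regmatches(r$smiles, gregexpr("@@|@", r$smiles))[[1]]
  expect_equal(length(marks), 1)

  # neopentane: four equivalent neighbors, no mark
  ctr <- c(0, 0, 0)
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  g <- molgraph(rep("C", 5), hcount = c(0L, rep(3L, 4)),
                coords = rbind(ctr, 1.54 * dirs))
  for (k in 2:5) g <- add_bond(g, 1, k)
  g <- perceive_tetrahedral(g)
  expect_true(is.null(g$parity[[1]]))
})

test_that("mirroring the coordinates flips every parity", {
  e <- fixture_entry("chiral_sohncke")
  r1 <- run_fixture("chiral_sohncke")
  e2 <- e
  e2$sites$fx <- -e2$sites$fx   # improper operation on the coordinates
  r2 <- suppressWarnings(run_entry(e2))
  expect_false(canon_smiles(r1$smiles) == canon_smiles(r2$smiles))
  expect_identical(canon_smiles(invert_stereo_marks(r1$smiles)),
                   canon_smiles(r2$smiles))
})

test_that("near-planar centres refuse a parity with a warning", {
  g <- molgraph(c("C", "F", "Cl", "Br", "N"), hcount = 0L,
                coords = rbind(c(0, 0, 0), c(1.35, 0, 0),
                               c(-0.9, 1.4, 0), c(-0.9, -1.4, 0),
                               c(0.3, 1.4, 0)))
  for (k in 2:5) g <- add_bond(g, 1, k)
  expect_warning(perceive_tetrahedral(g), "near-planar")
})

test_that("racemate policy strips, doubles or keeps as the group dictates", {
  # Sohncke: marks kept
  res <- apply_racemate_policy("C[C@H](N)C(=O)O", sohncke = TRUE)
  expect_identical(res$smiles, "C[C@H](N)C(=O)O")

  # non-Sohncke, single centre: mark stripped
  res <- apply_racemate_policy("C[C@H](N)C(=O)O", sohncke = FALSE)
  expect_canon_equal(res$smiles, "CC(N)C(=O)O")
  expect_false(grepl("@", res$smiles))

  # non-Sohncke, two centres: both enantiomers, canonical mirror images
  s <- "N[C@H](F)[C@@H](Cl)O"
  res <- apply_racemate_policy(s, sohncke = FALSE)
  parts <- strsplit(res$smiles, ".", fixed = TRUE)[[1]]
  expect_equal(length(parts), 2)
  expect_identical(canon_smiles(parts[1]),
                   canon_smiles(invert_stereo_marks(parts[2])))

  # idempotence
  res2 <- apply_racemate_policy(res$smiles, sohncke = FALSE)
  expect_identical(res2$smiles, res$smiles)
})

test_that("randomly generated racemic moieties double into mirror pairs", {
  set.seed(21)
  for (k in 1:100) {
    s <- random_chiral_moiety()
    res <- apply_racemate_policy(s, sohncke = FALSE)
    parts <- strsplit(res$smiles, ".", fixed = TRUE)[[1]]
    if (canon_smiles(s) == canon_smiles(invert_stereo_marks(s))) {
      expect_equal(length(parts), 1)   # meso: single copy
    } else {
      expect_equal(length(parts), 2)
      expect_identical(canon_smiles(parts[1]),
                       canon_smiles(invert_stereo_marks(parts[2])))
    }
  }
})

test_that("meso crystals stay single while racemic pairs double end-to-end", {
  r <- run_fixture("meso")
  expect_equal(length(strsplit(r$smiles, ".", fixed = TRUE)[[1]]), 1)
  expect_identical(canon_smiles(r$smiles),
                   canon_smiles(invert_stereo_marks(r$smiles)))

  r <- run_fixture("racemic_two_centers")
  parts <- strsplit(r$smiles, ".", fixed = TRUE)[[1]]
  expect_equal(length(parts), 2)
  expect_identical(canon_smiles(parts[1]),
                   canon_smiles(invert_stereo_marks(parts[2])))
})
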