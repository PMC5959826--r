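test_that("P1 expansion completes molecules on special positions", {
  e <- fixture_entry("trans_special")
  ex <- expand_to_p1(e)
  # centrosymmetric complex: everything doubles except the Cu on the centre
  expect_equal(nrow(ex$placements), 2 * nrow(e$sites) - 1)
  expect_equal(sum(ex$placements$element == "Cu"), 1)
})

test_that("expansion of an identity-symmetry entry reproduces the input", {
  e <- fixture_entry("pf6_salt")
  ex <- expand_to_p1(e)
  expect_equal(nrow(ex$placements), nrow(e$sites))
  expect_equal(sort(ex$placements$source_label), sort(e$sites$label))
  expect_true(all(vapply(ex$clusters, `[[`, integer(1), "dim") == 0L))
})

test_that("expansion output is invariant to atom-site order", {
  e <- fixture_entry("hemihydrate")
  r1 <- suppressWarnings(run_entry(e))
  set.seed(11)
  e2 <- e
  perm <- sample(nrow(e2$sites))
  e2$sites <- e2$sites[perm, ]
  rownames(e2$sites) <- NULL
  r2 <- suppressWarnings(run_entry(e2))
  expect_identical(canon_smiles(r1$smiles), canon_smiles(r2$smiles))
})

test_that("disorder selection keeps the majority group and logs ties", {
  pl <- data.frame(
    source_label = c("C1", "Cl1", "Cl2a", "Cl2b"),
    element = c("C", "Cl", "Cl", "Cl"),
    occupancy = c(1, 1, 0.6, 0.4),
    disorder_assembly = c(NA, NA, "A", "A"),
    disorder_group = c(NA, NA, "1", "2"),
    stringsAsFactors = FALSE)
  out <- select_disorder(pl)
  expect_false("Cl2b" %in% out$placements$source_label)
  pl$occupancy[3:4] <- 0.5
  out <- select_disorder(pl)
  expect_true(any(grepl("tie", out$log)))
  expect_false("Cl2b" %in% out$placements$source_label)
})

test_that("polymer dimensions classify framework, chain and sheet fixtures", {
  ex <- expand_to_p1(fixture_entry("nacl"))
  expect_equal(max(vapply(ex$clusters, `[[`, integer(1), "dim")), 3L)
  ex <- expand_to_p1(fixture_entry("chain_1d"))
  expect_equal(vapply(ex$clusters, `[[`, integer(1), "dim"), 1L)
  ex <- expand_to_p1(fixture_entry("sheet_2d"))
  expect_equal(vapply(ex$clusters, `[[`, integer(1), "dim"), 2L)
  ex <- expand_to_p1(fixture_entry("methanol_z2"))
  expect_true(all(vapply(ex$clusters, `[[`, integer(1), "dim") == 0L))
})

test_that("stoichiometry reduction merges duplicates and rounds up solvents", {
  m <- mg_moieties(parse_smiles("CCO.CCO"))
  red <- reduce_stoichiometry(m)
  expect_equal(red$mult, 1L)

  m <- mg_moieties(parse_smiles("CCO.CCO.c1ccncc1"))
  red <- reduce_stoichiometry(m)
  expect_equal(sort(red$mult), c(1L, 2L))  # 2:1 kept, no common divisor

  # hemihydrate: the main species is never duplicated
  b <- suppressWarnings(build_molecule(fixture_entry("hemihydrate")))
  expect_equal(sort(red2 <- b$mult), c(1L, 1L))
  forms <- vapply(b$moieties, molecular_formula, character(1))
  expect_setequal(forms, c("C5H5N", "H2O"))
})

test_that("element stoichiometry of the reduced set matches the cell contents", {
  for (nm in c("pyrrole", "uracil", "en_nickel", "zn_hexaaqua", "pf6_salt",
               "trans_special", "methanol_z2")) {
    e <- fixture_entry(nm)
    b <- suppressWarnings(build_molecule(e))
    # reduced moieties, expanded by multiplicity, must be proportional to the
    # P1 cell contents (heavy atoms; no solvents/inferred H in these fixtures)
    got <- table(unlist(lapply(seq_along(b$moieties), function(k) {
      rep(b$moieties[[k]]$atoms$element, b$mult[k])
    })))
    p1 <- expand_to_p1(e)$placements
    ref <- table(p1$element[p1$element != "H"])
    got <- got[sort(names(got))]
    ratio <- as.numeric(ref[names(got)]) / as.numeric(got)
    expect_true(all(abs(ratio - ratio[1]) < 1e-9), label = nm)
  }
})

test_that("obviously missing hydrogens are inferred", {
  # isolated O becomes water
  g <- molgraph("O", coords = matrix(0, 1, 3))
  g2 <- infer_missing_hydrogens(g)
  expect_equal(g2$atoms$hcount, 2L)

  # methanol missing its hydroxyl H (C-O 1.43 A)
  g <- molgraph(c("C", "O"), hcount = c(3L, 0L),
                coords = rbind(c(0, 0, 0), c(1.43, 0, 0)))
  g <- add_bond(g, 1, 2)
  g2 <- infer_missing_hydrogens(g)
  expect_equal(g2$atoms$hcount[2], 1L)

  # carbonyl O (C=O 1.22 A) stays bare
  g <- molgraph(c("C", "O"), hcount = c(2L, 0L),
                coords = rbind(c(0, 0, 0), c(1.22, 0, 0)))
  g <- add_bond(g, 1, 2)
  g2 <- infer_missing_hydrogens(g)
  expect_equal(g2$atoms$hcount[2], 0L)

  # counter-ion context suppresses the hydroxyl rule
  g <- molgraph(c("C", "O", "Na"), hcount = c(3L, 0L, 0L),
                coords = rbind(c(0, 0, 0), c(1.43, 0, 0), c(8, 0, 0)))
  g <- add_bond(g, 1, 2)
  g2 <- infer_missing_hydrogens(g)
  expect_equal(g2$atoms$hcount[2], 0L)
})

test_that("1-D polymers are represented by two connected repeat units", {
  e <- fixture_entry("chain_1d")
  b <- suppressWarnings(build_molecule(e))
  expect_equal(b$polymer_dims, 1L)
  frag <- b$moieties[[1]]
  expect_equal(n_atoms(frag), 4)  # unit of 2 atoms, doubled
  expect_true(isTRUE(attr(frag, "polymer_fragment")))

  r <- run_fixture("sheet_2d")
  expect_identical(r$status, "unsupported")

  g <- parse_smiles("CC")
  expect_error(extend_polymer_1d(g, list(), unit_cell(10, 10, 10)),
               "generating translation")
})

test_that("no finite moiety retains a bond to an atom outside the output", {
  for (nm in c("hemihydrate", "trans_special", "nacl")) {
    b <- suppressWarnings(build_molecule(fixture_entry(nm)))
    for (k in seq_along(b$moieties)) {
      if (b$polymer_dims[k] > 0) next
      m <- b$moieties[[k]]
      expect_true(all(m$bonds$a1 <= n_atoms(m) & m$bonds$a2 <= n_atoms(m)))
      expect_equal(max(mg_components(m)), 1)
    }
  }
})
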