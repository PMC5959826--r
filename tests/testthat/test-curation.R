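test_that("the carbonyl rule repairs crude metal-carbonyl fragments", {
  res <- apply_rules("[Co]([C][O])([C][O])[C][O]")
  expect_canon_equal(res$smiles, "[Co](C#[O])(C#[O])C#[O]")
  expect_true("carbonyl" %in% res$log$category)

  # text mode reproduces the historical find/replace behaviour
  res <- apply_rules("[Co]([C][O])", mode = "text")
  expect_identical(res$smiles, "[Co](C#[O])")
})

test_that("strings matching no rule pass through with an empty log", {
  res <- apply_rules("c1ccccc1CCO")
  expect_identical(res$smiles, "c1ccccc1CCO")
  expect_equal(nrow(res$log), 0)
})

test_that("a lone bare O moiety is completed to water", {
  res <- apply_rules("[O].c1ccccc1")
  g <- parse_smiles(res$smiles)
  o <- which(g$atoms$element == "O")
  expect_equal(g$atoms$hcount[o], 2L)
})

test_that("solvent and group rules fix the documented motifs", {
  # coordinated acetonitrile: N#C restored
  res <- apply_rules("[Cu][N][C]C")
  g <- parse_smiles(res$smiles)
  n <- which(g$atoms$element == "N")
  expect_true(3L %in% g$bonds$order)
  # coordinated DMSO: S=O restored
  res <- apply_rules("[Cu][O][S](C)C")
  expect_true(2L %in% parse_smiles(res$smiles)$bonds$order)
  # imine single C-N fixed to a double bond
  res <- apply_rules("[C](C)(C)[N]C")
  expect_true(2L %in% parse_smiles(res$smiles)$bonds$order)
  # coordinated azide
  res <- apply_rules("[Cu][N][N][N]")
  ords <- parse_smiles(res$smiles)$bonds$order
  expect_equal(sum(ords == 2L), 2)
})

test_that("curation rules are idempotent and the log replays exactly", {
  s <- "[Co]([C][O])([C][O])[C][O]"
  r1 <- apply_rules(s)
  r2 <- apply_rules(r1$smiles)
  expect_identical(r2$smiles, r1$smiles)
  expect_equal(nrow(r2$log), 0)
  expect_identical(replay_changelog(s, r1$log), r1$smiles)
})

test_that("rules files round-trip through TSV", {
  rules <- curation_rules()
  path <- tempfile(fileext = ".tsv")
  write_rules_file(rules, path)
  back <- read_rules_file(path)
  expect_identical(back$category, rules$category)
  expect_identical(back$enabled, rules$enabled)
})

test_that("haloanion recharge reproduces the worked example exactly", {
  expect_identical(recharge_haloanions("[P](F)(F)(F)(F)(F)[F-]"),
                   "[P-](F)(F)(F)(F)(F)F")
  expect_identical(recharge_haloanions("[B](F)(F)(F)[F-]"),
                   "[B-](F)(F)(F)F")
  expect_identical(recharge_haloanions("[Sn](C)(C)(Cl)Cl"),
                   "[Sn](C)(C)(Cl)Cl")   # 3 element types: untouched
})

test_that("recharge conserves charge and halogen neutrality by moiety", {
  set.seed(5)
  for (k in 1:100) {
    s <- random_haloanion()
    out <- recharge_haloanions(s)
    expect_equal(total_charge(out), total_charge(s), label = s)
    g <- parse_smiles(out)
    hal <- g$atoms$element %in% c("F", "Cl", "Br", "I")
    expect_true(all(g$atoms$charge[hal] == 0L), label = s)
    expect_identical(recharge_haloanions(out), out, label = s)  # idempotent
  }
})

test_that("non-candidate moieties pass recharge unchanged", {
  set.seed(6)
  for (k in 1:100) {
    s <- random_non_candidate()
    expect_identical(recharge_haloanions(s), s, label = s)
  }
})

test_that("recharge candidate selection needs a central atom with 3 halogens", {
  rec <- data.frame(smiles = c("[K+].[P](F)(F)(F)(F)(F)[F-]",
                               "ClC(Cl)Cl",
                               "[Sn](Cl)Cl"),
                    id = c("a", "b", "c"), stringsAsFactors = FALSE)
  out <- select_recharge_candidates(rec)
  expect_identical(out$id, "a")
})
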