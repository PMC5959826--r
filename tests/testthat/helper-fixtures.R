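# Shared helpers: cached pipeline runs, random generators for property tests.

.run_cache <- new.env(parent = emptyenv())

fixture_entry <- function(name) {
  parse_cif(build_fixture(name)$cif)[[1]]
}

run_fixture <- function(name) {
  if (is.null(.run_cache[[name]])) {
    .run_cache[[name]] <- suppressWarnings(run_entry(fixture_entry(name)))
  }
  .run_cache[[name]]
}

expect_canon_equal <- function(actual, expected) {
  expect_identical(canon_smiles(actual), canon_smiles(expected))
}

# a random valid symmetry operator
random_symop <- function() {
  repeat {
    perm <- sample(3)
    rot <- matrix(0L, 3, 3)
    for (i in 1:3) rot[i, perm[i]] <- sample(c(-1L, 1L), 1)
    tnum <- sample(0:11, 3, replace = TRUE)
    op <- try(symop(rot, tnum, c(12L, 12L, 12L)), silent = TRUE)
    if (!inherits(op, "try-error")) return(op)
  }
}

# a random haloanion moiety string [X](Hal)...(Hal) with a random negative
# charge distribution over terminal halogens
random_haloanion <- function() {
  central <- sample(c("B", "P", "As", "Sb", "Si", "Sn", "Al", "Bi"), 1)
  hal <- sample(c("F", "Cl", "Br"), 1)
  maxv <- switch(central, B = 3, Al = 3, P = 5, As = 5, Sb = 5, Bi = 5,
                 Si = 4, Sn = 4)
  n <- maxv + sample(1:2, 1)
  deficit <- n - maxv
  charged <- sample(n, deficit)
  parts <- vapply(seq_len(n), function(k) {
    if (k %in% charged) paste0("([", hal, "-])") else paste0("(", hal, ")")
  }, character(1))
  paste0("[", central, "]", paste(parts, collapse = ""))
}

# a random non-candidate moiety (carbon-centred or too few halogens)
random_non_candidate <- function() {
  if (runif(1) < 0.5) {
    paste0("C(", paste(rep(sample(c("F", "Cl", "Br"), 1), 3), collapse = ")("),
           ")", sample(c("F", "Cl", "Br"), 1))
  } else {
    sample(c("CCO", "c1ccccc1", "[Sn](C)(C)(Cl)Cl", "CC(=O)O"), 1)
  }
}

# a random acyclic moiety with >= 2 stereocenters and asymmetric ends (never
# meso by construction)
random_chiral_moiety <- function() {
  k <- sample(2:3, 1)
  subs <- sample(c("F", "Cl", "Br", "I"), k, replace = TRUE)
  marks <- sample(c("@", "@@"), k, replace = TRUE)
  mid <- paste(vapply(seq_len(k), function(i) {
    paste0("[C", marks[i], "H](", subs[i], ")")
  }, character(1)), collapse = "")
  paste0("N", mid, "O")   # distinct chain ends
}

total_charge <- function(smiles) {
  sum(parse_smiles(smiles)$atoms$charge)
}
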