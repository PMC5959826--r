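test_that("CIF parsing strips uncertainties and defaults occupancy", {
  cif <- paste(
    "data_t1",
    "_cell_length_a 10.123(4)",
    "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "_cell_formula_units_Z 1",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "_atom_site_occupancy",
    "C1 C 0.1 0.2 0.3 0.50(2)",
    sep = "\n")
  e <- parse_cif(cif)[[1]]
  expect_equal(e$cell$a, 10.123)
  expect_equal(e$sites$occupancy, 0.5)

  cif2 <- sub("_atom_site_occupancy\nC1 C 0.1 0.2 0.3 0.50\\(2\\)",
              "C1 C 0.1 0.2 0.3", paste0(cif, ""))
  e2 <- parse_cif(cif2)[[1]]
  expect_equal(e2$sites$occupancy, 1)
})

test_that("missing Z is an error, not a silent default", {
  cif <- paste(
    "data_t1",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.2 0.3",
    sep = "\n")
  expect_error(parse_cif(cif), "_cell_formula_units_Z")
})

test_that("malformed loops and unknown elements are reported by name", {
  bad <- paste(
    "data_t1",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "_cell_formula_units_Z 1",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.2",
    sep = "\n")
  expect_error(parse_cif(bad), "loop")
  expect_error(normalize_element("X", "X9"), "X9")
  expect_identical(normalize_element("D"), "H")
})

test_that("the rock-salt fixture exposes 2 sites and 192 operators", {
  e <- fixture_entry("nacl")
  expect_equal(nrow(e$sites), 2)
  expect_equal(length(e$symops), 192)
})

test_that("Jones-faithful operators parse, apply and round-trip", {
  id <- parse_symop("x,y,z")
  expect_true(symop_equal(id, symop()))
  inv <- parse_symop("-x,-y,-z")
  expect_equal(inv$rot, -diag(3), ignore_attr = TRUE)
  scr <- parse_symop("-x,y+1/2,-z")
  expect_equal(diag(scr$rot), c(-1, 1, -1))
  expect_equal(scr$tnum / scr$tden, c(0, 0.5, 0))

  expect_equal(apply_symop(id, c(0.1, 0.2, 0.3)), c(0.1, 0.2, 0.3))
  expect_equal(apply_symop(inv, c(0.1, 0.2, 0.3), wrap = TRUE), c(0.9, 0.8, 0.7))
  expect_equal(apply_symop(parse_symop("x+1/2,y,z"), c(0.7, 0, 0), wrap = TRUE),
               c(0.2, 0, 0))

  set.seed(7)
  for (k in 1:1000) {
    op <- random_symop()
    expect_true(symop_equal(parse_symop(serialize_symop(op)), op))
  }
})

test_that("fixture operator sets are closed under composition", {
  for (nm in c("nacl", "hemihydrate", "trans_special", "chiral_sohncke")) {
    ops <- fixture_entry(nm)$symops
    keys <- vapply(ops, serialize_symop, character(1))
    for (a in ops[seq_len(min(8, length(ops)))]) {
      for (b in ops[seq_len(min(8, length(ops)))]) {
        expect_true(serialize_symop(compose_symop(a, b)) %in% keys)
      }
    }
  }
})

test_that("orthogonalization follows the a-along-x convention", {
  cubic <- unit_cell(10, 10, 10)
  expect_equal(fract_to_cartesian(cubic, c(0.5, 0.5, 0.5)), c(5, 5, 5))
  d <- fract_to_cartesian(cubic, c(0.2, 0, 0)) -
    fract_to_cartesian(cubic, c(0.1, 0, 0))
  expect_equal(sqrt(sum(d^2)), 1.0)
  mono <- unit_cell(10, 10, 10, beta = 120)
  cart <- fract_to_cartesian(mono, c(0, 0, 1))
  expect_equal(cart[1], -5, tolerance = 1e-9)
  expect_error(unit_cell(10, 10, 10, alpha = 0), "angle")
})

test_that("P1 CIF writing round-trips through the parser", {
  cell <- unit_cell(20, 20, 20)
  atoms <- data.frame(label = c("C1", "O1"), element = c("C", "O"),
                      fx = c(0.1, 0.2), fy = c(0.3, 0.4), fz = c(0.5, 0.6))
  txt <- write_p1_cif(atoms, cell, id = "rt")
  e <- parse_cif(txt)[[1]]
  expect_equal(e$sites$label, atoms$label)
  expect_equal(e$sites$fx, atoms$fx, tolerance = 1e-9)
  expect_equal(length(e$symops), 1)

  empty <- write_p1_cif(atoms[0, ], cell, id = "empty")
  expect_equal(nrow(parse_cif(empty)[[1]]$sites), 0)

  wfx <- build_fixture("water")
  ent <- parse_cif(wfx$cif)[[1]]
  rt <- write_p1_cif(ent$sites, ent$cell, id = "water_rt")
  expect_equal(nrow(parse_cif(rt)[[1]]$sites), 3)
})

test_that("site-symmetry codes follow the n_klm convention", {
  expect_equal(parse_sitesym_code(".")$symop_index, 1L)
  c2 <- parse_sitesym_code("2_565")
  expect_equal(c2$symop_index, 2L)
  expect_equal(c2$shift, c(0L, 1L, 0L))
  expect_error(parse_sitesym_code("x_y"), "site-symmetry")
})
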