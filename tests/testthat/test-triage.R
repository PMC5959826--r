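test_that("Z' is exact rational arithmetic on a (z, n) grid", {
  for (z in 1:12) for (n in c(1:8, 12, 16, 24, 48, 96, 192)) {
    zp <- compute_zprime(z, n)
    g <- gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    expect_equal(zp$num / zp$den, z / n)
    expect_equal(gcd(zp$num, zp$den), 1)
  }
  expect_equal(compute_zprime(4, 4)[c("num", "den")], list(num = 1L, den = 1L))
  expect_equal(compute_zprime(2, 4)[c("num", "den")], list(num = 1L, den = 2L))
  expect_equal(compute_zprime(8, 4)[c("num", "den")], list(num = 2L, den = 1L))
})

test_that("disorder flag uses strict occupancy below one with tolerance", {
  e <- fixture_entry("water")
  expect_false(flag_disorder(e))
  e$sites$occupancy[1] <- 0.5
  expect_true(flag_disorder(e))
  e$sites$occupancy[1] <- 0.999
  expect_true(flag_disorder(e))
  e$sites$occupancy[1] <- 0.9999999   # formatting noise, not disorder
  expect_false(flag_disorder(e))
})

test_that("cross-unit bond flag reads the site-symmetry codes", {
  e <- fixture_entry("water")
  expect_false(flag_cross_unit_bonds(e))   # no geometry loop
  e$geom_bonds <- data.frame(label1 = "O1", label2 = "H1", distance = 0.96,
                             site_symmetry_2 = c("."))
  expect_false(flag_cross_unit_bonds(e))
  e$geom_bonds$site_symmetry_2 <- "1_555"
  expect_false(flag_cross_unit_bonds(e))
  e$geom_bonds$site_symmetry_2 <- "2_565"
  expect_true(flag_cross_unit_bonds(e))
})

test_that("triage routes fixtures as designed", {
  f <- triage(fixture_entry("water"))
  expect_identical(f$zprime_class, "one")
  expect_true(f$fast_path)

  f <- triage(fixture_entry("hemihydrate"))
  expect_true(f$cross_unit_bonds)
  expect_false(f$fast_path)

  f <- triage(fixture_entry("disorder_two_site"))
  expect_true(f$disordered)

  f <- triage(fixture_entry("trans_special"))
  expect_identical(f$zprime_class, "sub_one")
  expect_equal(f$zprime$num / f$zprime$den, 0.5)

  f <- triage(fixture_entry("methanol_z2"))
  expect_identical(f$zprime_class, "multi")
})

test_that("triage is a pure function of the parsed entry", {
  e <- fixture_entry("hemihydrate")
  f1 <- triage(e)
  f2 <- triage(e)
  expect_identical(f1, f2)
})
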