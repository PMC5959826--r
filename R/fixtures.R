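# Programmatic crystal-structure fixtures.
#
# Every fixture is generated from idealized geometry (standard bond lengths,
# generous cells) with no external data; expected SMILES for the
# well-documented convention cases are stored alongside, compared canonically
# by the tests. Geometries are designed so that every intended bond satisfies
# the default radius-plus-offset rule and intended non-bonds miss it by a
# clear margin (borderline chelate cross-ring contacts are the documented
# exception).

.fixture_env <- new.env(parent = emptyenv())

# ---- geometry helpers ------------------------------------------------------

.unit <- function(v) v / sqrt(sum(v^2))

# regular n-gon in the xy plane, given side length, centered at the origin
.ngon <- function(n, side, z = 0, phase = pi / 2) {
  r <- side / (2 * sin(pi / n))
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(ang), r * sin(ang), z)
}

# three methyl hydrogens around carbon at `m`, bond axis direction `dir`
.methyl_h <- function(m, dir, blen = 1.09) {
  u <- .unit(dir)
  v <- if (abs(u[3]) < 0.9) .unit(pracma_cross(u, c(0, 0, 1))) else
    .unit(pracma_cross(u, c(1, 0, 0)))
  w <- pracma_cross(u, v)
  t(vapply(0:2, function(k) {
    ang <- 2 * pi * k / 3
    m + blen * (u * 0.334 + (v * cos(ang) + w * sin(ang)) * 0.943)
  }, numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# atom accumulator
.atoms_new <- function() {
  data.frame(label = character(0), element = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             occupancy = numeric(0), assembly = character(0),
             group = character(0), stringsAsFactors = FALSE)
}

.atoms_add <- function(df, element, xyz, occupancy = 1,
                       assembly = NA_character_, group = NA_character_) {
  xyz <- matrix(xyz, ncol = 3)
  for (r in seq_len(nrow(xyz))) {
    n_el <- sum(df$element == element) + 1L
    df <- rbind(df, data.frame(
      label = paste0(element, n_el), element = element,
      x = xyz[r, 1], y = xyz[r, 2], z = xyz[r, 3],
      occupancy = occupancy, assembly = assembly, group = group,
      stringsAsFactors = FALSE))
  }
  df
}

# hydrogens pointing outward from a reference point
.add_h_outward <- function(df, heavy_rows, ref = c(0, 0, 0), blen = 1.08) {
  for (r in heavy_rows) {
    p <- c(df$x[r], df$y[r], df$z[r])
    df <- .atoms_add(df, "H", p + blen * .unit(p - ref))
  }
  df
}

# ---- CIF emission ----------------------------------------------------------

.fixture_cif <- function(id, sites, cell, symops = "x,y,z", z = 1L,
                         geom_bonds = NULL) {
  lines <- c(
    paste0("data_", id),
    sprintf("_cell_length_a %.6f", cell[1]),
    sprintf("_cell_length_b %.6f", cell[2]),
    sprintf("_cell_length_c %.6f", cell[3]),
    sprintf("_cell_angle_alpha %.4f", cell[4]),
    sprintf("_cell_angle_beta %.4f", cell[5]),
    sprintf("_cell_angle_gamma %.4f", cell[6]),
    sprintf("_cell_formula_units_Z %d", z),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    sprintf("'%s'", symops),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy"
  )
  has_dis <- any(!is.na(sites$assembly)) || any(!is.na(sites$group))
  if (has_dis) {
    lines <- c(lines, "_atom_site_disorder_assembly", "_atom_site_disorder_group")
  }
  for (r in seq_len(nrow(sites))) {
    row <- sprintf("%s %s %.6f %.6f %.6f %.4f", sites$label[r], sites$element[r],
                   sites$fx[r], sites$fy[r], sites$fz[r], sites$occupancy[r])
    if (has_dis) {
      row <- paste(row,
                   ifelse(is.na(sites$assembly[r]), ".", sites$assembly[r]),
                   ifelse(is.na(sites$group[r]), ".", sites$group[r]))
    }
    lines <- c(lines, row)
  }
  if (!is.null(geom_bonds) && nrow(geom_bonds) > 0) {
    lines <- c(lines,
               "loop_",
               "_geom_bond_atom_site_label_1",
               "_geom_bond_atom_site_label_2",
               "_geom_bond_distance",
               "_geom_bond_site_symmetry_2",
               sprintf("%s %s %.4f %s", geom_bonds$label1, geom_bonds$label2,
                       geom_bonds$distance, geom_bonds$code))
  }
  paste(c(lines, ""), collapse = "\n")
}

# molecular fixture: Cartesian atoms centered in a generous cubic P1 cell
.molecular_cif <- function(id, atoms, a = 25, z = 1L, geom_bonds = NULL,
                           symops = "x,y,z") {
  sites <- atoms
  sites$fx <- atoms$x / a + 0.5
  sites$fy <- atoms$y / a + 0.5
  sites$fz <- atoms$z / a + 0.5
  .fixture_cif(id, sites, c(a, a, a, 90, 90, 90), symops = symops, z = z,
               geom_bonds = geom_bonds)
}

# ---- individual fixture builders ------------------------------------------

.fx_water <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "O", c(0, 0, 0))
  at <- .atoms_add(at, "H", c(0.757, 0.586, 0))
  at <- .atoms_add(at, "H", c(-0.757, 0.586, 0))
  list(cif = .molecular_cif("water", at), expected = "O", tags = "organic")
}

.fx_methanol_z2 <- function() {
  one <- function(origin) {
    at <- list()
    c1 <- origin
    o1 <- origin + c(1.43, 0, 0)
    rbind(
      data.frame(element = "C", x = c1[1], y = c1[2], z = c1[3]),
      data.frame(element = "O", x = o1[1], y = o1[2], z = o1[3]),
      data.frame(element = "H", x = o1[1] + 0.52, y = o1[2] + 0.81, z = o1[3]),
      do.call(rbind, lapply(seq_len(3), function(k) {
        h <- .methyl_h(c1, c(-1, 0, 0))[k, ]
        data.frame(element = "H", x = h[1], y = h[2], z = h[3])
      }))
    )
  }
  raw <- rbind(one(c(-4, -4, 0)), one(c(3, 4, 0)))
  at <- .atoms_new()
  for (r in seq_len(nrow(raw))) {
    at <- .atoms_add(at, raw$element[r], c(raw$x[r], raw$y[r], raw$z[r]))
  }
  list(cif = .molecular_cif("methanol_z2", at, z = 2L),
       expected = "CO", tags = "zprime2")
}

# planar ring with per-atom elements, explicit coordinates and outward H on
# selected atoms
.planar_ring_fixture <- function(id, coords, elements, h_on, expected, tags,
                                 extra = NULL) {
  at <- .atoms_new()
  for (r in seq_len(nrow(coords))) {
    at <- .atoms_add(at, elements[r], coords[r, ])
  }
  ring_n <- nrow(coords)
  if (!is.null(extra)) {
    for (e in extra) at <- .atoms_add(at, e$element, e$xyz)
  }
  at <- .add_h_outward(at, h_on)
  list(cif = .molecular_cif(id, at), expected = expected, tags = tags)
}

.fx_pyrrole <- function() {
  xy <- .ngon(5, 1.38)
  .planar_ring_fixture("pyrrole", xy, c("N", "C", "C", "C", "C"),
                       h_on = 1:5, expected = "c1ccc[nH]1", tags = "aromatic")
}

.fx_thiophene <- function() {
  co <- rbind(c(0, 1.189, 0), c(1.234, 0.003, 0), c(0.709, -1.267, 0),
              c(-0.709, -1.267, 0), c(-1.234, 0.003, 0))
  .planar_ring_fixture("thiophene", co, c("S", "C", "C", "C", "C"),
                       h_on = 2:5, expected = "c1cccs1", tags = "aromatic")
}

.fx_cyclopentadiene <- function() {
  xy <- .ngon(5, 1.45)
  at <- .atoms_new()
  for (r in 1:5) at <- .atoms_add(at, "C", xy[r, ])
  # sp3 carbon (atom 1) gets two out-of-plane H
  p1 <- xy[1, ]
  d <- .unit(p1)
  at <- .atoms_add(at, "H", p1 + 1.09 * .unit(d + c(0, 0, 1.2)))
  at <- .atoms_add(at, "H", p1 + 1.09 * .unit(d + c(0, 0, -1.2)))
  at <- .add_h_outward(at, 2:5)
  list(cif = .molecular_cif("cyclopentadiene", at),
       expected = "C1=CC=CC1", tags = "aromatic")
}

.fx_cyclopentadienone <- function() {
  xy <- .ngon(5, 1.45)
  at <- .atoms_new()
  for (r in 1:5) at <- .atoms_add(at, "C", xy[r, ])
  at <- .atoms_add(at, "O", xy[1, ] + 1.22 * .unit(xy[1, ]))
  at <- .add_h_outward(at, 2:5)
  list(cif = .molecular_cif("cyclopentadienone", at),
       expected = "c1(=O)cccc1", tags = "aromatic")
}

.fx_pyridone2 <- function() {
  xy <- .ngon(6, 1.40)
  elements <- c("N", "C", "C", "C", "C", "C")  # N1, C2(=O), C3..C6
  at <- .atoms_new()
  for (r in 1:6) at <- .atoms_add(at, elements[r], xy[r, ])
  at <- .atoms_add(at, "O", xy[2, ] + 1.24 * .unit(xy[2, ]))
  at <- .add_h_outward(at, c(1, 3, 4, 5, 6))
  list(cif = .molecular_cif("pyridone2", at),
       expected = "c1(=O)[nH]cccc1", tags = "aromatic")
}

.fx_uracil <- function() {
  xy <- .ngon(6, 1.40)
  elements <- c("N", "C", "N", "C", "C", "C")  # N1 C2(=O) N3 C4(=O) C5 C6
  at <- .atoms_new()
  for (r in 1:6) at <- .atoms_add(at, elements[r], xy[r, ])
  at <- .atoms_add(at, "O", xy[2, ] + 1.23 * .unit(xy[2, ]))
  at <- .atoms_add(at, "O", xy[4, ] + 1.23 * .unit(xy[4, ]))
  at <- .add_h_outward(at, c(1, 3, 5, 6))
  list(cif = .molecular_cif("uracil", at),
       expected = "C1(=O)NC(=O)NC=C1", tags = "aromatic")
}

.fx_quinone <- function() {
  xy <- .ngon(6, 1.42)
  at <- .atoms_new()
  for (r in 1:6) at <- .atoms_add(at, "C", xy[r, ])
  at <- .atoms_add(at, "O", xy[1, ] + 1.22 * .unit(xy[1, ]))
  at <- .atoms_add(at, "O", xy[4, ] + 1.22 * .unit(xy[4, ]))
  at <- .add_h_outward(at, c(2, 3, 5, 6))
  list(cif = .molecular_cif("quinone", at),
       expected = "O=C1C=CC(=O)C=C1", tags = "aromatic")
}

# hexagon with vertical shared edges at x = cx +/- 1.2124
.hexagon_at <- function(cx) {
  rbind(c(cx, 1.4, 0), c(cx + 1.2124, 0.7, 0), c(cx + 1.2124, -0.7, 0),
        c(cx, -1.4, 0), c(cx - 1.2124, -0.7, 0), c(cx - 1.2124, 0.7, 0))
}

.fx_anthraquinone <- function() {
  vs <- rbind(.hexagon_at(-2.4248), .hexagon_at(0), .hexagon_at(2.4248))
  keep <- !duplicated(round(vs, 2))
  vs <- vs[keep, , drop = FALSE]
  at <- .atoms_new()
  for (r in seq_len(nrow(vs))) at <- .atoms_add(at, "C", vs[r, ])
  # carbonyls on the central ring apices
  at <- .atoms_add(at, "O", c(0, 2.62, 0))
  at <- .atoms_add(at, "O", c(0, -2.62, 0))
  # peripheral H: carbons with only two carbon neighbors within 1.6 A
  nC <- nrow(vs)
  per <- which(vapply(seq_len(nC), function(i) {
    d <- sqrt(rowSums((vs - matrix(vs[i, ], nC, 3, byrow = TRUE))^2))
    sum(d > 0.01 & d < 1.6) == 2 && abs(vs[i, 1]) > 1.3
  }, logical(1)))
  for (i in per) {
    ctr <- c(sign(vs[i, 1]) * 2.4249, 0, 0)
    at <- .atoms_add(at, "H", vs[i, ] + 1.08 * .unit(vs[i, ] - ctr))
  }
  list(cif = .molecular_cif("anthraquinone", at),
       expected = "c12ccccc1C(=O)c1ccccc1C2(=O)", tags = "aromatic")
}

.fx_caffeine <- function() {
  # six-ring: C6(0,1.4) N1(1.2124,.7) C2(1.2124,-.7) N3(0,-1.4) C4(-1.2124,-.7)
  # C5(-1.2124,.7); five-ring fused on C4-C5: N7, C8, N9
  C6 <- c(0, 1.4, 0); N1 <- c(1.2124, 0.7, 0); C2 <- c(1.2124, -0.7, 0)
  N3 <- c(0, -1.4, 0); C4 <- c(-1.2124, -0.7, 0); C5 <- c(-1.2124, 0.7, 0)
  N7 <- c(-2.543, 1.133, 0); C8 <- c(-3.366, 0, 0); N9 <- c(-2.543, -1.133, 0)
  O6 <- C6 + c(0, 1.23, 0)
  O2 <- C2 + 1.23 * .unit(c(0.866, -0.5, 0))
  Me1 <- N1 + 1.47 * .unit(c(0.866, 0.5, 0))
  Me3 <- N3 + c(0, -1.47, 0)
  Me7 <- N7 + 1.47 * .unit(N7 - c(-2.175, 0, 0))
  at <- .atoms_new()
  at <- .atoms_add(at, "C", C6); at <- .atoms_add(at, "N", N1)
  at <- .atoms_add(at, "C", C2); at <- .atoms_add(at, "N", N3)
  at <- .atoms_add(at, "C", C4); at <- .atoms_add(at, "C", C5)
  at <- .atoms_add(at, "N", N7); at <- .atoms_add(at, "C", C8)
  at <- .atoms_add(at, "N", N9)
  at <- .atoms_add(at, "O", O6); at <- .atoms_add(at, "O", O2)
  at <- .atoms_add(at, "C", Me1); at <- .atoms_add(at, "C", Me3)
  at <- .atoms_add(at, "C", Me7)
  at <- .atoms_add(at, "H", C8 + c(-1.08, 0, 0))
  at <- .atoms_add(at, "H", .methyl_h(Me1, Me1 - N1))
  at <- .atoms_add(at, "H", .methyl_h(Me3, Me3 - N3))
  at <- .atoms_add(at, "H", .methyl_h(Me7, Me7 - N7))
  list(cif = .molecular_cif("caffeine", at), expected = NA_character_,
       tags = "aromatic")
}

.fx_en_nickel <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Ni", c(0, 0, 0))
  N1 <- c(1.18, 1.62, 0); N2 <- c(-1.18, 1.62, 0)
  C1 <- c(0.76, 2.95, 0.3); C2 <- c(-0.76, 2.95, -0.3)
  at <- .atoms_add(at, "N", N1); at <- .atoms_add(at, "N", N2)
  at <- .atoms_add(at, "C", C1); at <- .atoms_add(at, "C", C2)
  at <- .atoms_add(at, "H", N1 + 1.01 * .unit(c(1, -0.3, 0.5)))
  at <- .atoms_add(at, "H", N1 + 1.01 * .unit(c(0.6, 0.2, -1)))
  at <- .atoms_add(at, "H", N2 + 1.01 * .unit(c(-1, -0.3, -0.5)))
  at <- .atoms_add(at, "H", N2 + 1.01 * .unit(c(-0.6, 0.2, 1)))
  at <- .atoms_add(at, "H", C1 + 1.09 * .unit(c(1, 0.5, 1)))
  at <- .atoms_add(at, "H", C1 + 1.09 * .unit(c(0.2, 1, -0.9)))
  at <- .atoms_add(at, "H", C2 + 1.09 * .unit(c(-1, 0.5, -1)))
  at <- .atoms_add(at, "H", C2 + 1.09 * .unit(c(-0.2, 1, 0.9)))
  list(cif = .molecular_cif("en_nickel", at),
       expected = "[Ni]1[NH2]CC[NH2]1", tags = "coordination")
}

# phenyl ring with ipso atom at `ipso`, extending along `dir`, ring plane
# spanned by dir and `pvec`
.phenyl_from <- function(ipso, dir, pvec, side = 1.40) {
  u <- .unit(dir)
  w <- .unit(pvec - sum(pvec * u) * u)
  ctr <- ipso + side * u  # ring center is one bond length beyond ipso? no:
  # regular hexagon: center at distance side from each vertex
  ctr <- ipso + side * u
  ang0 <- atan2(sum((ipso - ctr) * w), sum((ipso - ctr) * u))
  vs <- t(vapply(0:5, function(k) {
    a <- ang0 + pi * k / 3
    ctr + side * (cos(a) * u + sin(a) * w)
  }, numeric(3)))
  vs
}

.fx_phosphane_gold <- function() {
  at <- .atoms_new()
  P <- c(0, 0, 0)
  at <- .atoms_add(at, "Au", c(0, 0, -2.28))
  at <- .atoms_add(at, "P", P)
  for (k in 0:2) {
    ang <- 2 * pi * k / 3
    dir <- c(0.94 * cos(ang), 0.94 * sin(ang), 0.35)
    ipso <- P + 1.82 * .unit(dir)
    pv <- .unit(pracma_cross(dir, c(-sin(ang), cos(ang), 0.8)))
    ring <- .phenyl_from(ipso, dir, pv)
    ctr <- colMeans(ring)
    for (r in 1:6) at <- .atoms_add(at, "C", ring[r, ])
    for (r in 2:6) {
      at <- .atoms_add(at, "H", ring[r, ] + 1.08 * .unit(ring[r, ] - ctr))
    }
  }
  list(cif = .molecular_cif("phosphane_gold", at, a = 30),
       expected = "[Au][P](c1ccccc1)(c1ccccc1)c1ccccc1", tags = "coordination")
}

.fx_zn_hexaaqua <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Zn", c(0, 0, 0))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (k in 1:6) {
    O <- 2.1 * dirs[k, ]
    at <- .atoms_add(at, "O", O)
    perp <- if (abs(dirs[k, 3]) < 0.5) c(0, 0, 1) else c(1, 0, 0)
    at <- .atoms_add(at, "H", O + 0.96 * .unit(dirs[k, ] + 0.8 * perp))
    at <- .atoms_add(at, "H", O + 0.96 * .unit(dirs[k, ] - 0.8 * perp))
  }
  list(cif = .molecular_cif("zn_hexaaqua", at),
       expected = "[Zn]([OH2])([OH2])([OH2])([OH2])([OH2])[OH2]",
       tags = "coordination")
}

.fx_co_phenolate <- function() {
  at <- .atoms_new()
  O <- c(0, 0, 0)
  # bent Co-O-C: metal points away from the ring
  Co <- O + 1.90 * c(sin(pi / 3), -cos(pi / 3), 0)
  at <- .atoms_add(at, "Co", Co)
  at <- .atoms_add(at, "O", O)
  ring <- .phenyl_from(O + 1.36 * c(0, 1, 0), c(0, 1, 0), c(1, 0, 0))
  ctr <- colMeans(ring)
  for (r in 1:6) at <- .atoms_add(at, "C", ring[r, ])
  for (r in 2:6) at <- .atoms_add(at, "H", ring[r, ] + 1.08 * .unit(ring[r, ] - ctr))
  list(cif = .molecular_cif("co_phenolate", at),
       expected = "[Co]Oc1ccccc1", tags = "coordination")
}

# pyridine ring bound to metal at `m`, N at m + 2.02*dir
.pyridine_at <- function(at, m, dir, pvec) {
  N <- m + 2.02 * .unit(dir)
  ring <- .phenyl_from(N, .unit(dir), pvec)
  at <- .atoms_add(at, "N", ring[1, ])
  ctr <- colMeans(ring)
  for (r in 2:6) at <- .atoms_add(at, "C", ring[r, ])
  for (r in 2:6) at <- .atoms_add(at, "H", ring[r, ] + 1.08 * .unit(ring[r, ] - ctr))
  at
}

.fx_cu_pyridine <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Cu", c(0, 0, 0))
  at <- .pyridine_at(at, c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  at <- .pyridine_at(at, c(0, 0, 0), c(0, -1, 0), c(0, 0, 1))
  at <- .atoms_add(at, "Cl", c(2.25, 0, 0))
  at <- .atoms_add(at, "Cl", c(-2.25, 0, 0))
  list(cif = .molecular_cif("cu_pyridine", at),
       expected = "[Cu]([n]1ccccc1)([n]1ccccc1)(Cl)Cl", tags = "coordination")
}

# imidazole ring: returns 5x3 coords N1, C2, N3, C4, C5 (regular pentagon)
.imidazole_coords <- function() .ngon(5, 1.37)

.fx_mn_imidazole <- function() {
  co <- .imidazole_coords()
  # ring order: N1(H), C2, N3(->Mn), C4, C5
  at <- .atoms_new()
  at <- .atoms_add(at, "N", co[1, ])  # N1-H
  at <- .atoms_add(at, "C", co[2, ])  # C2 between the two N
  at <- .atoms_add(at, "N", co[3, ])  # N3 -> Mn
  at <- .atoms_add(at, "C", co[4, ])
  at <- .atoms_add(at, "C", co[5, ])
  at <- .atoms_add(at, "Mn", co[3, ] + 2.2 * .unit(co[3, ]))
  at <- .add_h_outward(at, c(1, 2, 4, 5))
  list(cif = .molecular_cif("mn_imidazole", at),
       expected = "[Mn][n]1c[nH]cc1", tags = "coordination")
}

.fx_mn_imidazolate <- function() {
  co <- .imidazole_coords()
  at <- .atoms_new()
  at <- .atoms_add(at, "N", co[1, ])  # N1 -> Mn (anionic)
  at <- .atoms_add(at, "C", co[2, ])
  at <- .atoms_add(at, "N", co[3, ])
  at <- .atoms_add(at, "C", co[4, ])
  at <- .atoms_add(at, "C", co[5, ])
  at <- .atoms_add(at, "Mn", co[1, ] + 2.2 * .unit(co[1, ]))
  at <- .add_h_outward(at, c(2, 4, 5))
  list(cif = .molecular_cif("mn_imidazolate", at),
       expected = "[Mn]n1cncc1", tags = "coordination")
}

# one chelating acetate: Cd at origin, bite along `axis` (+1 or -1 on x)
.acetate_at <- function(at, sgn) {
  O1 <- c(sgn * 2.08, 1.10, 0)
  O2 <- c(sgn * 2.08, -1.10, 0)
  Cc <- c(sgn * 2.70, 0, 0)
  Me <- c(sgn * 4.20, 0, 0)
  at <- .atoms_add(at, "O", O1)
  at <- .atoms_add(at, "O", O2)
  at <- .atoms_add(at, "C", Cc)
  at <- .atoms_add(at, "C", Me)
  at <- .atoms_add(at, "H", .methyl_h(Me, c(sgn, 0, 0)))
  at
}

.fx_cd_acetate <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Cd", c(0, 0, 0))
  at <- .acetate_at(at, +1)
  at <- .acetate_at(at, -1)
  list(cif = .molecular_cif("cd_acetate", at),
       expected = "[Cd]12([O]=C(O1)C)[O]=C(O2)C", tags = "coordination")
}

.fx_gd_acac <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Gd", c(0, 0, 0))
  O1 <- c(1.32, 1.87, 0); O2 <- c(-1.32, 1.87, 0)
  C2 <- c(1.24, 3.17, 0); C4 <- c(-1.24, 3.17, 0); C3 <- c(0, 3.80, 0)
  M2 <- C2 + 1.51 * .unit(c(1, 0.45, 0)); M4 <- C4 + 1.51 * .unit(c(-1, 0.45, 0))
  at <- .atoms_add(at, "O", O1); at <- .atoms_add(at, "O", O2)
  at <- .atoms_add(at, "C", C2); at <- .atoms_add(at, "C", C4)
  at <- .atoms_add(at, "C", C3)
  at <- .atoms_add(at, "C", M2); at <- .atoms_add(at, "C", M4)
  at <- .atoms_add(at, "H", C3 + c(0, 1.09, 0))
  at <- .atoms_add(at, "H", .methyl_h(M2, M2 - C2))
  at <- .atoms_add(at, "H", .methyl_h(M4, M4 - C4))
  list(cif = .molecular_cif("gd_acac", at),
       expected = "[Gd]1[O]=C(C)C=C(C)O1", tags = "coordination")
}

.fx_nickel_carbonyl <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Ni", c(0, 0, 0))
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  for (k in 1:4) {
    C <- 1.82 * dirs[k, ]; O <- 2.95 * dirs[k, ]
    at <- .atoms_add(at, "C", C); at <- .atoms_add(at, "O", O)
  }
  list(cif = .molecular_cif("nickel_carbonyl", at),
       expected = "[Ni](C#[O])(C#[O])(C#[O])C#[O]", tags = "carbonyl")
}

.fx_co_bridging_carbonyl <- function() {
  at <- .atoms_new()
  Co1 <- c(0, 0, 1.55); Co2 <- c(0, 0, -1.55)   # Co..Co 3.10: no M-M bond
  at <- .atoms_add(at, "Co", Co1); at <- .atoms_add(at, "Co", Co2)
  # two bridging CO in the xz/yz planes
  for (d in list(c(1.24, 0, 0), c(-1.24, 0, 0))) {
    C <- c(d[1], d[2], 0)
    at <- .atoms_add(at, "C", C)
    at <- .atoms_add(at, "O", C + 1.20 * .unit(d))
  }
  # three terminal CO per Co
  for (co in list(Co1, Co2)) {
    up <- sign(co[3])
    for (k in 0:2) {
      ang <- 2 * pi * k / 3 + (if (up > 0) 0 else pi / 3)
      dir <- .unit(c(1.3 * cos(ang), 1.3 * sin(ang), up * 1.05))
      C <- co + 1.80 * dir
      at <- .atoms_add(at, "C", C)
      at <- .atoms_add(at, "O", C + 1.13 * dir)
    }
  }
  list(cif = .molecular_cif("co_bridging_carbonyl", at, a = 28),
       expected = paste0("[Co]1(C#[O])(C#[O])(C#[O])C(=O)[Co]",
                         "(C#[O])(C#[O])(C#[O])C1=O"),
       tags = "carbonyl")
}

.fx_pbet4 <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Pb", c(0, 0, 0))
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  for (k in 1:4) {
    C1 <- 2.24 * dirs[k, ]
    perp <- .unit(pracma_cross(dirs[k, ], c(0, 0, 1) + 0.1 * k))
    C2 <- C1 + 1.53 * .unit(dirs[k, ] + 1.2 * perp)
    at <- .atoms_add(at, "C", C1)
    at <- .atoms_add(at, "C", C2)
    at <- .atoms_add(at, "H", C1 + 1.09 * .unit(dirs[k, ] - 1.2 * perp))
    at <- .atoms_add(at, "H", C1 + 1.09 * .unit(pracma_cross(dirs[k, ], perp)))
    at <- .atoms_add(at, "H", .methyl_h(C2, C2 - C1))
  }
  list(cif = .molecular_cif("pbet4", at, a = 28),
       expected = "[Pb](CC)(CC)(CC)CC", tags = "organometallic")
}

.allyl_at <- function(at, flip) {
  # eta-3 allyl: all three carbons bonded to Pd at origin
  s <- if (flip) -1 else 1
  C2 <- c(0, s * 2.05, 0)
  C1 <- c(1.2, s * 1.9, 0.5 * s)
  C3 <- c(-1.2, s * 1.9, 0.5 * s)
  at <- .atoms_add(at, "C", C1)
  at <- .atoms_add(at, "C", C2)
  at <- .atoms_add(at, "C", C3)
  at <- .atoms_add(at, "H", C2 + c(0, s * 1.0, -0.5 * s))
  for (C in list(C1, C3)) {
    out <- .unit(c(C[1], 0, 0))
    at <- .atoms_add(at, "H", C + 1.09 * .unit(out + c(0, s * 0.5, 0.6 * s)))
    at <- .atoms_add(at, "H", C + 1.09 * .unit(out + c(0, s * 0.2, -0.9 * s)))
  }
  at
}

.fx_pd_allyl <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Pd", c(0, 0, 0))
  at <- .allyl_at(at, FALSE)
  at <- .allyl_at(at, TRUE)
  list(cif = .molecular_cif("pd_allyl", at),
       expected = "[Pd]1234(C[CH]1=[CH2]2)C[CH]3=[CH2]4",
       tags = "organometallic")
}

.fx_ferrocene <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "Fe", c(0, 0, 0))
  for (zs in c(1.66, -1.66)) {
    ring <- .ngon(5, 1.40, z = zs, phase = if (zs > 0) pi / 2 else pi / 2 + pi / 5)
    for (r in 1:5) at <- .atoms_add(at, "C", ring[r, ])
    for (r in 1:5) {
      p <- ring[r, ]
      at <- .atoms_add(at, "H", p + 1.08 * .unit(c(p[1], p[2], 0)))
    }
  }
  list(cif = .molecular_cif("ferrocene", at),
       expected = paste0("[Fe]12345678([cH]9[cH]1[cH]2[cH]3[cH]49)",
                         "[cH]1[cH]5[cH]6[cH]7[cH]81"),
       tags = c("metallocene", "organometallic"))
}

.fx_carborane <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  ) * (1.77 / 2)
  # two adjacent vertices become carbon (ortho-carborane)
  els <- rep("B", 12)
  els[c(1, 2)] <- "C"
  at <- .atoms_new()
  for (r in 1:12) at <- .atoms_add(at, els[r], v[r, ])
  for (r in 1:12) at <- .atoms_add(at, "H", v[r, ] + 1.10 * .unit(v[r, ]))
  list(cif = .molecular_cif("carborane", at),
       expected = NA_character_, tags = "borane")
}

.NACL_GENERATORS <- c("-x,-y,z", "-x,y,-z", "z,x,y", "y,x,-z", "-x,-y,-z",
                      "x+1/2,y+1/2,z", "x+1/2,y,z+1/2")

.fx_nacl <- function() {
  ops <- close_symops(lapply(.NACL_GENERATORS, parse_symop))
  sites <- data.frame(
    label = c("Na1", "Cl1"), element = c("Na", "Cl"),
    fx = c(0, 0.5), fy = c(0, 0), fz = c(0, 0),
    occupancy = 1, assembly = NA_character_, group = NA_character_,
    stringsAsFactors = FALSE
  )
  list(cif = .fixture_cif("nacl", sites, c(5.64, 5.64, 5.64, 90, 90, 90),
                          symops = vapply(ops, serialize_symop, character(1)),
                          z = 4L),
       expected = "[Cl-].[Na+]", tags = "ionic")
}

.fx_copper_metal <- function() {
  sites <- data.frame(
    label = paste0("Cu", 1:4), element = "Cu",
    fx = c(0, 0.5, 0.5, 0), fy = c(0, 0.5, 0, 0.5), fz = c(0, 0, 0.5, 0.5),
    occupancy = 1, assembly = NA_character_, group = NA_character_,
    stringsAsFactors = FALSE
  )
  list(cif = .fixture_cif("copper_metal", sites,
                          c(3.615, 3.615, 3.615, 90, 90, 90), z = 4L),
       expected = "[Cu]", tags = "ionic")
}

.fx_crown_k <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "K", c(0, 0, 0))
  for (k in 0:5) {
    a0 <- pi * k / 3
    O <- c(2.80 * cos(a0), 2.80 * sin(a0), 0)
    at <- .atoms_add(at, "O", O)
    for (dd in c(1, 2)) {
      a <- a0 + dd * pi / 9
      C <- c(3.55 * cos(a), 3.55 * sin(a), (if (dd == 1) 0.35 else -0.35))
      at <- .atoms_add(at, "C", C)
      at <- .atoms_add(at, "H", C + 1.09 * .unit(c(C[1], C[2], 3)))
      at <- .atoms_add(at, "H", C + 1.09 * .unit(c(C[1], C[2], -3)))
    }
  }
  at <- .atoms_add(at, "I", c(0, 0, 8.5))
  list(cif = .molecular_cif("crown_k", at, a = 30),
       expected = NA_character_, tags = "ionic")
}

.fx_pf6_salt <- function() {
  at <- .atoms_new()
  at <- .atoms_add(at, "K", c(-5, 0, 0))
  at <- .atoms_add(at, "P", c(2, 0, 0))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (k in 1:6) at <- .atoms_add(at, "F", c(2, 0, 0) + 1.60 * dirs[k, ])
  list(cif = .molecular_cif("pf6_salt", at),
       expected = "[K+].[P](F)(F)(F)(F)(F)[F-]", tags = c("ionic", "haloanion"))
}

.fx_disorder_two_site <- function() {
  at <- .atoms_new()
  C <- c(0, 0, 0)
  at <- .atoms_add(at, "C", C)
  at <- .atoms_add(at, "Cl", c(1.45, 1.02, 0))
  at <- .atoms_add(at, "Cl", c(-1.45, 1.02, 0), occupancy = 0.6,
                   assembly = "A", group = "1")
  at <- .atoms_add(at, "Cl", c(-1.45, -0.7, 0.73), occupancy = 0.4,
                   assembly = "A", group = "2")
  at <- .atoms_add(at, "H", c(0.3, -0.8, 0.75))
  at <- .atoms_add(at, "H", c(0.3, -0.8, -0.75))
  list(cif = .molecular_cif("disorder_two_site", at),
       expected = "ClCCl", tags = "disorder")
}

.fx_hemihydrate <- function() {
  # pyridine in a general position of C2 (axis b), water O on the twofold axis
  a <- 14; b <- 11; cc <- 14
  ring <- .phenyl_from(c(3.0, 3.0, 3.0), c(0, 1, 0), c(1, 0, 0))
  at <- .atoms_new()
  at <- .atoms_add(at, "N", ring[1, ])
  for (r in 2:6) at <- .atoms_add(at, "C", ring[r, ])
  ctr <- colMeans(ring)
  for (r in 2:6) at <- .atoms_add(at, "H", ring[r, ] + 1.08 * .unit(ring[r, ] - ctr))
  at <- .atoms_add(at, "O", c(0, 5.5, 0))
  at <- .atoms_add(at, "H", c(0.76, 5.7, 0.35))
  sites <- at
  sites$fx <- at$x / a; sites$fy <- at$y / b; sites$fz <- at$z / cc
  gb <- data.frame(label1 = c("O1", "O1"), label2 = c("H6", "H6"),
                   distance = c(0.91, 0.91), code = c(".", "2_555"),
                   stringsAsFactors = FALSE)
  list(cif = .fixture_cif("hemihydrate", sites, c(a, b, cc, 90, 90, 90),
                          symops = c("x,y,z", "-x,y,-z"), z = 2L,
                          geom_bonds = gb),
       expected = "O.c1ccncc1", tags = c("special_position", "solvent"))
}

.fx_trans_special <- function() {
  # trans-[Cu(NH3)2Cl2] with Cu on an inversion centre
  a <- 12; b <- 13; cc <- 14
  at <- .atoms_new()
  at <- .atoms_add(at, "Cu", c(0, 0, 0))
  N <- c(2.02, 0, 0)
  at <- .atoms_add(at, "N", N)
  at <- .atoms_add(at, "Cl", c(0, 2.26, 0))
  at <- .atoms_add(at, "H", N + 1.01 * .unit(c(0.5, 0.8, 0)))
  at <- .atoms_add(at, "H", N + 1.01 * .unit(c(0.5, -0.4, 0.7)))
  at <- .atoms_add(at, "H", N + 1.01 * .unit(c(0.5, -0.4, -0.7)))
  sites <- at
  sites$fx <- at$x / a; sites$fy <- at$y / b; sites$fz <- at$z / cc
  gb <- data.frame(label1 = c("Cu1", "Cu1", "Cu1"),
                   label2 = c("N1", "Cl1", "N1"),
                   distance = c(2.02, 2.26, 2.02),
                   code = c(".", ".", "2_555"), stringsAsFactors = FALSE)
  list(cif = .fixture_cif("trans_special", sites, c(a, b, cc, 90, 90, 90),
                          symops = c("x,y,z", "-x,-y,-z"), z = 1L,
                          geom_bonds = gb),
       expected = "[Cu]([NH3])([NH3])(Cl)Cl",
       tags = c("special_position", "coordination"))
}

.fx_chain_1d <- function() {
  a <- 4.70; b <- 12; cc <- 12
  sites <- data.frame(
    label = c("Cu1", "Cl1"), element = c("Cu", "Cl"),
    fx = c(0, 0.5), fy = c(0, 0), fz = c(0, 0),
    occupancy = 1, assembly = NA_character_, group = NA_character_,
    stringsAsFactors = FALSE
  )
  gb <- data.frame(label1 = c("Cu1", "Cl1"), label2 = c("Cl1", "Cu1"),
                   distance = c(2.35, 2.35), code = c(".", "1_655"),
                   stringsAsFactors = FALSE)
  list(cif = .fixture_cif("chain_1d", sites, c(a, b, cc, 90, 90, 90), z = 1L,
                          geom_bonds = gb),
       expected = "[Cu][Cl][Cu]Cl", tags = "polymer_1d")
}

.fx_sheet_2d <- function() {
  # graphene-like B/O net: a covalent 2-D polymer, out of automated scope
  sites <- data.frame(
    label = c("B1", "O1"), element = c("B", "O"),
    fx = c(1 / 3, 2 / 3), fy = c(2 / 3, 1 / 3), fz = c(0, 0),
    occupancy = 1, assembly = NA_character_, group = NA_character_,
    stringsAsFactors = FALSE
  )
  gb <- data.frame(label1 = "B1", label2 = "O1", distance = 1.41,
                   code = "1_655", stringsAsFactors = FALSE)
  list(cif = .fixture_cif("sheet_2d", sites, c(2.45, 2.45, 12, 90, 90, 120),
                          z = 1L, geom_bonds = gb),
       expected = NA_character_, marker = "unsupported", tags = "polymer_2d")
}

# tetrahedral directions for a stereocentre
.TET <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

# three tetrahedral directions around axis u (109.47 deg from u)
.tet_dirs <- function(u) {
  u <- .unit(u)
  v <- if (abs(u[3]) < 0.9) .unit(pracma_cross(u, c(0, 0, 1))) else
    .unit(pracma_cross(u, c(1, 0, 0)))
  w <- pracma_cross(u, v)
  t(vapply(0:2, function(k) {
    ang <- 2 * pi * k / 3
    -u / 3 + sqrt(8) / 3 * (v * cos(ang) + w * sin(ang))
  }, numeric(3)))
}

.fx_chiral_sohncke <- function() {
  a <- 10; b <- 11; cc <- 12
  at <- .atoms_new()
  C <- c(2.5, 2.5, 2.5)
  at <- .atoms_add(at, "C", C)
  at <- .atoms_add(at, "F", C + 1.35 * .TET[1, ])
  at <- .atoms_add(at, "Cl", C + 1.77 * .TET[2, ])
  at <- .atoms_add(at, "Br", C + 1.94 * .TET[3, ])
  at <- .atoms_add(at, "H", C + 1.09 * .TET[4, ])
  sites <- at
  sites$fx <- at$x / a; sites$fy <- at$y / b; sites$fz <- at$z / cc
  list(cif = .fixture_cif("chiral_sohncke", sites, c(a, b, cc, 90, 90, 90),
                          symops = c("x,y,z", "x+1/2,-y+1/2,-z",
                                     "-x,y+1/2,-z+1/2", "-x+1/2,-y,z+1/2"),
                          z = 4L),
       expected = NA_character_, tags = c("sohncke", "chiral"))
}

# 2,3-dichloro-2,3-difluorobutane backbone with chosen relative configuration
.butane_stereo_atoms <- function(meso) {
  at <- .atoms_new()
  C2 <- c(0, 0, 0); C3 <- c(1.54, 0, 0)
  d <- .tet_dirs(c(1, 0, 0))   # directions away from the C2->C3 axis
  sub2 <- list(C = C2 + 1.53 * d[1, ], F = C2 + 1.36 * d[2, ],
               Cl = C2 + 1.78 * d[3, ])
  flip <- function(p) {
    if (meso) c(1.54 - p[1], -p[2], -p[3]) else c(1.54 - p[1], -p[2], p[3])
  }
  at <- .atoms_add(at, "C", C2)
  at <- .atoms_add(at, "C", C3)
  at <- .atoms_add(at, "C", sub2$C)
  at <- .atoms_add(at, "C", flip(sub2$C))
  at <- .atoms_add(at, "F", sub2$F)
  at <- .atoms_add(at, "F", flip(sub2$F))
  at <- .atoms_add(at, "Cl", sub2$Cl)
  at <- .atoms_add(at, "Cl", flip(sub2$Cl))
  at <- .atoms_add(at, "H", .methyl_h(sub2$C, sub2$C - C2))
  at <- .atoms_add(at, "H", .methyl_h(flip(sub2$C), flip(sub2$C) - C3))
  at
}

.fx_racemic_two_centers <- function() {
  at <- .butane_stereo_atoms(meso = FALSE)
  a <- 16
  sites <- at
  sites$fx <- at$x / a + 0.3; sites$fy <- at$y / a + 0.3
  sites$fz <- at$z / a + 0.3
  list(cif = .fixture_cif("racemic_two_centers", sites, c(a, a, a, 90, 90, 90),
                          symops = c("x,y,z", "-x,-y,-z"), z = 2L),
       expected = NA_character_, tags = c("racemic", "chiral"))
}

.fx_meso <- function() {
  at <- .butane_stereo_atoms(meso = TRUE)
  a <- 16
  sites <- at
  sites$fx <- at$x / a + 0.3; sites$fy <- at$y / a + 0.3
  sites$fz <- at$z / a + 0.3
  list(cif = .fixture_cif("meso", sites, c(a, a, a, 90, 90, 90),
                          symops = c("x,y,z", "-x,-y,-z"), z = 2L),
       expected = NA_character_, tags = c("meso", "chiral"))
}

.fx_silver_pair <- function() {
  # two Ag(NH3) units; the long Ag..Ag contact is author-listed only
  at <- .atoms_new()
  Ag1 <- c(0, 0, 0); Ag2 <- c(3.65, 0, 0)
  at <- .atoms_add(at, "Ag", Ag1)
  at <- .atoms_add(at, "Ag", Ag2)
  for (p in list(list(Ag1, -1), list(Ag2, 1))) {
    N <- p[[1]] + c(p[[2]] * 2.1, 0, 0)
    at <- .atoms_add(at, "N", N)
    at <- .atoms_add(at, "H", N + 1.01 * .unit(c(p[[2]] * 0.5, 0.9, 0)))
    at <- .atoms_add(at, "H", N + 1.01 * .unit(c(p[[2]] * 0.5, -0.45, 0.78)))
    at <- .atoms_add(at, "H", N + 1.01 * .unit(c(p[[2]] * 0.5, -0.45, -0.78)))
  }
  gb <- data.frame(label1 = "Ag1", label2 = "Ag2", distance = 3.65, code = ".",
                   stringsAsFactors = FALSE)
  list(cif = .molecular_cif("silver_pair", at, geom_bonds = gb),
       expected = NA_character_, marker = "review", tags = "coordination")
}

# ---- catalog ---------------------------------------------------------------

.FIXTURE_BUILDERS <- list(
  water = ".fx_water",
  methanol_z2 = ".fx_methanol_z2",
  pyrrole = ".fx_pyrrole",
  thiophene = ".fx_thiophene",
  cyclopentadiene = ".fx_cyclopentadiene",
  cyclopentadienone = ".fx_cyclopentadienone",
  pyridone2 = ".fx_pyridone2",
  uracil = ".fx_uracil",
  quinone = ".fx_quinone",
  anthraquinone = ".fx_anthraquinone",
  caffeine = ".fx_caffeine",
  en_nickel = ".fx_en_nickel",
  phosphane_gold = ".fx_phosphane_gold",
  zn_hexaaqua = ".fx_zn_hexaaqua",
  co_phenolate = ".fx_co_phenolate",
  cu_pyridine = ".fx_cu_pyridine",
  mn_imidazole = ".fx_mn_imidazole",
  mn_imidazolate = ".fx_mn_imidazolate",
  cd_acetate = ".fx_cd_acetate",
  gd_acac = ".fx_gd_acac",
  nickel_carbonyl = ".fx_nickel_carbonyl",
  co_bridging_carbonyl = ".fx_co_bridging_carbonyl",
  pbet4 = ".fx_pbet4",
  pd_allyl = ".fx_pd_allyl",
  ferrocene = ".fx_ferrocene",
  carborane = ".fx_carborane",
  nacl = ".fx_nacl",
  copper_metal = ".fx_copper_metal",
  crown_k = ".fx_crown_k",
  pf6_salt = ".fx_pf6_salt",
  disorder_two_site = ".fx_disorder_two_site",
  hemihydrate = ".fx_hemihydrate",
  trans_special = ".fx_trans_special",
  chain_1d = ".fx_chain_1d",
  sheet_2d = ".fx_sheet_2d",
  chiral_sohncke = ".fx_chiral_sohncke",
  racemic_two_centers = ".fx_racemic_two_centers",
  meso = ".fx_meso",
  silver_pair = ".fx_silver_pair"
)

# fixtures whose expected SMILES is printed verbatim in the source tables
.PAPER_STRING_FIXTURES <- c(
  "pyrrole", "thiophene", "cyclopentadiene", "cyclopentadienone", "pyridone2",
  "uracil", "quinone", "anthraquinone", "en_nickel", "phosphane_gold",
  "zn_hexaaqua", "co_phenolate", "cu_pyridine", "mn_imidazole",
  "mn_imidazolate", "cd_acetate", "gd_acac", "nickel_carbonyl",
  "co_bridging_carbonyl", "pbet4", "pd_allyl", "ferrocene", "nacl"
)

#' Names of all available fixtures
#' @return character vector.
#' @export
fixture_catalog <- function() names(.FIXTURE_BUILDERS)

#' Names of fixtures whose expected SMILES is a documented convention string
#' @return character vector.
#' @export
paper_string_fixtures <- function() .PAPER_STRING_FIXTURES

#' Build one fixture
#'
#' @param name a name from [fixture_catalog()].
#' @return object of class `fixture`: `name`, `cif` (CIF text), `expected`
#'   (SMILES string or NA), `marker` (`"none"`, `"unsupported"` or
#'   `"review"`), `tags`.
#' @export
build_fixture <- function(name) {
  if (!is.null(.fixture_env[[name]])) return(.fixture_env[[name]])
  fn <- .FIXTURE_BUILDERS[[name]]
  if (is.null(fn)) stop("unknown fixture '", name, "'")
  fx <- get(fn, mode = "function")()
  fx$name <- name
  if (is.null(fx$marker)) fx$marker <- "none"
  class(fx) <- "fixture"
  .fixture_env[[name]] <- fx
  fx
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("<fixture> %s [%s] expected: %s\n", x$name,
              paste(x$tags, collapse = ","),
              if (is.na(x$expected)) x$marker else x$expected))
  invisible(x)
}

#' Self-check a fixture's geometry against the bond policy
#'
#' Verifies that perceived connectivity separates cleanly: every non-bonded
#' heavy-atom pair must miss the radius criterion by at least `margin`
#' (chelate-ring metal-to-apex contacts, inherently borderline, are exempt).
#'
#' @param name fixture name.
#' @param policy a [bond_policy()].
#' @param margin required clearance in Angstrom.
#' @return data.frame of violating pairs (empty when clean).
#' @export
fixture_geometry_report <- function(name, policy = bond_policy(),
                                    margin = 0.3) {
  fx <- build_fixture(name)
  entry <- parse_cif(fx$cif)[[1]]
  cart <- fract_to_cartesian(entry$cell,
                             as.matrix(entry$sites[, c("fx", "fy", "fz")]))
  g <- molgraph(entry$sites$element, coords = cart)
  g <- perceive_bonds(g, policy)
  n <- n_atoms(g)
  bad <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (g$atoms$element[i] == "H" || g$atoms$element[j] == "H") next
    d <- .atom_dist(g, i, j)
    cut <- sum(covalent_radius(c(g$atoms$element[i], g$atoms$element[j]))) +
      policy$offset
    bonded <- !is.na(.bond_index(g, i, j))
    if (!bonded && d < cut + margin) {
      # chelate exemption: both atoms share a bonded neighbor
      if (length(intersect(neighbors(g, i), neighbors(g, j))) > 0) next
      bad[[length(bad) + 1L]] <- data.frame(
        i = i, j = j, el1 = g$atoms$element[i], el2 = g$atoms$element[j],
        dist = d, cutoff = cut)
    }
  }
  if (length(bad) == 0) {
    data.frame(i = integer(0), j = integer(0), el1 = character(0),
               el2 = character(0), dist = numeric(0), cutoff = numeric(0))
  } else {
    do.call(rbind, bad)
  }
}

#' Materialize all fixtures to a directory
#'
#' Writes each CIF plus an `expectations.tsv` manifest (name, expected, tags).
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in fixture_catalog()) {
    fx <- build_fixture(nm)
    writeLines(fx$cif, file.path(dir, paste0(nm, ".cif")))
    rows[[nm]] <- data.frame(name = nm,
                             expected = ifelse(is.na(fx$expected), fx$marker,
                                               fx$expected),
                             tags = paste(fx$tags, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "expectations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
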