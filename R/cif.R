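# CIF 1.1 subset reader/writer: cell, symmetry operators, atom sites,
# geometry bonds, Z. Point geometry only - standard uncertainties are stripped.

#' Unit cell
#'
#' @param a,b,c cell lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return an object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    stop("cell angles must lie in (0, 180)")
  }
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  M <- orthogonalization_matrix(cell)
  if (!all(is.finite(M)) || abs(det(M)) < 1e-9) stop("degenerate unit cell")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g alpha=%.4g beta=%.4g gamma=%.4g\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Standard crystallographic convention: `a` along x, `b` in the xy-plane.
#'
#' @param cell a [unit_cell()].
#' @return 3x3 matrix `M` with `cart = M %*% fract` (Angstrom).
#' @export
orthogonalization_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  cy <- cell$c * (ca - cb * cg) / sg
  cz2 <- cell$c^2 - (cell$c * cb)^2 - cy^2
  if (cz2 <= 0) stop("degenerate unit cell")
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cy,
           0,      0,           sqrt(cz2)),
         nrow = 3, byrow = TRUE)
}

#' Convert fractional to Cartesian coordinates
#'
#' @param cell a [unit_cell()].
#' @param fract numeric 3-vector or n x 3 matrix of fractional coordinates.
#' @return same shape, in Angstrom.
#' @export
fract_to_cartesian <- function(cell, fract) {
  M <- orthogonalization_matrix(cell)
  if (is.matrix(fract)) t(M %*% t(fract)) else as.numeric(M %*% fract)
}

# ---------------------------------------------------------------------------
# low-level CIF text machinery

# strip a standard-uncertainty suffix: "1.234(5)" -> 1.234
.strip_su <- function(x) {
  v <- sub("\\([0-9]+\\)\\s*$", "", trimws(x))
  suppressWarnings(as.numeric(v))
}

# tokenize one CIF line into values, honouring '...' and "..." quoting
.cif_tokens <- function(line) {
  line <- sub("^([^#]*)#.*$", "\\1", paste0(line, " "))
  toks <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "'" || ch == '"') {
      # quoted value: closing quote must be followed by whitespace/EOL
      rest <- substr(line, i + 1L, n)
      m <- regexpr(paste0(ch, "([[:space:]]|$)"), rest)
      if (m < 0) stop("unterminated quoted value in CIF line: ", line)
      toks <- c(toks, substr(rest, 1, m - 1))
      i <- i + 1L + m
    } else {
      rest <- substr(line, i, n)
      m <- regexpr("[[:space:]]", rest)
      if (m < 0) m <- nchar(rest) + 1L
      toks <- c(toks, substr(rest, 1, m - 1))
      i <- i + m
    }
  }
  toks
}

# parse CIF text into blocks: each block = list(name, items = named list,
# loops = list of data.frames (character columns))
.parse_cif_blocks <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  blocks <- list()
  cur <- NULL
  i <- 1L; nl <- length(lines)
  flush <- function() {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  }
  while (i <= nl) {
    line <- lines[i]
    tl <- trimws(line)
    if (tl == "" || startsWith(tl, "#")) { i <- i + 1L; next }
    if (grepl("^data_", tl, ignore.case = TRUE)) {
      flush()
      cur <- list(name = sub("^data_", "", tl, ignore.case = TRUE),
                  items = list(), loops = list())
      i <- i + 1L; next
    }
    if (is.null(cur)) stop("CIF content before any data_ block at line ", i)
    if (startsWith(tl, ";")) {
      # semicolon text field without preceding tag: skip to terminator
      i <- i + 1L
      while (i <= nl && !startsWith(trimws(lines[i]), ";")) i <- i + 1L
      i <- i + 1L; next
    }
    if (tolower(tl) == "loop_") {
      # collect header tags
      i <- i + 1L
      tags <- character(0)
      while (i <= nl) {
        t2 <- trimws(lines[i])
        if (startsWith(t2, "_")) {
          tags <- c(tags, tolower(.cif_tokens(t2)[1]))
          i <- i + 1L
        } else break
      }
      if (length(tags) == 0) stop("malformed loop (no tags) at line ", i)
      vals <- character(0)
      while (i <= nl) {
        t2 <- trimws(lines[i])
        if (t2 == "" || startsWith(t2, "#")) { i <- i + 1L; next }
        if (startsWith(t2, "_") || grepl("^data_", t2, ignore.case = TRUE) ||
            tolower(t2) == "loop_") break
        if (startsWith(t2, ";")) {
          txt <- character(0)
          i <- i + 1L
          while (i <= nl && !startsWith(trimws(lines[i]), ";")) {
            txt <- c(txt, lines[i]); i <- i + 1L
          }
          i <- i + 1L
          vals <- c(vals, paste(txt, collapse = "\n"))
          next
        }
        vals <- c(vals, .cif_tokens(lines[i]))
        i <- i + 1L
      }
      if (length(vals) %% length(tags) != 0) {
        stop("malformed loop for tags ", paste(tags, collapse = ", "),
             ": ", length(vals), " values not a multiple of ", length(tags),
             " columns (near line ", i, ")")
      }
      df <- as.data.frame(matrix(vals, ncol = length(tags), byrow = TRUE),
                          stringsAsFactors = FALSE)
      names(df) <- tags
      cur$loops[[length(cur$loops) + 1L]] <- df
      next
    }
    if (startsWith(tl, "_")) {
      toks <- .cif_tokens(tl)
      tag <- tolower(toks[1])
      if (length(toks) >= 2) {
        cur$items[[tag]] <- paste(toks[-1], collapse = " ")
        i <- i + 1L
      } else {
        # value on following line (possibly semicolon text)
        i <- i + 1L
        while (i <= nl && trimws(lines[i]) == "") i <- i + 1L
        if (i > nl) stop("tag ", tag, " without value at end of file")
        t2 <- trimws(lines[i])
        if (startsWith(t2, ";")) {
          txt <- character(0); i <- i + 1L
          while (i <= nl && !startsWith(trimws(lines[i]), ";")) {
            txt <- c(txt, lines[i]); i <- i + 1L
          }
          i <- i + 1L
          cur$items[[tag]] <- paste(txt, collapse = "\n")
        } else {
          cur$items[[tag]] <- .cif_tokens(t2)[1]
          i <- i + 1L
        }
      }
      next
    }
    stop("cannot interpret CIF line ", i, ": ", line)
  }
  flush()
  blocks
}

# find the first loop containing a given tag
.find_loop <- function(block, tag) {
  for (lp in block$loops) if (tag %in% names(lp)) return(lp)
  NULL
}

# ---------------------------------------------------------------------------

#' Parse CIF text into crystal entries
#'
#' Reads the CIF 1.1 subset needed for SMILES derivation: cell parameters,
#' symmetry operators (either the `_symmetry_equiv_pos_as_xyz` or the
#' `_space_group_symop_operation_xyz` tag family, first present wins), atom
#' sites with occupancies and disorder annotations, `_geom_bond_*` loops and
#' `_cell_formula_units_Z`. Standard-uncertainty suffixes are stripped.
#'
#' @param text CIF content: a single string, a character vector of lines, or a
#'   file path (when `is_file = TRUE`).
#' @param is_file treat `text` as a path.
#' @return list of `crystal_entry` objects, one per data block.
#' @export
parse_cif <- function(text, is_file = FALSE) {
  if (is_file) text <- readLines(text, warn = FALSE)
  blocks <- .parse_cif_blocks(text)
  if (length(blocks) == 0) stop("no data_ block found")
  lapply(blocks, .block_to_entry)
}

.block_to_entry <- function(block) {
  it <- block$items
  need <- function(tag) {
    v <- it[[tag]]
    if (is.null(v)) stop("block '", block$name, "' lacks required tag ", tag)
    v
  }
  cell <- unit_cell(
    a = .strip_su(need("_cell_length_a")),
    b = .strip_su(need("_cell_length_b")),
    c = .strip_su(need("_cell_length_c")),
    alpha = .strip_su(need("_cell_angle_alpha")),
    beta = .strip_su(need("_cell_angle_beta")),
    gamma = .strip_su(need("_cell_angle_gamma"))
  )

  # symmetry operators: accept both tag families; single-value or loop form
  sym_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  xyz <- NULL
  for (tag in sym_tags) {
    lp <- .find_loop(block, tag)
    if (!is.null(lp)) { xyz <- lp[[tag]]; break }
    if (!is.null(it[[tag]])) { xyz <- it[[tag]]; break }
  }
  if (is.null(xyz)) stop("block '", block$name, "' lacks symmetry operators")
  symops <- lapply(xyz, parse_symop)
  if (!any(vapply(symops, function(op) symop_equal(op, symop()), logical(1)))) {
    symops <- c(list(symop()), symops)
  }

  # atom sites
  lp <- .find_loop(block, "_atom_site_fract_x")
  if (is.null(lp)) stop("block '", block$name, "' lacks an atom-site loop")
  labels <- if ("_atom_site_label" %in% names(lp)) lp[["_atom_site_label"]]
            else paste0("A", seq_len(nrow(lp)))
  type_sym <- if ("_atom_site_type_symbol" %in% names(lp)) {
    lp[["_atom_site_type_symbol"]]
  } else {
    sub("^([A-Za-z]{1,2}).*$", "\\1", labels)
  }
  occ <- if ("_atom_site_occupancy" %in% names(lp)) {
    o <- .strip_su(lp[["_atom_site_occupancy"]])
    o[is.na(o)] <- 1
    o
  } else rep(1, nrow(lp))
  sites <- data.frame(
    label = labels,
    element = vapply(seq_along(labels),
                     function(i) normalize_element(type_sym[i], labels[i]),
                     character(1)),
    fx = .strip_su(lp[["_atom_site_fract_x"]]),
    fy = .strip_su(lp[["_atom_site_fract_y"]]),
    fz = .strip_su(lp[["_atom_site_fract_z"]]),
    occupancy = occ,
    disorder_assembly = if ("_atom_site_disorder_assembly" %in% names(lp))
      lp[["_atom_site_disorder_assembly"]] else rep(NA_character_, nrow(lp)),
    disorder_group = if ("_atom_site_disorder_group" %in% names(lp))
      lp[["_atom_site_disorder_group"]] else rep(NA_character_, nrow(lp)),
    stringsAsFactors = FALSE
  )
  sites$disorder_assembly[sites$disorder_assembly %in% c(".", "?")] <- NA
  sites$disorder_group[sites$disorder_group %in% c(".", "?")] <- NA
  if (anyNA(sites$fx) || anyNA(sites$fy) || anyNA(sites$fz)) {
    stop("block '", block$name, "' has non-numeric fractional coordinates")
  }

  # geometry bonds (optional)
  gb <- .find_loop(block, "_geom_bond_atom_site_label_1")
  geom_bonds <- if (is.null(gb)) {
    data.frame(label1 = character(0), label2 = character(0),
               distance = numeric(0), site_symmetry_2 = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      label1 = gb[["_geom_bond_atom_site_label_1"]],
      label2 = gb[["_geom_bond_atom_site_label_2"]],
      distance = if ("_geom_bond_distance" %in% names(gb))
        .strip_su(gb[["_geom_bond_distance"]]) else NA_real_,
      site_symmetry_2 = if ("_geom_bond_site_symmetry_2" %in% names(gb))
        gb[["_geom_bond_site_symmetry_2"]] else ".",
      stringsAsFactors = FALSE
    )
  }
  bad <- setdiff(c(geom_bonds$label1, geom_bonds$label2), sites$label)
  if (length(bad) > 0) {
    stop("block '", block$name, "' geometry bonds reference unknown sites: ",
         paste(bad, collapse = ", "))
  }

  zraw <- it[["_cell_formula_units_z"]]
  if (is.null(zraw)) {
    stop("block '", block$name,
         "' lacks _cell_formula_units_Z; refusing to guess Z")
  }
  z <- as.integer(.strip_su(zraw))
  if (is.na(z) || z < 1) stop("block '", block$name, "' has invalid Z: ", zraw)

  sg_name <- it[["_symmetry_space_group_name_h-m"]]
  if (is.null(sg_name)) sg_name <- it[["_space_group_name_h-m_alt"]]

  structure(list(id = block$name, cell = cell, symops = symops, sites = sites,
                 geom_bonds = geom_bonds, z = z,
                 space_group_name = if (is.null(sg_name)) NA_character_ else sg_name),
            class = "crystal_entry")
}

#' @export
print.crystal_entry <- function(x, ...) {
  cat(sprintf("<crystal_entry> %s: %d sites, %d symops, %d geom bonds, Z=%d\n",
              x$id, nrow(x$sites), length(x$symops), nrow(x$geom_bonds), x$z))
  invisible(x)
}

#' Interpret a CIF site-symmetry code
#'
#' Codes follow the `n_klm` convention: operator index `n` (1-based into the
#' block's operator list) and lattice shift `(k-5, l-5, m-5)`; `"."` and
#' `"1_555"` both denote the identity placement.
#'
#' @param code character scalar such as `"."`, `"1_555"`, `"2_565"`.
#' @return list with `symop_index` (integer) and `shift` (integer 3-vector).
#' @export
parse_sitesym_code <- function(code) {
  if (code == "." || code == "1_555") {
    return(list(symop_index = 1L, shift = c(0L, 0L, 0L)))
  }
  m <- regmatches(code, regexec("^([0-9]+)_([0-9])([0-9])([0-9])$", code))[[1]]
  if (length(m) == 0) {
    m <- regmatches(code, regexec("^([0-9]+)$", code))[[1]]
    if (length(m) == 0) stop("cannot parse site-symmetry code '", code, "'")
    return(list(symop_index = as.integer(m[2]), shift = c(0L, 0L, 0L)))
  }
  list(symop_index = as.integer(m[2]),
       shift = as.integer(m[3:5]) - 5L)
}

#' Write an atom list as a P1 CIF block
#'
#' Emits a single data block with symmetry reduced to `"x,y,z"`. The output is
#' parseable by [parse_cif()] and preserves atom order.
#'
#' @param atoms data.frame with columns `label`, `element`, `fx`, `fy`, `fz`
#'   and optionally `occupancy`.
#' @param cell a [unit_cell()].
#' @param id data block name.
#' @param comments optional character vector written as `#` comment lines
#'   (audit trail: disorder choices, added hydrogens).
#' @return CIF text as a single string.
#' @export
write_p1_cif <- function(atoms, cell, id = "molecule", comments = character(0)) {
  occ <- if ("occupancy" %in% names(atoms)) atoms$occupancy else rep(1, nrow(atoms))
  hdr <- c(
    paste0("data_", id),
    if (length(comments)) paste0("# ", comments),
    sprintf("_cell_length_a %.9g", cell$a),
    sprintf("_cell_length_b %.9g", cell$b),
    sprintf("_cell_length_c %.9g", cell$c),
    sprintf("_cell_angle_alpha %.9g", cell$alpha),
    sprintf("_cell_angle_beta %.9g", cell$beta),
    sprintf("_cell_angle_gamma %.9g", cell$gamma),
    "_cell_formula_units_Z 1",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x,y,z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy"
  )
  rows <- if (nrow(atoms) == 0) character(0) else sprintf(
    "%s %s %.9f %.9f %.9f %.6g",
    atoms$label, atoms$element, atoms$fx, atoms$fy, atoms$fz, occ
  )
  paste(c(hdr, rows, ""), collapse = "\n")
}
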