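# Per-entry triage: Z', disorder and cross-unit bond flags route each entry
# to the correct molecule-building treatment.

.OCC_TOL <- 1e-6   # "0.9999999" in the wild is full occupancy

#' Z' as an exact rational
#'
#' Z' (molecules per asymmetric unit) is the authors' Z divided by the number
#' of symmetry equivalents of the general position, i.e. the number of listed
#' operators including centring translations. The exact rational is reported;
#' the authors' Z is never "fixed".
#'
#' @param z formula units per cell (positive integer).
#' @param n_general_positions number of distinct symmetry operators.
#' @return list with integers `num`, `den` (reduced) and numeric `value`.
#' @export
compute_zprime <- function(z, n_general_positions) {
  stopifnot(z >= 1, n_general_positions >= 1)
  r <- .rat_reduce(as.integer(z), as.integer(n_general_positions))
  list(num = r$num, den = r$den, value = r$num / r$den)
}

#' Disorder flag
#'
#' TRUE iff any atom site has occupancy strictly below one (after stripping
#' standard uncertainties), with a small tolerance absorbing formatting noise.
#'
#' @param entry a `crystal_entry`.
#' @return logical scalar.
#' @export
flag_disorder <- function(entry) {
  any(entry$sites$occupancy < 1 - .OCC_TOL)
}

#' Cross-unit bond flag
#'
#' FALSE when the geometry-bond loop is absent or every
#' `_geom_bond_site_symmetry_2` code is `"."` or `"1_555"` (all listed bonds
#' lie within the asymmetric unit); TRUE otherwise, meaning a polymer or a
#' moiety on a symmetry element.
#'
#' @param entry a `crystal_entry`.
#' @return logical scalar.
#' @export
flag_cross_unit_bonds <- function(entry) {
  gb <- entry$geom_bonds
  if (nrow(gb) == 0) return(FALSE)
  !all(gb$site_symmetry_2 %in% c(".", "1_555"))
}

#' Triage a crystal entry
#'
#' Combines Z' classification, the disorder flag and the cross-unit bond
#' flag. The fast path (`Z' = 1`, ordered, no cross-unit bonds) lets the
#' pipeline skip symmetry reconstruction and go directly to SMILES
#' generation.
#'
#' @param entry a `crystal_entry`.
#' @return an object of class `entry_flags`: `zprime` (list num/den/value),
#'   `zprime_class` (`"sub_one"`, `"one"`, `"multi"`), `disordered`,
#'   `cross_unit_bonds`, `fast_path`, `polymer_dimension` (NA until molecule
#'   building).
#' @export
triage <- function(entry) {
  zp <- compute_zprime(entry$z, length(entry$symops))
  cls <- if (zp$num < zp$den) "sub_one" else if (zp$num == zp$den) "one" else "multi"
  dis <- flag_disorder(entry)
  cub <- flag_cross_unit_bonds(entry)
  structure(list(
    zprime = zp,
    zprime_class = cls,
    disordered = dis,
    cross_unit_bonds = cub,
    fast_path = cls == "one" && !dis && !cub,
    polymer_dimension = NA_integer_
  ), class = "entry_flags")
}

#' @export
print.entry_flags <- function(x, ...) {
  cat(sprintf("<entry_flags> Z'=%d/%d (%s), disordered=%s, cross_unit_bonds=%s%s\n",
              x$zprime$num, x$zprime$den, x$zprime_class, x$disordered,
              x$cross_unit_bonds, if (x$fast_path) " [fast path]" else ""))
  invisible(x)
}
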