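# Element data: symbols, single-bond covalent radii, organic-subset valences,
# metal classification. Kept as plain constants so the package has no binary data.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr"
)

# Single-bond covalent radii in Angstrom (Cordero et al. consensus values).
# C uses the sp3 value; only elements plausibly met in small-molecule CIFs listed,
# anything absent falls back to 1.5 A.
.COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Sc = 1.70,
  Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24,
  Cu = 1.32, Zn = 1.22, Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20,
  Kr = 1.16, Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54,
  Tc = 1.47, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44, In = 1.42,
  Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40, Cs = 2.44, Ba = 2.15,
  La = 2.07, Ce = 2.04, Pr = 2.03, Nd = 2.01, Pm = 1.99, Sm = 1.98, Eu = 1.98,
  Gd = 1.96, Tb = 1.94, Dy = 1.92, Ho = 1.92, Er = 1.89, Tm = 1.90, Yb = 1.87,
  Lu = 1.87, Hf = 1.75, Ta = 1.70, W = 1.62, Re = 1.51, Os = 1.44, Ir = 1.41,
  Pt = 1.36, Au = 1.36, Hg = 1.32, Tl = 1.45, Pb = 1.46, Bi = 1.48, Po = 1.40,
  At = 1.50, Fr = 2.60, Ra = 2.21, Ac = 2.15, Th = 2.06, Pa = 2.00, U = 1.96,
  Np = 1.90, Pu = 1.87
)

# OpenSMILES organic subset and its standard valences.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.STANDARD_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.HALOGENS <- c("F", "Cl", "Br", "I", "At")
.ALKALI <- c("Li", "Na", "K", "Rb", "Cs", "Fr")
.ALKALINE_EARTH <- c("Be", "Mg", "Ca", "Sr", "Ba", "Ra")

# d-block transition metals in the sense of the short metal-metal contact rule
# (Z 21-30, 39-48, 72-80; La/Ac excluded).
.TRANSITION_METALS <- c(
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg"
)

.LANTHANIDES <- c(
  "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy",
  "Ho", "Er", "Tm", "Yb", "Lu"
)
.ACTINIDES <- c(
  "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr"
)
.POST_TRANSITION <- c("Al", "Ga", "In", "Sn", "Tl", "Pb", "Bi", "Po")

# Central atoms eligible for the haloanion charge-redistribution step.
.HALOANION_CENTRALS <- c("B", "P", "S", "As", "Al", "Bi", "Sn", "Si", "Sb")

#' Covalent radius of an element
#'
#' Single-bond covalent radius used by distance-based bond perception.
#' Elements without a tabulated value fall back to 1.5 Angstrom.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .COVALENT_RADII[element]
  r[is.na(r)] <- 1.5
  unname(r)
}

#' Is an element a metal for bonding/representation purposes?
#'
#' Covers alkali, alkaline-earth, transition, lanthanide/actinide and
#' post-transition metals (metalloids B, Si, As, Te and the non-metals are not
#' metals here).
#'
#' @param element character vector of element symbols.
#' @return logical vector.
#' @export
is_metal <- function(element) {
  element %in% c(.ALKALI, .ALKALINE_EARTH, .TRANSITION_METALS, .LANTHANIDES,
                 .ACTINIDES, .POST_TRANSITION, "La", "Ac")
}

#' @rdname is_metal
#' @export
is_transition_metal <- function(element) element %in% .TRANSITION_METALS

is_alkali <- function(element) element %in% .ALKALI
is_alkaline_earth <- function(element) element %in% .ALKALINE_EARTH

#' Standard valences of an organic-subset element
#'
#' @param element single element symbol.
#' @return integer vector of standard valences, or `integer(0)` when the
#'   element is outside the OpenSMILES organic subset.
#' @export
standard_valences <- function(element) {
  v <- .STANDARD_VALENCES[[element]]
  if (is.null(v)) integer(0) else v
}

# Normalize an element symbol coming from a CIF _atom_site_type_symbol or
# label: strip charges/oxidation suffixes ("Cu2+", "O1-"), map deuterium to H,
# reject placeholder symbols.
normalize_element <- function(symbol, label = symbol) {
  s <- sub("^([A-Za-z]{1,2}).*$", "\\1", symbol)
  s <- paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
  if (s == "D" || s == "T") return("H")
  # two-letter guesses that are not elements get retried as one-letter
  if (!(s %in% .ELEMENTS)) {
    s1 <- substr(s, 1, 1)
    if (s1 %in% .ELEMENTS) s <- s1
  }
  if (s %in% c("X", "Q") || !(s %in% .ELEMENTS)) {
    stop("unknown element symbol '", symbol, "' for atom site '", label, "'")
  }
  s
}
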