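# Classify the discrepancy between two SMILES for the same entry into a
# severity-ordered taxonomy, reporting the single most severe category.

#' Discrepancy categories, least to most severe
#' @export
DISCREPANCY_CATEGORIES <- c(
  "identical",
  "missing_double_bond_config_in_other",
  "different_explicit_H_count",
  "missing_chirality_in_other",
  "missing_chirality_in_ours",
  "racemate_representation",
  "nitro_representation",
  "other_group_representation",
  "charge_settings",
  "aromaticity_settings",
  "bond_orders",
  "ionic_representation",
  "missing_O_moieties_in_other",
  "different_connectivity",
  "ring_count",
  "moiety_count",
  "double_bond_config_differs",
  "chiral_config_differs",
  "missing_moieties_in_other",
  "missing_moieties_in_ours",
  "missing_C_in_other",
  "missing_C_in_ours",
  "stoichiometry",
  "chemical_composition",
  "other_reason"
)

# ---- graph normalizations (each returns a transformed copy) ----------------

# tautomeric hydrogen differences live on heteroatoms (imidazole-like N-H);
# carbon hydrogens are structural and keep their stereo roles
.norm_strip_h <- function(g) {
  het <- g$atoms$element %in% c("N", "O", "S")
  g$parity[het] <- lapply(which(het), function(i) {
    p <- g$parity[[i]]
    if (is.null(p) || !any(p$neighbors == 0L)) p else NULL
  })
  g$atoms$hcount[het] <- 0L
  g
}

.norm_strip_chirality <- function(g) {
  g$parity <- vector("list", n_atoms(g))
  g
}

# racemate representation: side A writes both enantiomers as two
# mirror-image moieties where side B writes the molecule once
.is_racemate_pair <- function(ga, gb) {
  ms_a <- mg_moieties(ga)
  if (length(ms_a) < 2) return(FALSE)
  marked <- vapply(ms_a, function(m) {
    any(!vapply(m$parity, is.null, logical(1)))
  }, logical(1))
  if (!any(marked)) return(FALSE)
  keys <- vapply(ms_a, canonicalize, character(1))
  mirror_keys <- vapply(ms_a, function(m) {
    m$parity <- lapply(m$parity, function(p) {
      if (is.null(p)) NULL else { p$sign <- -p$sign; p }
    })
    canonicalize(m)
  }, character(1))
  for (i in seq_along(ms_a)) {
    if (!marked[i]) next
    for (j in seq_along(ms_a)) {
      if (j <= i || !marked[j]) next
      if (keys[j] != mirror_keys[i]) next
      rest <- Reduce(.mg_union, ms_a[-j])
      a2 <- .norm_strip_chirality(rest)
      b2 <- .norm_strip_chirality(gb)
      if (canonicalize(a2) == canonicalize(b2)) return(TRUE)
    }
  }
  FALSE
}

# nitro/nitrate zwitterion form [O-][N+](=O)... -> neutral O=N(=O)...
.norm_nitro <- function(g) {
  for (i in which(g$atoms$element == "N" & g$atoms$charge == 1L)) {
    nb <- neighbors(g, i)
    om <- nb[g$atoms$element[nb] == "O" & g$atoms$charge[nb] == -1L &
             vapply(nb, function(j) bond_order(g, i, j) == 1L, logical(1))]
    od <- nb[g$atoms$element[nb] == "O" &
             vapply(nb, function(j) bond_order(g, i, j) == 2L, logical(1))]
    if (length(om) >= 1L && length(od) >= 1L) {
      j <- om[1]
      g$atoms$charge[i] <- 0L
      g$atoms$charge[j] <- 0L
      g$bonds$order[.bond_index(g, i, j)] <- 2L
    }
  }
  g
}

# diazo/azide/N-oxide charge-separated forms -> neutral cumulated forms
.norm_other_groups <- function(g) {
  g <- .norm_nitro(g)
  # N-oxide [N+][O-] -> N=O
  for (i in which(g$atoms$element == "N" & g$atoms$charge == 1L)) {
    nb <- neighbors(g, i)
    om <- nb[g$atoms$element[nb] == "O" & g$atoms$charge[nb] == -1L]
    if (length(om) >= 1L) {
      j <- om[1]
      g$atoms$charge[c(i, j)] <- 0L
      g$bonds$order[.bond_index(g, i, j)] <- 2L
    }
  }
  # azide/diazo [N-]=[N+]=X -> neutralized
  for (i in which(g$atoms$element == "N" & g$atoms$charge != 0L)) {
    nb <- neighbors(g, i)
    buddy <- nb[g$atoms$element[nb] == "N" & g$atoms$charge[nb] == -g$atoms$charge[i]]
    if (length(buddy) >= 1L) g$atoms$charge[c(i, buddy[1])] <- 0L
  }
  g
}

.norm_strip_charges <- function(g) { g$atoms$charge <- 0L; g }

# harmonize aromatic-flag vs Kekule writings: perceive aromaticity on the
# Kekule side, then flatten every aromatic bond to order one on both
.norm_aromaticity <- function(g) {
  g2 <- tryCatch(perceive_aromaticity(g), error = function(e) g)
  g2$bonds$order[g2$bonds$aromatic] <- 1L
  g2$atoms$force_bracket <- FALSE
  g2$atoms$explicit_bracket <- FALSE
  g2$kekulized <- FALSE
  attr(g2, "ring_analysis") <- NULL
  g2
}

# order-insensitive skeleton: implicit H counts follow bond orders on carbon
# and are dropped along with them
.norm_strip_orders <- function(g) {
  g$bonds$order <- 1L
  g$atoms$hcount <- 0L
  g$parity <- vector("list", n_atoms(g))
  g
}

# drop metal-ligand bonds (ionic vs bonded representations of the same salt)
.norm_ionic <- function(g) {
  metal <- .atom_is_metal(g)
  keep <- !(metal[g$bonds$a1] | metal[g$bonds$a2])
  g$bonds <- g$bonds[keep, , drop = FALSE]
  g
}

.count_o_moieties <- function(g) {
  comp <- mg_components(g)
  sum(vapply(seq_len(max(comp, 0L)), function(ci) {
    m <- which(comp == ci)
    length(m) == 1L && g$atoms$element[m] == "O"
  }, logical(1)))
}

# drop isolated O / water moieties
.norm_drop_o_moieties <- function(g) {
  comp <- mg_components(g)
  drop <- integer(0)
  for (ci in seq_len(max(comp, 0L))) {
    m <- which(comp == ci)
    if (length(m) == 1L && g$atoms$element[m] == "O") drop <- c(drop, m)
  }
  if (length(drop) == 0) return(g)
  keep <- setdiff(seq_len(n_atoms(g)), drop)
  if (length(keep) == 0) return(g)
  mg_subgraph(g, keep)
}

# ---- helpers ---------------------------------------------------------------

# heavy atoms only: hydrogen-count differences have their own (least severe)
# category and must not masquerade as composition changes
.element_multiset <- function(g) {
  tab <- table(g$atoms$element[g$atoms$element != "H"])
  out <- as.integer(tab); names(out) <- names(tab)
  out[order(names(out))]
}

.moiety_keys <- function(g) {
  sort(vapply(mg_moieties(g), canonicalize, character(1)))
}

.has_marks <- function(s) grepl("@", s, fixed = TRUE)

#' Classify the discrepancy between two SMILES
#'
#' Both strings are parsed and canonicalized; a battery of normalizations is
#' applied cumulatively in severity order (directional bond marks, explicit
#' H, chirality, racemate doubling, nitro and related group conventions,
#' charges, aromaticity flags, bond orders, ionic representation, solvent-O
#' moieties) and the first level at which the two sides agree names the
#' category; pairs that stay different are classified structurally
#' (connectivity, ring/moiety counts, missing moieties or carbon,
#' stoichiometry, composition), most severe first.
#'
#' @param ours SMILES from this pipeline.
#' @param other SMILES from the external source.
#' @return a single category string, see [DISCREPANCY_CATEGORIES].
#' @export
classify_discrepancy <- function(ours, other) {
  go <- tryCatch(parse_smiles(ours), error = identity)
  gt <- tryCatch(parse_smiles(other), error = identity)
  if (inherits(go, "error") || inherits(gt, "error")) return("other_reason")
  # cosmetic bracketing ([n] vs n) is not a structural difference
  go$atoms$explicit_bracket <- FALSE
  gt$atoms$explicit_bracket <- FALSE
  if (canonicalize(go) == canonicalize(gt)) {
    # directional bond marks are not interpreted; their bare presence on one
    # side only is still reported
    slash_o <- grepl("[/\\\\]", ours); slash_t <- grepl("[/\\\\]", other)
    if (slash_o != slash_t) return("missing_double_bond_config_in_other")
    return("identical")
  }

  # cumulative representational normalizations, least severe first
  if (.is_racemate_pair(go, gt) || .is_racemate_pair(gt, go)) {
    return("racemate_representation")
  }
  steps <- list(
    list(fn = .norm_strip_h, cat = "different_explicit_H_count"),
    list(fn = .norm_strip_chirality, cat = "chirality"),
    list(fn = .norm_nitro, cat = "nitro_representation"),
    list(fn = .norm_other_groups, cat = "other_group_representation"),
    list(fn = .norm_strip_charges, cat = "charge_settings"),
    list(fn = .norm_aromaticity, cat = "aromaticity_settings"),
    list(fn = .norm_strip_orders, cat = "bond_orders"),
    list(fn = .norm_ionic, cat = "ionic_representation"),
    list(fn = .norm_drop_o_moieties, cat = "missing_O_moieties_in_other")
  )
  ho <- .has_marks(ours); ht <- .has_marks(other)
  n_o_ours <- .count_o_moieties(go); n_o_other <- .count_o_moieties(gt)
  co <- go; ct <- gt
  for (st in steps) {
    if (st$cat == "missing_O_moieties_in_other" && n_o_ours <= n_o_other) next
    co <- st$fn(co); ct <- st$fn(ct)
    if (canonicalize(co) == canonicalize(ct)) {
      if (st$cat == "chirality") {
        if (ho && !ht) return("missing_chirality_in_other")
        if (ht && !ho) return("missing_chirality_in_ours")
        return("chiral_config_differs")
      }
      return(st$cat)
    }
  }

  # structural classification, most severe first
  eo <- .element_multiset(go); et <- .element_multiset(gt)
  ko <- .moiety_keys(go); kt <- .moiety_keys(gt)
  if (!identical(eo, et)) {
    uo <- unique(ko); ut <- unique(kt)
    if (all(ut %in% uo) && length(setdiff(uo, ut)) > 0) {
      return("missing_moieties_in_other")
    }
    if (all(uo %in% ut) && length(setdiff(ut, uo)) > 0) {
      return("missing_moieties_in_ours")
    }
    if (setequal(uo, ut)) return("stoichiometry")
    no_c <- eo[setdiff(names(eo), "C")]; nt_c <- et[setdiff(names(et), "C")]
    c_o <- if ("C" %in% names(eo)) eo[["C"]] else 0L
    c_t <- if ("C" %in% names(et)) et[["C"]] else 0L
    if (identical(no_c, nt_c) && c_o != c_t) {
      return(if (c_t < c_o) "missing_C_in_other" else "missing_C_in_ours")
    }
    return("chemical_composition")
  }
  if (length(ko) != length(kt)) return("moiety_count")
  if (cycle_rank(go) != cycle_rank(gt)) return("ring_count")
  "different_connectivity"
}

#' Summarize a set of discrepancy classifications
#'
#' @param classifications character vector of category names.
#' @return data.frame (category, count, percent) in severity order.
#' @export
summarize_discrepancies <- function(classifications) {
  counts <- vapply(DISCREPANCY_CATEGORIES, function(cat) {
    sum(classifications == cat)
  }, integer(1))
  n <- length(classifications)
  data.frame(category = DISCREPANCY_CATEGORIES,
             count = counts,
             percent = if (n > 0) round(100 * counts / n, 2) else 0,
             stringsAsFactors = FALSE)
}
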