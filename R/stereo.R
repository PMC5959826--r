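# Tetrahedral stereocenters from 3-D geometry and the Sohncke/racemate
# conventions.
#
# Only tetrahedral centres are marked. In a Sohncke space group the crystal
# contains a single enantiomer and the asymmetric unit's configuration is
# representative; in a non-Sohncke group the crystal is racemic: a lone
# chiral mark is simply removed ("unspecified" is reread as "both
# enantiomers"), while a moiety with two or more marks is written twice, the
# second copy with every @ and @@ swapped. Meso moieties (identical to their
# mirror image) are written once.

.PLANARITY_CUTOFF <- 0.1   # A^3: |signed volume| below this refuses a parity

# invariant-refinement ranks WITHOUT tie-break desymmetrization: automorphic
# atoms share a rank, which is what neighbor-distinctness tests need
refined_ranks <- function(g) {
  n <- n_atoms(g)
  if (n == 0) return(integer(0))
  inv <- .atom_invariant(g)
  adjb <- replicate(n, list(to = integer(0), cls = character(0)),
                    simplify = FALSE)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    cl <- .bond_class(g, k)
    adjb[[i]]$to <- c(adjb[[i]]$to, j); adjb[[i]]$cls <- c(adjb[[i]]$cls, cl)
    adjb[[j]]$to <- c(adjb[[j]]$to, i); adjb[[j]]$cls <- c(adjb[[j]]$cls, cl)
  }
  rank <- match(inv, sort(unique(inv)))
  .refine_ranks(g, seq_len(n), rank, adjb)
}

#' Perceive tetrahedral stereocenters from coordinates
#'
#' An atom with four distinct substituents (an implicit hydrogen counts as
#' one, placed at the idealized fourth vertex) receives a parity from the
#' sign of the signed volume spanned by its neighbors. Substituent
#' distinctness uses graph-level refinement ranks, matching SMILES
#' semantics; near-planar centres are skipped with a warning.
#'
#' @param g graph with Cartesian coordinates, orders and hydrogens final.
#' @return the graph with `parity` entries set.
#' @export
perceive_tetrahedral <- function(g) {
  rk <- refined_ranks(g)
  for (i in seq_len(n_atoms(g))) {
    nb <- neighbors(g, i)
    h <- g$atoms$hcount[i]
    if (length(nb) + h != 4L || h > 1L) next
    if (g$atoms$element[i] %in% c("H")) next
    idx <- which(g$bonds$a1 == i | g$bonds$a2 == i)
    if (any(g$bonds$order[idx] > 1L) || any(g$bonds$aromatic[idx])) next
    subranks <- rk[nb]
    if (h == 1L) subranks <- c(subranks, -1L)   # implicit H distinct
    if (length(unique(subranks)) != 4L) next
    ctr <- c(g$atoms$x[i], g$atoms$y[i], g$atoms$z[i])
    if (anyNA(ctr)) next
    pos <- lapply(nb, function(j) c(g$atoms$x[j], g$atoms$y[j], g$atoms$z[j]))
    if (h == 1L) {
      u <- Reduce(`+`, lapply(pos, function(p) {
        v <- p - ctr; v / sqrt(sum(v^2))
      }))
      hpos <- ctr - u / max(sqrt(sum(u^2)), 1e-9)
      pos <- c(pos, list(hpos))
      nbl <- c(nb, 0L)
    } else {
      nbl <- nb
    }
    # store neighbors sorted by atom id, implicit H last
    ord <- order(ifelse(nbl == 0L, Inf, nbl))
    nbl <- nbl[ord]; pos <- pos[ord]
    v <- do.call(cbind, lapply(pos[2:4], function(p) p - pos[[1]]))
    vol <- det(v)
    if (abs(vol) < .PLANARITY_CUTOFF) {
      warning("near-planar centre at atom ", i, "; no parity assigned")
      next
    }
    g$parity[[i]] <- list(neighbors = nbl, sign = if (vol < 0) -1L else 1L)
  }
  g
}

#' Apply the Sohncke/racemate policy to a written moiety set
#'
#' @param smiles SMILES string (moieties joined by `"."`), marks present.
#' @param sohncke is the entry's space group a Sohncke group?
#' @return list: `smiles` (final string), `verdict` (data.frame per moiety:
#'   marks, policy one of kept/marks_stripped/enantiomer_doubled/meso_single/
#'   unchanged).
#' @export
apply_racemate_policy <- function(smiles, sohncke) {
  moieties <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  count_marks <- function(s) {
    lengths(regmatches(s, gregexpr("@@|@", s)))
  }
  marks <- count_marks(moieties)
  if (sohncke || all(marks == 0)) {
    pol <- ifelse(marks > 0, "kept", "unchanged")
    return(list(smiles = smiles,
                verdict = data.frame(moiety = moieties, marks = marks,
                                     policy = pol, stringsAsFactors = FALSE)))
  }
  canon_all <- vapply(moieties, canon_smiles, character(1))
  out <- character(0)
  policy <- character(length(moieties))
  for (k in seq_along(moieties)) {
    s <- moieties[k]
    if (marks[k] == 0L) {
      policy[k] <- "unchanged"
      out <- c(out, s)
    } else if (marks[k] == 1L) {
      g <- parse_smiles(s)
      had <- !vapply(g$parity, is.null, logical(1))
      g$parity <- vector("list", n_atoms(g))
      g$atoms$explicit_bracket[had] <- FALSE
      out <- c(out, canonicalize(g))
      policy[k] <- "marks_stripped"
    } else {
      mirror <- invert_stereo_marks(s)
      cm <- canon_smiles(mirror)
      if (cm == canon_all[k]) {
        policy[k] <- "meso_single"
        out <- c(out, s)
      } else if (cm %in% canon_all[-k]) {
        # the enantiomer is already present (idempotence on doubled output)
        policy[k] <- "enantiomer_doubled"
        out <- c(out, s)
      } else {
        policy[k] <- "enantiomer_doubled"
        out <- c(out, s, mirror)
      }
    }
  }
  list(smiles = paste(out, collapse = "."),
       verdict = data.frame(moiety = moieties, marks = marks, policy = policy,
                            stringsAsFactors = FALSE))
}

#' Stereochemistry verdict for an entry
#'
#' @param symops the entry's operator list.
#' @param smiles written SMILES before the racemate policy.
#' @return object of class `stereo_verdict`.
#' @export
stereo_verdict <- function(symops, smiles) {
  soh <- is_sohncke(symops)
  res <- apply_racemate_policy(smiles, soh)
  structure(list(is_sohncke = soh,
                 n_stereocenters = lengths(regmatches(
                   res$verdict$moiety, gregexpr("@@|@", res$verdict$moiety))),
                 verdict = res$verdict,
                 smiles = res$smiles),
            class = "stereo_verdict")
}
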