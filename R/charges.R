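# Formal charges and the ionic representation policy.
#
# Charges are assigned only where chemical convention places them beyond
# doubt: isolated monoatomic ions, terminal atoms of oxo- and haloanions,
# uncoordinated carboxylates/phenolates, ammonium/phosphonium. Coordination
# compounds never receive formal charges, neither on the metal nor on the
# ligands.

.moiety_has_metal <- function(g, members) any(is_metal(g$atoms$element[members]))

#' Assign conventional formal charges
#'
#' @param g graph with final connectivity, orders and hydrogen counts.
#' @return the graph with `charge` set; attribute `"charge_log"` records each
#'   assignment.
#' @export
assign_formal_charges <- function(g) {
  comp <- mg_components(g)
  tie_rank <- canonical_ranks(g)
  log <- character(0)
  for (ci in seq_len(max(comp, 0L))) {
    members <- which(comp == ci)
    els <- g$atoms$element[members]
    # monoatomic ions
    if (length(members) == 1L) {
      i <- members
      if (g$atoms$hcount[i] == 0L) {
        el <- els[1]
        chg <- if (is_alkali(el)) 1L else if (is_alkaline_earth(el)) 2L
               else if (el %in% .HALOGENS) -1L else 0L
        if (chg != 0L) {
          g$atoms$charge[i] <- chg
          log <- c(log, sprintf("monoatomic ion %s%+d", el, chg))
        }
      }
      next
    }
    # haloanion: one central atom from the conventional set plus halogens only
    uniq <- unique(els)
    if (length(uniq) == 2L && any(uniq %in% .HALOANION_CENTRALS) &&
        any(uniq %in% .HALOGENS)) {
      central_el <- uniq[uniq %in% .HALOANION_CENTRALS][1]
      hal_el <- uniq[uniq %in% .HALOGENS][1]
      if (central_el != hal_el) {
        centrals <- members[els == central_el]
        if (length(centrals) == 1L) {
          i <- centrals
          nhal <- sum(els == hal_el)
          maxval <- .max_central_valence(central_el)
          deficit <- nhal - maxval
          if (deficit > 0L && length(neighbors(g, i)) == nhal) {
            hs <- members[els == hal_el]
            hs <- hs[order(tie_rank[hs])]
            g$atoms$charge[hs[seq_len(deficit)]] <- -1L
            log <- c(log, sprintf("haloanion %s%s%d charge %+d on terminal halogen(s)",
                                  central_el, hal_el, nhal, -deficit))
            next
          }
        }
      }
    }
    # coordination compounds: no formal charges
    if (.moiety_has_metal(g, members)) next
    for (i in members) {
      el <- g$atoms$element[i]
      nb <- neighbors(g, i)
      if (el == "O" && g$atoms$hcount[i] == 0L && length(nb) == 1L &&
          bond_order(g, i, nb) == 1L) {
        # bare terminal single-bonded O: oxoanion / carboxylate / phenolate
        g$atoms$charge[i] <- -1L
        log <- c(log, sprintf("terminal anionic O at atom %d", i))
      }
      if (el %in% c("N", "P")) {
        idx <- which(g$bonds$a1 == i | g$bonds$a2 == i)
        s <- sum(g$bonds$order[idx]) + g$atoms$hcount[i]
        if (length(nb) + g$atoms$hcount[i] == 4L && s == 4L &&
            all(g$bonds$order[idx] == 1L) && !any(g$bonds$aromatic[idx])) {
          g$atoms$charge[i] <- 1L
          log <- c(log, sprintf("%s+ onium at atom %d", el, i))
        }
      }
    }
  }
  attr(g, "charge_log") <- log
  g
}

.max_central_valence <- function(el) {
  switch(el, B = 3L, Al = 3L, P = 5L, As = 5L, Sb = 5L, Bi = 5L,
         S = 6L, Si = 4L, Sn = 4L, 4L)
}

#' Apply the ionic representation policy
#'
#' Extended (polymeric) frameworks cannot be written as SMILES: alkali and
#' alkaline-earth cations embedded in a polymeric network are severed into
#' bare monoatomic cations (they keep their bonds in finite moieties such as
#' crown-ether complexes); purely metallic components collapse to isolated
#' atoms; a remaining polymeric framework made of one (transition or
#' post-transition) metal plus simple monoatomic inorganic anions is
#' disconnected into its ions.
#'
#' @param g built graph.
#' @param dims integer vector: polymer dimension of each atom's moiety
#'   (0 = finite), as computed by the molecule builder.
#' @return the graph with bonds severed accordingly; attribute `"ionic_log"`
#'   records the actions.
#' @export
apply_ionic_policy <- function(g, dims) {
  log <- character(0)
  comp <- mg_components(g)
  for (ci in seq_len(max(comp, 0L))) {
    members <- which(comp == ci)
    if (max(dims[members]) < 2L) next   # 1-D polymers keep their connectivity
    els <- g$atoms$element[members]
    if (all(is_metal(els)) && length(unique(els)) == 1L) {
      # metallic crystal: isolated atoms
      keep <- !(g$bonds$a1 %in% members & g$bonds$a2 %in% members)
      g$bonds <- g$bonds[keep, , drop = FALSE]
      log <- c(log, sprintf("metallic component of %s represented as isolated atoms",
                            els[1]))
      next
    }
    aek <- members[is_alkali(els) | is_alkaline_earth(els)]
    if (length(aek) > 0) {
      keep <- !(g$bonds$a1 %in% aek | g$bonds$a2 %in% aek)
      g$bonds <- g$bonds[keep, , drop = FALSE]
      log <- c(log, sprintf("severed %d alkali/alkaline-earth cation(s) from an extended framework",
                            length(aek)))
    }
  }
  # second pass: frameworks of a single metal plus simple monoatomic anions
  comp <- mg_components(g)
  for (ci in seq_len(max(comp, 0L))) {
    members <- which(comp == ci)
    if (max(dims[members]) < 2L) next
    els <- g$atoms$element[members]
    metals <- unique(els[is_metal(els)])
    anions <- unique(els[!is_metal(els)])
    simple <- length(anions) > 0 &&
      all(anions %in% c(.HALOGENS, "O", "S", "Se", "Te")) &&
      all(g$atoms$hcount[members] == 0L)
    if (length(metals) == 1L && simple) {
      keep <- !(g$bonds$a1 %in% members & g$bonds$a2 %in% members)
      g$bonds <- g$bonds[keep, , drop = FALSE]
      log <- c(log, sprintf("ionic framework %s/%s disconnected into ions",
                            metals, paste(anions, collapse = ",")))
    }
  }
  attr(g, "ionic_log") <- log
  g
}
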