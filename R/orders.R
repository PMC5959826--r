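# Kekule bond-order assignment.
#
# Unsaturation is distributed by a maximum matching over atoms that have not
# reached a standard valence, after the convention rules for metal carbonyls /
# isocyanides and hapto-aromatic (metallocene-type) rings have been applied.
# Metal-ligand bonds do not consume ligand valence during matching; a penalty
# steers double bonds away from metal-bound atoms, which reproduces the
# single-resonance-form conventions for chelates, eta-3 allyls and anionic
# aromatic N donors without dedicated rules.

# valence target for matching: smallest standard valence that accommodates the
# atom's non-metal sigma bonds plus hydrogens
.matching_need <- function(g, i, metal) {
  a <- g$atoms[i, ]
  if (metal[i]) return(0L)
  v <- standard_valences(a$element)
  if (length(v) == 0) return(0L)
  idxb <- which(g$bonds$a1 == i | g$bonds$a2 == i)
  s <- a$hcount
  for (k in idxb) {
    other <- if (g$bonds$a1[k] == i) g$bonds$a2[k] else g$bonds$a1[k]
    if (!metal[other]) s <- s + g$bonds$order[k]
  }
  fit <- v[v >= s]
  if (length(fit) == 0) return(0L)
  as.integer(fit[1] - s)
}

# terminal carbonyl / isocyanide conventions; returns list(g, handled)
.apply_carbonyl_rules <- function(g, metal) {
  handled <- logical(n_atoms(g))
  for (i in seq_len(n_atoms(g))) {
    if (g$atoms$element[i] != "C" || g$atoms$hcount[i] != 0L) next
    nb <- neighbors(g, i)
    mets <- nb[metal[nb]]
    rest <- nb[!metal[nb]]
    if (length(mets) == 0 || length(rest) != 1) next
    j <- rest[1]
    if (!(g$atoms$element[j] %in% c("O", "N"))) next
    jn <- neighbors(g, j)
    if (g$atoms$element[j] == "O") {
      if (length(jn) != 1 || g$atoms$hcount[j] != 0L) next
      ord <- if (length(mets) == 1) 3L else 2L   # terminal C#O vs bridging C=O
      g$bonds$order[.bond_index(g, i, j)] <- ord
      g$bonds$origin[.bond_index(g, i, j)] <- "convention_rule"
      handled[c(i, j)] <- TRUE
    } else {
      # isocyanide M-C#N-R: N carries one further substituent
      if (length(mets) != 1 || length(jn) > 2) next
      g$bonds$order[.bond_index(g, i, j)] <- 3L
      g$bonds$origin[.bond_index(g, i, j)] <- "convention_rule"
      handled[c(i, j)] <- TRUE
    }
  }
  list(g = g, handled = handled)
}

# oxo-group rule: central p-block atom with >= 2 bare terminal O gets double
# bonds up to its highest oxo valence; remaining terminal O stay single
# (charged later in anion context)
.OXO_VALENCE <- c(N = 5L, P = 5L, As = 5L, S = 6L, Se = 6L,
                  Cl = 7L, Br = 7L, I = 7L)

.apply_oxo_rules <- function(g, metal, handled, tie_rank) {
  for (i in seq_len(n_atoms(g))) {
    el <- g$atoms$element[i]
    if (!(el %in% names(.OXO_VALENCE)) || metal[i] || handled[i]) next
    nb <- neighbors(g, i)
    term_o <- nb[vapply(nb, function(j) {
      g$atoms$element[j] == "O" && g$atoms$hcount[j] == 0L &&
        length(neighbors(g, j)) == 1 && !handled[j]
    }, logical(1))]
    if (length(term_o) < 2) next
    sigma <- length(nb) + g$atoms$hcount[i]
    ndouble <- min(length(term_o), .OXO_VALENCE[[el]] - sigma)
    if (ndouble <= 0) { handled[i] <- TRUE; handled[term_o] <- TRUE; next }
    term_o <- term_o[order(tie_rank[term_o])]
    for (j in term_o[seq_len(ndouble)]) {
      g$bonds$order[.bond_index(g, i, j)] <- 2L
      g$bonds$origin[.bond_index(g, i, j)] <- "convention_rule"
    }
    handled[i] <- TRUE
    handled[term_o] <- TRUE
  }
  list(g = g, handled = handled)
}

# detect hapto-aromatic rings: every ring atom is a carbon bonded to one
# common metal atom (metallocene Cp, eta-6 arenes); mark them aromatic with
# forced brackets and no Kekule unsaturation
.apply_hapto_rings <- function(g, metal, handled) {
  # ring search on the metal-free subgraph: the metal centre itself closes
  # 3-cycles with every bonded ring pair and would mask the carbocycle
  organic <- which(!metal)
  if (length(organic) < 4) return(list(g = g, handled = handled))
  sub <- mg_subgraph(g, organic)
  rings <- lapply(find_rings(sub, max_size = 8L),
                  function(r) organic[r])
  for (ring in rings) {
    if (length(ring) < 4) next
    if (!all(g$atoms$element[ring] == "C")) next
    common <- NULL
    ok <- TRUE
    for (v in ring) {
      mets <- neighbors(g, v)
      mets <- mets[metal[mets]]
      if (length(mets) == 0) { ok <- FALSE; break }
      common <- if (is.null(common)) mets else intersect(common, mets)
      if (length(common) == 0) { ok <- FALSE; break }
    }
    if (!ok) next
    g$atoms$aromatic[ring] <- TRUE
    g$atoms$force_bracket[ring] <- TRUE
    handled[ring] <- TRUE
    for (k in seq_along(ring)) {
      v <- ring[k]; w <- ring[if (k == length(ring)) 1 else k + 1]
      bi <- .bond_index(g, v, w)
      g$bonds$aromatic[bi] <- TRUE
      g$bonds$order[bi] <- 1L
    }
  }
  list(g = g, handled = handled)
}

# fullerene special case: an all-carbon 3-connected cage of >= 60 atoms is
# aromatic wholesale; substituted (4-connected) cage carbons stay aliphatic
.apply_fullerene <- function(g, handled) {
  comp <- mg_components(g)
  for (ci in seq_len(max(comp, 0L))) {
    members <- which(comp == ci)
    if (length(members) < 60) next
    if (!all(g$atoms$element[members] == "C")) next
    deg <- vapply(members, function(i) length(neighbors(g, i)), integer(1))
    if (!all(deg %in% c(3L, 4L))) next
    if (sum(deg == 3L) < 0.8 * length(members)) next
    arom <- members[deg == 3L]
    g$atoms$aromatic[arom] <- TRUE
    handled[members] <- TRUE
    for (k in seq_len(nrow(g$bonds))) {
      if (g$bonds$a1[k] %in% arom && g$bonds$a2[k] %in% arom) {
        g$bonds$aromatic[k] <- TRUE
      }
    }
  }
  list(g = g, handled = handled)
}

# exact small-scale maximum matching with (size, -metal_penalty, lexicographic)
# objective; returns list of edge index increments
.match_unsaturation <- function(g, need, metal_bound, tie_rank, max_nodes = 200000L) {
  cand_edges <- which(vapply(seq_len(nrow(g$bonds)), function(k) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    need[i] > 0L && need[j] > 0L && !g$bonds$aromatic[k]
  }, logical(1)))
  if (length(cand_edges) == 0) return(integer(0))
  # deterministic edge order by tie ranks
  ekey <- vapply(cand_edges, function(k) {
    r <- sort(c(tie_rank[g$bonds$a1[k]], tie_rank[g$bonds$a2[k]]))
    r[1] * 100000 + r[2]
  }, numeric(1))
  cand_edges <- cand_edges[order(ekey)]
  penalty <- vapply(cand_edges, function(k) {
    as.integer(metal_bound[g$bonds$a1[k]]) + as.integer(metal_bound[g$bonds$a2[k]])
  }, integer(1))

  best <- NULL
  best_score <- c(-1, 0)
  nodes <- 0L
  atoms_in <- sort(unique(c(g$bonds$a1[cand_edges], g$bonds$a2[cand_edges])))

  recurse <- function(need, chosen, size, pen) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) return(invisible(NULL))
    live <- which(vapply(cand_edges, function(k) {
      need[g$bonds$a1[k]] > 0L && need[g$bonds$a2[k]] > 0L
    }, logical(1)))
    if (length(live) == 0) {
      if (size > best_score[1] ||
          (size == best_score[1] && pen < best_score[2]) ||
          (size == best_score[1] && pen == best_score[2] && is.null(best))) {
        best <<- chosen
        best_score <<- c(size, pen)
      }
      return(invisible(NULL))
    }
    ub <- size + floor(sum(need[atoms_in]) / 2)
    if (ub < best_score[1]) return(invisible(NULL))
    # branch on the unsatisfied atom of lowest tie rank that still has live
    # edges: either one of its live edges carries an increment, or the atom
    # stays unsatisfied
    ends <- unique(c(g$bonds$a1[cand_edges[live]], g$bonds$a2[cand_edges[live]]))
    a <- ends[which.min(tie_rank[ends])]
    inc <- live[g$bonds$a1[cand_edges[live]] == a |
                g$bonds$a2[cand_edges[live]] == a]
    for (li in inc) {
      k <- cand_edges[li]
      n2 <- need
      n2[g$bonds$a1[k]] <- n2[g$bonds$a1[k]] - 1L
      n2[g$bonds$a2[k]] <- n2[g$bonds$a2[k]] - 1L
      recurse(n2, c(chosen, k), size + 1L, pen + penalty[li])
    }
    n3 <- need
    n3[a] <- 0L
    recurse(n3, chosen, size, pen)
    invisible(NULL)
  }
  recurse(need, integer(0), 0L, 0L)
  if (is.null(best)) integer(0) else best
}

#' Assign Kekule bond orders
#'
#' Applies the representation conventions (terminal metal carbonyls written
#' `C#[O]`, bridging carbonyls ketone-like `C=O`, oxo groups with doubles on
#' uncharged oxygens, hapto-aromatic rings, fullerene cages), then places the
#' remaining unsaturation by maximum matching so organic-subset atoms reach a
#' standard valence where possible. Atoms with leftover unsaturation bonded to
#' a single metal raise that metal bond's order (carbene-like); otherwise they
#' are flagged for brackets.
#'
#' @param g graph with final connectivity, explicit H folded into `hcount`.
#' @return the graph with orders assigned; attribute `"order_log"` lists the
#'   convention decisions taken.
#' @export
assign_bond_orders <- function(g) {
  metal <- .atom_is_metal(g)
  log <- character(0)
  tie_rank <- canonical_ranks(g)

  res <- .apply_carbonyl_rules(g, metal)
  g <- res$g; handled <- res$handled
  if (any(handled)) log <- c(log, "carbonyl/isocyanide convention applied")
  res <- .apply_hapto_rings(g, metal, handled)
  g <- res$g; handled <- res$handled
  res <- .apply_fullerene(g, handled)
  g <- res$g; handled <- res$handled
  res <- .apply_oxo_rules(g, metal, handled, tie_rank)
  g <- res$g; handled <- res$handled

  need <- vapply(seq_len(n_atoms(g)), function(i) {
    if (handled[i]) 0L else .matching_need(g, i, metal)
  }, integer(1))
  metal_bound <- vapply(seq_len(n_atoms(g)), function(i) {
    any(metal[neighbors(g, i)])
  }, logical(1))

  # repeated single increments let the matching build double and triple bonds
  repeat {
    incr <- .match_unsaturation(g, need, metal_bound, tie_rank)
    if (length(incr) == 0) break
    for (k in incr) {
      g$bonds$order[k] <- g$bonds$order[k] + 1L
      need[g$bonds$a1[k]] <- need[g$bonds$a1[k]] - 1L
      need[g$bonds$a2[k]] <- need[g$bonds$a2[k]] - 1L
    }
  }

  # leftovers: carbene-like metal double bonds, otherwise brackets
  for (i in which(need > 0L)) {
    nb <- neighbors(g, i)
    mets <- nb[metal[nb]]
    if (g$atoms$element[i] == "C" && length(mets) == 1) {
      k <- .bond_index(g, i, mets[1])
      newo <- min(3L, max(g$bonds$order[k], need[i]))
      if (newo != g$bonds$order[k]) {
        g$bonds$order[k] <- newo
        g$bonds$origin[k] <- "convention_rule"
        log <- c(log, sprintf("metal-carbon bond order %d at atom %d", newo, i))
      }
    } else if (length(mets) == 0) {
      g$atoms$force_bracket[i] <- TRUE
      log <- c(log, sprintf("atom %d left without a standard valence", i))
    }
  }
  attr(g, "order_log") <- log
  g
}
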