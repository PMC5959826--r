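# Aromaticity perception on a Kekule graph.
#
# A ring without exocyclic double bonds is aromatic when every atom can take
# part in the conjugated system and the pi count obeys Hueckel's 4n+2 rule
# (each atom engaged in a double bond contributes one pi electron; an
# endocyclic singly bonded N, O or S contributes its lone pair, as does a
# carbanion - such atoms do not break aromaticity). A ring that carries
# exocyclic double bonds is aromatic iff at least one in-ring single bond
# flanked by two in-ring double bonds survives, which separates
# cyclopentadienone and 2-pyridone (aromatic) from quinones (non-aromatic).

.ring_bond_orders <- function(g, ring) {
  m <- length(ring)
  vapply(seq_len(m), function(k) {
    v <- ring[k]; w <- ring[if (k == m) 1 else k + 1]
    g$bonds$order[.bond_index(g, v, w)]
  }, integer(1))
}

# does atom i have a double/triple bond (to anyone)?
.has_multiple_bond <- function(g, i) {
  any(g$bonds$order[g$bonds$a1 == i | g$bonds$a2 == i] >= 2L)
}

#' Perceive aromatic rings
#'
#' Evaluates every smallest ring of size 4-7 on the assigned Kekule
#' structure; aromatic rings get lower-case atoms and aromatic ring bonds
#' (Kekule orders are retained alongside). Hapto-aromatic (metallocene) rings
#' set during order assignment are left untouched.
#'
#' @param g graph with Kekule orders assigned.
#' @return the graph; attribute `"ring_analysis"` holds a data.frame with one
#'   row per examined ring (size, pi count where defined, verdict).
#' @export
perceive_aromaticity <- function(g) {
  rings <- Filter(function(r) length(r) >= 4 && length(r) <= 7,
                  find_rings(g, max_size = 7L))
  analysis <- list()
  for (ring in rings) {
    m <- length(ring)
    if (any(g$atoms$force_bracket[ring] & g$atoms$aromatic[ring])) next  # hapto
    elig <- vapply(ring, function(i) {
      el <- g$atoms$element[i]
      if (.has_multiple_bond(g, i)) return(el %in% c("B", "C", "N", "O", "P", "S"))
      if (el %in% c("N", "O", "S")) return(TRUE)
      el == "C" && g$atoms$charge[i] == -1L
    }, logical(1))
    ring_orders <- .ring_bond_orders(g, ring)
    exo_double <- vapply(ring, function(i) {
      idx <- which(g$bonds$a1 == i | g$bonds$a2 == i)
      any(vapply(idx, function(k) {
        other <- if (g$bonds$a1[k] == i) g$bonds$a2[k] else g$bonds$a1[k]
        g$bonds$order[k] >= 2L && !(other %in% ring)
      }, logical(1)))
    }, logical(1))
    pi <- NA_integer_
    if (!all(elig)) {
      verdict <- FALSE
    } else if (any(exo_double)) {
      # single bond comprised between two double bonds must survive in-ring
      nxt <- c(seq_len(m)[-1], 1L)
      prv <- c(m, seq_len(m)[-m])
      verdict <- any(ring_orders == 1L &
                     ring_orders[nxt] == 2L & ring_orders[prv] == 2L)
    } else {
      pi <- sum(vapply(ring, function(i) {
        if (.has_multiple_bond(g, i)) return(1L)
        el <- g$atoms$element[i]
        if (el %in% c("N", "O", "S")) return(2L)
        if (el == "C" && g$atoms$charge[i] == -1L) return(2L)
        0L
      }, integer(1)))
      verdict <- pi %% 4L == 2L
    }
    analysis[[length(analysis) + 1L]] <-
      data.frame(size = m, pi = pi, aromatic = verdict,
                 atoms = paste(ring, collapse = ","))
    if (verdict) {
      g$atoms$aromatic[ring] <- TRUE
      for (k in seq_len(m)) {
        v <- ring[k]; w <- ring[if (k == m) 1 else k + 1]
        g$bonds$aromatic[.bond_index(g, v, w)] <- TRUE
      }
    }
  }
  attr(g, "ring_analysis") <- if (length(analysis) > 0) {
    do.call(rbind, analysis)
  } else {
    data.frame(size = integer(0), pi = integer(0), aromatic = logical(0),
               atoms = character(0))
  }
  g
}
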