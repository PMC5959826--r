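# Molecular graph container used throughout the pipeline.
#
# Atoms carry element, formal charge, explicit-H count, aromatic flag,
# Cartesian coordinates (NA when graph was parsed from a string), and
# bookkeeping flags; bonds carry a Kekule order (1/2/3) plus an aromatic flag.
# A graph built by the pipeline is "kekulized": orders on aromatic bonds are
# real Kekule orders. A graph parsed from SMILES is not (aromatic bonds store
# order 1 and the aromatic flag).

#' Construct a molecular graph
#'
#' @param elements character vector of element symbols.
#' @param charge integer vector of formal charges.
#' @param hcount integer vector of explicit hydrogen counts.
#' @param coords optional n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param aromatic logical vector of aromatic flags.
#' @param kekulized do bond orders on aromatic bonds carry Kekule information?
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(elements, charge = 0L, hcount = 0L, coords = NULL,
                     aromatic = FALSE, kekulized = TRUE) {
  n <- length(elements)
  atoms <- data.frame(
    element = as.character(elements),
    charge = as.integer(rep_len(charge, n)),
    hcount = as.integer(rep_len(hcount, n)),
    aromatic = rep_len(aromatic, n),
    force_bracket = rep_len(FALSE, n),
    explicit_bracket = rep_len(FALSE, n),
    label = rep_len(NA_character_, n),
    occupancy = rep_len(1, n),
    stringsAsFactors = FALSE
  )
  if (is.null(coords)) {
    coords <- matrix(NA_real_, n, 3)
  } else {
    coords <- matrix(as.numeric(coords), n, 3)
  }
  atoms$x <- coords[, 1]; atoms$y <- coords[, 2]; atoms$z <- coords[, 3]
  structure(list(
    atoms = atoms,
    bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                       aromatic = logical(0), origin = character(0),
                       stringsAsFactors = FALSE),
    parity = vector("list", n),
    kekulized = kekulized
  ), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds%s\n", nrow(x$atoms), nrow(x$bonds),
              if (x$kekulized) "" else " (non-kekulized)"))
  invisible(x)
}

#' Number of atoms
#' @param g a [molgraph()].
#' @return integer.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' Add (or overwrite) a bond
#'
#' @param g a [molgraph()].
#' @param i,j atom indices (1-based); self-bonds are rejected.
#' @param order bond order 1, 2 or 3.
#' @param aromatic aromatic-bond flag.
#' @param origin provenance tag (`"distance"`, `"cif_listed"`,
#'   `"convention_rule"`, ...).
#' @return the modified graph.
#' @export
add_bond <- function(g, i, j, order = 1L, aromatic = FALSE, origin = "distance") {
  if (i == j) stop("self-bonds are not allowed")
  a1 <- min(i, j); a2 <- max(i, j)
  k <- which(g$bonds$a1 == a1 & g$bonds$a2 == a2)
  row <- data.frame(a1 = a1, a2 = a2, order = as.integer(order),
                    aromatic = aromatic, origin = origin,
                    stringsAsFactors = FALSE)
  if (length(k) > 0) g$bonds[k[1], ] <- row else g$bonds <- rbind(g$bonds, row)
  g
}

#' Delete a bond if present
#' @inheritParams add_bond
#' @export
drop_bond <- function(g, i, j) {
  a1 <- min(i, j); a2 <- max(i, j)
  k <- which(g$bonds$a1 == a1 & g$bonds$a2 == a2)
  if (length(k) > 0) g$bonds <- g$bonds[-k, , drop = FALSE]
  g
}

# adjacency list: integer vector of neighbors per atom
.adjacency <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Neighbors of an atom
#' @param g a [molgraph()].
#' @param i atom index.
#' @return integer vector of neighbor indices.
#' @export
neighbors <- function(g, i) {
  c(g$bonds$a2[g$bonds$a1 == i], g$bonds$a1[g$bonds$a2 == i])
}

# bond row index between i and j, or NA
.bond_index <- function(g, i, j) {
  a1 <- min(i, j); a2 <- max(i, j)
  k <- which(g$bonds$a1 == a1 & g$bonds$a2 == a2)
  if (length(k) == 0) NA_integer_ else k[1]
}

#' Bond order between two atoms (0 when not bonded)
#' @inheritParams add_bond
#' @export
bond_order <- function(g, i, j) {
  k <- .bond_index(g, i, j)
  if (is.na(k)) 0L else g$bonds$order[k]
}

# sum of Kekule bond orders at an atom (excluding implicit H)
.order_sum <- function(g, i) {
  sum(g$bonds$order[g$bonds$a1 == i | g$bonds$a2 == i])
}

#' Connected components (moieties)
#'
#' @param g a [molgraph()].
#' @return integer vector: component id per atom, numbered in order of first
#'   appearance.
#' @export
mg_components <- function(g) {
  n <- n_atoms(g)
  adj <- .adjacency(g)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' Extract the subgraph induced by a set of atoms
#'
#' Bonds to atoms outside `idx` are dropped; parities referencing dropped
#' neighbors are removed.
#'
#' @param g a [molgraph()].
#' @param idx integer vector of atom indices to keep.
#' @return a [molgraph()].
#' @export
mg_subgraph <- function(g, idx) {
  idx <- sort(unique(as.integer(idx)))
  map <- integer(n_atoms(g)); map[idx] <- seq_along(idx)
  out <- g
  out$atoms <- g$atoms[idx, , drop = FALSE]
  rownames(out$atoms) <- NULL
  keep <- g$bonds$a1 %in% idx & g$bonds$a2 %in% idx
  b <- g$bonds[keep, , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  sw <- b$a1 > b$a2
  tmp <- b$a1[sw]; b$a1[sw] <- b$a2[sw]; b$a2[sw] <- tmp
  rownames(b) <- NULL
  out$bonds <- b
  out$parity <- lapply(g$parity[idx], function(p) {
    if (is.null(p)) return(NULL)
    nb <- p$neighbors
    if (any(nb > 0L & !(nb %in% idx))) return(NULL)
    nz <- nb > 0L
    nb[nz] <- map[nb[nz]]
    p$neighbors <- nb
    p
  })
  out
}

#' Split a graph into its moieties
#' @param g a [molgraph()].
#' @return list of [molgraph()]s in component order.
#' @export
mg_moieties <- function(g) {
  comp <- mg_components(g)
  lapply(seq_len(max(comp, 0L)), function(ci) mg_subgraph(g, which(comp == ci)))
}

#' Permute the storage order of atoms
#'
#' Relabels atoms so that old atom `perm[k]` becomes new atom `k`; the
#' represented structure is unchanged. Used by the canonical-invariance
#' property tests.
#'
#' @param g a [molgraph()].
#' @param perm a permutation of `1:n_atoms(g)`.
#' @return a [molgraph()].
#' @export
mg_permute <- function(g, perm) {
  n <- n_atoms(g)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- integer(n); inv[perm] <- seq_len(n)
  out <- g
  out$atoms <- g$atoms[perm, , drop = FALSE]
  rownames(out$atoms) <- NULL
  b <- g$bonds
  b$a1 <- inv[b$a1]; b$a2 <- inv[b$a2]
  sw <- b$a1 > b$a2
  tmp <- b$a1[sw]; b$a1[sw] <- b$a2[sw]; b$a2[sw] <- tmp
  out$bonds <- b
  out$parity <- lapply(g$parity[perm], function(p) {
    if (is.null(p)) return(NULL)
    nb <- p$neighbors
    nz <- nb > 0L
    nb[nz] <- inv[nb[nz]]
    p$neighbors <- nb
    p
  })
  out
}

#' Smallest rings of a graph
#'
#' For every bond, the shortest cycle through it is located by breadth-first
#' search; duplicates are merged. Rings longer than `max_size` are ignored.
#'
#' @param g a [molgraph()].
#' @param max_size largest ring size reported.
#' @return list of integer vectors (atom indices in ring order).
#' @export
find_rings <- function(g, max_size = 12L) {
  adj <- .adjacency(g)
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    # shortest path i -> j avoiding the direct edge
    n <- n_atoms(g)
    prev <- integer(n); prev[] <- -1L
    prev[i] <- 0L
    queue <- i
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == i && w == j) next
        if (prev[w] == -1L) {
          prev[w] <- v
          if (w == j) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (!found) next
    path <- j
    v <- j
    while (prev[v] != 0L) { v <- prev[v]; path <- c(path, v) }
    if (length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

#' Cycle rank (number of independent rings)
#' @param g a [molgraph()].
#' @return integer: bonds - atoms + components.
#' @export
cycle_rank <- function(g) {
  n <- n_atoms(g)
  if (n == 0) return(0L)
  nrow(g$bonds) - n + max(mg_components(g))
}

# metal flag per atom
.atom_is_metal <- function(g) is_metal(g$atoms$element)

#' Does an atom need square brackets when written?
#'
#' Brackets are needed when the Kekule bond-order sum plus explicit hydrogens
#' does not equal a standard valence, the charge is non-zero, a tetrahedral
#' parity is recorded, or the element lies outside the organic subset
#' (conventionally-aromatic ring atoms bound to metals are forced).
#'
#' @param g a [molgraph()].
#' @return logical vector over atoms.
#' @export
atom_needs_bracket <- function(g) {
  vapply(seq_len(n_atoms(g)), function(i) .needs_bracket(g, i), logical(1))
}

.arom_implied_h <- function(element, degree) {
  if (element == "C" && degree == 2) 1L else 0L
}

.needs_bracket <- function(g, i) {
  a <- g$atoms[i, ]
  if (a$force_bracket || a$explicit_bracket) return(TRUE)
  if (a$charge != 0L) return(TRUE)
  if (!is.null(g$parity[[i]])) return(TRUE)
  if (!(a$element %in% .ORGANIC_SUBSET)) return(TRUE)
  deg <- length(neighbors(g, i))
  if (a$aromatic) {
    if (!(a$element %in% c("B", "C", "N", "O", "P", "S"))) return(TRUE)
    if (a$hcount != .arom_implied_h(a$element, deg)) return(TRUE)
    if (g$kekulized) {
      s <- .order_sum(g, i) + a$hcount
      if (!(s %in% standard_valences(a$element))) return(TRUE)
    }
    return(FALSE)
  }
  s <- .order_sum(g, i)
  v <- standard_valences(a$element)
  # Kekule graphs follow the convention: brackets whenever the bond-order
  # sum (plus hydrogens) is not a standard valence
  if (g$kekulized && !((s + a$hcount) %in% v)) return(TRUE)
  fit <- v[v >= s]
  implied <- if (length(fit) == 0) 0L else fit[1] - s
  implied != a$hcount
}
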