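# SMILES writer. Two orderings: "canonical" (invariant-refinement ranks,
# moiety strings sorted) and "input" (atom order as stored - used where a
# rewritten string should keep the layout of its source, e.g. the haloanion
# recharge step).

# permutation parity: +1 even, -1 odd; perm maps positions -> values
.perm_sign <- function(perm) {
  n <- length(perm)
  visited <- logical(n)
  sgn <- 1L
  for (i in seq_len(n)) {
    if (!visited[i]) {
      j <- i; len <- 0L
      while (!visited[j]) { visited[j] <- TRUE; j <- perm[j]; len <- len + 1L }
      if (len %% 2L == 0L) sgn <- -sgn
    }
  }
  sgn
}

# chirality token for atom i given the written neighbor order (0 = implicit H)
.parity_token <- function(g, i, written) {
  p <- g$parity[[i]]
  if (is.null(p)) return("")
  if (length(written) != 4L || length(p$neighbors) != 4L) {
    stop("internal error: parity on atom ", i, " without 4 distinct neighbors")
  }
  perm <- match(written, p$neighbors)
  if (anyNA(perm)) stop("internal error: parity neighbor mismatch on atom ", i)
  sgn <- p$sign * .perm_sign(perm)
  if (sgn < 0L) "@" else "@@"
}

.atom_token <- function(g, i, written_nbrs) {
  a <- g$atoms[i, ]
  sym <- a$element
  arom_ok <- a$element %in% c("B", "C", "N", "O", "P", "S")
  if (a$aromatic && arom_ok) sym <- tolower(sym)
  if (!.needs_bracket(g, i)) return(sym)
  chir <- .parity_token(g, i, written_nbrs)
  hpart <- if (a$hcount == 1L) "H" else if (a$hcount > 1L) paste0("H", a$hcount) else ""
  cpart <- ""
  if (a$charge == 1L) cpart <- "+"
  else if (a$charge == -1L) cpart <- "-"
  else if (a$charge > 1L) cpart <- paste0("+", a$charge)
  else if (a$charge < -1L) cpart <- paste0("-", abs(a$charge))
  paste0("[", sym, chir, hpart, cpart, "]")
}

# bond token preceding a neighbor (chain bond or ring digit)
.bond_token <- function(g, k) {
  if (g$bonds$aromatic[k]) return("")
  ord <- g$bonds$order[k]
  if (ord == 2L) return("=")
  if (ord == 3L) return("#")
  i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
  if (g$atoms$aromatic[i] && g$atoms$aromatic[j]) return("-")
  ""
}

# write one moiety given a global rank vector; returns the string
.write_moiety <- function(g, members, rank) {
  root <- members[which.min(rank[members])]
  adj <- .adjacency(g)
  visited <- logical(n_atoms(g))
  parent <- integer(n_atoms(g))

  # spanning DFS to classify ring edges
  ring_edges <- list()   # per atom: list of partner atoms
  order_visit <- integer(0)
  stack <- root
  visited[root] <- TRUE
  edge_seen <- character(0)
  dfs_children <- vector("list", n_atoms(g))
  dfs <- function(v) {
    order_visit <<- c(order_visit, v)
    nbrs <- adj[[v]]
    nbrs <- nbrs[order(rank[nbrs])]
    for (w in nbrs) {
      ek <- paste(min(v, w), max(v, w))
      if (ek %in% edge_seen) next
      if (visited[w]) {
        edge_seen <<- c(edge_seen, ek)
        ring_edges[[length(ring_edges) + 1L]] <<- c(v, w)
      } else {
        edge_seen <<- c(edge_seen, ek)
        visited[w] <<- TRUE
        parent[w] <<- v
        dfs_children[[v]] <<- c(dfs_children[[v]], w)
        dfs(w)
      }
    }
  }
  dfs(root)

  # ring digit bookkeeping: for each ring edge, digit assigned when its first
  # endpoint (in visit order) is written
  pos_in_visit <- integer(n_atoms(g))
  pos_in_visit[order_visit] <- seq_along(order_visit)
  ring_at <- vector("list", n_atoms(g))  # atom -> list of (partner, bondrow)
  for (re in ring_edges) {
    v <- re[1]; w <- re[2]
    k <- .bond_index(g, v, w)
    first <- if (pos_in_visit[v] < pos_in_visit[w]) v else w
    second <- if (first == v) w else v
    ring_at[[first]] <- c(ring_at[[first]], list(list(partner = second, bond = k)))
    ring_at[[second]] <- c(ring_at[[second]], list(list(partner = first, bond = k)))
  }

  digit_free <- c(1:9, 10:99)
  open_digit <- list()  # key "i-j" -> digit
  written <- logical(n_atoms(g))

  emit <- function(v) {
    toks <- character(0)
    written[v] <<- TRUE
    written_nbrs <- integer(0)
    if (parent[v] != 0L) written_nbrs <- parent[v]
    a <- g$atoms[v, ]
    will_bracket <- .needs_bracket(g, v)
    if (!is.null(g$parity[[v]]) && a$hcount > 0L && will_bracket) {
      written_nbrs <- c(written_nbrs, 0L)
    }
    # ring closures at this atom, ordered: closures (partner already written)
    # by digit, then openings by partner rank
    ras <- ring_at[[v]]
    ring_toks <- character(0)
    if (length(ras) > 0) {
      closes <- Filter(function(r) written[r$partner], ras)
      opens <- Filter(function(r) !written[r$partner], ras)
      if (length(closes) > 0) {
        dg <- vapply(closes, function(r) {
          open_digit[[paste(min(v, r$partner), max(v, r$partner))]]
        }, numeric(1))
        closes <- closes[order(dg)]
      }
      if (length(opens) > 0) {
        opens <- opens[order(rank[vapply(opens, `[[`, numeric(1), "partner")])]
      }
      for (r in c(closes, opens)) {
        key <- paste(min(v, r$partner), max(v, r$partner))
        if (!is.null(open_digit[[key]])) {
          d <- open_digit[[key]]
          open_digit[[key]] <<- NULL
          digit_free <<- sort(c(digit_free, d))
          ring_toks <- c(ring_toks, if (d > 9) paste0("%", d) else as.character(d))
        } else {
          d <- digit_free[1]
          digit_free <<- digit_free[-1]
          open_digit[[key]] <<- d
          ring_toks <- c(ring_toks,
                         paste0(.bond_token(g, r$bond),
                                if (d > 9) paste0("%", d) else as.character(d)))
        }
        written_nbrs <- c(written_nbrs, r$partner)
      }
    }
    kids <- dfs_children[[v]]
    written_nbrs <- c(written_nbrs, kids)
    toks <- c(toks, .atom_token(g, v, written_nbrs), ring_toks)
    if (length(kids) > 0) {
      for (ki in seq_along(kids)) {
        w <- kids[ki]
        sub <- emit(w)
        btok <- .bond_token(g, .bond_index(g, v, w))
        if (ki < length(kids)) {
          toks <- c(toks, "(", btok, sub, ")")
        } else {
          toks <- c(toks, btok, sub)
        }
      }
    }
    paste(toks, collapse = "")
  }
  emit(root)
}

#' Write a molecular graph as SMILES
#'
#' Bracket atoms carry explicit H counts and charges; aromatic atoms are
#' written lower-case; ring-closure digits are reused after closing, with
#' `%nn` beyond 9; moieties are joined with `"."`.
#'
#' @param g a [molgraph()].
#' @param order `"canonical"` (default) ranks atoms by the canonicalizer and
#'   sorts moiety strings; `"input"` keeps stored atom order and moiety order.
#' @return a SMILES string.
#' @export
write_smiles <- function(g, order = c("canonical", "input")) {
  order <- match.arg(order)
  if (n_atoms(g) == 0) return("")
  comp <- mg_components(g)
  rank <- if (order == "canonical") canonical_ranks(g) else seq_len(n_atoms(g))
  parts <- vapply(seq_len(max(comp)), function(ci) {
    .write_moiety(g, which(comp == ci), rank)
  }, character(1))
  if (order == "canonical") parts <- sort(parts)
  paste(parts, collapse = ".")
}

#' Canonical SMILES of a graph
#'
#' @param g a [molgraph()].
#' @return character scalar: the canonical serialization.
#' @export
canonicalize <- function(g) write_smiles(g, order = "canonical")

#' Canonical form of a SMILES string
#'
#' Convenience wrapper: `canonicalize(parse_smiles(s))`. Two strings denote
#' the same structure under the package's conventions iff their canonical
#' forms are equal.
#'
#' @param smiles a SMILES string.
#' @return character scalar.
#' @export
canon_smiles <- function(smiles) canonicalize(parse_smiles(smiles))
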