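# OpenSMILES-dialect parser: organic subset, bracket atoms with charge /
# explicit H / tetrahedral @ marks, ring closures including %nn, dots,
# aromatic lower-case atoms. Directional bond characters / and \ are accepted
# and read as single bonds (no E/Z interpretation). Errors carry the 1-based
# character position.

.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

.smiles_error <- function(msg, pos) {
  stop(sprintf("SMILES parse error at position %d: %s", pos, msg), call. = FALSE)
}

# parse a bracket atom body (without the enclosing []), return list
.parse_bracket_body <- function(body, pos) {
  m <- regexec(
    "^([0-9]*)(\\*|[A-Z][a-z]?|as|se|[bcnops])(@@|@)?(H[0-9]*)?(\\+[0-9]+|-[0-9]+|\\++|-+)?(:[0-9]+)?$",
    body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0) .smiles_error(paste0("bad bracket atom '[", body, "]'"), pos)
  sym <- g[3]
  aromatic <- sym %in% c(.AROMATIC_ORGANIC, "as", "se")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
  } else sym
  if (element == "*") .smiles_error("wildcard atoms not supported", pos)
  if (!(element %in% .ELEMENTS)) {
    .smiles_error(paste0("unknown element '", sym, "'"), pos)
  }
  h <- 0L
  if (g[5] != "") {
    h <- if (g[5] == "H") 1L else as.integer(substring(g[5], 2))
  }
  chg <- 0L
  if (g[6] != "") {
    c1 <- g[6]
    if (grepl("^[+-][0-9]+$", c1)) {
      chg <- as.integer(c1)
    } else {
      chg <- nchar(c1) * (if (startsWith(c1, "+")) 1L else -1L)
    }
  }
  chir <- g[4]
  list(element = element, aromatic = aromatic, hcount = h, charge = chg,
       chirality = if (chir == "") NA_character_ else chir)
}

#' Parse a SMILES string into a molecular graph
#'
#' Implicit hydrogens on unbracketed atoms are materialized into the atoms'
#' explicit-H counts. Aromatic bonds (implicit between two aromatic atoms, or
#' `:`) are flagged aromatic with order 1; the resulting graph is marked
#' non-kekulized when it contains aromatic atoms.
#'
#' @param smiles a SMILES string.
#' @return a [molgraph()].
#' @export
parse_smiles <- function(smiles) {
  s <- smiles
  n <- nchar(s)
  atoms <- list()          # list of atom description lists
  bonds <- list()          # list(i, j, class) class: 1,2,3,"a"
  written_nbrs <- list()   # per atom: written neighbor order (0 = implicit H)
  ring_open <- list()      # digit -> list(atom, class, pos)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL          # pending bond class before next atom/ring digit
  i <- 1L

  add_atom <- function(desc, pos) {
    atoms[[length(atoms) + 1L]] <<- desc
    id <- length(atoms)
    written_nbrs[[id]] <<- integer(0)
    if (!is.na(prev)) {
      cls <- if (!is.null(pending)) pending else {
        if (isTRUE(atoms[[prev]]$aromatic) && isTRUE(desc$aromatic)) "a" else 1L
      }
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = id, class = cls, pos = pos)
      written_nbrs[[prev]] <<- c(written_nbrs[[prev]], id)
      written_nbrs[[id]] <<- c(written_nbrs[[id]], prev)
    }
    pending <<- NULL
    # implicit H placeholder for parity accounting comes right after the
    # preceding atom
    if (!is.na(desc$chirality) && desc$hcount > 0L) {
      written_nbrs[[id]] <<- c(written_nbrs[[id]], 0L)
    }
    prev <<- id
    id
  }

  handle_ring <- function(digit, pos) {
    if (is.na(prev)) .smiles_error("ring closure before any atom", pos)
    key <- as.character(digit)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      if (op$atom == prev) .smiles_error("ring closure to the same atom", pos)
      cls <- pending
      if (is.null(cls)) cls <- op$class
      if (is.null(cls)) {
        cls <- if (isTRUE(atoms[[op$atom]]$aromatic) &&
                   isTRUE(atoms[[prev]]$aromatic)) "a" else 1L
      }
      if (!is.null(op$class) && !is.null(pending) && !identical(op$class, pending)) {
        .smiles_error(paste0("conflicting bond symbols on ring closure ", key), pos)
      }
      bonds[[length(bonds) + 1L]] <<- list(i = op$atom, j = prev, class = cls, pos = pos)
      # fill the reserved position on the opening atom; append on the closer
      wn <- written_nbrs[[op$atom]]
      wn[wn == -digit - 1000L] <- prev
      written_nbrs[[op$atom]] <<- wn
      written_nbrs[[prev]] <<- c(written_nbrs[[prev]], op$atom)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <- list(atom = prev, class = pending, pos = pos)
      ring_open <<- ring_open
      written_nbrs[[prev]] <<- c(written_nbrs[[prev]], -digit - 1000L)
    }
    pending <<- NULL
  }

  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == " " || ch == "\t") { i <- i + 1L; next }
    if (ch == "[") {
      close <- regexpr("]", substr(s, i + 1L, n), fixed = TRUE)
      if (close < 0) .smiles_error("unterminated bracket atom", i)
      body <- substr(s, i + 1L, i + close - 1L)
      desc <- .parse_bracket_body(body, i)
      desc$bracket <- TRUE
      add_atom(desc, i)
      i <- i + close + 1L
      next
    }
    two <- substr(s, i, i + 1L)
    if (two %in% c("Cl", "Br")) {
      add_atom(list(element = two, aromatic = FALSE, hcount = NA_integer_,
                    charge = 0L, chirality = NA_character_, bracket = FALSE), i)
      i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(list(element = ch, aromatic = FALSE, hcount = NA_integer_,
                    charge = 0L, chirality = NA_character_, bracket = FALSE), i)
      i <- i + 1L; next
    }
    if (ch %in% .AROMATIC_ORGANIC) {
      add_atom(list(element = toupper(ch), aromatic = TRUE, hcount = NA_integer_,
                    charge = 0L, chirality = NA_character_, bracket = FALSE), i)
      i <- i + 1L; next
    }
    if (ch %in% c("-", "/", "\\")) { pending <- 1L; i <- i + 1L; next }
    if (ch == "=") { pending <- 2L; i <- i + 1L; next }
    if (ch == "#") { pending <- 3L; i <- i + 1L; next }
    if (ch == ":") { pending <- "a"; i <- i + 1L; next }
    if (ch == "(") {
      if (is.na(prev)) .smiles_error("branch before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L; next
    }
    if (ch == ")") {
      if (length(stack) == 0) .smiles_error("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (grepl("^[0-9]$", ch)) { handle_ring(as.integer(ch), i); i <- i + 1L; next }
    if (ch == "%") {
      dd <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", dd)) .smiles_error("bad %nn ring closure", i)
      handle_ring(as.integer(dd), i)
      i <- i + 3L; next
    }
    if (ch == ".") {
      prev <- NA_integer_
      pending <- NULL
      i <- i + 1L; next
    }
    .smiles_error(paste0("unexpected character '", ch, "'"), i)
  }
  if (length(stack) > 0) .smiles_error("unclosed branch", n)
  if (length(ring_open) > 0) {
    .smiles_error(paste0("unmatched ring closure(s): ",
                         paste(names(ring_open), collapse = ", ")), n)
  }
  if (length(atoms) == 0) .smiles_error("empty SMILES", 1L)

  g <- molgraph(vapply(atoms, `[[`, character(1), "element"),
                charge = vapply(atoms, `[[`, integer(1), "charge"),
                hcount = 0L,
                aromatic = vapply(atoms, function(a) isTRUE(a$aromatic), logical(1)),
                kekulized = TRUE)
  for (b in bonds) {
    if (!is.na(.bond_index(g, b$i, b$j))) {
      .smiles_error("duplicate bond between the same atom pair", b$pos)
    }
    g <- add_bond(g, b$i, b$j,
                  order = if (identical(b$class, "a")) 1L else b$class,
                  aromatic = identical(b$class, "a"), origin = "parsed")
  }
  if (any(g$atoms$aromatic)) g$kekulized <- FALSE

  # materialize hydrogens
  for (k in seq_along(atoms)) {
    a <- atoms[[k]]
    if (a$bracket) {
      g$atoms$hcount[k] <- a$hcount
      g$atoms$explicit_bracket[k] <- TRUE
    } else {
      g$atoms$hcount[k] <- .implied_hydrogens(g, k)
    }
  }

  # record tetrahedral parities
  for (k in seq_along(atoms)) {
    chir <- atoms[[k]]$chirality
    if (is.na(chir)) next
    nb <- written_nbrs[[k]]
    if (any(nb < 0)) .smiles_error("internal: unresolved ring neighbor", 1L)
    if (length(nb) != 4L) {
      .smiles_error(paste0("chiral atom ", k, " does not have 4 neighbors"), 1L)
    }
    g$parity[[k]] <- list(neighbors = nb,
                          sign = if (chir == "@") -1L else 1L)
  }
  g
}

# implicit H count a reader would infer for an unbracketed atom
.implied_hydrogens <- function(g, i) {
  a <- g$atoms[i, ]
  deg <- length(neighbors(g, i))
  if (a$aromatic) return(.arom_implied_h(a$element, deg))
  idx <- g$bonds$a1 == i | g$bonds$a2 == i
  ords <- ifelse(g$bonds$aromatic[idx], 1.5, g$bonds$order[idx])
  s <- ceiling(sum(ords))
  v <- standard_valences(a$element)
  fit <- v[v >= s]
  if (length(fit) == 0) 0L else as.integer(fit[1] - s)
}

#' Swap every tetrahedral mark in a SMILES string
#'
#' Replaces each `@@` token by `@` and vice versa, leaving everything else
#' untouched; applying it twice restores the input. This is the string-level
#' enantiomer operation used when a racemic crystal requires both enantiomers
#' to be written.
#'
#' @param smiles a SMILES string.
#' @return the inverted string.
#' @export
invert_stereo_marks <- function(smiles) {
  s <- gsub("@@", "\x01", smiles, fixed = TRUE)
  s <- gsub("@", "@@", s, fixed = TRUE)
  gsub("\x01", "@", s, fixed = TRUE)
}
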