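# Symmetry operators in Jones-faithful notation, kept exact: integer rotation
# matrix plus a rational translation (numerators over a common denominator).

.rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(live <- b != 0)) {
    t <- b[live]
    b[live] <- a[live] %% b[live]
    a[live] <- t
  }
  ifelse(a == 0, 1, a)
}

# reduce num/den elementwise; den always > 0
.rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  sgn <- ifelse(den < 0, -1L, 1L)
  num <- as.integer(num * sgn); den <- as.integer(abs(den))
  g <- .rat_gcd(num, den)
  list(num = as.integer(num / g), den = as.integer(den / g))
}

# reduce num/den modulo 1 into [0, 1)
.rat_mod1 <- function(num, den) {
  num <- ((num %% den) + den) %% den
  .rat_reduce(num, den)
}

#' Construct a symmetry operator
#'
#' @param rot 3x3 integer matrix with entries in -1, 0, 1.
#' @param tnum,tden integer 3-vectors: translation numerators and denominators.
#' @return an object of class `symop`.
#' @export
symop <- function(rot = diag(3), tnum = c(0L, 0L, 0L), tden = c(1L, 1L, 1L)) {
  rot <- matrix(as.integer(round(rot)), 3, 3)
  if (!all(rot %in% -1:1)) stop("rotation entries must be in {-1, 0, 1}")
  d <- det(rot)
  if (!(round(d) %in% c(-1, 1))) stop("rotation determinant must be +1 or -1")
  tr <- .rat_mod1(as.integer(tnum), as.integer(tden))
  structure(list(rot = rot, tnum = tr$num, tden = tr$den), class = "symop")
}

#' @export
print.symop <- function(x, ...) {
  cat("<symop> ", serialize_symop(x), "\n", sep = "")
  invisible(x)
}

# parse one linear expression like "-x+1/2" -> coefficients on x,y,z + constant
.parse_symop_component <- function(expr, full) {
  s <- gsub("[[:space:]]", "", tolower(expr))
  if (s == "") stop("malformed symmetry operator component in '", full, "'")
  # tokenize into signed terms
  toks <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
  coef <- c(x = 0L, y = 0L, z = 0L)
  cnum <- 0L; cden <- 1L
  for (tk in toks) {
    sign <- 1L
    body <- tk
    if (startsWith(tk, "-")) { sign <- -1L; body <- substring(tk, 2) }
    else if (startsWith(tk, "+")) body <- substring(tk, 2)
    if (body %in% c("x", "y", "z")) {
      coef[body] <- coef[body] + sign
    } else if (grepl("^[0-9]+/[0-9]+$", body)) {
      p <- as.integer(strsplit(body, "/", fixed = TRUE)[[1]])
      r <- .rat_reduce(cnum * p[2] + sign * p[1] * cden, cden * p[2])
      cnum <- r$num; cden <- r$den
    } else if (grepl("^[0-9]*\\.?[0-9]+$", body)) {
      # decimal constant: snap to a denominator of 12 (covers all space groups)
      v <- as.numeric(body)
      p <- round(v * 12)
      if (abs(p - v * 12) > 1e-6) stop("non-crystallographic constant '", body,
                                       "' in '", full, "'")
      r <- .rat_reduce(cnum * 12L + sign * as.integer(p) * cden, cden * 12L)
      cnum <- r$num; cden <- r$den
    } else {
      stop("cannot parse term '", tk, "' in symmetry operator '", full, "'")
    }
  }
  if (any(abs(coef) > 1)) stop("coefficient outside {-1,0,1} in '", full, "'")
  list(coef = coef, cnum = cnum, cden = cden)
}

#' Parse a Jones-faithful symmetry operator string
#'
#' Accepts forms such as `"x,y,z"`, `"-x,y+1/2,-z"` or `"1/2+x,1/2+y,z"`.
#' Translations are reduced modulo one and kept as exact rationals.
#'
#' @param jones operator string (comma-separated triplet).
#' @return a [symop()] object.
#' @export
parse_symop <- function(jones) {
  parts <- strsplit(jones, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("symmetry operator must have 3 components: '",
                               jones, "'")
  rot <- matrix(0L, 3, 3)
  tnum <- integer(3); tden <- rep(1L, 3)
  for (i in 1:3) {
    p <- .parse_symop_component(parts[i], jones)
    rot[i, ] <- p$coef
    tnum[i] <- p$cnum; tden[i] <- p$cden
  }
  symop(rot, tnum, tden)
}

#' Serialize a symmetry operator back to Jones-faithful notation
#'
#' `parse_symop(serialize_symop(op))` round-trips exactly.
#'
#' @param op a [symop()] object.
#' @return character scalar like `"-x,y+1/2,-z"`.
#' @export
serialize_symop <- function(op) {
  vars <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      co <- op$rot[i, j]
      if (co == 1L) s <- paste0(s, if (nzchar(s)) "+" else "", vars[j])
      else if (co == -1L) s <- paste0(s, "-", vars[j])
    }
    if (op$tnum[i] != 0L) {
      s <- paste0(s, "+", op$tnum[i], "/", op$tden[i])
    }
    if (!nzchar(s)) s <- "0"
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op a [symop()] object.
#' @param fract numeric 3-vector of fractional coordinates.
#' @param wrap reduce the result into the unit cell (componentwise modulo 1)?
#' @return numeric 3-vector.
#' @export
apply_symop <- function(op, fract, wrap = FALSE) {
  v <- as.numeric(op$rot %*% fract) + op$tnum / op$tden
  if (wrap) v <- v - floor(v)
  v
}

#' Compose two symmetry operators
#'
#' Returns the operator `a` followed-after `b`, i.e. `x -> a(b(x))`, with the
#' translation reduced modulo lattice translations.
#'
#' @param a,b [symop()] objects.
#' @return a [symop()] object.
#' @export
compose_symop <- function(a, b) {
  rot <- a$rot %*% b$rot
  # t = Ra * tb + ta  (exact: common denominator)
  den <- b$tden * a$tden  # per-component denominators after mixing
  tnum <- integer(3); tden <- integer(3)
  for (i in 1:3) {
    # row i of Ra times tb
    n <- 0L; d <- 1L
    for (j in 1:3) {
      if (a$rot[i, j] != 0L) {
        nn <- a$rot[i, j] * b$tnum[j]; dd <- b$tden[j]
        n2 <- n * dd + nn * d; d2 <- d * dd
        r <- .rat_reduce(n2, d2); n <- r$num; d <- r$den
      }
    }
    n2 <- n * a$tden[i] + a$tnum[i] * d
    d2 <- d * a$tden[i]
    r <- .rat_reduce(n2, d2)
    tnum[i] <- r$num; tden[i] <- r$den
  }
  symop(rot, tnum, tden)
}

#' @export
symop_equal <- function(a, b) {
  identical(a$rot, b$rot) && all(a$tnum == b$tnum) && all(a$tden == b$tden)
}

# stable key for set operations on operators
.symop_key <- function(op) serialize_symop(op)

#' Close a set of symmetry operators under composition
#'
#' Composes operators (modulo lattice translations) until no new operator
#' appears. Used to expand generator lists into full space-group operator sets.
#'
#' @param ops list of [symop()] objects.
#' @param max_order safety bound on the group order.
#' @return list of [symop()] objects including the identity.
#' @export
close_symops <- function(ops, max_order = 250L) {
  # crystallographic translations are all multiples of 1/12: closure runs on
  # integer (rotation, translation*12) pairs for speed
  den_ok <- all(vapply(ops, function(op) all(12L %% op$tden == 0L), logical(1)))
  if (!den_ok) return(.close_symops_rational(ops, max_order))
  as12 <- function(op) list(rot = op$rot,
                            t = (op$tnum * (12L %/% op$tden)) %% 12L)
  key <- function(o) paste(c(o$rot, o$t), collapse = ",")
  pool <- list(list(rot = diag(3), t = c(0L, 0L, 0L)))
  storage.mode(pool[[1]]$rot) <- "integer"
  keys <- new.env(parent = emptyenv())
  keys[[key(pool[[1]])]] <- TRUE
  add <- function(o) {
    k <- key(o)
    if (is.null(keys[[k]])) {
      pool[[length(pool) + 1L]] <<- o
      keys[[k]] <- TRUE
    }
  }
  for (op in ops) add(as12(op))
  i <- 1L
  while (i <= length(pool)) {
    a <- pool[[i]]
    j <- 1L
    while (j <= length(pool)) {
      b <- pool[[j]]
      add(list(rot = a$rot %*% b$rot, t = (a$rot %*% b$t + a$t)[, 1] %% 12L))
      add(list(rot = b$rot %*% a$rot, t = (b$rot %*% a$t + b$t)[, 1] %% 12L))
      if (length(pool) > max_order) stop("operator closure exceeded ", max_order)
      j <- j + 1L
    }
    i <- i + 1L
  }
  lapply(pool, function(o) symop(o$rot, o$t, c(12L, 12L, 12L)))
}

.close_symops_rational <- function(ops, max_order = 250L) {
  pool <- list()
  keys <- new.env(parent = emptyenv())
  add <- function(op) {
    k <- .symop_key(op)
    if (is.null(keys[[k]])) {
      pool[[length(pool) + 1L]] <<- op
      keys[[k]] <- TRUE
    }
  }
  add(symop())
  for (op in ops) add(op)
  i <- 1L
  while (i <= length(pool)) {
    a <- pool[[i]]
    j <- 1L
    while (j <= length(pool)) {
      b <- pool[[j]]
      add(compose_symop(a, b))
      add(compose_symop(b, a))
      if (length(pool) > max_order) stop("operator closure exceeded ", max_order)
      j <- j + 1L
    }
    i <- i + 1L
  }
  pool
}

#' Is a space group (given by its operators) a Sohncke group?
#'
#' A Sohncke group contains only operations of the first kind (translations,
#' rotations, screw rotations); operationally, every rotation part must have
#' determinant +1. Only Sohncke groups can host a single-enantiomer crystal.
#'
#' @param symops non-empty list of [symop()] objects.
#' @return logical scalar.
#' @export
is_sohncke <- function(symops) {
  stopifnot(length(symops) > 0)
  all(vapply(symops, function(op) round(det(op$rot)) == 1, logical(1)))
}
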