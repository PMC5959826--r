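# Canonical atom ranking: iterative invariant refinement with bounded
# tie-break branching. The canonical string of a graph is invariant under any
# permutation of its atom storage order.

# bond class label as seen from atom i along bond row k
.bond_class <- function(g, k) {
  if (g$bonds$aromatic[k]) "a" else as.character(g$bonds$order[k])
}

# initial per-atom invariant strings
.atom_invariant <- function(g) {
  br <- atom_needs_bracket(g)
  n <- n_atoms(g)
  inv <- character(n)
  classes_at <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    cl <- .bond_class(g, k)
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    classes_at[[i]] <- c(classes_at[[i]], cl)
    classes_at[[j]] <- c(classes_at[[j]], cl)
  }
  for (i in seq_len(n)) {
    a <- g$atoms[i, ]
    inv[i] <- paste(a$element, as.integer(a$aromatic), a$charge, a$hcount,
                    as.integer(br[i]), length(classes_at[[i]]),
                    paste(sort(classes_at[[i]]), collapse = ""), sep = "|")
  }
  inv
}

# one refinement pass: ranks -> refined ranks (dense integers, order-stable
# under permutation because keys are content-based)
.refine_ranks <- function(g, members, rank, adjb) {
  repeat {
    keys <- vapply(members, function(i) {
      nb <- adjb[[i]]
      if (length(nb$to) == 0) {
        as.character(rank[i])
      } else {
        pair <- paste0(rank[nb$to], nb$cls)
        paste(rank[i], paste(sort(pair), collapse = ","), sep = ";")
      }
    }, character(1))
    new_rank <- rank
    new_rank[members] <- match(keys, sort(unique(keys)))
    if (length(unique(new_rank[members])) == length(unique(rank[members]))) {
      return(new_rank)
    }
    rank <- new_rank
  }
}

# leaf signature used to pick the minimal canonical labeling
.rank_signature <- function(g, members, rank, adjb, inv) {
  pieces <- vapply(members, function(i) {
    nb <- adjb[[i]]
    edge <- if (length(nb$to) == 0) "" else {
      paste(sort(paste0(rank[nb$to], nb$cls)), collapse = ",")
    }
    paste(inv[i], edge, sep = "~")
  }, character(1))
  # tied cells are serialized content-sorted so the signature is storage-order
  # independent even for non-discrete partitions
  o <- order(rank[members], pieces)
  sig <- paste(rank[members][o], pieces[o], collapse = " ")
  # tetrahedral parities resolved against the rank order: distinguishes
  # labelings that differ only in handedness (meso vs chiral forms)
  ptoks <- character(0)
  for (i in members) {
    p <- g$parity[[i]]
    if (is.null(p)) next
    nb <- p$neighbors
    key <- rep(-1, length(nb))
    key[nb > 0L] <- rank[nb[nb > 0L]]
    if (anyNA(key) || length(unique(key)) != length(key)) {
      ptoks <- c(ptoks, paste0(rank[i], ":?"))
    } else {
      sgn <- .perm_sign(order(key)) * p$sign
      ptoks <- c(ptoks, paste0(rank[i], ":", sgn))
    }
  }
  if (length(ptoks) > 0) sig <- paste(sig, paste(sort(ptoks), collapse = ","))
  sig
}

# canonical ranks within one moiety; returns rank vector updated on members
.canon_moiety <- function(g, members, rank0, adjb, inv, max_leaves = 2000L) {
  leaves <- list()
  n_leaf <- 0L
  capped <- FALSE
  recurse <- function(rank) {
    rank <- .refine_ranks(g, members, rank, adjb)
    rvals <- rank[members]
    tab <- table(rvals)
    dup <- as.integer(names(tab)[tab > 1])
    if (length(dup) == 0) {
      n_leaf <<- n_leaf + 1L
      leaves[[n_leaf]] <<- rank
      return(invisible(NULL))
    }
    cell_val <- min(dup)
    cands <- members[rank[members] == cell_val]
    if (capped || n_leaf + length(cands) > max_leaves) {
      capped <<- TRUE
      cands <- cands[1]
    }
    seen_sigs <- character(0)
    for (cand in cands) {
      r2 <- as.numeric(rank)
      # give the candidate a rank just below its cell, then re-densify
      r2[cand] <- r2[cand] - 0.5
      r2[members] <- match(r2[members], sort(unique(r2[members])))
      r2 <- .refine_ranks(g, members, as.integer(r2), adjb)
      # candidates whose refined partition has identical content-signature
      # explore equivalent subtrees; visit one representative
      sig <- .rank_signature(g, members, r2, adjb, inv)
      if (sig %in% seen_sigs) next
      seen_sigs <- c(seen_sigs, sig)
      recurse(r2)
      if (capped && n_leaf > 0L) break
    }
    invisible(NULL)
  }
  recurse(rank0)
  if (length(leaves) == 1) return(leaves[[1]])
  sigs <- vapply(leaves, function(r) .rank_signature(g, members, r, adjb, inv),
                 character(1))
  leaves[[which(sigs == min(sigs))[1]]]
}

#' Canonical atom ranks
#'
#' Ranks atoms by iterative refinement of content-based invariants (element,
#' charge, explicit H, aromatic flag, bracket status, degree, bond-class
#' multiset); remaining ties are broken by exploring candidate
#' desymmetrizations and keeping the lexicographically smallest labeling,
#' with a cap on the number of explored labelings (highly symmetric cages
#' fall back to a greedy but deterministic choice).
#'
#' @param g a [molgraph()].
#' @param max_leaves branching cap per moiety.
#' @return integer vector: rank per atom, unique within each moiety.
#' @export
canonical_ranks <- function(g, max_leaves = 2000L) {
  n <- n_atoms(g)
  if (n == 0) return(integer(0))
  inv <- .atom_invariant(g)
  # adjacency with bond classes, precomputed once
  adjb <- replicate(n, list(to = integer(0), cls = character(0)),
                    simplify = FALSE)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    cl <- .bond_class(g, k)
    adjb[[i]]$to <- c(adjb[[i]]$to, j); adjb[[i]]$cls <- c(adjb[[i]]$cls, cl)
    adjb[[j]]$to <- c(adjb[[j]]$to, i); adjb[[j]]$cls <- c(adjb[[j]]$cls, cl)
  }
  comp <- mg_components(g)
  rank <- match(inv, sort(unique(inv)))
  out <- integer(n)
  for (ci in seq_len(max(comp))) {
    members <- which(comp == ci)
    r <- .canon_moiety(g, members, rank, adjb, inv, max_leaves)
    out[members] <- match(r[members], sort(unique(r[members])))
  }
  out
}
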