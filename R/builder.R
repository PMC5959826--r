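# Building the "molecule": the finite atom set a chemist would draw.
#
# The asymmetric unit is expanded through the symmetry operators; bonded
# clusters are grown across cell boundaries so that no perceived bond
# dangles; atoms on special positions are merged; disorder is resolved to the
# majority image; hydrogens are folded into heavy-atom counts and obviously
# missing ones inferred; duplicate moieties are reduced to the compound's
# stoichiometry; polymers are detected and, for the 1-D case, represented by
# two connected repeat units.

.DUP_MERGE_TOL <- 0.2     # A: duplicate-placement merge on special positions
.CELL_SPAN_BOUND <- 3L    # cells: growth bound before declaring polymeric

# minimum-image Cartesian distance between two fractional positions
.min_image_dist <- function(M, fa, fb) {
  d <- fb - fa
  d <- d - round(d)
  sqrt(sum((M %*% d)^2))
}

#' Expand a crystal entry to its P1 contents as contiguous molecules
#'
#' Applies every symmetry operator (plus lattice shifts as needed) to the
#' asymmetric unit, merging duplicate placements on special positions, and
#' grows bonded clusters so that each finite moiety is complete. Clusters
#' that map onto themselves under pure lattice translations are reported as
#' polymeric with the rank of the translation lattice as their dimension.
#'
#' @param entry a `crystal_entry`.
#' @param policy a [bond_policy()] used for the growth connectivity.
#' @return list with `placements` (data.frame: source_label, element, fract,
#'   cart, occupancy, disorder fields, symop_index, shift, cluster) and
#'   `clusters` (per cluster: polymer dimension and generating translations).
#' @export
expand_to_p1 <- function(entry, policy = bond_policy()) {
  M <- orthogonalization_matrix(entry$cell)
  sites <- entry$sites
  nops <- length(entry$symops)

  # unique cell atoms: (site, op) placements deduplicated on special positions
  cell_atoms <- list()
  for (si in seq_len(nrow(sites))) {
    fr0 <- c(sites$fx[si], sites$fy[si], sites$fz[si])
    for (oi in seq_len(nops)) {
      fr <- apply_symop(entry$symops[[oi]], fr0, wrap = TRUE)
      dup <- FALSE
      for (ca in cell_atoms) {
        if (ca$site == si && .min_image_dist(M, ca$fract, fr) < .DUP_MERGE_TOL) {
          dup <- TRUE; break
        }
      }
      if (!dup) {
        cell_atoms[[length(cell_atoms) + 1L]] <-
          list(site = si, op = oi, fract = fr)
      }
    }
  }
  nca <- length(cell_atoms)
  ca_fract <- do.call(rbind, lapply(cell_atoms, `[[`, "fract"))
  ca_site <- vapply(cell_atoms, `[[`, integer(1), "site")
  ca_op <- vapply(cell_atoms, `[[`, integer(1), "op")
  rad <- covalent_radius(sites$element)[ca_site]
  is_h <- sites$element[ca_site] == "H"

  # precompute for each cell-atom pair the lattice shifts that put them in
  # bonding range
  maxbond <- 2 * max(rad) + policy$offset
  shift_grid <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  bonded_shifts <- function(i, j) {
    cut <- rad[i] + rad[j] + policy$offset
    out <- list()
    for (r in seq_len(nrow(shift_grid))) {
      d <- ca_fract[j, ] + shift_grid[r, ] - ca_fract[i, ]
      if (sqrt(sum((M %*% d)^2)) <= cut) out[[length(out) + 1L]] <- shift_grid[r, ]
    }
    out
  }

  # instance = (cell atom, lattice shift); grow clusters by BFS
  inst_key <- function(a, s) paste(a, s[1], s[2], s[3])
  covered <- logical(nca)            # cell atom included in some cluster
  placements <- list()
  clusters <- list()
  cl_id <- 0L

  for (seed in seq_len(nca)) {
    if (covered[seed]) next
    cl_id <- cl_id + 1L
    frontier <- list(list(a = seed, s = c(0L, 0L, 0L)))
    seen <- inst_key(seed, c(0L, 0L, 0L))
    inst <- frontier
    gens <- list()
    first_shift <- list()            # cell atom -> first shift in this cluster
    first_shift[[as.character(seed)]] <- c(0L, 0L, 0L)
    covered[seed] <- TRUE
    polymeric <- FALSE
    while (length(frontier) > 0) {
      cur <- frontier[[1]]; frontier <- frontier[-1]
      for (j in seq_len(nca)) {
        if (is_h[cur$a] && is_h[j]) next
        for (sh in bonded_shifts(cur$a, j)) {
          s2 <- cur$s + sh
          if (j == cur$a && all(sh == 0L)) next
          k <- inst_key(j, s2)
          if (k %in% seen) next
          fs <- first_shift[[as.character(j)]]
          if (!is.null(fs)) {
            tr <- s2 - fs
            if (any(tr != 0L)) {
              # pure lattice translation onto an already-included image
              polymeric <- TRUE
              gens[[length(gens) + 1L]] <- tr
              next
            }
          }
          if (any(abs(s2) > .CELL_SPAN_BOUND)) { polymeric <- TRUE; next }
          seen <- c(seen, k)
          first_shift[[as.character(j)]] <- s2
          covered[j] <- TRUE
          node <- list(a = j, s = s2)
          inst[[length(inst) + 1L]] <- node
          frontier[[length(frontier) + 1L]] <- node
        }
      }
    }
    dim <- 0L
    if (polymeric && length(gens) > 0) {
      Gm <- do.call(rbind, gens)
      dim <- qr(Gm)$rank
    } else if (polymeric) {
      dim <- 1L
    }
    for (node in inst) {
      a <- node$a
      placements[[length(placements) + 1L]] <- data.frame(
        source_label = sites$label[ca_site[a]],
        element = sites$element[ca_site[a]],
        fx = ca_fract[a, 1] + node$s[1],
        fy = ca_fract[a, 2] + node$s[2],
        fz = ca_fract[a, 3] + node$s[3],
        occupancy = sites$occupancy[ca_site[a]],
        disorder_assembly = sites$disorder_assembly[ca_site[a]],
        disorder_group = sites$disorder_group[ca_site[a]],
        symop_index = ca_op[a],
        shift1 = node$s[1], shift2 = node$s[2], shift3 = node$s[3],
        cluster = cl_id,
        stringsAsFactors = FALSE
      )
    }
    clusters[[cl_id]] <- list(
      dim = dim,
      generators = if (length(gens) > 0) unique(lapply(gens, as.integer)) else list()
    )
  }
  pl <- do.call(rbind, placements)
  cart <- fract_to_cartesian(entry$cell, as.matrix(pl[, c("fx", "fy", "fz")]))
  pl$cx <- cart[, 1]; pl$cy <- cart[, 2]; pl$cz <- cart[, 3]
  list(placements = pl, clusters = clusters)
}

#' Resolve positional disorder
#'
#' Within each disorder assembly the group with the largest occupancy sum is
#' kept (ties broken by the lexicographically smallest group label, logged);
#' the alternatives are discarded.
#'
#' @param placements placement data.frame from [expand_to_p1()].
#' @return list `placements` (filtered) and `log`.
#' @export
select_disorder <- function(placements) {
  log <- character(0)
  pl <- placements
  grouped <- !is.na(pl$disorder_group)
  if (!any(grouped)) return(list(placements = pl, log = log))
  asm <- pl$disorder_assembly
  asm[is.na(asm)] <- "."
  keep <- rep(TRUE, nrow(pl))
  for (a in unique(asm[grouped])) {
    in_a <- grouped & asm == a
    groups <- sort(unique(pl$disorder_group[in_a]))
    if (length(groups) < 2) next
    sums <- vapply(groups, function(gr) {
      sum(pl$occupancy[in_a & pl$disorder_group == gr])
    }, numeric(1))
    best <- groups[sums == max(sums)]
    if (length(best) > 1) {
      log <- c(log, sprintf("assembly %s: occupancy tie, keeping group %s", a, best[1]))
    }
    best <- best[1]
    keep[in_a & pl$disorder_group != best] <- FALSE
    log <- c(log, sprintf("assembly %s: kept disorder group %s (sum %.3g)",
                          a, best, max(sums)))
  }
  list(placements = pl[keep, , drop = FALSE], log = log)
}

# build a molgraph from placements (coordinates + metadata, no bonds yet)
.graph_from_placements <- function(pl) {
  g <- molgraph(pl$element, coords = cbind(pl$cx, pl$cy, pl$cz))
  g$atoms$label <- pl$source_label
  g$atoms$source_label <- pl$source_label
  g$atoms$occupancy <- pl$occupancy
  g$atoms$symop_index <- pl$symop_index
  g$atoms$shift1 <- pl$shift1; g$atoms$shift2 <- pl$shift2
  g$atoms$shift3 <- pl$shift3
  g$atoms$cluster <- pl$cluster
  g
}

# fold explicit H atoms into the hcount of their bonded heavy atom
.fold_hydrogens <- function(g) {
  hs <- which(g$atoms$element == "H")
  if (length(hs) == 0) return(g)
  drop <- integer(0)
  for (i in hs) {
    nb <- neighbors(g, i)
    nb <- nb[g$atoms$element[nb] != "H"]
    if (length(nb) == 0) next
    j <- nb[1]
    g$atoms$hcount[j] <- g$atoms$hcount[j] + 1L
    drop <- c(drop, i)
  }
  if (length(drop) > 0) g <- mg_subgraph(g, setdiff(seq_len(n_atoms(g)), drop))
  g
}

#' Infer chemically obvious missing hydrogens
#'
#' Isolated oxygen atoms are read as water (2 implicit H); an oxygen singly
#' bonded to carbon at more than 1.38 Angstrom with no hydrogen of its own
#' gains a hydroxyl H unless a counter-ion context (a monoatomic alkali,
#' alkaline-earth or halide moiety) suggests an anion. Metal-bound atoms and
#' atoms severed by the ionic policy are never touched.
#'
#' @param g built graph with bonds and folded hydrogens.
#' @param severed optional logical vector marking atoms severed by
#'   [apply_ionic_policy()].
#' @return the graph; attribute `"h_log"` lists additions.
#' @export
infer_missing_hydrogens <- function(g, severed = NULL) {
  if (is.null(severed)) severed <- rep(FALSE, n_atoms(g))
  log <- character(0)
  comp <- mg_components(g)
  counterion <- any(vapply(seq_len(max(comp, 0L)), function(ci) {
    m <- which(comp == ci)
    length(m) == 1L && g$atoms$hcount[m] == 0L &&
      (is_alkali(g$atoms$element[m]) || is_alkaline_earth(g$atoms$element[m]) ||
       g$atoms$element[m] %in% .HALOGENS)
  }, logical(1)))
  for (i in which(g$atoms$element == "O" & !severed)) {
    nb <- neighbors(g, i)
    if (length(nb) == 0 && g$atoms$hcount[i] == 0L) {
      g$atoms$hcount[i] <- 2L
      log <- c(log, sprintf("isolated O at atom %d read as water", i))
      next
    }
    if (length(nb) == 1 && g$atoms$hcount[i] == 0L &&
        g$atoms$element[nb] == "C" && !counterion) {
      d <- .atom_dist(g, i, nb)
      if (!is.na(d) && d > 1.38) {
        g$atoms$hcount[i] <- 1L
        log <- c(log, sprintf("hydroxyl H added on O atom %d (C-O %.2f A)", i, d))
      }
    }
  }
  attr(g, "h_log") <- log
  g
}

# polymer dimension per component of the current graph: two placements of the
# same (source label, symop) within one component differ by a pure lattice
# translation
.component_polymer_dims <- function(g) {
  comp <- mg_components(g)
  dims <- integer(n_atoms(g))
  if (!("source_label" %in% names(g$atoms))) return(dims)
  for (ci in seq_len(max(comp, 0L))) {
    m <- which(comp == ci)
    key <- paste(g$atoms$source_label[m], g$atoms$symop_index[m])
    gens <- list()
    for (k in unique(key[duplicated(key)])) {
      idx <- m[key == k]
      base <- idx[1]
      for (other in idx[-1]) {
        gens[[length(gens) + 1L]] <- c(
          g$atoms$shift1[other] - g$atoms$shift1[base],
          g$atoms$shift2[other] - g$atoms$shift2[base],
          g$atoms$shift3[other] - g$atoms$shift3[base])
      }
    }
    if (length(gens) > 0) {
      dims[m] <- qr(do.call(rbind, gens))$rank
    }
  }
  dims
}

#' Moiety multiplicities and stoichiometry reduction
#'
#' Isomorphic moieties (decided on the canonical SMILES of each moiety's
#' connectivity graph) are merged with multiplicities; multiplicities are
#' divided by the greatest common divisor of the non-solvent moieties; a
#' whitelisted solvent moiety left with a fractional share is rounded up to
#' one - the main species is never duplicated.
#'
#' @param moieties list of moiety [molgraph()]s.
#' @return list with `moieties` (one representative per class), `mult`
#'   (integer multiplicities) and `log`.
#' @export
reduce_stoichiometry <- function(moieties) {
  if (length(moieties) == 0) {
    return(list(moieties = list(), mult = integer(0), log = character(0)))
  }
  keys <- vapply(moieties, canonicalize, character(1))
  classes <- unique(keys)
  counts <- vapply(classes, function(k) sum(keys == k), integer(1))
  reps <- lapply(classes, function(k) moieties[[which(keys == k)[1]]])
  solvent <- vapply(reps, is_solvent_moiety, logical(1))
  log <- character(0)
  base <- counts[!solvent]
  if (length(base) == 0) base <- counts
  g0 <- Reduce(function(a, b) .rat_gcd(a, b), base)
  mult <- counts / g0
  if (any(solvent)) {
    frac <- solvent & (mult != round(mult))
    if (any(frac)) {
      log <- c(log, sprintf("%d solvent moiety class(es) rounded up to 1",
                            sum(frac)))
      mult[frac] <- 1
    }
  }
  if (any(mult != round(mult))) {
    # a non-solvent fractional share cannot be rounded: fall back to raw counts
    mult <- counts
    log <- c(log, "fractional non-solvent share; multiplicities left unreduced")
  }
  list(moieties = reps, mult = as.integer(round(mult)), log = log)
}

# conventional solvent whitelist, matched on molecular formula (nothing more
# complex than toluene is ever treated as solvent)
.SOLVENT_FORMULAS <- c(
  "H2O", "CH4O", "C2H6O", "C2H3N", "C3H6O", "CH2Cl2", "CHCl3",
  "C4H8O", "C4H8O2", "C3H7NO", "C2H6OS", "C4H10O", "C6H6", "C7H8"
)

#' Molecular formula of a graph (Hill order)
#' @param g a [molgraph()].
#' @return character scalar such as `"C2H6O"`.
#' @export
molecular_formula <- function(g) {
  counts <- table(g$atoms$element)
  h <- sum(g$atoms$hcount) + if ("H" %in% names(counts)) counts[["H"]] else 0L
  counts <- counts[names(counts) != "H"]
  cl <- as.list(counts)
  if (h > 0) cl[["H"]] <- h
  els <- sort(names(cl))
  # Hill order: C first, then H, then alphabetical; without C, alphabetical
  if ("C" %in% els) {
    els <- c("C", if ("H" %in% els) "H", setdiff(els, c("C", "H")))
  }
  paste(vapply(els, function(e) {
    paste0(e, if (cl[[e]] > 1) cl[[e]] else "")
  }, character(1)), collapse = "")
}

#' Is a moiety a whitelisted solvent?
#' @param g a moiety [molgraph()].
#' @return logical scalar.
#' @export
is_solvent_moiety <- function(g) molecular_formula(g) %in% .SOLVENT_FORMULAS

#' Extend a 1-D polymer moiety to two connected repeat units
#'
#' The fragment is the unit plus its image under the generating lattice
#' translation (the recorded generator of smallest norm); bonds between the
#' two units are retained, dangling continuation bonds are dropped.
#'
#' @param g moiety graph (one repeat unit, with placement metadata).
#' @param generators list of integer 3-vectors: lattice translations mapping
#'   the polymer onto itself.
#' @param cell the entry's [unit_cell()].
#' @param policy a [bond_policy()].
#' @return the fragment graph, attribute `"polymer_fragment" = TRUE`.
#' @export
extend_polymer_1d <- function(g, generators, cell, policy = bond_policy()) {
  if (length(generators) == 0) stop("no generating translation recorded")
  M <- orthogonalization_matrix(cell)
  norms <- vapply(generators, function(t) sqrt(sum((M %*% t)^2)), numeric(1))
  t0 <- generators[[which.min(norms)]]
  n <- n_atoms(g)
  shift_cart <- as.numeric(M %*% t0)
  g2 <- g
  g2$atoms <- rbind(g$atoms, within(g$atoms, {
    x <- x + shift_cart[1]; y <- y + shift_cart[2]; z <- z + shift_cart[3]
    shift1 <- shift1 + t0[1]; shift2 <- shift2 + t0[2]; shift3 <- shift3 + t0[3]
  }))
  rownames(g2$atoms) <- NULL
  g2$parity <- c(g$parity, g$parity)
  b2 <- g$bonds
  b2$a1 <- b2$a1 + n; b2$a2 <- b2$a2 + n
  g2$bonds <- rbind(g$bonds, b2)
  g2 <- perceive_bonds(g2, policy)   # adds the inter-unit bonds
  attr(g2, "polymer_fragment") <- TRUE
  attr(g2, "generator") <- t0
  g2
}

#' Build the molecule of a crystal entry
#'
#' Full treatment: P1 expansion with cluster growth (skipped on the fast path
#' when the triage flags allow), disorder resolution, bond perception with
#' the chosen bond source, hydrogen folding and inference, ionic policy,
#' low-occupancy moiety removal, stoichiometry reduction and 1-D polymer
#' extension.
#'
#' @param entry a `crystal_entry`.
#' @param policy a [bond_policy()].
#' @param flags optional precomputed [triage()] flags.
#' @return list with `graph` (the molecule), `moieties`, `mult`,
#'   `polymer_dims` (per moiety of the output), `log`, and `unsupported`
#'   (character: non-empty when e.g. a 2-D/3-D covalent polymer remains).
#' @export
build_molecule <- function(entry, policy = bond_policy(), flags = NULL) {
  if (is.null(flags)) flags <- triage(entry)
  log <- character(0)
  fast <- flags$zprime_class == "one" && !flags$disordered &&
    !flags$cross_unit_bonds
  if (fast) {
    pl <- data.frame(
      source_label = entry$sites$label,
      element = entry$sites$element,
      fx = entry$sites$fx, fy = entry$sites$fy, fz = entry$sites$fz,
      occupancy = entry$sites$occupancy,
      disorder_assembly = entry$sites$disorder_assembly,
      disorder_group = entry$sites$disorder_group,
      symop_index = 1L, shift1 = 0L, shift2 = 0L, shift3 = 0L,
      cluster = 1L, stringsAsFactors = FALSE
    )
    cart <- fract_to_cartesian(entry$cell,
                               as.matrix(pl[, c("fx", "fy", "fz")]))
    pl$cx <- cart[, 1]; pl$cy <- cart[, 2]; pl$cz <- cart[, 3]
    log <- c(log, "fast path: asymmetric unit used directly")
    cluster_dims <- 0L
    cluster_gens <- list(list())
  } else {
    ex <- expand_to_p1(entry, policy)
    pl <- ex$placements
    log <- c(log, sprintf("expanded to P1: %d placements in %d cluster(s)",
                          nrow(pl), length(ex$clusters)))
    cluster_dims <- vapply(ex$clusters, `[[`, integer(1), "dim")
    cluster_gens <- lapply(ex$clusters, `[[`, "generators")
    if (flags$disordered) {
      sd <- select_disorder(pl)
      pl <- sd$placements
      log <- c(log, sd$log)
    }
  }

  g <- .graph_from_placements(pl)
  g <- perceive_bonds(g, policy)
  if (policy$bond_source != "perceived" && nrow(entry$geom_bonds) > 0) {
    g <- merge_geom_bonds(g, entry$geom_bonds, mode = policy$bond_source)
  }
  listed <- if (nrow(entry$geom_bonds) > 0) {
    suppressWarnings(resolve_geom_bonds(g, entry$geom_bonds))
  } else NULL
  g <- apply_metal_metal_policy(g, listed, policy)
  g <- .fold_hydrogens(g)

  # polymer dimension per atom, from the expansion clusters
  dims <- cluster_dims[g$atoms$cluster]
  severed <- rep(FALSE, n_atoms(g))
  if (any(dims >= 2L)) {
    pre <- mg_components(g)
    g <- apply_ionic_policy(g, dims)
    log <- c(log, attr(g, "ionic_log"))
    post <- mg_components(g)
    severed <- vapply(seq_len(n_atoms(g)), function(i) {
      sum(post == post[i]) < sum(pre == pre[i])
    }, logical(1))
    # severed monoatomic pieces are finite ions now
    for (i in seq_len(n_atoms(g))) {
      if (sum(post == post[i]) == 1L) dims[i] <- 0L
    }
  }
  g <- infer_missing_hydrogens(g, severed)
  log <- c(log, attr(g, "h_log"))

  # drop very low occupancy moieties (mineral-like mixtures)
  comp <- mg_components(g)
  drop <- integer(0)
  for (ci in seq_len(max(comp, 0L))) {
    m <- which(comp == ci)
    if (mean(g$atoms$occupancy[m]) < 0.1) {
      drop <- c(drop, m)
      log <- c(log, sprintf("dropped moiety %d (mean occupancy below 0.1)", ci))
    }
  }
  if (length(drop) > 0) {
    keepidx <- setdiff(seq_len(n_atoms(g)), drop)
    dims <- dims[keepidx]
    g <- mg_subgraph(g, keepidx)
  }

  comp <- mg_components(g)
  unsupported <- character(0)
  moieties <- list()
  moi_dims <- integer(0)
  for (ci in seq_len(max(comp, 0L))) {
    m <- which(comp == ci)
    d <- max(dims[m])
    sub <- mg_subgraph(g, m)
    if (d >= 2L) {
      unsupported <- c(unsupported,
                       sprintf("%d-D polymeric moiety (atoms %s...) has no automatic SMILES",
                               d, paste(utils::head(m, 4), collapse = ",")))
      next
    }
    if (d == 1L) {
      gens <- cluster_gens[[g$atoms$cluster[m[1]]]]
      if (length(gens) == 0) gens <- .moiety_generators(g, m)
      sub <- extend_polymer_1d(sub, gens, entry$cell, policy)
      log <- c(log, sprintf("1-D polymer: fragment of two repeat units (generator %s)",
                            paste(attr(sub, "generator"), collapse = ",")))
    }
    moieties[[length(moieties) + 1L]] <- sub
    moi_dims <- c(moi_dims, d)
  }

  finite <- moi_dims == 0L
  red <- reduce_stoichiometry(moieties[finite])
  log <- c(log, red$log)
  out_moieties <- c(red$moieties, moieties[!finite])
  out_mult <- c(red$mult, rep(1L, sum(!finite)))
  out_dims <- c(rep(0L, length(red$moieties)), moi_dims[!finite])

  list(graph = .combine_moieties(out_moieties, out_mult),
       moieties = out_moieties, mult = out_mult, polymer_dims = out_dims,
       log = log, unsupported = unsupported)
}

# lattice translations for a 1-D moiety, from duplicated (label, op) images
.moiety_generators <- function(g, members) {
  key <- paste(g$atoms$source_label[members], g$atoms$symop_index[members])
  gens <- list()
  for (k in unique(key[duplicated(key)])) {
    idx <- members[key == k]
    base <- idx[1]
    for (other in idx[-1]) {
      gens[[length(gens) + 1L]] <- as.integer(c(
        g$atoms$shift1[other] - g$atoms$shift1[base],
        g$atoms$shift2[other] - g$atoms$shift2[base],
        g$atoms$shift3[other] - g$atoms$shift3[base]))
    }
  }
  unique(gens)
}

# one graph holding `mult[k]` copies of each moiety
.combine_moieties <- function(moieties, mult) {
  if (length(moieties) == 0) return(molgraph(character(0)))
  out <- NULL
  for (k in seq_along(moieties)) {
    for (r in seq_len(mult[k])) {
      out <- if (is.null(out)) moieties[[k]] else .mg_union(out, moieties[[k]])
    }
  }
  out
}

.mg_union <- function(g1, g2) {
  n1 <- n_atoms(g1)
  out <- g1
  a2 <- g2$atoms
  for (col in setdiff(names(g1$atoms), names(a2))) a2[[col]] <- NA
  for (col in setdiff(names(a2), names(g1$atoms))) out$atoms[[col]] <- NA
  out$atoms <- rbind(out$atoms[, sort(names(out$atoms))],
                     a2[, sort(names(out$atoms))])
  rownames(out$atoms) <- NULL
  b2 <- g2$bonds
  b2$a1 <- b2$a1 + n1; b2$a2 <- b2$a2 + n1
  out$bonds <- rbind(g1$bonds, b2)
  out$parity <- c(g1$parity, lapply(g2$parity, function(p) {
    if (is.null(p)) return(NULL)
    nz <- p$neighbors > 0L
    p$neighbors[nz] <- p$neighbors[nz] + n1
    p
  }))
  out$kekulized <- g1$kekulized && g2$kekulized
  out
}
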