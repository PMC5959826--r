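# End-to-end orchestration: triage -> molecule building -> bond model ->
# stereochemistry -> writing -> curation, including the dual bond-source
# consistency check, and the collection files.

#' Finalize a built molecule graph into a SMILES-ready graph
#'
#' Assigns Kekule orders, perceives aromaticity, assigns conventional formal
#' charges and perceives tetrahedral stereocenters.
#'
#' @param g graph from [build_molecule()].
#' @return the finalized graph.
#' @export
finalize_graph <- function(g) {
  g <- assign_bond_orders(g)
  g <- perceive_aromaticity(g)
  g <- assign_formal_charges(g)
  g <- perceive_tetrahedral(g)
  g
}

.crude_smiles <- function(entry, policy, flags) {
  built <- build_molecule(entry, policy, flags)
  if (length(built$moieties) == 0 && length(built$unsupported) > 0) {
    return(list(smiles = NA_character_, built = built))
  }
  g <- finalize_graph(built$graph)
  list(smiles = write_smiles(g), built = built, graph = g)
}

#' Convert one crystal entry to a curated SMILES record
#'
#' The crude SMILES is computed twice - from perceived bonds only and from
#' the union with the CIF-listed bonds. When the canonical results agree the
#' entry proceeds directly; when they disagree both candidates are reported,
#' the review flag is set, and the perceived-only result is carried forward.
#' The stereochemistry policy and the curation rules are then applied and
#' the final string is re-parsed as a validity check.
#'
#' @param entry a `crystal_entry`.
#' @param policy a [bond_policy()].
#' @param rules curation-rule catalog, see [curation_rules()].
#' @return object of class `smiles_result`: `status` (`"ok"`,
#'   `"unsupported"`, `"error"`), `smiles`, `id`, `review` flag,
#'   `candidates`, `flags`, `stereo`, `changelog`, `log`.
#' @export
run_entry <- function(entry, policy = bond_policy(), rules = curation_rules()) {
  flags <- triage(entry)
  out <- list(id = entry$id, flags = flags, review = FALSE,
              candidates = character(0), log = character(0))
  class(out) <- "smiles_result"

  stage <- "molecule_building"
  res <- tryCatch({
    p1 <- policy; p1$bond_source <- "perceived"
    crude1 <- .crude_smiles(entry, p1, flags)
    crude2 <- NULL
    if (nrow(entry$geom_bonds) > 0) {
      p2 <- policy; p2$bond_source <- "merged"
      crude2 <- .crude_smiles(entry, p2, flags)
    }
    list(crude1 = crude1, crude2 = crude2)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    out$status <- "error"; out$stage <- stage
    out$message <- conditionMessage(res)
    return(out)
  }
  crude1 <- res$crude1; crude2 <- res$crude2
  out$log <- c(out$log, crude1$built$log)
  if (length(crude1$built$unsupported) > 0 && is.na(crude1$smiles)) {
    out$status <- "unsupported"
    out$stage <- "molecule_building"
    out$message <- paste(crude1$built$unsupported, collapse = "; ")
    return(out)
  }
  smiles <- crude1$smiles
  if (!is.null(crude2) && !is.na(crude2$smiles)) {
    c1 <- canon_smiles(crude1$smiles)
    c2 <- canon_smiles(crude2$smiles)
    if (c1 != c2) {
      out$review <- TRUE
      out$candidates <- c(perceived = crude1$smiles, merged = crude2$smiles)
      out$log <- c(out$log,
                   "bond-source disagreement: perceived-only result kept")
    }
  }
  if (length(crude1$built$unsupported) > 0) {
    out$log <- c(out$log, crude1$built$unsupported)
  }

  stage <- "stereochemistry"
  st <- tryCatch(apply_racemate_policy(smiles, is_sohncke(entry$symops)),
                 error = function(e) e)
  if (inherits(st, "error")) {
    out$status <- "error"; out$stage <- stage
    out$message <- conditionMessage(st)
    return(out)
  }
  out$stereo <- st$verdict
  smiles <- st$smiles

  stage <- "curation"
  cu <- tryCatch(apply_rules(smiles, rules), error = function(e) e)
  if (inherits(cu, "error")) {
    out$status <- "error"; out$stage <- stage
    out$message <- conditionMessage(cu)
    return(out)
  }
  out$changelog <- cu$log
  smiles <- cu$smiles

  stage <- "validation"
  ok <- tryCatch({ parse_smiles(smiles); TRUE }, error = function(e) e)
  if (inherits(ok, "error")) {
    out$status <- "error"; out$stage <- stage
    out$message <- conditionMessage(ok)
    return(out)
  }
  out$smiles <- smiles
  out$status <- "ok"
  out
}

#' @export
print.smiles_result <- function(x, ...) {
  cat(sprintf("<smiles_result> %s [%s]%s\n", x$id, x$status,
              if (isTRUE(x$review)) " review" else ""))
  if (!is.null(x$smiles)) cat("  ", x$smiles, "\n", sep = "")
  invisible(x)
}

#' Convert CIF files to SMILES records
#'
#' @param paths CIF file paths (each may contain several data blocks).
#' @param policy a [bond_policy()].
#' @param rules curation-rule catalog.
#' @return data.frame: `smiles`, `id`, `status`, `review`.
#' @export
convert_files <- function(paths, policy = bond_policy(),
                          rules = curation_rules()) {
  rows <- list()
  for (p in paths) {
    for (entry in parse_cif(p, is_file = TRUE)) {
      r <- run_entry(entry, policy, rules)
      rows[[length(rows) + 1L]] <- data.frame(
        smiles = if (is.null(r$smiles)) NA_character_ else r$smiles,
        id = r$id, status = r$status, review = isTRUE(r$review),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a SMILES collection file
#'
#' One `SMILES<TAB>ID` line per record, in stable ID order. Every line is
#' re-parsed before writing; any syntax error aborts the whole write naming
#' the offending line.
#'
#' @param records data.frame with columns `smiles` and `id`.
#' @param path optional file path; when NULL the text is returned.
#' @return the collection text, invisibly when written to a file.
#' @export
write_collection <- function(records, path = NULL) {
  records <- records[order(records$id), , drop = FALSE]
  for (k in seq_len(nrow(records))) {
    ok <- tryCatch({ parse_smiles(records$smiles[k]); TRUE },
                   error = function(e) e)
    if (inherits(ok, "error")) {
      stop("invalid SMILES at collection line ", k, " (id ", records$id[k],
           "): ", conditionMessage(ok))
    }
  }
  txt <- paste0(paste(records$smiles, records$id, sep = "\t"), collapse = "\n")
  if (nrow(records) > 0) txt <- paste0(txt, "\n") else txt <- ""
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Read a SMILES collection file
#'
#' @param text_or_path collection text or a file path.
#' @param is_file treat the argument as a path.
#' @return data.frame with columns `smiles`, `id`.
#' @export
read_collection <- function(text_or_path, is_file = FALSE) {
  lines <- if (is_file) readLines(text_or_path, warn = FALSE) else
    strsplit(text_or_path, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(smiles = vapply(parts, `[[`, character(1), 1),
             id = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                         character(1)),
             stringsAsFactors = FALSE)
}

#' Write the alternative (recharged haloanion) collection
#'
#' Records containing a conventional haloanion central atom with at least
#' three halogen neighbors are selected and filtered through
#' [recharge_haloanions()]; other records are excluded.
#'
#' @inheritParams write_collection
#' @return the alternative collection text.
#' @export
write_alt_collection <- function(records, path = NULL) {
  cand <- select_recharge_candidates(records)
  if (nrow(cand) > 0) {
    cand$smiles <- vapply(cand$smiles, recharge_haloanions, character(1))
  }
  write_collection(cand, path)
}
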