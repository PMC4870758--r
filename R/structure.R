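#' Read an atomic-coordinate structure from PDB text
#'
#' Fixed-column parsing of ATOM and HETATM records. Only the first MODEL
#' block is kept (a warning reports dropped models); alternate-location
#' indicators other than blank or `A` are dropped. The ligand (chromophore)
#' is designated by residue name, default `RET` (retinal).
#'
#' @param path Path to a PDB file, or a character vector of PDB lines via
#'   `text`.
#' @param text Optional PDB lines (overrides `path`).
#' @param ligand Residue name designating the chromophore (default "RET").
#' @return An object of class `structure_model`: a list with `atoms` (data
#'   frame: serial, name, altloc, residue_name, chain, residue_seq, x, y, z,
#'   element, is_hetero, is_ligand) and `ligand` (the selector).
#' @export
read_structure <- function(path = NULL, text = NULL, ligand = "RET") {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  model_no <- 0L; in_dropped_model <- FALSE; dropped <- 0L
  keep <- list(); lineno <- 0L
  for (ln in lines) {
    lineno <- lineno + 1L
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      model_no <- model_no + 1L
      in_dropped_model <- model_no > 1L
      if (in_dropped_model) dropped <- dropped + 1L
      next
    }
    if (!(startsWith(rec, "ATOM") || startsWith(rec, "HETATM"))) next
    if (in_dropped_model) next
    altloc <- substr(ln, 17, 17)
    if (!altloc %in% c(" ", "", "A")) next
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed coordinate field at line ", lineno, call. = FALSE)
    keep[[length(keep) + 1L]] <- data.frame(
      serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
      name = trimws(substr(ln, 13, 16)),
      altloc = trimws(altloc),
      residue_name = trimws(substr(ln, 18, 20)),
      chain = trimws(substr(ln, 22, 22)),
      residue_seq = suppressWarnings(as.integer(substr(ln, 23, 26))),
      x = xyz[1], y = xyz[2], z = xyz[3],
      element = trimws(substr(ln, 77, 78)),
      is_hetero = startsWith(rec, "HETATM"),
      stringsAsFactors = FALSE)
  }
  if (length(keep) == 0L)
    stop("no parsable ATOM/HETATM records", call. = FALSE)
  if (dropped > 0L)
    warning(dropped, " MODEL block(s) beyond the first ignored")
  atoms <- do.call(rbind, keep)
  # infer element from the atom name when the element column is blank
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substr(gsub("[^A-Za-z].*$", "", atoms$name[blank]), 1, 1)
  atoms$is_ligand <- atoms$residue_name == ligand
  structure(list(atoms = atoms, ligand = ligand), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("Structure model: ", nrow(a), " atoms (", sum(a$is_hetero), " hetero), ",
      sum(a$is_ligand), " ligand atoms (", x$ligand, "), ",
      length(unique(paste(a$chain, a$residue_seq)[!a$is_ligand])),
      " polymer residues\n", sep = "")
  invisible(x)
}

.residue_key <- function(atoms) paste(atoms$chain, atoms$residue_seq, sep = ":")

.atom_subset <- function(atoms, hydrogen_policy) {
  if (hydrogen_policy == "exclude_h") atoms[toupper(atoms$element) != "H", , drop = FALSE]
  else atoms
}

#' Minimum distance between a residue and the chromophore
#'
#' @param model A `structure_model`.
#' @param residue Residue id as `"chain:resseq"` (e.g. `"A:125"`).
#' @param hydrogen_policy `"exclude_h"` (default) or `"include_h"`.
#' @return Minimum Euclidean distance in Angstrom between any atom of the
#'   residue and any ligand atom.
#' @export
min_ligand_distance <- function(model, residue,
                                hydrogen_policy = c("exclude_h", "include_h")) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  lig <- model$atoms[model$atoms$is_ligand, , drop = FALSE]
  if (nrow(lig) == 0L)
    stop("no ligand atoms (residue name ", model$ligand, ") in structure", call. = FALSE)
  res <- model$atoms[!model$atoms$is_ligand & .residue_key(model$atoms) == residue, , drop = FALSE]
  res <- .atom_subset(res, hydrogen_policy)
  lig <- .atom_subset(lig, hydrogen_policy)
  if (nrow(res) == 0L)
    stop("residue ", residue, " not found (or has no atoms under hydrogen policy)", call. = FALSE)
  a <- as.matrix(res[, c("x", "y", "z")]); b <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Chromophore-binding-pocket residues by the distance rule
#'
#' A polymer residue belongs to the pocket when its minimum distance to any
#' ligand atom is at or below the cutoff (residues at exactly the cutoff are
#' included). Default cutoff 4.0 Angstrom, the standard retinal-contact
#' criterion.
#'
#' @param model A `structure_model` with ligand atoms present.
#' @param cutoff Distance cutoff in Angstrom (> 0), default 4.0.
#' @param hydrogen_policy `"exclude_h"` (default) or `"include_h"`.
#' @return Data frame (chain, residue_seq, residue_name, min_distance,
#'   in_pocket) for all polymer residues, sorted by chain and residue_seq.
#' @export
binding_pocket <- function(model, cutoff = 4.0,
                           hydrogen_policy = c("exclude_h", "include_h")) {
  hydrogen_policy <- match.arg(hydrogen_policy)
  stopifnot(cutoff > 0)
  atoms <- model$atoms
  lig <- .atom_subset(atoms[atoms$is_ligand, , drop = FALSE], hydrogen_policy)
  if (nrow(lig) == 0L)
    stop("no ligand atoms (residue name ", model$ligand, ") in structure", call. = FALSE)
  poly <- .atom_subset(atoms[!atoms$is_ligand, , drop = FALSE], hydrogen_policy)
  key <- .residue_key(poly)
  b <- as.matrix(lig[, c("x", "y", "z")])
  a <- as.matrix(poly[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  atom_min <- sqrt(pmax(0, apply(d2, 1, min)))
  res_min <- tapply(atom_min, key, min)
  first <- !duplicated(key)
  out <- data.frame(chain = poly$chain[first], residue_seq = poly$residue_seq[first],
                    residue_name = poly$residue_name[first],
                    min_distance = as.numeric(res_min[key[first]]),
                    stringsAsFactors = FALSE)
  out$in_pocket <- out$min_distance <= cutoff
  out[order(out$chain, out$residue_seq), ]
}

#' Write a pocket table to TSV
#'
#' Distances are reported to 0.01 Angstrom.
#'
#' @param pocket Data frame from [binding_pocket()].
#' @param path Output path.
#' @export
write_pocket_tsv <- function(pocket, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# chromophore binding pocket: min residue-ligand distance in Angstrom", con)
  pocket$min_distance <- round(pocket$min_distance, 2)
  utils::write.table(pocket, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
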