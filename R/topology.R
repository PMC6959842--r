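#' Molecule-class vocabularies
#'
#' Residue-name lists used to classify atoms into molecule classes
#' (protein, nucleic, cofactor, solvent, ion).  Topology formats disagree on
#' naming (TIP3 vs HOH, SOD vs NA), so every classifier below accepts
#' user-extensible overrides.
#'
#' @name molclass_vocab
#' @keywords internal
NULL

.protein_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX", "CYM", "ASH", "GLH", "LYN")

.nucleic_resnames <- c(
  "DA", "DT", "DG", "DC", "DU", "DA3", "DA5", "DT3", "DT5", "DG3", "DG5",
  "DC3", "DC5", "ADE", "THY", "GUA", "CYT", "URA", "A", "U", "G", "C", "T")

.cofactor_resnames <- c("ADP", "ATP", "GDP", "GTP", "ANP", "AGS", "NAD", "FAD")

.solvent_resnames <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "TIP5", "SPC",
                       "SPCE", "SOL", "TP3", "TP4")

.ion_resnames <- c("NA", "CL", "SOD", "CLA", "POT", "K", "MG", "CAL", "ZN",
                   "CS", "LI", "RB", "BR", "IOD", "F", "NA+", "CL-", "K+", "MG2")

classify_residue <- function(resname, solvent_extra = character(),
                             ion_extra = character()) {
  rn <- toupper(trimws(resname))
  out <- rep("other", length(rn))
  out[rn %in% .protein_resnames] <- "protein"
  out[rn %in% .nucleic_resnames] <- "nucleic"
  out[rn %in% .cofactor_resnames] <- "cofactor"
  out[rn %in% c(.solvent_resnames, toupper(solvent_extra))] <- "solvent"
  out[rn %in% c(.ion_resnames, toupper(ion_extra))] <- "ion"
  out
}

# Guess the element from a PDB-style atom name when no element column exists.
# Handles leading digits ("1HB2"); a two-letter element is assigned only when
# the whole stripped name IS a known ion/metal name, so "CA" stays an alpha
# carbon while the ion residue atom "CLA" maps to chlorine.
guess_element <- function(name) {
  nm <- gsub("[0-9'\"*+-]", "", toupper(trimws(name)))
  ion_map <- c(CL = "CL", BR = "BR", MG = "MG", ZN = "ZN", FE = "FE",
               MN = "MN", NA. = "NA", SOD = "NA", CLA = "CL", POT = "K")
  names(ion_map)[names(ion_map) == "NA."] <- "NA"
  ele <- substr(nm, 1, 1)
  hit <- nm %in% names(ion_map)
  ele[hit] <- unname(ion_map[nm[hit]])
  ele
}

#' Construct a topology table
#'
#' A topology is a data frame with one row per atom carrying the identifiers
#' used throughout the pipeline: atom name, element, residue name/number,
#' segment (chain) id, a heavy-atom flag and a molecule class
#' (`protein`, `nucleic`, `cofactor`, `solvent`, `ion`, `other`).
#'
#' @param name atom names (character).
#' @param resname residue names, recycled to the atom count.
#' @param resno residue numbers (integer), recycled.
#' @param segid segment / chain identifiers, recycled.
#' @param element optional element symbols; guessed from `name` when `NULL`.
#' @param solvent_extra,ion_extra extra residue names to classify as
#'   solvent / ion on top of the built-in vocabularies.
#' @return a `data.frame` of class `"topology"` with columns `name`,
#'   `element`, `resname`, `resno`, `segid`, `heavy`, `molclass`.
#' @examples
#' top <- topology(c("N", "CA", "C", "O"), "GLY", 1, "A")
#' table(top$molclass)
#' @export
topology <- function(name, resname, resno, segid = "A", element = NULL,
                     solvent_extra = character(), ion_extra = character()) {
  n <- length(name)
  if (n < 1) stopf("topology needs at least one atom")
  resname <- rep_len(as.character(resname), n)
  resno <- rep_len(as.integer(resno), n)
  segid <- rep_len(as.character(segid), n)
  if (is.null(element)) element <- guess_element(name)
  element <- rep_len(toupper(as.character(element)), n)
  top <- data.frame(
    name = as.character(name), element = element,
    resname = resname, resno = resno, segid = segid,
    heavy = element != "H",
    molclass = classify_residue(resname, solvent_extra, ion_extra),
    stringsAsFactors = FALSE)
  class(top) <- c("topology", "data.frame")
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, segments [%s]\n",
              nrow(x), length(unique(paste(x$segid, x$resno))),
              paste(unique(x$segid), collapse = ", ")))
  print(table(x$molclass))
  invisible(x)
}

# per-atom residue key "SEG:RESNAME+RESNO", e.g. "MSH6:THR781"
residue_key <- function(top) paste0(top$segid, ":", top$resname, top$resno)

# per-atom identity key used for cross-trajectory atom matching
atom_key <- function(top) paste0(top$segid, ":", top$resname, top$resno, ":", top$name)

#' Resolve an atom selection on a topology
#'
#' Selection shorthand used across the package: `"calpha"` (protein CA atoms),
#' `"heavy"` (non-hydrogen), `"protein"`, `"nucleic"`, `"all"`, an integer
#' vector of atom indices, or a logical mask.
#'
#' @param top a [topology()].
#' @param selection shorthand string, integer indices or logical mask.
#' @return integer atom indices (1-based).
#' @export
select_atoms <- function(top, selection = "calpha") {
  if (is.logical(selection)) {
    if (length(selection) != nrow(top)) stopf("logical mask length mismatch")
    return(which(selection))
  }
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1 | idx > nrow(top))) stopf("atom index out of range")
    return(idx)
  }
  idx <- switch(match.arg(selection, c("calpha", "heavy", "protein", "nucleic", "all")),
    calpha = which(top$name == "CA" & top$molclass == "protein"),
    heavy = which(top$heavy),
    protein = which(top$molclass == "protein"),
    nucleic = which(top$molclass == "nucleic"),
    all = seq_len(nrow(top)))
  if (length(idx) == 0) stopf("selection '%s' matches no atoms", selection)
  idx
}
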