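#' @title Structure input/output
#' @description Read AlphaFold-style monomeric PDB models into a light
#'   internal representation carrying heavy-atom coordinates and the
#'   per-residue confidence (pLDDT) track stored in the B-factor column.
#' @name structure-io
NULL

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1_TO_3 <- setNames(names(AA3_TO_1), AA3_TO_1)

new_structure_model <- function(protein_id, atoms, source_path = NA_character_) {
  stopifnot(is.data.frame(atoms))
  need <- c("resno", "aa", "elety", "element", "x", "y", "z", "b")
  if (!all(need %in% names(atoms))) {
    stop("atom table must carry columns: ", paste(need, collapse = ", "))
  }
  resno_seq <- unique(atoms$resno)
  if (any(diff(resno_seq) <= 0)) {
    atoms <- atoms[order(atoms$resno), , drop = FALSE]
    resno_seq <- unique(atoms$resno)
    if (any(diff(resno_seq) <= 0)) stop("residue indices are not strictly increasing")
  }
  structure(
    list(protein_id = protein_id, atoms = atoms, source_path = source_path),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %s: %d residues, %d heavy atoms\n",
    x$protein_id, n_residues(x), nrow(x$atoms)
  ))
  invisible(x)
}

#' Number of residues in a structure model
#' @param model A `structure_model`.
#' @return Integer count of residues.
#' @export
n_residues <- function(model) length(unique(model$atoms$resno))

#' Per-residue summary of a structure model
#'
#' @param model A `structure_model`.
#' @return A data frame with one row per residue: `resno` (1-based position),
#'   `aa` (one-letter code, `X` for unknown) and `plddt` (CA B-factor clipped
#'   to \[0, 100\], `NA` when the residue has no CA atom).
#' @export
model_residues <- function(model) {
  at <- model$atoms
  resno <- unique(at$resno)
  first <- match(resno, at$resno)
  data.frame(
    resno = resno,
    aa = at$aa[first],
    plddt = extract_plddt(model, warn = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Read an AlphaFold-style monomeric PDB model
#'
#' Parses a PDB file into a `structure_model`. Only `ATOM` records are kept:
#' HETATM entries (waters, ligands) are excluded, hydrogens and deuteriums
#' are dropped, and alternate locations other than blank or `A` are
#' discarded. Residue names outside the 20 standard amino acids are retained
#' with one-letter code `X` and a warning. Multi-chain files are rejected —
#' the expected inputs are monomeric models with pLDDT in the B-factor
#' column.
#'
#' @param path Path to a PDB file.
#' @param format Input dialect; only `"pdb"` is supported.
#' @return A `structure_model`: protein id (file stem), heavy-atom table and
#'   provenance path.
#' @export
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to read PDB file '", path, "': ", conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in '", path, "' (empty model)")
  chains <- unique(at$chain[!is.na(at$chain)])
  if (length(chains) > 1L) {
    stop("multi-chain structure in '", path, "' (chains ",
         paste(chains, collapse = ","), "); monomeric models expected")
  }
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  element <- at$elesy
  bad <- is.na(element) | element == ""
  if (any(bad)) element[bad] <- toupper(substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1))
  element <- toupper(trimws(element))
  keep <- !(element %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  element <- element[keep]
  if (nrow(at) == 0L) stop("no heavy atoms in '", path, "'")

  aa <- unname(AA3_TO_1[toupper(at$resid)])
  if (anyNA(aa)) {
    unknown <- unique(toupper(at$resid)[is.na(aa)])
    warning("unknown residue name(s) kept as 'X': ", paste(unknown, collapse = ", "))
    aa[is.na(aa)] <- "X"
  }

  atoms <- data.frame(
    resno = at$resno, aa = aa, elety = trimws(at$elety), element = element,
    x = at$x, y = at$y, z = at$z, b = at$b, stringsAsFactors = FALSE
  )
  pid <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  new_structure_model(pid, atoms, source_path = path)
}

#' Extract the per-residue pLDDT track
#'
#' AlphaFold stores the per-residue pLDDT confidence in the B-factor column,
#' identically for every atom of a residue; the CA atom is used as the
#' canonical carrier. Values are clipped to \[0, 100\].
#'
#' @param model A `structure_model`.
#' @param warn Warn when a residue lacks a CA atom (its value is `NA`).
#' @return Numeric vector, one value per residue in residue order.
#' @export
extract_plddt <- function(model, warn = TRUE) {
  at <- model$atoms
  resno <- unique(at$resno)
  ca <- at[at$elety == "CA", , drop = FALSE]
  out <- ca$b[match(resno, ca$resno)]
  if (warn && anyNA(out)) {
    warning("residue(s) without CA atom, pLDDT set to NA: ",
            paste(resno[is.na(out)], collapse = ", "))
  }
  pmin(pmax(out, 0), 100)
}

#' Write a structure model as a PDB file
#'
#' Writes heavy atoms with the stored B-factor (pLDDT) in columns 61-66.
#' `read_structure(write_structure(x))` reproduces residues, coordinates to
#' PDB precision (1e-3 Angstrom) and B-factors to 1e-2.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  resid3 <- unname(AA1_TO_3[at$aa])
  resid3[is.na(resid3)] <- "UNK"
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write '", path, "': directory does not exist")
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, resno = at$resno, resid = resid3,
    eleno = seq_len(nrow(at)), elety = at$elety,
    chain = rep("A", nrow(at)), o = rep(1.0, nrow(at)), b = at$b,
    elesy = at$element
  )
  invisible(path)
}
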