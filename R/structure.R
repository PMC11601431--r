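# Structure input/output and titratable-site identification.
#
# Parsing of the PDB fixed-column format is delegated to bio3d::read.pdb;
# this layer adds input validation, the heavy-atom convention (hydrogens
# dropped), altloc resolution and the protein/ligand split.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

TITRATABLE_AA <- c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS")
ACID_AA <- c("ASP", "GLU", "CYS", "TYR")
BASE_AA <- c("HIS", "LYS")

ANCHOR_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"),
  CYS = "SG",
  TYR = "OH",
  LYS = "NZ"
)

#' Read a protein structure from PDB text or a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations to
#' the highest-occupancy conformer (first record wins a tie), drops
#' hydrogens (heavy-atom convention: experimental structures typically lack
#' them and all downstream features use heavy atoms only), and separates
#' protein residues from waters and other heteroatoms, which are retained
#' in a `ligands` table.
#'
#' @param source path to a PDB file, or a character scalar/vector of PDB
#'   text lines.
#' @param source_id optional structure label; defaults to the file stem or
#'   `"structure"` for inline text.
#' @return an object of class `prot_structure`: a list with `atoms` (one
#'   row per retained protein heavy atom), `ligands`, and `source_id`.
#'   Residues are keyed by `(chain, resno, insert)`.
#' @export
read_structure <- function(source, source_id = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(source_id))
      source_id <- sub("\\.(pdb|ent|cif)$", "", basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(source_id)) source_id <- "structure"
  }
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("PDB format error: empty input")

  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_rec))
    stop("PDB format error: no ATOM/HETATM records found")
  for (i in which(is_rec)) {
    ln <- lines[i]
    bad <- nchar(ln) < 54L
    if (!bad) {
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      bad <- anyNA(xyz)
    }
    if (bad)
      stop(sprintf("PDB format error at line %d: %s", i, ln))
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE, multi = FALSE))
  at <- pdb$atom

  element <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                   NA_character_, at$elesy)))
  guess <- toupper(substr(gsub("[0-9' ]", "", at$elety), 1, 1))
  element[is.na(element)] <- guess[is.na(element)]
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = element,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    type = at$type,
    stringsAsFactors = FALSE
  )

  # heavy-atom convention
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]

  # altloc: highest occupancy per (residue, atom name); first record on tie
  atoms$ord <- seq_len(nrow(atoms))
  grp <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, atoms$type,
               sep = "\r")
  atoms <- atoms[order(grp, -atoms$occ, atoms$ord), , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$name, atoms$type, sep = "\r")), ,
                 drop = FALSE]
  atoms <- atoms[order(atoms$ord), , drop = FALSE]
  atoms$ord <- NULL

  is_protein <- atoms$type == "ATOM" & atoms$resname %in% AA3
  prot <- atoms[is_protein, , drop = FALSE]
  lig <- atoms[!is_protein, , drop = FALSE]
  prot$type <- NULL
  lig$type <- NULL
  if (nrow(prot) == 0L)
    stop("no protein residues in input")
  prot$res_key <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
  if (nrow(lig)) lig$res_key <- paste(lig$chain, lig$resno, lig$insert, sep = "|")
  rownames(prot) <- NULL

  structure(list(atoms = prot, ligands = lig, source_id = source_id),
            class = "prot_structure")
}

#' @export
print.prot_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat(sprintf("<prot_structure %s: %d residues, %d atoms, %d ligand atoms>\n",
              x$source_id, nrow(res), nrow(x$atoms),
              if (is.null(x$ligands)) 0L else nrow(x$ligands)))
  invisible(x)
}

#' Residue table of a structure
#'
#' @param structure a `prot_structure`.
#' @return data.frame with one row per residue: chain, resno, insert,
#'   resname, res_key, natoms, in file order.
#' @export
structure_residues <- function(structure) {
  at <- structure$atoms
  keep <- !duplicated(at$res_key)
  res <- at[keep, c("chain", "resno", "insert", "resname", "res_key")]
  res$natoms <- as.integer(table(at$res_key)[res$res_key])
  rownames(res) <- NULL
  res
}

#' Atom coordinates of a structure as an n x 3 matrix
#' @param structure a `prot_structure`.
#' @export
atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure (same atom order)
#' @param structure a `prot_structure`.
#' @param coords n x 3 matrix matching `nrow(structure$atoms)`.
#' @export
set_atom_coords <- function(structure, coords) {
  stopifnot(nrow(coords) == nrow(structure$atoms))
  structure$atoms$x <- coords[, 1]
  structure$atoms$y <- coords[, 2]
  structure$atoms$z <- coords[, 3]
  structure
}

#' Write a structure back to PDB format
#'
#' Writes the retained protein heavy atoms through bio3d::write.pdb, so a
#' read / write / read round trip is idempotent on the retained fields.
#'
#' @param structure a `prot_structure`.
#' @param file output path; if missing, the PDB text is returned invisibly
#'   as a character vector.
#' @export
write_structure <- function(structure, file = tempfile(fileext = ".pdb")) {
  at <- structure$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resname,
                   eleno = at$serial, elety = at$name,
                   chain = at$chain, insert = ifelse(at$insert == "", NA, at$insert),
                   o = at$occ, b = rep(0, nrow(at)),
                   elesy = at$element)
  invisible(file)
}

#' Locate the titratable residues of a structure
#'
#' One site per Asp/Glu/His/Cys/Tyr/Lys residue that has at least one of
#' its anchor atoms (the sidechain atoms that exchange the proton: Asp
#' OD1/OD2, Glu OE1/OE2, His ND1/NE2, Cys SG, Tyr OH, Lys NZ). The site's
#' anchor point is the arithmetic mean of the anchor atoms present; all
#' microenvironment features and graphs are measured from it. Residues of
#' the six types missing every anchor atom are reported via a warning and
#' skipped.
#'
#' @param structure a `prot_structure`.
#' @return list of `titratable_site` objects (possibly empty).
#' @export
identify_titratable_sites <- function(structure) {
  res <- structure_residues(structure)
  res <- res[res$resname %in% TITRATABLE_AA, , drop = FALSE]
  sites <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    at <- structure$atoms[structure$atoms$res_key == r$res_key, , drop = FALSE]
    anch <- at[at$name %in% ANCHOR_ATOMS[[r$resname]], , drop = FALSE]
    if (nrow(anch) == 0L) {
      skipped <- c(skipped, r$res_key)
      next
    }
    am <- as.matrix(anch[, c("x", "y", "z")])
    rownames(am) <- anch$name
    sites[[length(sites) + 1L]] <- structure(list(
      chain = r$chain, resno = r$resno, insert = r$insert,
      aa = r$resname, res_key = r$res_key,
      anchor_atoms = am,
      anchor_point = colMeans(am),
      structure_id = structure$source_id
    ), class = "titratable_site")
  }
  if (length(skipped))
    warning(sprintf("%d titratable residue(s) missing all anchor atoms, skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  sites
}

#' @export
print.titratable_site <- function(x, ...) {
  cat(sprintf("<titratable_site %s %s%d%s anchor=(%.2f, %.2f, %.2f)>\n",
              x$aa, x$chain, x$resno, x$insert,
              x$anchor_point[1], x$anchor_point[2], x$anchor_point[3]))
  invisible(x)
}
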