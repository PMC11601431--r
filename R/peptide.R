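# Internal ideal-geometry peptide builder.
#
# Backbone atoms are placed sequentially from ideal bond lengths/angles and
# user-supplied phi/psi torsions (omega fixed at 180); sidechains follow
# small per-residue internal-coordinate recipes with default rotamers.
# Used by the synthetic-structure generator and by geometry tests; not a
# substitute for real modelling.

# each step: atom name, three reference atoms, bond (A), angle (deg), torsion (deg)
SIDECHAIN_RECIPES <- list(
  GLY = list(),
  ALA = list(),
  SER = list(c("OG",  "N", "CA", "CB", 1.417, 110.8, -65)),
  CYS = list(c("SG",  "N", "CA", "CB", 1.808, 113.8, -65)),
  THR = list(c("OG1", "N", "CA", "CB", 1.430, 109.6, -60),
             c("CG2", "N", "CA", "CB", 1.520, 110.5, 60)),
  ASP = list(c("CG",  "N", "CA", "CB", 1.520, 113.1, -65),
             c("OD1", "CA", "CB", "CG", 1.250, 118.4, -20),
             c("OD2", "CA", "CB", "CG", 1.250, 118.4, 160)),
  ASN = list(c("CG",  "N", "CA", "CB", 1.520, 112.6, -65),
             c("OD1", "CA", "CB", "CG", 1.230, 120.8, -20),
             c("ND2", "CA", "CB", "CG", 1.330, 116.4, 160)),
  GLU = list(c("CG",  "N", "CA", "CB", 1.520, 114.1, -65),
             c("CD",  "CA", "CB", "CG", 1.520, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.250, 118.4, -20),
             c("OE2", "CB", "CG", "CD", 1.250, 118.4, 160)),
  GLN = list(c("CG",  "N", "CA", "CB", 1.520, 114.1, -65),
             c("CD",  "CA", "CB", "CG", 1.520, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.230, 120.8, -20),
             c("NE2", "CB", "CG", "CD", 1.330, 116.4, 160)),
  HIS = list(c("CG",  "N", "CA", "CB", 1.500, 113.8, -65),
             c("ND1", "CA", "CB", "CG", 1.380, 122.7, -75),
             c("CD2", "CA", "CB", "CG", 1.360, 131.0, 105),
             c("CE1", "CB", "CG", "ND1", 1.320, 109.3, 180),
             c("NE2", "CG", "ND1", "CE1", 1.320, 108.4, 0)),
  TYR = list(c("CG",  "N", "CA", "CB", 1.510, 113.9, -65),
             c("CD1", "CA", "CB", "CG", 1.390, 120.8, 90),
             c("CD2", "CA", "CB", "CG", 1.390, 120.8, -90),
             c("CE1", "CB", "CG", "CD1", 1.390, 121.1, 180),
             c("CE2", "CB", "CG", "CD2", 1.390, 121.1, 180),
             c("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, 0),
             c("OH",  "CD1", "CE1", "CZ", 1.380, 120.0, 180)),
  LYS = list(c("CG",  "N", "CA", "CB", 1.520, 114.1, -65),
             c("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
             c("CE",  "CB", "CG", "CD", 1.520, 111.3, 180),
             c("NZ",  "CG", "CD", "CE", 1.490, 111.9, 180)),
  ARG = list(c("CG",  "N", "CA", "CB", 1.520, 114.1, -65),
             c("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
             c("NE",  "CB", "CG", "CD", 1.460, 112.0, 180),
             c("CZ",  "CG", "CD", "NE", 1.330, 124.2, 180),
             c("NH1", "CD", "NE", "CZ", 1.330, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.330, 120.0, 180))
)

element_of <- function(name) toupper(substr(gsub("[0-9]", "", name), 1, 1))

#' Build an ideal-geometry peptide
#'
#' @param sequence character vector of 3-letter residue codes.
#' @param phi,psi backbone torsions in degrees; scalars are recycled.
#' @param chain chain identifier.
#' @param start_resno first residue number.
#' @return atom data.frame compatible with `prot_structure$atoms`.
#' @keywords internal
build_peptide <- function(sequence, phi = -140, psi = 135, chain = "A",
                          start_resno = 1L) {
  n <- length(sequence)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, names(SIDECHAIN_RECIPES))
  if (length(bad))
    stop("no sidechain recipe for: ", paste(unique(bad), collapse = ", "))

  rows <- list()
  add <- function(resno, resname, name, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element_of(name), resname = resname,
      chain = chain, resno = resno, insert = "",
      x = p[1], y = p[2], z = p[3], occ = 1,
      stringsAsFactors = FALSE)
  }

  Nprev <- CAprev <- Cprev <- NULL
  for (i in seq_len(n)) {
    resno <- start_resno + i - 1L
    if (i == 1L) {
      Ni <- c(0, 0, 0)
      CAi <- c(1.458, 0, 0)
      th <- 68.8 * pi / 180  # gives the N-CA-C angle of 111.2 deg
      Ci <- CAi + 1.525 * c(cos(th), sin(th), 0)
    } else {
      Ni <- place_atom(Nprev, CAprev, Cprev, 1.329, 116.2, psi[i - 1L])
      CAi <- place_atom(CAprev, Cprev, Ni, 1.458, 121.7, 180)
      Ci <- place_atom(Cprev, Ni, CAi, 1.525, 111.2, phi[i])
    }
    Oi <- place_atom(Ni, CAi, Ci, 1.231, 120.8, psi[i] + 180)
    add(resno, sequence[i], "N", Ni)
    add(resno, sequence[i], "CA", CAi)
    add(resno, sequence[i], "C", Ci)
    add(resno, sequence[i], "O", Oi)

    pos <- list(N = Ni, CA = CAi, C = Ci, O = Oi)
    if (sequence[i] != "GLY") {
      pos$CB <- place_atom(Ci, Ni, CAi, 1.530, 110.5, 122.7)
      add(resno, sequence[i], "CB", pos$CB)
    }
    for (st in SIDECHAIN_RECIPES[[sequence[i]]]) {
      p <- place_atom(pos[[st[2]]], pos[[st[3]]], pos[[st[4]]],
                      as.numeric(st[5]), as.numeric(st[6]), as.numeric(st[7]))
      pos[[st[1]]] <- p
      add(resno, sequence[i], st[1], p)
    }
    Nprev <- Ni; CAprev <- CAi; Cprev <- Ci
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at$res_key <- paste(at$chain, at$resno, at$insert, sep = "|")
  at
}

#' Assemble an atom table into a prot_structure and/or PDB text
#' @keywords internal
atoms_to_structure <- function(atoms, source_id = "synthetic") {
  atoms$serial <- seq_len(nrow(atoms))
  atoms$res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  atoms$altloc <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, ligands = atoms[0, , drop = FALSE],
                 source_id = source_id),
            class = "prot_structure")
}

#' Render a structure as PDB text lines (via bio3d)
#' @keywords internal
structure_to_pdb_text <- function(structure) {
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f), add = TRUE)
  write_structure(structure, f)
  readLines(f, warn = FALSE)
}
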