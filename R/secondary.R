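# Three-state secondary structure from backbone geometry.
#
# A deliberately small DSSP-like assigner: helix requires helical backbone
# dihedrals supported by a short i->i+4 (or i->i+2 turn) O...N contact;
# strand requires extended dihedrals. Residues with incomplete backbone
# context are coil.

#' Assign 3-state secondary structure (H/E/C)
#'
#' Helix (H): phi in (-100, -30) and psi in (-80, 0) degrees, plus an
#' O(i)...N(i+4) or O(i)...N(i+2) distance <= `hbond_cutoff` involving the
#' residue. Strand (E): phi in (-180, -90) and |psi| in (90, 180]. All
#' other residues, including chain termini and residues with missing
#' backbone atoms, are coil (C).
#'
#' @param structure a `prot_structure`.
#' @param hbond_cutoff backbone N-O hydrogen-bond distance cutoff, Angstrom.
#' @return character vector in {"H","E","C"} named by residue `res_key`,
#'   one class per residue.
#' @export
assign_secondary_structure <- function(structure, hbond_cutoff = 3.5) {
  res <- structure_residues(structure)
  n <- nrow(res)
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  lookup <- function(name) {
    idx <- match(paste(res$res_key, name), paste(at$res_key, at$name))
    lapply(seq_len(n), function(i)
      if (is.na(idx[i])) NULL else xyz[idx[i], ])
  }
  N <- lookup("N")
  CA <- lookup("CA")
  C <- lookup("C")
  O <- lookup("O")

  same_chain <- function(i, j) {
    j >= 1L && j <= n && res$chain[i] == res$chain[j]
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.null(N[[i]]) || is.null(CA[[i]]) || is.null(C[[i]])) next
    if (same_chain(i, i - 1L) && !is.null(C[[i - 1L]]))
      phi[i] <- dihedral(C[[i - 1L]], N[[i]], CA[[i]], C[[i]])
    if (same_chain(i, i + 1L) && !is.null(N[[i + 1L]]))
      psi[i] <- dihedral(N[[i]], CA[[i]], C[[i]], N[[i + 1L]])
  }

  # O(i)...N(i+k) contacts, k in {2, 4}
  hb <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (k in c(2L, 4L)) {
      j <- i + k
      if (!same_chain(i, j) || is.null(O[[i]]) || is.null(N[[j]])) next
      if (sqrt(sum((O[[i]] - N[[j]])^2)) <= hbond_cutoff) {
        hb[i:j] <- TRUE
      }
    }
  }

  cls <- rep("C", n)
  helical <- !is.na(phi) & !is.na(psi) &
    phi > -100 & phi < -30 & psi > -80 & psi < 0
  extended <- !is.na(phi) & !is.na(psi) &
    phi > -180 & phi < -90 & abs(psi) > 90
  cls[extended] <- "E"
  cls[helical & hb] <- "H"
  names(cls) <- res$res_key
  cls
}
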