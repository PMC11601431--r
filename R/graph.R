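# Residue-centred atom graphs for the attention network.
#
# The microenvironment of a titratable site is truncated to the atoms
# within 10 A of the anchor point (the approximate range of electrostatics
# relevant for pKa shifts). Nodes carry a 42-wide physicochemical block
# plus a 24-wide atom-type one-hot (total width 66); edges connect heavy
# atoms within 4 A, covering covalent bonds and close contacts.

GRAPH_NODE_VERSION <- "gatnode-1"

ATOM_TYPES_24 <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CD1", "CD2",
                   "CE", "CE1", "CE2", "CZ", "OD1", "OD2", "OE1", "OE2",
                   "ND1", "NE2", "NZ", "OG", "OH", "SG", "OTHER")

AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

HB_DONOR_ATOMS <- c("N", "NZ", "NE", "NH1", "NH2", "ND1", "NE1", "ND2",
                    "NE2", "OG", "OG1", "OH", "SG")
HB_ACCEPTOR_ATOMS <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
                       "OH", "ND1", "NE2", "SD", "SG")

# base node block: 37 informative positions padded to width 42
GAT_BASE_WIDTH <- 42L
GAT_TYPE_WIDTH <- 24L

node_feature_matrix <- function(atoms, anchor, central_acid) {
  n <- nrow(atoms)
  x <- matrix(0, n, GAT_BASE_WIDTH + GAT_TYPE_WIDTH)
  # residue-type one-hot [1:20]
  ri <- match(atoms$resname, AA3)
  ok <- !is.na(ri)
  x[cbind(which(ok), ri[ok])] <- 1
  # backbone flag [21]
  x[, 21] <- as.numeric(atoms$name %in% c("N", "CA", "C", "O", "OXT"))
  # formal charge class one-hot (neg/neutral/pos) [22:24], standard pH-7 states
  neg <- (atoms$resname == "ASP" & atoms$name %in% c("OD1", "OD2")) |
    (atoms$resname == "GLU" & atoms$name %in% c("OE1", "OE2")) |
    atoms$name == "OXT"
  pos <- (atoms$resname == "LYS" & atoms$name == "NZ") |
    (atoms$resname == "ARG" & atoms$name %in% c("NE", "NH1", "NH2"))
  x[, 22] <- as.numeric(neg)
  x[, 23] <- as.numeric(!neg & !pos)
  x[, 24] <- as.numeric(pos)
  # aromatic flag [25]
  arom <- rep(FALSE, n)
  for (rn in names(AROMATIC_ATOMS))
    arom <- arom | (atoms$resname == rn & atoms$name %in% AROMATIC_ATOMS[[rn]])
  x[, 25] <- as.numeric(arom)
  # h-bond donor/acceptor flags [26:27]
  x[, 26] <- as.numeric(atoms$name %in% HB_DONOR_ATOMS)
  x[, 27] <- as.numeric(atoms$name %in% HB_ACCEPTOR_ATOMS)
  # anchor-distance radial bins (0,2.5], (2.5,5], (5,7.5], (7.5,10] [28:31]
  d <- dist_to(anchor, as.matrix(atoms[, c("x", "y", "z")]))
  bin <- pmin(findInterval(d, c(2.5, 5, 7.5)) + 1L, 4L)
  x[cbind(seq_len(n), 27L + bin)] <- 1
  # acid/base flag of the central residue [32]
  x[, 32] <- as.numeric(central_acid)
  # element group one-hot C/N/O/S/other [33:37]
  eg <- match(atoms$element, c("C", "N", "O", "S"))
  eg[is.na(eg)] <- 5L
  x[cbind(seq_len(n), 32L + eg)] <- 1
  # [38:42] reserved padding, zeros
  # atom-type one-hot block [43:66]
  ti <- match(atoms$name, ATOM_TYPES_24)
  ti[is.na(ti)] <- match("OTHER", ATOM_TYPES_24)
  x[cbind(seq_len(n), GAT_BASE_WIDTH + ti)] <- 1
  x
}

#' Build the residue-centred atom graph of a titratable site
#'
#' @param structure a `prot_structure`.
#' @param site a `titratable_site`.
#' @param radius sphere radius around the anchor point, Angstrom.
#' @param edge_cutoff undirected edges connect atom pairs within this
#'   distance, Angstrom.
#' @param label optional pKa-shift label (experimental pKa minus the model
#'   pKa of the site's type).
#' @return object of class `residue_graph`: node feature matrix `x`
#'   (n x 66), `edges` (2-column matrix of node index pairs, i < j),
#'   `label`, `aa`, `site_key`, `structure_id`, `atom_ids`, `coords`.
#'   Nodes are ordered by (chain, resno, insert, atom name). Fewer than 4
#'   atoms in the sphere is an error ("environment too sparse").
#' @export
build_graph <- function(structure, site, radius = 10.0, edge_cutoff = 4.0,
                        label = NA_real_) {
  at <- structure$atoms
  d <- dist_to(site$anchor_point, as.matrix(at[, c("x", "y", "z")]))
  at <- at[d <= radius, , drop = FALSE]
  if (nrow(at) < 4L)
    stop(sprintf("environment too sparse: %d atoms within %.1f A of %s",
                 nrow(at), radius, site$res_key))
  at <- at[order(at$chain, at$resno, at$insert, at$name), , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dm <- dist_mat(xyz, xyz)
  idx <- which(dm <= edge_cutoff & upper.tri(dm), arr.ind = TRUE)
  x <- node_feature_matrix(at, site$anchor_point, site$aa %in% ACID_AA)
  structure(list(
    x = x, edges = unname(idx), label = label, aa = site$aa,
    site_key = site$res_key, structure_id = structure$source_id,
    atom_ids = paste(at$res_key, at$name, sep = ":"), coords = xyz,
    node_version = GRAPH_NODE_VERSION
  ), class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph %s %s: %d nodes, %d edges, label %s>\n",
              x$structure_id, x$site_key, nrow(x$x), nrow(x$edges),
              if (is.na(x$label)) "NA" else sprintf("%.2f", x$label)))
  invisible(x)
}

#' Graphs for every (record, structure) pair of a pKa table
#'
#' Labels are pKa shifts (experimental minus model pKa), the regression
#' target of the attention network.
#'
#' @param records a `pka_records` data.frame.
#' @param structures named map from structure id to `prot_structure` or
#'   PDB text.
#' @param radius,edge_cutoff passed to [build_graph()].
#' @return list of `residue_graph` objects with a `unique_key` field added.
#' @export
build_graphs <- function(records, structures, radius = 10.0,
                         edge_cutoff = 4.0) {
  parsed <- new.env(parent = emptyenv())
  refs <- record_structures(records)
  out <- list()
  for (i in seq_len(nrow(records))) {
    for (sid in refs[[i]]) {
      if (!nzchar(sid)) next
      if (is.null(parsed[[sid]])) {
        s <- parse_structure_source(structures[[sid]], sid)
        parsed[[sid]] <- list(s = s, sites = identify_titratable_sites(s))
      }
      env <- parsed[[sid]]
      site <- Filter(function(x) x$chain == records$chain[i] &&
                       x$resno == records$resid[i], env$sites)
      if (length(site) == 0L)
        stop(sprintf("no titratable site %s/%s in structure %s",
                     records$chain[i], records$resid[i], sid))
      g <- build_graph(env$s, site[[1]], radius, edge_cutoff,
                       label = records$pka[i] - model_pka(records$aa[i]))
      g$unique_key <- records$unique_key[i]
      out[[length(out) + 1L]] <- g
    }
  }
  out
}
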