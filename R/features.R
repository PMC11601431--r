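# Microenvironment features of titratable sites.
#
# Three numeric groups mirror the physical determinants of pKa shifts:
# solvent accessibility (burial), hydrogen bonding and electrostatics
# (neighbour counts and nearest distances), plus categorical descriptors
# of residue identity, secondary structure and local net charge. The
# catalog is versioned so alternative feature lists can be dropped in.

FEATURE_SENTINEL <- 20.0  # distance reported when no partner exists (A)

# model (solution) pKa values of the free sidechains
MODEL_PKA <- c(ASP = 3.7, GLU = 4.2, HIS = 6.5, CYS = 8.5, TYR = 9.5,
               LYS = 10.4)

# sidechain atom classes used for counts and distances
POLAR_SIDECHAIN_ATOMS <- list(
  SER = "OG", THR = "OG1", ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  TYR = "OH", HIS = c("ND1", "NE2"), CYS = "SG", TRP = "NE1")
POSITIVE_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                       HIS = c("ND1", "NE2"))
NEGATIVE_O_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
HIS_N_ATOMS <- list(HIS = c("ND1", "NE2"))

#' Model (solution) pKa of a titratable amino acid
#'
#' @param aa 3-letter code, one of ASP, GLU, HIS, CYS, TYR, LYS
#'   (vectorised).
#' @return numeric pKa constant(s): Asp 3.7, Glu 4.2, His 6.5, Cys 8.5,
#'   Tyr 9.5, Lys 10.4.
#' @export
model_pka <- function(aa) {
  aa <- toupper(aa)
  if (!all(aa %in% names(MODEL_PKA)))
    stop("not a titratable amino acid: ",
         paste(setdiff(aa, names(MODEL_PKA)), collapse = ", "))
  unname(MODEL_PKA[aa])
}

#' Feature catalog: the ordered, versioned feature list
#'
#' @param version catalog version string; `"pkafeat-1"` is the only
#'   built-in version.
#' @return object of class `feature_catalog` with an `entries` data.frame
#'   (name, unit, group, kind) whose order defines the feature-vector
#'   layout.
#' @export
feature_catalog <- function(version = "pkafeat-1") {
  if (version != "pkafeat-1")
    stop("unsupported feature catalog version: ", version)
  e <- function(name, unit, group, kind = "numeric")
    data.frame(name = name, unit = unit, group = group, kind = kind,
               stringsAsFactors = FALSE)
  entries <- rbind(
    e("model_pka", "pKa", "identity"),
    e("buried_ratio", "fraction", "accessibility"),
    e("sasa_sidechain", "A^2", "accessibility"),
    e("n_polar10", "count", "hbond"),
    e("n_polar15", "count", "hbond"),
    e("n_pos10", "count", "electrostatics"),
    e("n_pos15", "count", "electrostatics"),
    e("n_neg10", "count", "electrostatics"),
    e("n_neg15", "count", "electrostatics"),
    e("n_heavy6", "count", "accessibility"),
    e("n_heavy8", "count", "accessibility"),
    e("n_heavy10", "count", "accessibility"),
    e("d0_neg_O", "A", "electrostatics"),
    e("d1_neg_O", "A", "electrostatics"),
    e("d0_pos_N", "A", "electrostatics"),
    e("d1_pos_N", "A", "electrostatics"),
    e("d0_polar", "A", "hbond"),
    e("d1_polar", "A", "hbond"),
    e("d0_hbond_h", "A", "hbond"),
    e("d1_hbond_h", "A", "hbond"),
    e("d0_bb_O", "A", "hbond"),
    e("d1_bb_O", "A", "hbond"),
    e("d0_bb_N", "A", "hbond"),
    e("d1_bb_N", "A", "hbond"),
    e("res_type", "code", "categorical", "categorical"),
    e("ss_site", "code", "categorical", "categorical"),
    e("ss_env10", "code", "categorical", "categorical"),
    e("charge_sign10", "sign", "categorical", "categorical")
  )
  stopifnot(!anyDuplicated(entries$name))
  structure(list(version = version, entries = entries),
            class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog %s: %d features (%d numeric, %d categorical)>\n",
              x$version, nrow(x$entries), sum(x$entries$kind == "numeric"),
              sum(x$entries$kind == "categorical")))
  invisible(x)
}

# --- atom selections ---------------------------------------------------

select_atoms <- function(structure, which) {
  at <- structure$atoms
  if (is.function(which)) return(which(at))
  tab <- switch(which,
    polar = POLAR_SIDECHAIN_ATOMS,
    positive = POSITIVE_ATOMS,
    negative_O = NEGATIVE_O_ATOMS,
    his_N = HIS_N_ATOMS,
    bb_O = NULL, bb_N = NULL, heavy = NULL,
    charged_pos_residues = NULL, charged_neg_residues = NULL,
    stop("unknown atom selection: ", which))
  if (which == "bb_O") return(at$name %in% c("O", "OXT"))
  if (which == "bb_N") return(at$name == "N")
  if (which == "heavy") return(rep(TRUE, nrow(at)))
  if (which == "charged_pos_residues")
    return(select_atoms_charged(structure, TRUE))
  if (which == "charged_neg_residues")
    return(select_atoms_charged(structure, FALSE))
  sel <- rep(FALSE, nrow(at))
  for (rn in names(tab))
    sel <- sel | (at$resname == rn & at$name %in% tab[[rn]])
  # OXT terminal carboxylate counts as a negatively charged oxygen
  if (which == "negative_O") sel <- sel | at$name == "OXT"
  sel
}

#' Count residues with a selected atom inside a radius of a site
#'
#' Residue-level counting: a residue contributes 1 however many of its
#' qualifying atoms fall inside the (inclusive) radius. The site's own
#' residue is excluded.
#'
#' @param site a `titratable_site`.
#' @param structure the owning `prot_structure`.
#' @param selection one of "polar", "positive", "negative_O", "his_N",
#'   "bb_O", "bb_N", "heavy", or a predicate `function(atoms) -> logical`.
#' @param radius cutoff in Angstrom (distance to the site anchor point,
#'   `<= radius` included).
#' @param per_atom count atoms instead of residues (used for packing
#'   counts).
#' @return integer count.
#' @export
count_in_radius <- function(site, structure, selection, radius,
                            per_atom = FALSE) {
  stopifnot(radius > 0)
  at <- structure$atoms
  sel <- select_atoms(structure, selection) & at$res_key != site$res_key
  if (!any(sel)) return(0L)
  d <- dist_to(site$anchor_point, as.matrix(at[sel, c("x", "y", "z")]))
  hit <- d <= radius
  if (per_atom) return(sum(hit))
  length(unique(at$res_key[sel][hit]))
}

#' Rank-th nearest distance from a site anchor to a selected atom class
#'
#' @inheritParams count_in_radius
#' @param rank 0 for the nearest partner, 1 for the second nearest, ...
#' @return distance in Angstrom; when fewer than `rank + 1` partners exist
#'   the sentinel cap of 20 A is returned (twice the 10 A electrostatic
#'   relevance radius).
#' @export
nearest_distance <- function(site, structure, selection, rank = 0L) {
  stopifnot(rank >= 0)
  at <- structure$atoms
  sel <- select_atoms(structure, selection) & at$res_key != site$res_key
  if (sum(sel) < rank + 1L) return(FEATURE_SENTINEL)
  d <- sort(dist_to(site$anchor_point, as.matrix(at[sel, c("x", "y", "z")])))
  min(d[rank + 1L], FEATURE_SENTINEL)
}

# --- burial ------------------------------------------------------------

.protpka_env <- new.env(parent = emptyenv())

#' Reference maximum sidechain SASA of a titratable residue type
#'
#' Computed once per session from an extended Gly-X-Gly tripeptide built
#' with ideal geometry and the package's own Shrake-Rupley settings, so the
#' numerator and denominator of the buried ratio share one method.
#' @param aa 3-letter code of a titratable residue.
#' @return area in Angstrom^2.
#' @export
reference_sidechain_sasa <- function(aa) {
  aa <- toupper(aa)
  stopifnot(aa %in% TITRATABLE_AA)
  key <- paste0("refsasa_", aa)
  if (!is.null(.protpka_env[[key]])) return(.protpka_env[[key]])
  s <- atoms_to_structure(build_peptide(c("GLY", aa, "GLY"),
                                        phi = -140, psi = 135))
  sasa <- shrake_rupley_sasa(s)
  val <- unname(sidechain_sasa(s, sasa)[paste("A", 2, "", sep = "|")])
  .protpka_env[[key]] <- val
  val
}

#' Buried ratio of a titratable site
#'
#' 1 minus the ratio of the sidechain's solvent-accessible area in its
#' structural context to the reference maximum sidechain area of that
#' amino acid, clamped to [0, 1]. 0 means fully exposed, 1 fully buried.
#'
#' @param site a `titratable_site`.
#' @param structure the owning `prot_structure`.
#' @param sasa_map per-atom SASA from [shrake_rupley_sasa()]; computed on
#'   the fly when missing.
#' @return fraction in [0, 1].
#' @export
buried_ratio <- function(site, structure, sasa_map = NULL) {
  if (is.null(sasa_map)) sasa_map <- shrake_rupley_sasa(structure)
  sc <- sidechain_sasa(structure, sasa_map)[site$res_key]
  ref <- reference_sidechain_sasa(site$aa)
  at <- structure$atoms
  side_names <- at$name[at$res_key == site$res_key &
                          !(at$name %in% c("N", "CA", "C", "O", "OXT"))]
  expected <- length(SIDECHAIN_RECIPES[[site$aa]]) + 1L  # + CB
  if (length(side_names) < expected)
    warning(sprintf("site %s: %d of %d sidechain atoms present; buried ratio computed over present atoms",
                    site$res_key, length(side_names), expected))
  min(max(1 - unname(sc) / ref, 0), 1)
}

# --- full featurization ------------------------------------------------

SS_CODE <- c(H = 1L, E = 2L, C = 3L)

#' Compute the full feature vector of a titratable site
#'
#' Deterministic featurization of one site against the whole structure
#' (all chains form the environment). Distances are measured from the site
#' anchor point; counts are residue-level except the heavy-atom packing
#' counts; absent partners yield the 20 A sentinel.
#'
#' @param structure a `prot_structure`.
#' @param site a `titratable_site` from [identify_titratable_sites()].
#' @param catalog a [feature_catalog()]; its order defines the layout.
#' @param sasa_map,ss optional precomputed [shrake_rupley_sasa()] map and
#'   [assign_secondary_structure()] classes (recomputed when missing;
#'   pass them when featurizing many sites of one structure).
#' @return named numeric vector aligned with the catalog (categorical
#'   entries integer-coded: res_type ASP=1..LYS=6; ss H=1,E=2,C=3;
#'   charge sign -1/0/1), with attributes `catalog_version`, `site_key`,
#'   `structure_id` and `aa`.
#' @export
featurize_site <- function(structure, site, catalog = feature_catalog(),
                           sasa_map = NULL, ss = NULL) {
  if (is.null(sasa_map)) sasa_map <- shrake_rupley_sasa(structure)
  if (is.null(ss)) ss <- assign_secondary_structure(structure)
  at <- structure$atoms

  v <- c(
    model_pka = model_pka(site$aa),
    buried_ratio = buried_ratio(site, structure, sasa_map),
    sasa_sidechain = unname(sidechain_sasa(structure, sasa_map)[site$res_key]),
    n_polar10 = count_in_radius(site, structure, "polar", 10),
    n_polar15 = count_in_radius(site, structure, "polar", 15),
    n_pos10 = count_in_radius(site, structure, "positive", 10),
    n_pos15 = count_in_radius(site, structure, "positive", 15),
    n_neg10 = count_in_radius(site, structure, "negative_O", 10),
    n_neg15 = count_in_radius(site, structure, "negative_O", 15),
    n_heavy6 = count_in_radius(site, structure, "heavy", 6, per_atom = TRUE),
    n_heavy8 = count_in_radius(site, structure, "heavy", 8, per_atom = TRUE),
    n_heavy10 = count_in_radius(site, structure, "heavy", 10, per_atom = TRUE),
    d0_neg_O = nearest_distance(site, structure, "negative_O", 0L),
    d1_neg_O = nearest_distance(site, structure, "negative_O", 1L),
    d0_pos_N = nearest_distance(site, structure, "positive", 0L),
    d1_pos_N = nearest_distance(site, structure, "positive", 1L),
    d0_polar = nearest_distance(site, structure, "polar", 0L),
    d1_polar = nearest_distance(site, structure, "polar", 1L),
    d0_hbond_h = nearest_distance(site, structure, "his_N", 0L),
    d1_hbond_h = nearest_distance(site, structure, "his_N", 1L),
    d0_bb_O = nearest_distance(site, structure, "bb_O", 0L),
    d1_bb_O = nearest_distance(site, structure, "bb_O", 1L),
    d0_bb_N = nearest_distance(site, structure, "bb_N", 0L),
    d1_bb_N = nearest_distance(site, structure, "bb_N", 1L)
  )

  # categorical block
  res_type <- match(site$aa, TITRATABLE_AA)
  ss_site <- unname(SS_CODE[ss[site$res_key]])
  # majority secondary-structure class among residues within 10 A
  d_atom <- dist_to(site$anchor_point, as.matrix(at[, c("x", "y", "z")]))
  d_res <- tapply(d_atom, at$res_key, min)[names(ss)]
  env_cls <- ss[d_res <= 10]
  ss_env <- if (length(env_cls)) {
    tb <- table(factor(env_cls, levels = names(SS_CODE)))
    unname(SS_CODE[names(tb)[which.max(tb)]])
  } else 3L
  # sign of summed formal charge within 10 A (standard states at pH 7),
  # the site's own residue excluded
  pos_n <- count_in_radius(site, structure, "charged_pos_residues", 10)
  neg_n <- count_in_radius(site, structure, "charged_neg_residues", 10)
  v <- c(v, res_type = res_type, ss_site = ss_site, ss_env10 = ss_env,
         charge_sign10 = sign(pos_n - neg_n))

  cat_names <- catalog$entries$name
  stopifnot(identical(sort(names(v)), sort(cat_names)))
  v <- v[cat_names]
  attr(v, "catalog_version") <- catalog$version
  attr(v, "site_key") <- site$res_key
  attr(v, "structure_id") <- structure$source_id
  attr(v, "aa") <- site$aa
  v
}

# residue-level charge carriers at pH 7 (Lys+, Arg+, Asp-, Glu-)
select_atoms_charged <- function(structure, positive) {
  at <- structure$atoms
  if (positive)
    (at$resname == "LYS" & at$name == "NZ") |
      (at$resname == "ARG" & at$name %in% c("NH1", "NH2", "NE"))
  else
    (at$resname == "ASP" & at$name %in% c("OD1", "OD2")) |
      (at$resname == "GLU" & at$name %in% c("OE1", "OE2")) |
      at$name == "OXT"
}

#' Featurize every titratable site of a structure
#'
#' @param structure a `prot_structure`.
#' @param sites optional list of sites; defaults to
#'   [identify_titratable_sites()].
#' @param catalog a [feature_catalog()].
#' @return data.frame with one row per site: `structure_id`, `res_key`,
#'   `aa`, then one column per catalog feature.
#' @export
featurize_structure <- function(structure, sites = NULL,
                                catalog = feature_catalog()) {
  if (is.null(sites)) sites <- identify_titratable_sites(structure)
  sasa_map <- shrake_rupley_sasa(structure)
  ss <- assign_secondary_structure(structure)
  rows <- lapply(sites, function(s) {
    v <- featurize_site(structure, s, catalog, sasa_map = sasa_map, ss = ss)
    cbind(data.frame(structure_id = structure$source_id, res_key = s$res_key,
                     aa = s$aa, stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}
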