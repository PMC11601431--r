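# Seeded synthetic-structure and label generators.
#
# Each synthetic "protein" is a Gly-X-Gly tripeptide (X titratable) whose
# microenvironment is controlled explicitly: single-residue surrogate
# fragments realize planned polar / positive / negative / His neighbours
# at planned anchor distances, and a shell of carbon pseudo-atoms ("cage")
# around the sidechain controls burial. Labels come from a monotone
# ground-truth model whose coefficient signs mirror the physical
# determinants of acid vs base pKa shifts, plus Gaussian noise.

#' Specification of a synthetic site population
#'
#' @param n_sites number of sites (one structure per site).
#' @param aa_mix named probability weights over the six titratable types.
#' @param burial_range range from which per-site burial levels are drawn;
#'   every 5th site is forced to a high burial (>= 0.7) so that a
#'   realistic share (>= 10%) of sites carries a pKa shift above 2 and
#'   exercises the augmentation path.
#' @param polar_range,polar15_range integer ranges for planned polar
#'   neighbours within 10 A and additional ones in the 10-15 A shell.
#' @param pos_range,neg_range,his_range integer ranges for positive,
#'   negative and His neighbours within 10 A.
#' @param noise_sigma label noise standard deviation, pKa units.
#' @param seed master seed; per-site seeds are derived deterministically.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sites = 10L,
                           aa_mix = c(ASP = 1, GLU = 1, HIS = 1, CYS = 1,
                                      TYR = 1, LYS = 1),
                           burial_range = c(0, 1),
                           polar_range = c(0L, 5L),
                           polar15_range = c(0L, 4L),
                           pos_range = c(0L, 2L),
                           neg_range = c(0L, 2L),
                           his_range = c(0L, 1L),
                           noise_sigma = 0.3,
                           seed = 1L) {
  stopifnot(n_sites >= 1, noise_sigma >= 0,
            all(names(aa_mix) %in% TITRATABLE_AA))
  structure(list(n_sites = as.integer(n_sites), aa_mix = aa_mix,
                 burial_range = burial_range, polar_range = polar_range,
                 polar15_range = polar15_range, pos_range = pos_range,
                 neg_range = neg_range, his_range = his_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# neighbour surrogate fragments: local coordinates with the "key" atom
# (the one realizing the planned distance) at the origin and every other
# atom strictly outward along +x, so the key atom is the fragment's
# nearest atom to the site anchor.
FRAGMENTS <- list(
  polar = list(resname = "SER", key = "OG",
               atoms = list(OG = c(0, 0, 0), CB = c(1.30, 0.55, 0),
                            CA = c(2.55, 1.35, 0))),
  negative = list(resname = "GLU", key = "OE1",
                  atoms = list(OE1 = c(0, 0, 0), CD = c(1.10, 0.60, 0),
                               OE2 = c(1.25, 1.85, 0), CG = c(2.45, 0.05, 0.4),
                               CA = c(3.90, 0.60, 0.8))),
  positive = list(resname = "ARG", key = "NH1",
                  atoms = list(NH1 = c(0, 0, 0), CZ = c(1.15, 0.65, 0),
                               NH2 = c(1.30, 1.95, 0), NE = c(2.30, 0.05, 0.4),
                               CD = c(3.60, 0.60, 0.8),
                               CA = c(5.00, 1.10, 1.2))),
  his = list(resname = "HIS", key = "ND1",
             atoms = list(ND1 = c(0, 0, 0), CE1 = c(0.95, 0.95, 0),
                          CG = c(1.30, -0.55, 0.2), NE2 = c(2.25, 0.80, 0.2),
                          CD2 = c(2.45, -0.45, 0.3), CB = c(2.30, -1.95, 0.4),
                          CA = c(3.65, -2.55, 0.8)))
)

site_seed <- function(spec, i) (spec$seed %% 100000L) * 13L + 7919L * i

ri <- function(range) if (range[1] >= range[2]) range[1] else
  sample(seq(range[1], range[2]), 1L)

#' Per-site generation plan (deterministic in spec seed and site index)
#' @keywords internal
site_plan <- function(spec, i) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(site_seed(spec, i))
  aa <- sample(names(spec$aa_mix), 1L, prob = spec$aa_mix)
  burial <- stats::runif(1, spec$burial_range[1], spec$burial_range[2])
  if (i %% 5L == 0L) burial <- max(burial, stats::runif(1, 0.7, 1))
  n_polar <- ri(spec$polar_range)
  n_polar_far <- ri(spec$polar15_range)
  n_pos <- ri(spec$pos_range)
  n_neg <- ri(spec$neg_range)
  n_his <- ri(spec$his_range)
  plan <- list(
    aa = aa, burial = burial,
    polar_d = sort(stats::runif(n_polar, 4.5, 9.5)),
    polar_far_d = sort(stats::runif(n_polar_far, 10.6, 14.4)),
    pos_d = sort(stats::runif(n_pos, 4.5, 9.5)),
    neg_d = sort(stats::runif(n_neg, 4.5, 9.5)),
    his_d = sort(stats::runif(n_his, 4.2, 9.5))
  )
  # counts the featurizer should report (His fragments are both polar and
  # positively classed)
  plan$expect <- list(
    n_polar10 = n_polar + n_his,
    n_polar15 = n_polar + n_his + n_polar_far,
    n_pos10 = n_pos + n_his,
    n_neg10 = n_neg,
    d0_hbond_h = if (n_his) plan$his_d[1] else FEATURE_SENTINEL,
    d0_neg_O = if (n_neg) plan$neg_d[1] else FEATURE_SENTINEL
  )
  plan
}

place_fragment <- function(frag, direction, dist, anchor, resno, chain = "B") {
  R <- rotation_to(direction)
  rows <- lapply(names(frag$atoms), function(nm) {
    p <- anchor + as.numeric(R %*% frag$atoms[[nm]]) + direction * dist
    data.frame(name = nm, element = element_of(nm), resname = frag$resname,
               chain = chain, resno = resno, insert = "",
               x = p[1], y = p[2], z = p[3], occ = 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate one synthetic site structure as PDB text
#'
#' Builds the Gly-X-Gly host peptide, places the planned neighbour
#' fragments clash-free (>= 2.4 A to any existing atom), and adds the
#' burial cage: a fixed candidate shell of carbon pseudo-atoms around the
#' sidechain of which the first `burial * n` clash-free members are kept,
#' making computed burial monotone in the burial level.
#'
#' @param spec a [synthetic_spec()].
#' @param site_index site number in 1..n_sites.
#' @return character vector of PDB lines (attribute `plan` carries the
#'   site plan). Byte-identical for identical spec and index.
#' @export
generate_structure <- function(spec, site_index) {
  plan <- site_plan(spec, site_index)
  base <- build_peptide(c("GLY", plan$aa, "GLY"), phi = -140, psi = 135)
  s <- atoms_to_structure(base)
  site <- identify_titratable_sites(s)[[1]]
  anchor <- site$anchor_point

  cols <- c("name", "element", "resname", "chain", "resno", "insert",
            "x", "y", "z", "occ")
  atoms <- base[, cols]
  # prefer directions pointing away from the host backbone
  dirs <- sphere_points(48L)
  ca <- as.numeric(base[base$name == "CA" & base$resno == 2L, c("x", "y", "z")])
  away <- anchor - ca
  away <- away / sqrt(sum(away^2))
  dirs <- dirs[order(-(dirs %*% away)), , drop = FALSE]

  jobs <- rbind(
    if (length(plan$his_d)) data.frame(kind = "his", d = plan$his_d),
    if (length(plan$neg_d)) data.frame(kind = "negative", d = plan$neg_d),
    if (length(plan$pos_d)) data.frame(kind = "positive", d = plan$pos_d),
    if (length(plan$polar_d)) data.frame(kind = "polar", d = plan$polar_d),
    if (length(plan$polar_far_d)) data.frame(kind = "polar", d = plan$polar_far_d)
  )
  resno <- 100L
  used <- 0L
  if (!is.null(jobs)) for (j in seq_len(nrow(jobs))) {
    frag <- FRAGMENTS[[jobs$kind[j]]]
    placed <- FALSE
    while (used < nrow(dirs)) {
      used <- used + 1L
      cand <- place_fragment(frag, dirs[used, ], jobs$d[j], anchor, resno)
      dmin <- min(dist_mat(as.matrix(cand[, c("x", "y", "z")]),
                           as.matrix(atoms[, c("x", "y", "z")])))
      if (dmin >= 2.4) {
        atoms <- rbind(atoms, cand[, cols])
        resno <- resno + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("infeasible neighbour plan: cannot place %s fragment %d clash-free",
                   jobs$kind[j], j))
  }

  # burial cage around the sidechain centroid
  side <- base[base$resno == 2L & !(base$name %in% c("N", "CA", "C", "O")), ,
               drop = FALSE]
  centroid <- colMeans(as.matrix(side[, c("x", "y", "z")]))
  reach <- max(dist_to(centroid, as.matrix(side[, c("x", "y", "z")])))
  shell <- rbind(sweep(sphere_points(70L) * (reach + 3.6), 2, centroid, "+"),
                 sweep(sphere_points(40L) * (reach + 5.2), 2, centroid, "+"))
  # fixed interleaved order so the first k candidates sample the whole
  # shell uniformly and burial grows gradually with the level
  shell <- shell[order((seq_len(nrow(shell)) * 0.61803398875) %% 1), ,
                 drop = FALSE]
  keep <- rowSums(dist_mat(shell, as.matrix(atoms[, c("x", "y", "z")])) <
                    2.4) == 0L
  shell <- shell[keep, , drop = FALSE]
  n_cage <- round(plan$burial * nrow(shell))
  if (n_cage > 0L) {
    cage <- data.frame(name = "CA", element = "C", resname = "GLY",
                       chain = "C", resno = 500L + seq_len(n_cage) - 1L,
                       insert = "",
                       x = shell[seq_len(n_cage), 1],
                       y = shell[seq_len(n_cage), 2],
                       z = shell[seq_len(n_cage), 3], occ = 1,
                       stringsAsFactors = FALSE)
    atoms <- rbind(atoms, cage[, cols])
  }

  out <- structure_to_pdb_text(atoms_to_structure(atoms,
           source_id = sprintf("syn%04d", site_index)))
  attr(out, "plan") <- plan
  out
}

#' Ground-truth pKa model of the synthetic generator
#'
#' Linear-in-features shift model whose coefficient signs encode the
#' physics: burial and polar crowding protonate acids (shift up) while a
#' nearby His nitrogen deprotonates them; for bases, burial and polar
#' crowding deprotonate (shift down) while a nearby carboxylate oxygen
#' protonates (shift up). Distance terms act through the bounded proximity
#' (20 - d0)/1, zero at the sentinel.
#'
#' @param acid named coefficients `burial`, `polar10`, `hbond_h`.
#' @param base named coefficients `burial`, `polar15`, `neg_O`.
#' @return object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(acid = c(burial = 5.0, polar10 = 0.25,
                                        hbond_h = -0.08),
                               base = c(burial = -4.0, polar15 = -0.20,
                                        neg_O = 0.10)) {
  stopifnot(acid["burial"] > 0, base["polar15"] < 0)
  structure(list(acid = acid, base = base), class = "ground_truth_model")
}

#' Noise-free ground-truth pKa for feature rows
#'
#' @param features data.frame with columns `aa`, `buried_ratio`,
#'   `n_polar10`, `n_polar15`, `d0_hbond_h`, `d0_neg_O` (e.g. from
#'   [featurize_structure()]).
#' @param model a [ground_truth_model()].
#' @return numeric pKa vector, `model_pka(aa)` plus the acid or base shift,
#'   clipped to [0, 16].
#' @export
ground_truth_pka <- function(features, model = ground_truth_model()) {
  aa <- toupper(features$aa)
  acid <- aa %in% ACID_AA
  shift <- ifelse(acid,
    model$acid["burial"] * features$buried_ratio +
      model$acid["polar10"] * features$n_polar10 +
      model$acid["hbond_h"] * (FEATURE_SENTINEL - features$d0_hbond_h),
    model$base["burial"] * features$buried_ratio +
      model$base["polar15"] * features$n_polar15 +
      model$base["neg_O"] * (FEATURE_SENTINEL - features$d0_neg_O))
  pmin(pmax(model_pka(aa) + shift, 0), 16)
}

#' Generate a full synthetic dataset: structures, features and pKa table
#'
#' @param spec a [synthetic_spec()].
#' @param model a [ground_truth_model()].
#' @param catalog a [feature_catalog()].
#' @return list with `structures` (named list of PDB text vectors),
#'   `features` (one row per site, [featurize_structure()] layout),
#'   `table` (a `pka_records` data.frame with labels = ground truth +
#'   N(0, noise_sigma), clipped to [0, 16]), and `truth` (noise-free
#'   labels).
#' @export
generate_dataset <- function(spec, model = ground_truth_model(),
                             catalog = feature_catalog()) {
  structures <- list()
  feats <- list()
  for (i in seq_len(spec$n_sites)) {
    txt <- generate_structure(spec, i)
    id <- sprintf("syn%04d", i)
    structures[[id]] <- txt
    s <- read_structure(txt, source_id = id)
    sites <- identify_titratable_sites(s)
    # the host titratable residue is residue 2 of chain A
    host <- Filter(function(x) x$chain == "A" && x$resno == 2L, sites)[[1]]
    feats[[i]] <- featurize_structure(s, sites = list(host), catalog = catalog)
  }
  features <- do.call(rbind, feats)
  truth <- ground_truth_pka(features, model)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed + 424243L)
  labels <- pmin(pmax(truth + stats::rnorm(spec$n_sites, 0, spec$noise_sigma),
                      0), 16)

  table <- data.frame(
    protein = names(structures), aa = features$aa, resid = 2L, chain = "A",
    mutation = "WT", state = "S1", pka = labels,
    structures = names(structures), stringsAsFactors = FALSE)
  table$unique_key <- paste(table$protein, table$resid, table$mutation,
                            table$state, sep = "|")
  class(table) <- c("pka_records", "data.frame")
  list(structures = structures, features = features, table = table,
       truth = truth)
}

#' Write a pKa record table to CSV
#'
#' @param records a `pka_records` data.frame.
#' @param file output path.
#' @export
write_pkad_table <- function(records, file) {
  cols <- c("protein", "aa", "resid", "chain", "mutation", "state", "pka",
            "structures")
  utils::write.csv(as.data.frame(records)[, cols], file, row.names = FALSE)
  invisible(file)
}

#' Jittered conformers of a structure
#'
#' Adds isotropic Gaussian noise to every heavy-atom coordinate,
#' rejecting draws that bring non-bonded atom pairs (original separation
#' >= 2.0 A; pairs of single-atom occluder pseudo-residues exempt) below
#' 1.6 A. Stands in for alternative structural models of the same residue
#' in augmentation experiments.
#'
#' @param source a `prot_structure` or PDB text/path.
#' @param k number of conformers (<= 10).
#' @param amplitude per-coordinate noise SD in Angstrom (<= 0.5).
#' @param seed RNG seed.
#' @return list of k PDB text vectors (fewer, with a warning, when a
#'   clash-free draw is not found in 100 tries).
#' @export
jitter_conformers <- function(source, k, amplitude = 0.3, seed = 1L) {
  stopifnot(k >= 0, k <= 10, amplitude <= 0.5)
  if (k == 0L) return(list())
  s <- if (inherits(source, "prot_structure")) source else read_structure(source)
  xyz <- atom_coords(s)
  d0 <- dist_mat(xyz, xyz)
  # clash criterion: non-bonded pairs (>= 2 A apart originally) must stay
  # >= 1.6 A. Pairs of single-atom occluder pseudo-residues (burial cage)
  # are not part of the criterion -- they carry no chemistry.
  natoms <- table(s$atoms$res_key)
  single <- natoms[s$atoms$res_key] == 1L
  nonbonded <- d0 >= 2.0 & !outer(single, single, "&")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  out <- list()
  for (i in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      if (amplitude == 0) {
        new <- xyz
      } else {
        new <- xyz + matrix(stats::rnorm(length(xyz), 0, amplitude),
                            ncol = 3L)
      }
      d <- dist_mat(new, new)
      if (all(d[nonbonded] >= 1.6)) { ok <- TRUE; break }
    }
    if (!ok) {
      warning(sprintf("conformer %d: no clash-free draw in 100 tries; returning %d conformer(s)",
                      i, length(out)))
      break
    }
    si <- set_atom_coords(s, new)
    si$source_id <- sprintf("%s_conf%02d", s$source_id, i)
    out[[si$source_id]] <- structure_to_pdb_text(si)
  }
  out
}
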