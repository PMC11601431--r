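# Shared fixtures, all built in code.

# Gly-X-Gly host tripeptide as a parsed structure (round-tripped through
# the PDB writer/reader so tests exercise the real I/O path).
gxg <- function(aa = "ASP", phi = -140, psi = 135) {
  at <- protpka:::build_peptide(c("GLY", aa, "GLY"), phi = phi, psi = psi)
  s <- protpka:::atoms_to_structure(at, source_id = paste0("gxg_", tolower(aa)))
  read_structure(protpka:::structure_to_pdb_text(s),
                 source_id = s$source_id)
}

host_site <- function(structure) {
  sites <- identify_titratable_sites(structure)
  Filter(function(x) x$chain == "A" && x$resno == 2L, sites)[[1]]
}

# single carbon enclosed by an n-atom carbon cage at the given radius
caged_atom <- function(n_cage = 26L, radius = 3.0) {
  pts <- protpka:::sphere_points(n_cage) * radius
  at <- data.frame(
    name = "CA", element = "C", resname = "GLY", chain = "A",
    resno = seq_len(n_cage + 1L), insert = "",
    x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3]), occ = 1,
    stringsAsFactors = FALSE)
  protpka:::atoms_to_structure(at, source_id = "cage")
}

# place a surrogate neighbour fragment near a host structure's site
with_fragment <- function(structure, kind, dist, direction = c(1, 0.2, 0.1),
                          resno = 100L) {
  site <- host_site(structure)
  u <- direction / sqrt(sum(direction^2))
  frag <- protpka:::place_fragment(protpka:::FRAGMENTS[[kind]], u, dist,
                                   site$anchor_point, resno)
  at <- structure$atoms
  cols <- c("name", "element", "resname", "chain", "resno", "insert",
            "x", "y", "z", "occ")
  protpka:::atoms_to_structure(rbind(at[, cols], frag[, cols]),
                               source_id = structure$source_id)
}

# synthetic pKa table with given number of unique keys (no structures)
synthetic_key_table <- function(n_keys, seed = 1L, aa = NULL) {
  set.seed(seed)
  aa <- if (is.null(aa))
    sample(c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS"), n_keys, TRUE)
  else rep_len(aa, n_keys)
  df <- data.frame(
    protein = sprintf("p%04d", seq_len(n_keys)), aa = aa,
    resid = seq_len(n_keys), chain = "A", mutation = "WT", state = "S1",
    pka = pmin(pmax(model_pka(aa) + rnorm(n_keys, 0, 1.8), 0), 16),
    structures = "", stringsAsFactors = FALSE)
  df$unique_key <- paste(df$protein, df$resid, df$mutation, df$state,
                         sep = "|")
  class(df) <- c("pka_records", "data.frame")
  df
}

# a deterministically cached small synthetic dataset shared across tests
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_spec(
        n_sites = 40L, seed = 77L, noise_sigma = 0.2,
        polar_range = c(0L, 3L), polar15_range = c(0L, 2L),
        pos_range = c(0L, 1L), neg_range = c(0L, 1L),
        his_range = c(0L, 1L)))
    cache
  }
})
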