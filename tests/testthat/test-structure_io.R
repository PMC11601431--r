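# PDB reading, titratable-site identification, SASA and secondary
# structure.

test_that("reading a tripeptide recovers residues, anchors and survives a write/read round trip", {
  s <- gxg("ASP")
  res <- structure_residues(s)
  expect_equal(nrow(res), 3L)
  expect_equal(res$resname, c("GLY", "ASP", "GLY"))
  asp <- s$atoms[s$atoms$resno == 2L, ]
  expect_true(all(c("OD1", "OD2") %in% asp$name))

  sites <- identify_titratable_sites(s)
  expect_length(sites, 1L)
  expect_equal(sites[[1]]$aa, "ASP")
  od <- asp[asp$name %in% c("OD1", "OD2"), c("x", "y", "z")]
  expect_equal(unname(sites[[1]]$anchor_point), unname(colMeans(od)),
               tolerance = 1e-6)

  # write-back then re-read is idempotent on retained fields
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  for (col in c("name", "resname", "chain", "resno"))
    expect_identical(s2$atoms[[col]], s$atoms[[col]])
  expect_equal(atom_coords(s2), atom_coords(s), tolerance = 1e-3)
})

test_that("altloc resolves to the highest-occupancy conformer, first on tie", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   9.000   9.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      6  CB AALA A   1       2.000  -1.000   0.500  0.50  0.00           C",
    "ATOM      7  CB BALA A   1       8.000  -8.000   8.500  0.50  0.00           C")
  s <- read_structure(pdb)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.458, tolerance = 1e-3)     # higher occupancy wins
  cb <- s$atoms[s$atoms$name == "CB", ]
  expect_equal(cb$x, 2.0, tolerance = 1e-3)       # first record wins the tie
})

test_that("degenerate inputs raise informative format errors", {
  expect_error(read_structure(c("HEADER junk", "END")), "no ATOM/HETATM")
  expect_error(read_structure("ATOM      1  CA  ALA A   1      bad"),
               "line 1")
  water <- c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O")
  expect_error(read_structure(water), "no protein residues")
})

test_that("hydrogens are dropped and waters land in the ligand table", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  HA  ALA A   1       1.600   1.000   0.000  1.00  0.00           H",
    "ATOM      4  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "HETATM    6  O   HOH A  90       8.000   0.000   0.000  1.00  0.00           O")
  s <- read_structure(pdb)
  expect_false(any(s$atoms$element == "H"))
  expect_equal(nrow(s$ligands), 1L)
  expect_equal(s$ligands$resname, "HOH")
})

test_that("site identification covers exactly the six types and partial anchors", {
  # Ser/Thr only -> no sites
  st <- protpka:::atoms_to_structure(
    protpka:::build_peptide(c("SER", "THR"), phi = -140, psi = 135))
  expect_length(identify_titratable_sites(st), 0L)

  # His with a single anchor atom present: anchor point is that atom
  s <- gxg("HIS")
  keep <- !(s$atoms$resno == 2L & s$atoms$name == "NE2")
  s$atoms <- s$atoms[keep, ]
  site <- identify_titratable_sites(s)[[1]]
  nd1 <- s$atoms[s$atoms$resno == 2L & s$atoms$name == "ND1", c("x", "y", "z")]
  expect_equal(unname(site$anchor_point), as.numeric(nd1), tolerance = 1e-9)

  # all six types with anchors are found, count is exact
  ds <- shared_dataset()
  for (id in names(ds$structures)[1:5]) {
    s <- read_structure(ds$structures[[id]], source_id = id)
    res <- structure_residues(s)
    expected <- sum(res$resname %in% protpka:::TITRATABLE_AA)
    expect_length(identify_titratable_sites(s), expected)
  }
})

test_that("Shrake-Rupley matches the analytic sphere and non-overlap limits", {
  one <- caged_atom(n_cage = 0L)
  one$atoms <- one$atoms[1, ]
  a <- shrake_rupley_sasa(one)
  expect_equal(a[1], 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01 * a[1])

  two <- protpka:::atoms_to_structure(data.frame(
    name = "CA", element = "C", resname = "GLY", chain = "A", resno = 1:2,
    insert = "", x = c(0, 100), y = 0, z = 0, occ = 1))
  a2 <- shrake_rupley_sasa(two)
  expect_equal(as.vector(a2), rep(4 * pi * 3.1^2, 2), tolerance = 1e-6)
})

test_that("a 26-atom cage at 3 A occludes the central atom almost entirely", {
  s <- caged_atom(26L, 3.0)
  a <- shrake_rupley_sasa(s)
  expect_lt(a[1], 0.05 * 4 * pi * 3.1^2)
})

test_that("SASA is rigid-motion invariant and converges with quadrature", {
  s <- gxg("GLU")
  a <- shrake_rupley_sasa(s)
  R <- rotation_matrix("z", 63) %*% rotation_matrix("x", -31)
  s2 <- set_atom_coords(s, rigid_transform(atom_coords(s), R, c(5, -3, 11)))
  a2 <- shrake_rupley_sasa(s2)
  iso <- 4 * pi * 3.1^2
  expect_lt(max(abs(a - a2)), 0.01 * iso)

  a_fine <- shrake_rupley_sasa(s, n_sphere_points = 1920L)
  expect_lt(max(abs(a - a_fine)), 0.02 * iso)
})

test_that("unknown elements fall back to the generic radius with a warning", {
  s <- caged_atom(0L)
  s$atoms <- s$atoms[1, ]
  s$atoms$element <- "X"
  expect_warning(a <- shrake_rupley_sasa(s), "generic")
  expect_equal(a[1], 4 * pi * (1.8 + 1.4)^2, tolerance = 1e-6)
})

test_that("secondary structure separates helix, strand and coil", {
  hx <- protpka:::atoms_to_structure(
    protpka:::build_peptide(rep("ALA", 12), phi = -57, psi = -47))
  cls <- assign_secondary_structure(hx)
  expect_true(all(cls[2:11] == "H"))

  ex <- protpka:::atoms_to_structure(
    protpka:::build_peptide(rep("ALA", 12), phi = -140, psi = 135))
  expect_false(any(assign_secondary_structure(ex) == "H"))

  one <- protpka:::atoms_to_structure(protpka:::build_peptide("ALA"))
  expect_equal(unname(assign_secondary_structure(one)), "C")
})
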