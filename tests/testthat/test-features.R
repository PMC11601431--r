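# Microenvironment features: burial, counts, distances, full vectors.

test_that("model pKa constants cover the six types and reject others", {
  expect_equal(model_pka("ASP"), 3.7)
  expect_equal(model_pka("GLU"), 4.2)
  expect_equal(model_pka("HIS"), 6.5)
  expect_equal(model_pka("CYS"), 8.5)
  expect_equal(model_pka("TYR"), 9.5)
  expect_equal(model_pka("LYS"), 10.4)
  expect_error(model_pka("SER"), "titratable")
})

test_that("buried ratio is ~0 for an isolated extended site and ~1 when caged", {
  s <- gxg("ASP")
  expect_lt(abs(buried_ratio(host_site(s), s)), 0.05)

  sp <- synthetic_spec(n_sites = 1, aa_mix = c(ASP = 1),
                       burial_range = c(1, 1), polar_range = c(0, 0),
                       polar15_range = c(0, 0), pos_range = c(0, 0),
                       neg_range = c(0, 0), his_range = c(0, 0), seed = 3)
  sc <- read_structure(generate_structure(sp, 1))
  expect_gte(buried_ratio(host_site(sc), sc), 0.95)
})

test_that("buried ratio is monotone in cage density and spans the middle range", {
  sp0 <- synthetic_spec(n_sites = 1, aa_mix = c(LYS = 1),
                        polar_range = c(0, 0), polar15_range = c(0, 0),
                        pos_range = c(0, 0), neg_range = c(0, 0),
                        his_range = c(0, 0), seed = 5)
  brs <- vapply(seq(0, 1, by = 0.2), function(b) {
    sp <- sp0
    sp$burial_range <- c(b, b)
    s <- read_structure(generate_structure(sp, 1))
    buried_ratio(host_site(s), s)
  }, numeric(1))
  expect_true(all(diff(brs) >= 0))
  expect_true(any(brs > 0.2 & brs < 0.8))
})

test_that("radius counts use residue-level counting with an inclusive boundary", {
  s <- gxg("ASP")
  expect_equal(count_in_radius(host_site(s), s, "polar", 10), 0L)

  s3 <- s
  for (d in c(5, 8, 9))
    s3 <- with_fragment(s3, "polar", d,
                        direction = c(1, 0.3 * d, 0.1 * d),
                        resno = 100L + d)
  expect_equal(count_in_radius(host_site(s3), s3, "polar", 10), 3L)

  # an atom at exactly the cutoff is included (axis-aligned placement so
  # the distance is exact in floating point)
  sb <- with_fragment(s, "polar", 10.0, direction = c(1, 0, 0))
  expect_equal(count_in_radius(host_site(sb), sb, "polar", 10), 1L)
  expect_equal(count_in_radius(host_site(sb), sb, "polar", 9.99), 0L)
})

test_that("nearest distances honour construction, rank and the sentinel", {
  s <- gxg("ASP")
  expect_equal(nearest_distance(host_site(s), s, "negative_O"), 20.0)

  sh <- with_fragment(s, "his", 4.2, direction = c(0.2, 1, 0.4))
  expect_equal(nearest_distance(host_site(sh), sh, "his_N"), 4.2,
               tolerance = 1e-6)

  # two carboxylate fragments with key oxygens at 3.0 and 4.0 A; the near
  # fragment's second oxygen sits beyond 4.5 A by construction
  sg <- with_fragment(s, "negative", 3.0, direction = c(0.1, -1, 0.2))
  sg <- with_fragment(sg, "negative", 4.0, direction = c(1, 0.8, -0.5),
                      resno = 101L)
  expect_equal(nearest_distance(host_site(sg), sg, "negative_O", rank = 0L),
               3.0, tolerance = 1e-6)
  expect_equal(nearest_distance(host_site(sg), sg, "negative_O", rank = 1L),
               4.0, tolerance = 1e-6)
  expect_equal(nearest_distance(host_site(sg), sg, "negative_O", rank = 5L),
               20.0)
})

test_that("an empty environment yields the baseline feature vector", {
  s <- gxg("ASP")
  v <- featurize_site(s, host_site(s))
  expect_equal(unname(v["model_pka"]), 3.7)
  expect_lt(v["buried_ratio"], 0.05)
  expect_equal(unname(v[c("n_polar10", "n_polar15", "n_pos10", "n_neg10")]),
               rep(0, 4))
  expect_equal(unname(v["d0_neg_O"]), 20.0)
  expect_equal(unname(v["d0_hbond_h"]), 20.0)
})

test_that("feature vectors are rigid-motion invariant at per-group tolerances", {
  ds <- shared_dataset()
  cat <- feature_catalog()
  num_dist <- grep("^d[01]_", cat$entries$name, value = TRUE)
  counts <- grep("^n_", cat$entries$name, value = TRUE)
  for (id in names(ds$structures)[c(2, 9)]) {
    s <- read_structure(ds$structures[[id]], source_id = id)
    v1 <- featurize_site(s, host_site(s))
    R <- rotation_matrix("y", 90) %*% rotation_matrix("z", 17)
    s2 <- set_atom_coords(s, rigid_transform(atom_coords(s), R, c(10, 10, 10)))
    v2 <- featurize_site(s2, host_site(s2))
    expect_equal(v1[counts], v2[counts])                       # exact
    expect_lt(max(abs(v1[num_dist] - v2[num_dist])), 1e-6)     # distances
    expect_lt(abs(v1["buried_ratio"] - v2["buried_ratio"]), 0.01)
    expect_lt(abs(v1["sasa_sidechain"] - v2["sasa_sidechain"]),
              0.01 * 4 * pi * 3.1^2)
    cats <- c("res_type", "ss_site", "ss_env10", "charge_sign10")
    expect_equal(v1[cats], v2[cats])
  }
})

test_that("nested radii and monotone counting hold on generated fixtures", {
  ds <- shared_dataset()
  f <- ds$features
  expect_true(all(f$n_polar10 <= f$n_polar15))
  expect_true(all(f$n_pos10 <= f$n_pos15))
  expect_true(all(f$n_neg10 <= f$n_neg15))
  expect_true(all(f$n_heavy6 <= f$n_heavy8 & f$n_heavy8 <= f$n_heavy10))
  expect_true(all(f$buried_ratio >= 0 & f$buried_ratio <= 1))
  dists <- as.matrix(f[, grep("^d[01]_", names(f))])
  expect_true(all(dists >= 0 & dists <= 20))

  # adding a polar sidechain inside 10 A: count up, polar distance down
  s <- gxg("CYS")
  v0 <- featurize_site(s, host_site(s))
  s1 <- with_fragment(s, "polar", 6.5, direction = c(0.4, 1, 0.1))
  v1 <- featurize_site(s1, host_site(s1))
  expect_gte(v1["n_polar10"], v0["n_polar10"])
  expect_lte(v1["d0_polar"], v0["d0_polar"])
})

test_that("feature vectors conform to the catalog in length, order and version", {
  cat <- feature_catalog()
  s <- gxg("TYR")
  v <- featurize_site(s, host_site(s), cat)
  expect_identical(names(v), cat$entries$name)
  expect_identical(attr(v, "catalog_version"), cat$version)
  expect_error(feature_catalog("no-such-version"), "unsupported")
})
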