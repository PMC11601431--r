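# Tree regressors: degenerate fits, determinism, partition guard,
# protocol mechanics and permutation importance.

fast_cfg <- function(family = "xgb", seed = 1L) {
  grid <- if (family %in% c("xgb", "gbm", "catboost"))
    expand.grid(max_depth = 4L, eta = 0.2, nrounds = 120L)
  else
    expand.grid(mtry_frac = 0.5, min_node = 3L, num_trees = 150L)
  tree_train_config(family, cv_folds = 3L, grid = grid, seed = seed)
}

toy_features <- function(n, seed = 1L, aa = "ASP") {
  set.seed(seed)
  f <- data.frame(matrix(0, n, nrow(feature_catalog()$entries)))
  names(f) <- feature_catalog()$entries$name
  f$model_pka <- model_pka(aa)
  f$res_type <- match(aa, protpka:::TITRATABLE_AA)
  f$buried_ratio <- runif(n)
  f$n_polar10 <- rpois(n, 2)
  f$n_polar15 <- f$n_polar10 + rpois(n, 1)
  f$d0_hbond_h <- runif(n, 3, 20)
  f$d0_neg_O <- runif(n, 3, 20)
  f$ss_site <- sample(1:3, n, TRUE)
  f$ss_env10 <- sample(1:3, n, TRUE)
  f
}

test_that("constant labels give a constant predictor and non-finite labels an error", {
  f <- toy_features(40)
  expect_warning(m <- train_tree(f, rep(4.2, 40), fast_cfg()), "constant")
  expect_equal(predict(m, f[1:5, ]), rep(4.2, 5), tolerance = 1e-6)
  expect_error(train_tree(f, c(rep(4, 39), NA), fast_cfg()), "non-finite")
})

test_that("training is deterministic given the seed, for every model family", {
  f <- toy_features(80)
  y <- 4 + 3 * f$buried_ratio + rnorm(80, 0, 0.1)
  for (fam in c("xgb", "catboost", "gbm", "randomforest", "extratrees")) {
    m1 <- train_tree(f, y, fast_cfg(fam, seed = 7))
    m2 <- train_tree(f, y, fast_cfg(fam, seed = 7))
    expect_equal(predict(m1, f), predict(m2, f), tolerance = 1e-12)
  }
})

test_that("the partition guard refuses rows of the other partition", {
  f <- toy_features(60)
  y <- 3.7 + 2 * f$buried_ratio
  m <- train_tree(f, y, fast_cfg(), partition = "acid")
  lys <- toy_features(3, aa = "LYS")
  expect_error(predict(m, lys), "partition mismatch")
  expect_length(predict(m, f[0, ]), 0L)
})

test_that("a deep tree interpolates noiseless training rows closely", {
  f <- toy_features(120, seed = 3)
  y <- 3.7 + 4 * f$buried_ratio + 0.3 * f$n_polar10
  cfg <- tree_train_config("xgb", cv_folds = 3L,
                           grid = expand.grid(max_depth = 8L, eta = 0.3,
                                              nrounds = 400L))
  m <- train_tree(f, y, cfg)
  expect_lt(max(abs(predict(m, f) - y)), 0.2)
})

test_that("permutation importance finds the generative feature and is null on noise", {
  f <- toy_features(300, seed = 5)
  y <- 3.7 + 5 * f$buried_ratio
  m <- train_tree(f, y, fast_cfg())
  imp <- permutation_importance(m, f, y, n_repeats = 3, seed = 2)
  expect_equal(imp$feature[1], "buried_ratio")

  set.seed(6)
  ynoise <- rnorm(300)
  mn <- train_tree(f, ynoise, fast_cfg())
  impn <- permutation_importance(mn, f, ynoise, n_repeats = 3, seed = 2)
  expect_lt(max(abs(impn$importance)), 0.05 * stats::var(ynoise) * 10)

  imp1 <- permutation_importance(m, f, y, n_repeats = 1, seed = 9)
  expect_equal(imp1$feature[1], imp$feature[1])
})

test_that("the holdout protocol never trains on a test key and augmentation only grows training", {
  ds <- shared_dataset()
  plan <- suppressWarnings(make_splits(ds$table, n_splits = 3, seed = 2))
  cfg <- fast_cfg()
  pp <- run_protocol(ds$table, ds$structures, plan, cfg)
  expect_length(pp, 3L)
  for (s in 1:3) {
    expect_length(intersect(pp[[s]]$unique_key, plan$splits[[s]]$train), 0L)
    expect_setequal(unique(pp[[s]]$unique_key), plan$splits[[s]]$test)
    expect_true(all(is.finite(pp[[s]]$pka_pred)))
  }

  # with conformer augmentation: training rows increase, test rows do not
  shifted <- ds$table$unique_key[abs(ds$table$pka - model_pka(ds$table$aa)) > 2]
  structures <- ds$structures
  conf_map <- list()
  for (k in shifted[1:2]) {
    sid <- ds$table$structures[ds$table$unique_key == k][1]
    confs <- jitter_conformers(read_structure(structures[[sid]],
                                              source_id = sid),
                               2, amplitude = 0.2, seed = 3)
    structures <- c(structures, confs)
    conf_map[[k]] <- names(confs)
  }
  pa <- run_protocol(ds$table, structures, plan, cfg,
                     augmentation = augmentation_policy(),
                     conformer_source = conf_map)
  expect_true(all(attr(pa, "n_train_rows") >= attr(pp, "n_train_rows")))
  expect_gt(sum(attr(pa, "n_train_rows")), sum(attr(pp, "n_train_rows")))
  for (s in 1:3) expect_equal(nrow(pa[[s]]), nrow(pp[[s]]))
})

test_that("the protocol learns most of the noiseless signal at desk scale", {
  sp <- synthetic_spec(n_sites = 60, seed = 55, noise_sigma = 0,
                       aa_mix = c(ASP = 1),
                       polar_range = c(0L, 3L), polar15_range = c(0L, 2L),
                       pos_range = c(0L, 1L), neg_range = c(0L, 1L),
                       his_range = c(0L, 1L))
  ds <- generate_dataset(sp)
  plan <- suppressWarnings(make_splits(ds$table, n_splits = 2,
                                       test_fraction = 0.2, seed = 11))
  pp <- run_protocol(ds$table, ds$structures, plan,
                     tree_train_config("xgb", cv_folds = 3L,
                                       grid = expand.grid(max_depth = 6L,
                                                          eta = 0.2,
                                                          nrounds = 250L)))
  rep <- aggregate_protocol(pp)
  # holdout error well below the label spread: the signal is learned
  expect_lt(rep$regression$mean["rmse"], 0.5 * stats::sd(ds$table$pka))
  expect_gt(rep$regression$mean["pcc"], 0.9)
})
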