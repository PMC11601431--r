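# Acid and base tree regressors and the 20-holdout training protocol.
#
# The boosting/forest cores are delegated to established implementations
# (xgboost, ranger); this module owns the protocol around them: grid
# selection by 10-fold cross-validated MSE on pKa, seeding, the acid/base
# partition guard, leakage-free featurization of (record, structure)
# pairs and permutation importance.

TREE_FAMILIES <- c("catboost", "extratrees", "randomforest", "gbm", "xgb")

#' Training configuration for the pKa tree regressors
#'
#' @param model_family one of `"catboost"`, `"extratrees"`,
#'   `"randomforest"`, `"gbm"`, `"xgb"`. The boosting-style families
#'   (`catboost`, `gbm`, `xgb`) are backed by xgboost presets; the forest
#'   families by ranger (`extratrees` uses the extremely-randomized split
#'   rule). All five share one interface and protocol.
#' @param cv_folds folds for cross-validated grid selection (default 10).
#' @param grid data.frame of candidate hyperparameters; defaults to a
#'   small documented grid (boosting: depth {4,6,8} x learning rate
#'   {0.05,0.1} x rounds {300,600}; forests: mtry fraction {1/3,2/3} x
#'   min node size {3,5}, 500 trees).
#' @param seed seed controlling fold assignment and the fitted model.
#' @return object of class `tree_train_config`.
#' @export
tree_train_config <- function(model_family = "catboost", cv_folds = 10L,
                              grid = NULL, seed = 1L) {
  model_family <- match.arg(model_family, TREE_FAMILIES)
  stopifnot(cv_folds >= 2)
  boosting <- model_family %in% c("catboost", "gbm", "xgb")
  if (is.null(grid)) {
    grid <- if (boosting)
      expand.grid(max_depth = c(4L, 6L, 8L), eta = c(0.05, 0.1),
                  nrounds = c(300L, 600L))
    else
      expand.grid(mtry_frac = c(1 / 3, 2 / 3), min_node = c(3L, 5L),
                  num_trees = 500L)
  }
  structure(list(model_family = model_family, cv_folds = as.integer(cv_folds),
                 grid = grid, boosting = boosting, loss = "mse",
                 seed = as.integer(seed)),
            class = "tree_train_config")
}

feature_cols <- function(features, catalog = feature_catalog()) {
  nm <- catalog$entries$name
  missing <- setdiff(nm, colnames(features))
  if (length(missing))
    stop("feature table does not conform to catalog ", catalog$version,
         ": missing ", paste(missing, collapse = ", "))
  as.matrix(as.data.frame(features)[, nm, drop = FALSE])
}

fit_backend <- function(x, y, config, pars) {
  if (config$boosting) {
    subsample <- if (config$model_family == "catboost") 0.9 else 1.0
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = pars$max_depth, eta = pars$eta,
                    subsample = subsample, colsample_bytree = 1,
                    nthread = 1, seed = config$seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = pars$nrounds, verbose = 0)
  } else {
    df <- as.data.frame(x)
    df$.y <- y
    ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = pars$num_trees,
      mtry = max(1L, floor(pars$mtry_frac * ncol(x))),
      min.node.size = pars$min_node,
      splitrule = if (config$model_family == "extratrees") "extratrees"
                  else "variance",
      num.threads = 1, seed = config$seed)
  }
}

predict_backend <- function(fit, x, config) {
  if (config$boosting)
    as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  else as.numeric(stats::predict(fit, data = as.data.frame(x),
                                 num.threads = 1)$predictions)
}

#' Train a pKa tree regressor under the cross-validation protocol
#'
#' Selects hyperparameters by mean `cv_folds`-fold cross-validated MSE of
#' pKa over the config grid, then refits on all rows. Deterministic given
#' the config seed.
#'
#' @param features feature table conforming to the catalog (e.g. from
#'   [featurize_structure()]); only catalog columns are used.
#' @param labels experimental pKa values, one per row.
#' @param config a [tree_train_config()].
#' @param partition `"acid"`, `"base"`, or NULL; recorded in the model and
#'   enforced at prediction time so an acid model can never score a
#'   His/Lys row.
#' @param catalog the [feature_catalog()] the features conform to.
#' @param split_id optional identifier recorded in the training
#'   fingerprint.
#' @return object of class `pka_tree_model`.
#' @export
train_tree <- function(features, labels, config = tree_train_config(),
                       partition = NULL, catalog = feature_catalog(),
                       split_id = NA) {
  x <- feature_cols(features, catalog)
  labels <- as.numeric(labels)
  if (nrow(x) != length(labels)) stop("features/labels length mismatch")
  if (any(!is.finite(labels))) stop("non-finite labels")
  if (!is.null(partition)) partition <- match.arg(partition, c("acid", "base"))

  base <- list(partition = partition, catalog_version = catalog$version,
               config = config, feature_names = colnames(x),
               fingerprint = list(split_id = split_id, seed = config$seed))
  if (length(unique(labels)) == 1L) {
    warning("single unique label: returning constant predictor")
    return(structure(c(base, list(constant = labels[1], fit = NULL,
                                  best_params = NULL)),
                     class = "pka_tree_model"))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  folds <- sample(rep_len(seq_len(config$cv_folds), nrow(x)))

  cv_mse <- vapply(seq_len(nrow(config$grid)), function(g) {
    pars <- as.list(config$grid[g, , drop = FALSE])
    errs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      if (sum(tr) < 2L || sum(!tr) < 1L) return(NA_real_)
      fit <- fit_backend(x[tr, , drop = FALSE], labels[tr], config, pars)
      mean((predict_backend(fit, x[!tr, , drop = FALSE], config) -
              labels[!tr])^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(cv_mse)
  pars <- as.list(config$grid[best, , drop = FALSE])
  fit <- fit_backend(x, labels, config, pars)
  structure(c(base, list(constant = NULL, fit = fit, best_params = pars,
                         cv_mse = cv_mse)),
            class = "pka_tree_model")
}

#' @export
print.pka_tree_model <- function(x, ...) {
  cat(sprintf("<pka_tree_model %s%s, %d features%s>\n",
              x$config$model_family,
              if (is.null(x$partition)) "" else paste0(" (", x$partition, ")"),
              length(x$feature_names),
              if (!is.null(x$constant)) ", constant" else ""))
  invisible(x)
}

#' Predict pKa values with a trained tree model
#'
#' @param object a `pka_tree_model`.
#' @param features feature table conforming to the model's catalog; when a
#'   partition was recorded, rows of the other partition (by the
#'   `res_type` code) are refused.
#' @param ... unused.
#' @return numeric vector of predicted pKa values (unclipped).
#' @export
predict.pka_tree_model <- function(object, features, ...) {
  if (is.null(dim(features)) || nrow(features) == 0L) return(numeric(0))
  x <- feature_cols(features, feature_catalog(object$catalog_version))
  if (!is.null(object$partition)) {
    codes <- x[, "res_type"]
    allowed <- match(if (object$partition == "acid") ACID_AA else BASE_AA,
                     TITRATABLE_AA)
    if (any(!(codes %in% allowed)))
      stop(sprintf("partition mismatch: %s model asked to score %s rows",
                   object$partition,
                   paste(unique(TITRATABLE_AA[codes[!(codes %in% allowed)]]),
                         collapse = ", ")))
  }
  if (!is.null(object$constant)) return(rep(object$constant, nrow(x)))
  predict_backend(object$fit, x, object$config)
}

#' Permutation importance of the model features
#'
#' Mean increase in MSE when one feature column is permuted, averaged over
#' `n_repeats` seeded permutations; a model-agnostic stand-in for
#' attribution analyses.
#'
#' @param model a `pka_tree_model`.
#' @param features,labels evaluation data.
#' @param n_repeats permutations per feature.
#' @param seed RNG seed.
#' @return data.frame (feature, importance) in decreasing importance;
#'   ties broken by catalog order.
#' @export
permutation_importance <- function(model, features, labels, n_repeats = 5L,
                                   seed = 1L) {
  x <- feature_cols(features, feature_catalog(model$catalog_version))
  if (ncol(x) < 2L) stop("need at least 2 features")
  labels <- as.numeric(labels)
  base_mse <- mean((predict.pka_tree_model(model, x) - labels)^2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(xp)), j]
      mean((predict.pka_tree_model(model, xp) - labels)^2)
    }, numeric(1))) - base_mse
  }, numeric(1))
  out <- data.frame(feature = colnames(x), importance = imp,
                    stringsAsFactors = FALSE)
  out[order(-out$importance, seq_len(ncol(x))), , drop = FALSE]
}

# --- the holdout protocol ---------------------------------------------

parse_structure_source <- function(src, id) {
  if (inherits(src, "prot_structure")) {
    src$source_id <- id
    src
  } else read_structure(src, source_id = id)
}

#' Featurize every (record, structure) pair of a pKa table
#'
#' @param records a `pka_records` data.frame.
#' @param structures named list/map from structure id to a
#'   `prot_structure` or PDB text.
#' @param catalog a [feature_catalog()].
#' @return data.frame: `unique_key`, `structure_id`, `pka_exp`, `row` (the
#'   record row), then the catalog feature columns. One row per (record,
#'   structure) pair; pairs whose structure or site cannot be resolved
#'   raise an error naming the pair.
#' @export
featurize_records <- function(records, structures,
                              catalog = feature_catalog()) {
  parsed <- new.env(parent = emptyenv())
  site_cache <- new.env(parent = emptyenv())
  get_sf <- function(sid) {
    if (is.null(parsed[[sid]])) {
      if (is.null(structures[[sid]]))
        stop("unknown structure id: ", sid)
      s <- parse_structure_source(structures[[sid]], sid)
      parsed[[sid]] <- list(s = s, sasa = shrake_rupley_sasa(s),
                            ss = assign_secondary_structure(s),
                            sites = identify_titratable_sites(s))
    }
    parsed[[sid]]
  }
  refs <- record_structures(records)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    for (sid in refs[[i]]) {
      if (!nzchar(sid)) next
      ck <- paste(sid, records$chain[i], records$resid[i], sep = "\r")
      if (is.null(site_cache[[ck]])) {
        env <- get_sf(sid)
        site <- Filter(function(x) x$chain == records$chain[i] &&
                         x$resno == records$resid[i], env$sites)
        if (length(site) == 0L)
          stop(sprintf("no titratable site %s/%s in structure %s",
                       records$chain[i], records$resid[i], sid))
        site_cache[[ck]] <- featurize_site(env$s, site[[1]], catalog,
                                           sasa_map = env$sasa, ss = env$ss)
      }
      v <- site_cache[[ck]]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(unique_key = records$unique_key[i], structure_id = sid,
                   aa = records$aa[i], pka_exp = records$pka[i], row = i,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(v)))
    }
  }
  do.call(rbind, rows)
}

#' Run the multi-holdout acid/base training protocol
#'
#' For each split of the plan: featurize, partition into acid and base,
#' train one tree model per partition on the training keys (optionally
#' conformer-augmented), and predict every (record, structure) test pair.
#' Test keys are never featurized into training and never augmented.
#'
#' @param records a `pka_records` data.frame.
#' @param structures named map from structure id to `prot_structure` or
#'   PDB text, covering all referenced ids (including conformers).
#' @param split_plan a [make_splits()] plan over the records.
#' @param config a [tree_train_config()].
#' @param catalog a [feature_catalog()].
#' @param augmentation optional [augmentation_policy()].
#' @param conformer_source conformer map/function for
#'   [augment_training()]; required when `augmentation` is given.
#' @return object of class `protocol_predictions`: list of per-split
#'   data.frames (split, unique_key, structure_id, aa, partition,
#'   pka_exp, pka_pred) plus attributes with training row counts.
#' @export
run_protocol <- function(records, structures, split_plan,
                         config = tree_train_config(),
                         catalog = feature_catalog(),
                         augmentation = NULL, conformer_source = NULL) {
  feats <- featurize_records(records, structures, catalog)
  aug_feats <- NULL
  if (!is.null(augmentation)) {
    if (is.null(conformer_source))
      stop("augmentation policy given without a conformer source")
    # featurize all candidate conformer rows once; each split reuses the
    # ones whose key landed in its training side
    aug_all <- augment_training(records, conformer_source, augmentation)
    aug_all <- aug_all[aug_all$augmented, , drop = FALSE]
    if (nrow(aug_all))
      aug_feats <- featurize_records(aug_all, structures, catalog)
  }
  out <- vector("list", split_plan$n_splits)
  n_train_rows <- integer(split_plan$n_splits)
  for (s in seq_len(split_plan$n_splits)) {
    sp <- split_plan$splits[[s]]
    train_feats <- feats[feats$unique_key %in% sp$train, , drop = FALSE]
    if (!is.null(aug_feats))
      train_feats <- rbind(train_feats,
                           aug_feats[aug_feats$unique_key %in% sp$train, ,
                                     drop = FALSE])
    test_feats <- feats[feats$unique_key %in% sp$test, , drop = FALSE]
    n_train_rows[s] <- nrow(train_feats)

    preds <- test_feats[, c("unique_key", "structure_id", "aa", "pka_exp")]
    preds$split <- s
    preds$partition <- ifelse(preds$aa %in% ACID_AA, "acid", "base")
    preds$pka_pred <- NA_real_
    for (part in c("acid", "base")) {
      aa_set <- if (part == "acid") ACID_AA else BASE_AA
      tr <- train_feats[train_feats$aa %in% aa_set, , drop = FALSE]
      te <- preds$partition == part
      if (!any(te)) next
      if (nrow(tr) < 2L)
        stop(sprintf("split %d: too few %s training rows", s, part))
      cfg <- config
      cfg$seed <- config$seed + s
      model <- train_tree(tr, tr$pka_exp, cfg, partition = part,
                          catalog = catalog, split_id = s)
      preds$pka_pred[te] <-
        predict.pka_tree_model(model, test_feats[te, , drop = FALSE])
    }
    out[[s]] <- preds
  }
  structure(out, class = "protocol_predictions",
            n_train_rows = n_train_rows)
}
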