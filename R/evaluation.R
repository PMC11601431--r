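# Regression and protonation-state classification metrics under the
# multi-holdout protocol.
#
# Regression metrics (PCC, RMSE, MAXE) are computed per split and
# averaged; classification metrics are pooled: all predictions from all
# holdout sets are accumulated into one confusion table before precision,
# recall and the critical error rate are computed. The two orders are not
# interchangeable and the package fixes them as stated.

#' Regression metrics: PCC, RMSE, MAXE
#'
#' @param pred,true equal-length numeric vectors.
#' @return object of class `regression_metrics`: `pcc` (Pearson
#'   correlation; NA with `pcc_undefined = TRUE` when either side has zero
#'   variance or n < 2), `rmse`, `maxe` (maximum absolute error), `n`.
#' @export
regression_metrics <- function(pred, true) {
  if (length(pred) != length(true)) stop("pred/true length mismatch")
  ok <- !is.na(pred) & !is.na(true)
  pred <- pred[ok]; true <- true[ok]
  n <- length(pred)
  undef <- n < 2L || stats::sd(pred) == 0 || stats::sd(true) == 0
  pcc <- if (undef) NA_real_ else stats::cor(pred, true)
  structure(list(pcc = pcc, pcc_undefined = undef,
                 rmse = sqrt(mean((pred - true)^2)),
                 maxe = if (n) max(abs(pred - true)) else NA_real_,
                 n = n),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("PCC %s  RMSE %.3f  MAXE %.3f  (n = %d)\n",
              if (x$pcc_undefined) "undef" else sprintf("%.3f", x$pcc),
              x$rmse, x$maxe, x$n))
  invisible(x)
}

#' Protonation-state classification report with critical error rate
#'
#' Both columns are discretized with [classify_pka()]; an instance is
#' scored only when *both* its experimental and its predicted class are
#' non-titrating (titrating experimental pKa's are outside the analysis by
#' design, and a titrating prediction makes no protonated/deprotonated
#' claim to score). Missing predictions (NA) are excluded and counted.
#' The critical error rate (CER) is the fraction of scored instances
#' where a protonated residue is predicted deprotonated or vice versa --
#' the most consequential misclassification. Metrics whose denominator is
#' empty (e.g. precision of a never-predicted class) are NA, never 0.
#'
#' @param pred_pka,true_pka equal-length numeric vectors of predicted and
#'   experimental pKa values.
#' @param boundaries a [class_boundaries()].
#' @return object of class `classification_report`: `precision` and
#'   `recall` (named vectors over protonated/deprotonated),
#'   `cer_numerator`, `cer_denominator`, `cer`, `excluded_titrating`,
#'   `missing`, `n_total`, and the full 3x3 `confusion` table
#'   (experimental x predicted).
#' @export
classification_report <- function(pred_pka, true_pka,
                                  boundaries = class_boundaries()) {
  if (length(pred_pka) != length(true_pka))
    stop("pred/true length mismatch")
  n_total <- length(pred_pka)
  missing <- is.na(pred_pka) | is.na(true_pka)
  pc <- classify_pka(pred_pka[!missing], boundaries)
  tc <- classify_pka(true_pka[!missing], boundaries)
  lv <- c("protonated", "deprotonated", "titrating")
  confusion <- table(experimental = factor(tc, lv),
                     predicted = factor(pc, lv))
  scored <- pc != "titrating" & tc != "titrating"
  excluded_titrating <- sum(!scored)
  pcs <- pc[scored]; tcs <- tc[scored]
  prf <- function(cls) {
    pre <- if (sum(pcs == cls) == 0L) NA_real_
           else sum(pcs == cls & tcs == cls) / sum(pcs == cls)
    rec <- if (sum(tcs == cls) == 0L) NA_real_
           else sum(pcs == cls & tcs == cls) / sum(tcs == cls)
    c(pre, rec)
  }
  pp <- prf("protonated"); dd <- prf("deprotonated")
  cer_num <- sum(tcs == "protonated" & pcs == "deprotonated") +
    sum(tcs == "deprotonated" & pcs == "protonated")
  cer_den <- length(pcs)
  structure(list(
    precision = c(protonated = pp[1], deprotonated = dd[1]),
    recall = c(protonated = pp[2], deprotonated = dd[2]),
    cer_numerator = cer_num, cer_denominator = cer_den,
    cer = if (cer_den) cer_num / cer_den else NA_real_,
    excluded_titrating = excluded_titrating, missing = sum(missing),
    n_total = n_total, confusion = confusion,
    exclusion_rule = "scored iff both experimental and predicted class non-titrating"
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undef", sprintf("%.2f", v))
  cat(sprintf("Pre (prot) %s  Rec (prot) %s\nPre (dep)  %s  Rec (dep)  %s\nCER %d/%d  (excluded titrating %d, missing %d)\n",
              fmt(x$precision["protonated"]), fmt(x$recall["protonated"]),
              fmt(x$precision["deprotonated"]), fmt(x$recall["deprotonated"]),
              x$cer_numerator, x$cer_denominator, x$excluded_titrating,
              x$missing))
  invisible(x)
}

as_prediction_frame <- function(predictions) {
  if (inherits(predictions, "protocol_predictions") ||
      (is.list(predictions) && !is.data.frame(predictions)))
    predictions <- do.call(rbind, predictions)
  stopifnot(all(c("split", "pka_exp", "pka_pred") %in% names(predictions)))
  predictions
}

#' Aggregate per-split predictions into a full evaluation report
#'
#' Regression metrics are computed within each split and summarized as
#' mean and SD (n - 1 denominator) over splits; classification metrics
#' are pooled over all splits' predictions first. Per-amino-acid slices
#' follow the same two rules.
#'
#' @param predictions a `protocol_predictions` object, a list of per-split
#'   prediction data.frames, or one data.frame with a `split` column
#'   (columns: split, aa, pka_exp, pka_pred).
#' @param boundaries a [class_boundaries()].
#' @return object of class `eval_report`: `per_split` (one
#'   [regression_metrics()] row per split), `regression` (mean/sd of
#'   pcc, rmse, maxe), `classification` (pooled
#'   [classification_report()]), `per_aa` (the same pair per amino acid),
#'   `n_splits`.
#' @export
aggregate_protocol <- function(predictions,
                               boundaries = class_boundaries()) {
  df <- as_prediction_frame(predictions)
  splits <- sort(unique(df$split))
  per_split_of <- function(d) {
    rows <- lapply(splits, function(s) {
      dd <- d[d$split == s, , drop = FALSE]
      if (nrow(dd) == 0L) return(NULL)
      m <- regression_metrics(dd$pka_pred, dd$pka_exp)
      data.frame(split = s, pcc = m$pcc, rmse = m$rmse, maxe = m$maxe,
                 n = m$n)
    })
    do.call(rbind, rows)
  }
  summarize <- function(ps) {
    if (is.null(ps)) return(NULL)
    list(mean = c(pcc = mean(ps$pcc, na.rm = TRUE), rmse = mean(ps$rmse),
                  maxe = mean(ps$maxe)),
         sd = c(pcc = stats::sd(ps$pcc), rmse = stats::sd(ps$rmse),
                maxe = stats::sd(ps$maxe)))
  }
  per_split <- per_split_of(df)
  per_aa <- lapply(stats::setNames(nm = sort(unique(df$aa))), function(a) {
    d <- df[df$aa == a, , drop = FALSE]
    ps <- per_split_of(d)
    list(per_split = ps, regression = summarize(ps),
         classification = classification_report(d$pka_pred, d$pka_exp,
                                                boundaries))
  })
  structure(list(
    per_split = per_split, regression = summarize(per_split),
    classification = classification_report(df$pka_pred, df$pka_exp,
                                           boundaries),
    per_aa = per_aa, n_splits = length(splits), boundaries = boundaries
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  r <- x$regression
  cat(sprintf("== %d holdout splits ==\nPCC  %.3f +/- %.3f\nRMSE %.3f +/- %.3f\nMAXE %.3f +/- %.3f\n",
              x$n_splits, r$mean["pcc"], r$sd["pcc"], r$mean["rmse"],
              r$sd["rmse"], r$mean["maxe"], r$sd["maxe"]))
  cat("-- pooled protonation-state classification --\n")
  print(x$classification)
  invisible(x)
}

#' Side-by-side evaluation of several predictors against one truth table
#'
#' @param tables named list of prediction data.frames, each with columns
#'   `unique_key`, `structure_id`, `pka_pred` (external predictors may be
#'   missing rows).
#' @param truth data.frame with `unique_key`, `structure_id`, `aa`,
#'   `pka_exp` (and optionally `split`; absent, a single pooled split is
#'   assumed).
#' @param boundaries a [class_boundaries()].
#' @return named list of class `predictor_comparison`: per predictor a
#'   list with `regression` ([regression_metrics()]), `classification`
#'   ([classification_report()]) and `n_missing` (truth rows the
#'   predictor did not cover). A predictor sharing no instance with the
#'   truth is an error.
#' @export
compare_predictors <- function(tables, truth,
                               boundaries = class_boundaries()) {
  stopifnot(length(names(tables)) == length(tables))
  key <- function(d) paste(d$unique_key, d$structure_id, sep = "\r")
  tk <- key(truth)
  out <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    idx <- match(tk, key(tb))
    if (all(is.na(idx)))
      stop("predictor ", nm, " shares no instance with the truth table")
    pred <- tb$pka_pred[idx]
    list(regression = regression_metrics(pred[!is.na(idx)],
                                         truth$pka_exp[!is.na(idx)]),
         classification = classification_report(pred, truth$pka_exp,
                                                boundaries),
         n_missing = sum(is.na(idx)))
  })
  names(out) <- names(tables)
  class(out) <- "predictor_comparison"
  out
}

#' @export
print.predictor_comparison <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, sprintf("(missing %d) ==\n", x[[nm]]$n_missing))
    print(x[[nm]]$regression)
    print(x[[nm]]$classification)
  }
  invisible(x)
}
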