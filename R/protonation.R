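# Henderson-Hasselbalch protonation fractions and three-class
# protonation-state discretization.

#' Protonation probability of a single independent site
#'
#' Henderson-Hasselbalch form: 1 / (1 + 10^(pH - pKa)). Strictly
#' increasing in pKa, strictly decreasing in pH.
#'
#' @param pka,ph numeric (vectorised).
#' @return fraction in (0, 1).
#' @export
protonation_fraction <- function(pka, ph = 7.0) {
  stopifnot(all(is.finite(pka)), all(is.finite(ph)))
  1 / (1 + 10^(ph - pka))
}

#' pKa boundaries of the three protonation classes
#'
#' At probability threshold t the class boundaries are
#' pH -/+ log10(t / (1 - t)); at pH 7 and t = 0.75 these are 6.52 and 7.48
#' (to two decimals). Classification uses the full-precision values;
#' the two-decimal figures are display roundings.
#'
#' @param ph pH of interest.
#' @param prob_threshold protonation-probability threshold in (0.5, 1).
#' @return object of class `class_boundaries` with fields `ph`,
#'   `prob_threshold`, `lo`, `hi`.
#' @export
class_boundaries <- function(ph = 7.0, prob_threshold = 0.75) {
  stopifnot(prob_threshold > 0.5, prob_threshold < 1)
  w <- log10(prob_threshold / (1 - prob_threshold))
  structure(list(ph = ph, prob_threshold = prob_threshold,
                 lo = ph - w, hi = ph + w),
            class = "class_boundaries")
}

#' @export
print.class_boundaries <- function(x, ...) {
  cat(sprintf("<class_boundaries pH %.2f, Prob > %.2f: protonated pKa > %.2f, deprotonated pKa < %.2f, titrating in between>\n",
              x$ph, x$prob_threshold, x$hi, x$lo))
  invisible(x)
}

#' Classify a pKa into protonated / deprotonated / titrating
#'
#' A residue whose pKa is far above the pH is predominantly protonated
#' (protonation probability above the threshold), far below predominantly
#' deprotonated; the band in between, boundaries included, is titrating.
#'
#' @param pka numeric vector of pKa values.
#' @param boundaries a [class_boundaries()] object.
#' @return character vector in {"protonated", "deprotonated", "titrating"};
#'   NA inputs give NA.
#' @export
classify_pka <- function(pka, boundaries = class_boundaries()) {
  out <- rep(NA_character_, length(pka))
  ok <- !is.na(pka)
  out[ok & pka > boundaries$hi] <- "protonated"
  out[ok & pka < boundaries$lo] <- "deprotonated"
  out[ok & is.na(out)] <- "titrating"
  out
}

#' Null-model pKa prediction
#'
#' Baseline predictor returning the model (solution) pKa of the residue
#' type, regardless of environment.
#'
#' @param aa 3-letter code(s) of titratable residues.
#' @return numeric pKa value(s).
#' @export
null_predict <- function(aa) model_pka(aa)
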