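## Bias correction of raw age predictions and the Brain Age Index.
##
## Raw brain-age predictions regress toward the training mean; the corrected
## age removes the fitted linear trend of predicted-on-chronological age and
## adds the fit cohort's MAE as a constant offset:
##   corrected = predicted + [Omega - (alpha*Omega + beta)] + MAE
## The Brain Age Index normalizes the corrected deviation by scale:
##   BAI = (corrected - Omega) / (corrected + Omega),  bounded in (-1, 1).

#' Fit the linear age-bias correction on a reference cohort
#'
#' Ordinary least squares of predicted on chronological age gives the slope
#' `alpha` and intercept `beta`; the MAE term is the mean absolute error on
#' the same fit cohort, frozen at fit time so the correction is a fixed
#' transform at inference.
#'
#' @param predicted raw model outputs (years).
#' @param chronological chronological ages (years), not all equal.
#' @param fitCohortId provenance label stored with the fit.
#' @return a [BiasCorrection].
#' @export
fitBiasCorrection <- function(predicted, chronological,
                              fitCohortId = "healthy_train") {
  if (length(predicted) != length(chronological) || length(predicted) < 3L)
    stop("need at least 3 paired predictions")
  if (var(chronological) == 0)
    stop("chronological ages have zero variance; cannot fit bias correction")
  fit <- lm(predicted ~ chronological)
  new("BiasCorrection",
      alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]),
      maeTerm = mean(abs(predicted - chronological)),
      fitCohortId = fitCohortId)
}

#' Bias-corrected predicted age
#'
#' `corrected = predicted + [Omega - (alpha*Omega + beta)] + MAE`. On the
#' noiseless fit cohort (predicted exactly `alpha*Omega + beta`) the
#' corrected gap `corrected - Omega` is the constant MAE term for every
#' subject: the age dependence of the raw gap is removed exactly.
#'
#' @param predicted raw model output (years).
#' @param omega chronological age (years, > 0).
#' @param correction a [BiasCorrection].
#' @param includeMae include the constant MAE term (the formula as printed);
#'   set `FALSE` for the purely linear correction.
#' @return corrected predicted age (years); vectorized.
#' @export
correctedAge <- function(predicted, omega, correction, includeMae = TRUE) {
  stopifnot(is(correction, "BiasCorrection"))
  if (any(omega <= 0)) stop("chronological age must be positive")
  predicted + (omega - (correction@alpha * omega + correction@beta)) +
    if (includeMae) correction@maeTerm else 0
}

#' Brain Age Index
#'
#' `BAI = (corrected - Omega) / (corrected + Omega)`: the normalized,
#' scale-free deviation of corrected brain age from chronological age,
#' strictly inside (-1, 1) for positive inputs, with sign matching
#' `corrected - Omega` and invariant to rescaling both ages by any c > 0.
#'
#' @param corrected corrected predicted age (years).
#' @param omega chronological age (years); `corrected + omega` must be > 0.
#' @return dimensionless index; vectorized.
#' @export
brainAgeIndex <- function(corrected, omega) {
  if (any(corrected + omega <= 0))
    stop("degenerate corrected age: corrected + omega must be positive")
  (corrected - omega) / (corrected + omega)
}

#' Full prediction table: raw, corrected and BAI per subject
#'
#' @param ids subject identifiers.
#' @param predicted raw predictions (years).
#' @param omega chronological ages (years).
#' @param correction a [BiasCorrection].
#' @param includeMae see [correctedAge()].
#' @return data.frame with id, age, predicted, corrected, bai.
#' @export
agePredictionTable <- function(ids, predicted, omega, correction,
                               includeMae = TRUE) {
  corr <- correctedAge(predicted, omega, correction, includeMae)
  data.frame(id = ids, age = omega, predicted = predicted,
             corrected = corr, bai = brainAgeIndex(corr, omega),
             stringsAsFactors = FALSE)
}
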