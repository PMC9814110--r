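#' Root-mean-squared error between predicted and reference EC3 values
#'
#' Computed on the raw percent-concentration scale (the scale on which the
#' predicted and in vivo EC3 values are reported); see [ann_benchmark()] for
#' the log10-scale model benchmark.
#'
#' @param predicted,reference Numeric vectors of equal, non-zero length.
#' @return `sqrt(mean((predicted - reference)^2))`.
#' @examples
#' rmse(c(1), c(3))  # 2
#' @export
rmse <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) == 0L)
    stop("predicted and reference must have equal non-zero length",
         call. = FALSE)
  sqrt(mean((predicted - reference)^2))
}

#' Mean absolute error between predicted and reference EC3 values
#'
#' @inheritParams rmse
#' @return `mean(abs(predicted - reference))`.
#' @export
mae <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) == 0L)
    stop("predicted and reference must have equal non-zero length",
         call. = FALSE)
  mean(abs(predicted - reference))
}

#' Convert an LLNA EC3 percent concentration to dose per skin area
#'
#' In the LLNA, 25 uL of test solution is applied to a mouse ear of about
#' 1 cm2; a concentration of x% w/v is x * 10 ug/uL, so the applied dose per
#' area is `ec3 * 250` ug/cm2. Dose per area is the preferred point-of-
#' departure metric for skin-sensitization risk assessment. The conversion is
#' exact; reporting conventionally rounds to 2 significant figures (e.g.
#' 0.83% -> 207.5 -> 210 ug/cm2).
#'
#' @param ec3 EC3 in percent (non-negative).
#' @return Dose per skin area in ug/cm2.
#' @examples
#' ec3_to_dose_per_area(0.83)            # 207.5
#' signif(ec3_to_dose_per_area(0.83), 2) # 210
#' @export
ec3_to_dose_per_area <- function(ec3) {
  if (any(!is.finite(ec3)) || any(ec3 < 0))
    stop("EC3 must be non-negative", call. = FALSE)
  ec3 * 250
}

#' Ratio of a point of departure to a published NESIL
#'
#' Fold difference between a dose-per-area point of departure and a
#' no-expected-sensitization-induction level (NESIL).
#'
#' @param dose_per_area Point of departure in ug/cm2.
#' @param nesil NESIL in ug/cm2 (positive).
#' @return `dose_per_area / nesil`.
#' @examples
#' nesil_ratio(210, 15)  # 14
#' @export
nesil_ratio <- function(dose_per_area, nesil) {
  if (any(!is.finite(nesil)) || any(nesil <= 0))
    stop("NESIL must be positive", call. = FALSE)
  dose_per_area / nesil
}

#' h-CLAT potency category from the minimum induction threshold
#'
#' Sequential-testing-strategy categorization: substances with a minimum
#' induction threshold of 10 ug/mL or less are categorized as strong
#' sensitizers, above 10 ug/mL as weak.
#'
#' @param mit Minimum induction threshold in ug/mL (positive).
#' @return `"strong"` or `"weak"` (vectorized).
#' @examples
#' hclat_potency_category(c(0.92, 11.6))  # strong, weak
#' @export
hclat_potency_category <- function(mit) {
  if (any(!is.finite(mit)) || any(mit <= 0))
    stop("MIT must be positive", call. = FALSE)
  ifelse(mit <= 10, "strong", "weak")
}

#' Concordance of predicted and reference potency classes
#'
#' Pairwise agreement of classification calls (e.g. GHS 1A/1B/NC) over the
#' chemicals shared by both maps. Over-classification means the prediction
#' assigns a more potent class than the reference (1A vs 1B, or a class vs
#' NC); under-classification the converse. Chemicals present in the
#' predictions but lacking a reference are listed separately, not counted.
#'
#' @param pred_classes,ref_classes Named character vectors mapping chemical
#'   to class (`"1A"`, `"1B"`, `"NC"`).
#' @return List of class `"concordance"`: `n`, `agreement` (count),
#'   `proportion`, `over_classified`, `under_classified` (chemical names),
#'   `no_reference` (chemicals without a reference class).
#' @export
concordance <- function(pred_classes, ref_classes) {
  ref_classes <- ref_classes[!is.na(ref_classes)]
  shared <- intersect(names(pred_classes), names(ref_classes))
  if (length(shared) == 0L)
    stop("no chemicals shared between predictions and references",
         call. = FALSE)
  sev <- c("1A" = 2L, "1B" = 1L, "NC" = 0L)
  p <- pred_classes[shared]; r <- ref_classes[shared]
  agree <- p == r
  structure(list(
    n = length(shared),
    agreement = sum(agree),
    proportion = mean(agree),
    over_classified = shared[sev[p] > sev[r]],
    under_classified = shared[sev[p] < sev[r]],
    no_reference = setdiff(names(pred_classes), names(ref_classes))),
    class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Potency-class concordance: %d/%d (%.0f%%)\n",
              x$agreement, x$n, 100 * x$proportion))
  if (length(x$over_classified))
    cat("  over-classified: ", paste(x$over_classified, collapse = ", "), "\n")
  if (length(x$under_classified))
    cat("  under-classified:", paste(x$under_classified, collapse = ", "), "\n")
  if (length(x$no_reference))
    cat("  no reference:    ", paste(x$no_reference, collapse = ", "), "\n")
  invisible(x)
}
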