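#' Acceptability checklist attributes for an LLNA study
#'
#' Names of the study-design attributes every reference LLNA study must
#' satisfy: topical application to both ears, proliferation measured in the
#' draining nodes during the induction phase, a vehicle control, available
#' concentration/stimulation-index data, in vivo (not ex vivo) radiolabel
#' administration, no sodium lauryl sulfate enhancement, and 3-4 days of
#' chemical application.
#'
#' @return Character vector of flag names.
#' @export
llna_checklist_flags <- function() {
  c("topical_both_ears", "draining_node_proliferation", "induction_phase",
    "vehicle_control", "concentration_si_available", "in_vivo_radiolabel",
    "no_sls", "application_3_4_days")
}

#' A single LLNA dose-response study
#'
#' @param chemical Chemical identifier.
#' @param concentration Tested concentrations, percent w/v in `(0, 100]`,
#'   strictly increasing.
#' @param si Stimulation index at each concentration (proliferation relative
#'   to the vehicle control), non-negative.
#' @param vehicle Vehicle string (e.g. `"AOO"` for acetone:olive oil 4:1).
#' @param flags Named logical vector over [llna_checklist_flags()]; missing
#'   names default to `TRUE`, `NA` counts as a failure at screening.
#' @param source Free-text provenance.
#' @param study_id Study identifier.
#' @return An object of class `"llna_study"`.
#' @export
llna_study <- function(chemical, concentration, si, vehicle = "AOO",
                       flags = NULL, source = "", study_id = NA_character_) {
  if (any(concentration > 100))
    stop("LLNA concentrations are percent w/v and cannot exceed 100",
         call. = FALSE)
  if (any(si < 0)) stop("stimulation indices must be non-negative",
                        call. = FALSE)
  series <- dose_response(concentration, si, unit = "pct",
                          kind = "stimulation_index")
  all_flags <- stats::setNames(rep(TRUE, length(llna_checklist_flags())),
                               llna_checklist_flags())
  if (!is.null(flags)) {
    bad <- setdiff(names(flags), llna_checklist_flags())
    if (length(bad))
      stop("unknown checklist flags: ", paste(bad, collapse = ", "),
           call. = FALSE)
    all_flags[names(flags)] <- flags
  }
  structure(list(chemical = chemical, vehicle = vehicle, series = series,
                 flags = all_flags, source = source, study_id = study_id),
            class = "llna_study")
}

#' Screen an LLNA study against the acceptability checklist
#'
#' @param study An [llna_study].
#' @return List with `accepted` (all flags `TRUE`) and `reasons` (names of
#'   failed or missing flags).
#' @export
checklist_screen <- function(study) {
  stopifnot(inherits(study, "llna_study"))
  f <- study$flags
  failed <- names(f)[is.na(f) | !f]
  list(accepted = length(failed) == 0L, reasons = failed)
}

.ec3_estimate <- function(value, method, negative = FALSE,
                          reasons = character()) {
  structure(list(value = value, method = method, negative = negative,
                 accepted = length(reasons) == 0L && !negative,
                 rejection_reasons = reasons),
            class = "ec3_estimate")
}

#' EC3 from a single LLNA study
#'
#' EC3 is the concentration estimated to produce a stimulation index (SI) of
#' 3, the threshold positive response of the local lymph node assay. When
#' SI = 3 is bracketed by tested concentrations the estimate is a linear
#' interpolation (in arithmetic concentration, the conventional LLNA scale)
#' between the lowest bracketing pair. When the whole curve sits below SI 3
#' but trends upward, EC3 is extrapolated above the tested range from the two
#' highest points; when already above SI 3 at the lowest tested
#' concentration, it is extrapolated below the range from the two lowest
#' points. Extrapolated estimates must subsequently pass [ryan_screen()]. A
#' flat or downward series with all SI below 3 is a negative call.
#'
#' @param series [dose_response] of stimulation indices (or an [llna_study]).
#' @param scale Interpolation scale, `"linear"` (default) or `"log"` in
#'   concentration, for sensitivity analysis.
#' @return An object of class `"ec3_estimate"`: list with `value` (percent,
#'   `NA` for a negative call), `method` (`"interpolated"`/`"extrapolated"`/
#'   `"negative"`), `negative`, `accepted`, `rejection_reasons`.
#' @examples
#' s <- dose_response(c(0.1, 0.3), c(2, 5), unit = "pct",
#'                    kind = "stimulation_index")
#' ec3_from_study(s)$value  # 0.1667
#' @export
ec3_from_study <- function(series, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (inherits(series, "llna_study")) series <- series$series
  if (!inherits(series, "dose_response") ||
      series$kind != "stimulation_index")
    stop("series must be a stimulation-index dose_response", call. = FALSE)
  conc <- series$concentration
  si <- series$response
  if (length(conc) < 2L)
    return(.ec3_estimate(NA_real_, "negative", TRUE, "no_data"))

  x <- if (scale == "log") log10(conc) else conc
  back <- function(v) if (scale == "log") 10^v else v

  if (si[1L] >= 3) {
    if (si[1L] == 3) return(.ec3_estimate(conc[1L], "interpolated"))
    # below tested range: extend the line through the two lowest points
    slope <- (si[2L] - si[1L]) / (x[2L] - x[1L])
    if (!is.finite(slope) || slope <= 0)
      return(.ec3_estimate(NA_real_, "negative", TRUE, "no_data"))
    val <- back(x[1L] + (3 - si[1L]) / slope)
    if (!is.finite(val) || val <= 0)
      return(.ec3_estimate(NA_real_, "negative", TRUE, "no_data"))
    return(.ec3_estimate(val, "extrapolated"))
  }

  cross <- crossing_concentration(series, 3, "up", scale)
  if (!is.na(cross)) return(.ec3_estimate(cross, "interpolated"))

  # all SI < 3: extrapolate upward if the top of the curve trends up
  n <- length(conc)
  slope <- (si[n] - si[n - 1L]) / (x[n] - x[n - 1L])
  if (!is.finite(slope) || slope <= 0)
    return(.ec3_estimate(NA_real_, "negative", TRUE))
  val <- back(x[n] + (3 - si[n]) / slope)
  .ec3_estimate(val, "extrapolated")
}

#' Screen an extrapolated EC3 estimate (Ryan criteria)
#'
#' Extrapolated EC3 values are acceptable only when: (1) the lowest measured
#' stimulation index is below 5; (2) the extrapolated EC3 is within 10-fold
#' of the closest tested concentration (the lowest concentration for
#' downward, the highest for upward extrapolation); and (3) the slope ratio
#' -- the slope from the high to the mid dose divided by the slope from the
#' mid to the low dose, over the three tested concentrations nearest the
#' extrapolation end -- is non-negative and at most 2. Studies with fewer
#' than three concentrations cannot be screened and are rejected.
#' Interpolated estimates pass through unchanged.
#'
#' @param estimate An [ec3_estimate].
#' @param series The study's stimulation-index [dose_response] (or
#'   [llna_study]).
#' @return The estimate with `rejection_reasons` appended (possible reasons:
#'   `lowest_si_ge_5`, `extrapolation_gt_10x`, `slope_ratio_fail`) and
#'   `accepted` updated.
#' @export
ryan_screen <- function(estimate, series) {
  stopifnot(inherits(estimate, "ec3_estimate"))
  if (estimate$method != "extrapolated") return(estimate)
  if (inherits(series, "llna_study")) series <- series$series
  conc <- series$concentration
  si <- series$response
  n <- length(conc)
  reasons <- estimate$rejection_reasons
  downward <- estimate$value < conc[1L]

  if (min(si) >= 5) reasons <- c(reasons, "lowest_si_ge_5")

  closest <- if (downward) conc[1L] else conc[n]
  ratio <- if (downward) closest / estimate$value else estimate$value / closest
  if (ratio >= 10) reasons <- c(reasons, "extrapolation_gt_10x")

  if (n < 3L) {
    reasons <- c(reasons, "slope_ratio_fail")
  } else {
    idx <- if (downward) 1:3 else (n - 2L):n
    c3 <- conc[idx]; s3 <- si[idx]
    hi_mid <- (s3[3L] - s3[2L]) / (c3[3L] - c3[2L])
    mid_lo <- (s3[2L] - s3[1L]) / (c3[2L] - c3[1L])
    sr <- hi_mid / mid_lo
    if (!is.finite(sr) || sr < 0 || sr > 2)
      reasons <- c(reasons, "slope_ratio_fail")
  }

  .ec3_estimate(estimate$value, estimate$method, estimate$negative,
                unique(reasons))
}

#' GHS skin-sensitizer subcategory from an EC3 value
#'
#' GHS subcategory 1A (high frequency of occurrence or high potency) is
#' assigned for EC3 at or below 2%, subcategory 1B above 2%, and negative
#' substances are not classified (NC).
#'
#' @param ec3 EC3 in percent (positive), or `NA` for a negative call.
#' @return `"1A"`, `"1B"` or `"NC"`.
#' @examples
#' ghs_classify(1.54)   # "1A"
#' ghs_classify(10.57)  # "1B"
#' @export
ghs_classify <- function(ec3) {
  vapply(ec3, function(v) {
    if (is.na(v)) return("NC")
    if (!is.finite(v) || v <= 0)
      stop("EC3 must be positive (or NA for a negative call)", call. = FALSE)
    if (v <= 2) "1A" else "1B"
  }, character(1L))
}

.reference_ec3 <- function(approach, mean, ci_low, ci_high, n, values) {
  structure(list(approach = approach, mean = mean, ci_low = ci_low,
                 ci_high = ci_high, n_studies = n, values = values,
                 ghs_class = ghs_classify(mean)),
            class = "reference_ec3")
}

#' Representative EC3 by single-study selection (Approach 1)
#'
#' Restricts the accepted studies to preferred vehicles (by default acetone
#' and acetone:olive oil 4:1 v/v, so that potencies are compared in the same
#' solvent) and selects the study with the lowest EC3. Studies whose EC3 lies
#' within `tie_fold` of that minimum are kept as a tied set and reported as a
#' range, with the midpoint used as the representative value.
#'
#' @param studies List of [llna_study] objects.
#' @param estimates List of matching accepted/updated [ec3_estimate]s.
#' @param preferred_vehicles Character vector of vehicle labels to retain.
#' @param tie_fold Studies with EC3 within this fold of the minimum are
#'   treated as tied (default 1.25).
#' @return An object of class `"reference_ec3"` with `approach = "A1"`.
#' @export
approach1_select <- function(studies, estimates,
                             preferred_vehicles = c("acetone", "AOO"),
                             tie_fold = 1.25) {
  stopifnot(length(studies) == length(estimates))
  ok <- vapply(seq_along(studies), function(i) {
    est <- estimates[[i]]
    est$accepted && !est$negative &&
      studies[[i]]$vehicle %in% preferred_vehicles
  }, logical(1L))
  if (!any(ok))
    stop("no accepted study in a preferred vehicle; no Approach 1 reference",
         call. = FALSE)
  vals <- vapply(estimates[ok], `[[`, numeric(1L), "value")
  sel <- vals[vals <= min(vals) * tie_fold]
  if (length(sel) > 1L) {
    .reference_ec3("A1", mean(range(sel)), min(sel), max(sel),
                   length(sel), sort(sel))
  } else {
    .reference_ec3("A1", sel, NA_real_, NA_real_, 1L, sel)
  }
}

#' Representative EC3 as a mean with 95% confidence interval (Approach 2)
#'
#' Aggregates all accepted EC3 values for a substance into their arithmetic
#' mean with a t-based 95% confidence interval
#' (`mean +/- t(0.975, n-1) * sd / sqrt(n)`); a lower bound below zero is
#' censored to zero. Negative studies contribute no EC3 and are not counted
#' in `n`. A single value yields no interval.
#'
#' @param ec3_values Numeric vector of accepted EC3 values (percent).
#' @param quantile `"t"` (default) or `"normal"` for the CI multiplier.
#' @return An object of class `"reference_ec3"` with `approach = "A2"`.
#' @examples
#' approach2_aggregate(c(1, 2, 3))  # mean 2, CI censored at 0
#' @export
approach2_aggregate <- function(ec3_values, quantile = c("t", "normal")) {
  quantile <- match.arg(quantile)
  ec3_values <- ec3_values[!is.na(ec3_values)]
  if (length(ec3_values) == 0L)
    stop("no accepted EC3 values; no Approach 2 reference", call. = FALSE)
  if (any(ec3_values <= 0))
    stop("EC3 values must be positive", call. = FALSE)
  n <- length(ec3_values)
  m <- mean(ec3_values)
  if (n == 1L) return(.reference_ec3("A2", m, NA_real_, NA_real_, n, ec3_values))
  q <- if (quantile == "t") stats::qt(0.975, n - 1L) else stats::qnorm(0.975)
  half <- q * stats::sd(ec3_values) / sqrt(n)
  .reference_ec3("A2", m, max(0, m - half), m + half, n, ec3_values)
}

#' @export
print.reference_ec3 <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else
    sprintf(" (%.4g-%.4g)", x$ci_low, x$ci_high)
  cat(sprintf("Representative LLNA EC3 [%s]: %.4g%%%s  (n = %d)  GHS %s\n",
              x$approach, x$mean, ci, x$n_studies, x$ghs_class))
  invisible(x)
}

#' @export
print.ec3_estimate <- function(x, ...) {
  if (x$negative) {
    cat("EC3 estimate: negative study (no EC3)\n")
  } else {
    cat(sprintf("EC3 estimate: %.4g%% (%s)%s\n", x$value, x$method,
                if (x$accepted) "" else
                  paste0("  REJECTED: ",
                         paste(x$rejection_reasons, collapse = ", "))))
  }
  invisible(x)
}
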