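#' Percent peptide depletion from HPLC peak areas
#'
#' Depletion of the cysteine- or lysine-containing synthetic peptide relative
#' to peptide incubated with solvent alone, the DPRA's measure of protein
#' reactivity (the molecular initiating event of the skin-sensitization AOP).
#'
#' @param peak_area_sample Peak area of the peptide after co-incubation with
#'   the test substance (non-negative).
#' @param peak_area_control Peak area of the solvent control (positive).
#' @return Percent depletion, `100 * (1 - sample/control)`, clamped to
#'   `[0, 100]` (a sample area exceeding the control reports 0).
#' @examples
#' percent_depletion(447, 1000)  # 55.3
#' @export
percent_depletion <- function(peak_area_sample, peak_area_control) {
  if (any(!is.finite(peak_area_control)) || any(peak_area_control <= 0))
    stop("control peak area must be positive", call. = FALSE)
  if (any(!is.finite(peak_area_sample)) || any(peak_area_sample < 0))
    stop("sample peak area must be non-negative", call. = FALSE)
  pmin(100, pmax(0, 100 * (1 - peak_area_sample / peak_area_control)))
}

#' Weighted molecular weight of a mixture
#'
#' Mole-fraction-weighted molecular weight, used to express a multi-component
#' preparation (e.g. a CMIT/MIT biocide mixture) at a defined molar
#' concentration for the in chemico and in vitro assays.
#'
#' @param mw Numeric vector of component molecular weights (g/mol).
#' @param mole_fraction Numeric vector of mole fractions, summing to 1
#'   (tolerance 1e-6).
#' @return Weighted molecular weight in g/mol.
#' @examples
#' weighted_mw(c(149.592, 115.15), c(0.761, 0.239))  # 141.36
#' @export
weighted_mw <- function(mw, mole_fraction) {
  if (length(mw) != length(mole_fraction) || length(mw) < 1L)
    stop("mw and mole_fraction must be non-empty and of equal length",
         call. = FALSE)
  if (abs(sum(mole_fraction) - 1) > 1e-6)
    stop("mole fractions must sum to 1", call. = FALSE)
  if (any(mw <= 0) || any(mole_fraction < 0))
    stop("molecular weights must be positive and fractions non-negative",
         call. = FALSE)
  sum(mw * mole_fraction)
}

# TG 442C reactivity bins. Avg.Lys.Cys model: positive above 6.38 %.
# Cysteine-only model (used when the test substance co-elutes with the lysine
# peptide): positive above 13.89 %.
.dpra_bins_avg <- c(minimal = 6.38, low = 22.62, moderate = 42.47)
.dpra_bins_cys <- c(minimal = 13.89, low = 23.09, moderate = 98.24)

.dpra_class <- function(x, bins) {
  if (x <= bins[["minimal"]]) "minimal" else
  if (x <= bins[["low"]]) "low" else
  if (x <= bins[["moderate"]]) "moderate" else "high"
}

#' Evaluate a DPRA result from cysteine and lysine depletions
#'
#' Applies the Avg.Lys.Cys prediction model when both peptide depletions are
#' available: the decision value is their arithmetic mean, positive above
#' 6.38% with reactivity classes binned per the cysteine/lysine model
#' (minimal <= 6.38 < low <= 22.62 < moderate <= 42.47 < high). When the test
#' substance co-elutes with the lysine peptide (lysine depletion not
#' evaluable) the cysteine-only model is applied instead: positive above
#' 13.89%, classes binned at 13.89 / 23.09 / 98.24.
#'
#' @param cys_depletion Cysteine peptide percent depletion in `[0, 100]`, or
#'   `NA` if co-eluted.
#' @param lys_depletion Lysine peptide percent depletion, or `NA` if
#'   co-eluted.
#' @return An object of class `"dpra_result"`: list with `cys_depletion`,
#'   `lys_depletion`, `avg_lys_cys` (`NA` under the cysteine-only model),
#'   `positive`, `reactivity_class`, `model_used`.
#' @examples
#' dpra_evaluate(55.2, 55.2)   # positive, high reactivity
#' dpra_evaluate(100, NA)      # cysteine-only model (lysine co-elution)
#' @export
dpra_evaluate <- function(cys_depletion, lys_depletion) {
  cys_ok <- !is.na(cys_depletion)
  lys_ok <- !is.na(lys_depletion)
  if (!cys_ok && !lys_ok)
    stop("no valid DPRA model: both peptide depletions are unavailable",
         call. = FALSE)
  chk <- function(x, lab) {
    if (!is.finite(x) || x < 0 || x > 100)
      stop(sprintf("%s depletion must be in [0, 100]", lab), call. = FALSE)
  }
  if (cys_ok) chk(cys_depletion, "cysteine")
  if (lys_ok) chk(lys_depletion, "lysine")

  if (cys_ok && lys_ok) {
    avg <- mean(c(cys_depletion, lys_depletion))
    res <- list(cys_depletion = cys_depletion, lys_depletion = lys_depletion,
                avg_lys_cys = avg,
                positive = avg > .dpra_bins_avg[["minimal"]],
                reactivity_class = .dpra_class(avg, .dpra_bins_avg),
                model_used = "cys_lys")
  } else if (cys_ok) {
    res <- list(cys_depletion = cys_depletion, lys_depletion = NA_real_,
                avg_lys_cys = NA_real_,
                positive = cys_depletion > .dpra_bins_cys[["minimal"]],
                reactivity_class = .dpra_class(cys_depletion, .dpra_bins_cys),
                model_used = "cys_only")
  } else {
    # no lysine-only prediction model exists in the guideline
    stop("no valid DPRA model: cysteine depletion unavailable", call. = FALSE)
  }
  structure(res, class = "dpra_result")
}

#' @export
print.dpra_result <- function(x, ...) {
  cat("DPRA result (", x$model_used, " model)\n", sep = "")
  cat(sprintf("  Cys depletion: %s   Lys depletion: %s   Avg.Lys.Cys: %s\n",
              format(x$cys_depletion), format(x$lys_depletion),
              format(x$avg_lys_cys)))
  cat(sprintf("  Call: %s, reactivity %s\n",
              if (x$positive) "POSITIVE" else "NEGATIVE", x$reactivity_class))
  invisible(x)
}
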