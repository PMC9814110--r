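#' Purity adjustment of a nominal concentration
#'
#' Rescales a concentration calculated from the as-supplied preparation to the
#' active-ingredient scale, e.g. a biocide supplied at 14.2% combined active
#' content.
#'
#' @param concentration Nominal concentration (any unit).
#' @param purity_fraction Active-ingredient mass fraction in `(0, 1]`.
#' @return `concentration * purity_fraction`, same unit.
#' @examples
#' purity_adjust(25.7, 0.142)  # 3.65 ug/mL
#' @export
purity_adjust <- function(concentration, purity_fraction) {
  if (any(!is.finite(purity_fraction)) || any(purity_fraction <= 0) ||
      any(purity_fraction > 1))
    stop("purity fraction must be in (0, 1]", call. = FALSE)
  concentration * purity_fraction
}

#' Concentration correction for substances tested at a default molecular weight
#'
#' Substances without a defined molecular weight are prepared at a default
#' assumed MW (200 g/mol under TG 442D); once the constituent-weighted MW is
#' known, the nominal molar concentration is corrected by the purity and by
#' the ratio of the weighted to the assumed MW. For the CMIT/MIT mixture:
#' 2000 uM x 0.142 / (141.36/200 = 0.7068) = 401.8 uM.
#'
#' @param nominal Nominal concentration (uM) prepared at the assumed MW.
#' @param purity_fraction Active-ingredient fraction in `(0, 1]`.
#' @param mw_ratio Weighted MW divided by the assumed MW (positive).
#' @return Corrected concentration, `nominal * purity_fraction / mw_ratio`.
#' @examples
#' mw_corrected_concentration(2000, 0.142, 141.36 / 200)  # 401.8 uM
#' @export
mw_corrected_concentration <- function(nominal, purity_fraction, mw_ratio) {
  if (any(!is.finite(mw_ratio)) || any(mw_ratio <= 0))
    stop("MW ratio must be positive", call. = FALSE)
  purity_adjust(nominal, purity_fraction) / mw_ratio
}

#' Evaluate a KeratinoSens result
#'
#' Derives Imax (the average maximum fold induction of luciferase activity
#' over the tested concentrations) and EC1.5 (the concentration producing
#' 1.5-fold induction, by interpolation linear in log10 concentration), and
#' applies the positivity conditions of the keratinocyte ARE-reporter assay:
#' Imax >= 1.5-fold, cell viability > 70% at the lowest concentration with
#' >= 1.5-fold induction, EC1.5 below 1000 uM, and a dose-dependent increase
#' in induction.
#'
#' Dose dependence is operationalized as either (a) the fold induction at the
#' tested concentration immediately above the EC1.5 crossing being at least
#' the induction at the crossing, or (b) a positive Spearman rank correlation
#' between concentration and induction over the concentrations with viability
#' above 70%.
#'
#' @param induction [dose_response] of fold induction (unit uM); replicate
#'   plates should be averaged before calling.
#' @param viability [dose_response] of percent viability on the same
#'   concentration grid.
#' @param ec15_limit Positivity requires EC1.5 strictly below this
#'   concentration (default 1000 uM).
#' @return An object of class `"keratinosens_result"`: list with `imax`,
#'   `ec15`, `viability_at_first_induction`, `dose_dependent`, `positive`.
#' @examples
#' ind <- dose_response(c(125, 250, 500, 1000), c(1.0, 1.2, 1.6, 2.4),
#'                      unit = "uM", kind = "fold_induction")
#' via <- dose_response(c(125, 250, 500, 1000), c(100, 98, 95, 90),
#'                      unit = "uM", kind = "viability_percent")
#' keratinosens_evaluate(ind, via)
#' @export
keratinosens_evaluate <- function(induction, viability, ec15_limit = 1000) {
  if (!inherits(induction, "dose_response") ||
      !inherits(viability, "dose_response"))
    stop("induction and viability must be dose_response objects", call. = FALSE)
  if (!isTRUE(all.equal(induction$concentration, viability$concentration)))
    stop("induction and viability must share the same concentration grid",
         call. = FALSE)
  conc <- induction$concentration
  fold <- induction$response
  viab <- viability$response

  imax <- max(fold)
  ec15 <- crossing_concentration(induction, 1.5, "up", "log")

  first_ind <- which(fold >= 1.5)[1L]
  viab_first <- if (is.na(first_ind)) NA_real_ else viab[first_ind]

  dose_dep <- FALSE
  if (!is.na(ec15)) {
    above <- which(conc > ec15)[1L]
    if (!is.na(above)) {
      at_cross <- 1.5  # interpolated induction at the crossing by construction
      dose_dep <- fold[above] >= at_cross
    }
  }
  if (!dose_dep) {
    ok <- viab > 70
    if (sum(ok) >= 3L) {
      rho <- suppressWarnings(
        stats::cor(conc[ok], fold[ok], method = "spearman"))
      dose_dep <- isTRUE(rho > 0)
    }
  }

  positive <- imax >= 1.5 &&
    !is.na(ec15) && ec15 < ec15_limit &&
    !is.na(viab_first) && viab_first > 70 &&
    dose_dep

  structure(list(imax = imax, ec15 = ec15,
                 viability_at_first_induction = viab_first,
                 dose_dependent = dose_dep, positive = positive),
            class = "keratinosens_result")
}

#' @export
print.keratinosens_result <- function(x, ...) {
  cat("KeratinoSens result\n")
  cat(sprintf("  Imax: %.3g-fold   EC1.5: %s uM   viability at first induction: %s%%\n",
              x$imax, format(signif(x$ec15, 3)),
              format(x$viability_at_first_induction)))
  cat(sprintf("  Call: %s%s\n", if (x$positive) "POSITIVE" else "NEGATIVE",
              if (x$dose_dependent) " (dose-dependent)" else ""))
  invisible(x)
}
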