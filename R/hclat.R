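#' CV75 from an h-CLAT range-finder viability series
#'
#' The concentration producing 75% cell viability (25% cytotoxicity),
#' interpolated linearly in log10 concentration on the propidium-iodide
#' viability series. A series that never falls below 75% has no CV75
#' (non-cytotoxic substance; the solvent-specific starting-concentration
#' default then applies).
#'
#' @param viability [dose_response] of percent viability (unit ug/mL).
#' @return CV75 in ug/mL, or `NA_real_` when viability never crosses 75%.
#' @examples
#' v <- dose_response(c(1, 2, 4), c(100, 75, 50), unit = "ug/mL",
#'                    kind = "viability_percent")
#' hclat_cv75(v)  # 2
#' @export
hclat_cv75 <- function(viability) {
  crossing_concentration(viability, 75, "down", "log")
}

#' h-CLAT main-assay dose series from CV75
#'
#' Eight concentrations descending by a factor of 1.2 from a starting (highest)
#' concentration of 1.2 x CV75, capped at the solubility-driven maximum for
#' the solvent (5000 ug/mL in PBS, 1000 ug/mL in DMSO). Substances without a
#' CV75 (non-cytotoxic) start at the cap.
#'
#' @param cv75 CV75 in ug/mL, or `NA` for non-cytotoxic substances.
#' @param solvent `"PBS"` or `"DMSO"`.
#' @return Numeric vector of 8 concentrations (ug/mL), highest first.
#' @examples
#' hclat_dose_series(13.1, "DMSO")  # starts at 15.7 (3 s.f.)
#' @export
hclat_dose_series <- function(cv75, solvent = c("PBS", "DMSO")) {
  solvent <- match.arg(solvent)
  cap <- if (solvent == "PBS") 5000 else 1000
  if (is.na(cv75)) {
    start <- cap
  } else {
    if (!is.finite(cv75) || cv75 <= 0)
      stop("CV75 must be positive", call. = FALSE)
    start <- min(1.2 * cv75, cap)
  }
  start / 1.2^(0:7)
}

#' A single h-CLAT run
#'
#' Bundles the CD86 and CD54 relative fluorescence intensity (RFI) series and
#' the viability series of one independent run, all on the same concentration
#' grid. RFI is expressed in percent of the solvent control
#' (`100 * (MFI_treated - MFI_isotype) / (MFI_solvent - MFI_solvent_isotype)`);
#' precomputed RFI series are accepted directly.
#'
#' @param cd86_rfi,cd54_rfi [dose_response] series of percent RFI.
#' @param viability [dose_response] of percent viability, same grid.
#' @param cv75 Optional CV75 (ug/mL) from the range finder.
#' @return An object of class `"hclat_run"`.
#' @export
hclat_run <- function(cd86_rfi, cd54_rfi, viability, cv75 = NA_real_) {
  series <- list(cd86_rfi = cd86_rfi, cd54_rfi = cd54_rfi,
                 viability = viability)
  for (s in series)
    if (!inherits(s, "dose_response"))
      stop("cd86_rfi, cd54_rfi and viability must be dose_response objects",
           call. = FALSE)
  grid <- cd86_rfi$concentration
  if (!isTRUE(all.equal(grid, cd54_rfi$concentration)) ||
      !isTRUE(all.equal(grid, viability$concentration)))
    stop("the three series of an h-CLAT run must share one concentration grid",
         call. = FALSE)
  structure(c(series, list(cv75 = cv75)), class = "hclat_run")
}

# does this run meet the marker condition (RFI >= threshold at >= 1 tested
# concentration with viability >= 50 %)?
.hclat_run_qualifies <- function(run, marker, threshold) {
  rfi <- run[[marker]]$response
  viab <- run$viability$response
  any(rfi >= threshold & viab >= 50)
}

#' Evaluate an h-CLAT result over independent runs
#'
#' Positivity follows the two-run rule of the dendritic-cell activation assay:
#' a substance is positive if CD86 RFI >= 150% (or CD54 RFI >= 200%) at one
#' or more tested concentrations with viability >= 50% in at least two
#' independent runs. For positive markers the effective concentrations EC150
#' (CD86) and EC200 (CD54) are interpolated, linearly in log10 concentration,
#' on the geometric-mean RFI across the qualifying runs, restricted to
#' concentrations with geometric-mean viability >= 50%. The minimum induction
#' threshold (MIT) is the lower of the defined EC values; it is the h-CLAT's
#' quantitative potency endpoint.
#'
#' A marker already above its threshold at the lowest tested concentration
#' has no within-range crossing: the run is positive but the EC (and possibly
#' the MIT) is undefined, and `positive_at_lowest` is flagged.
#'
#' @param runs List of at least two [hclat_run] objects on a common grid.
#' @return An object of class `"hclat_result"`: list with `ec150`, `ec200`,
#'   `mit`, `positive`, `cd86_positive`, `cd54_positive`,
#'   `positive_at_lowest`, `runs_used`.
#' @export
hclat_evaluate <- function(runs) {
  if (!is.list(runs) || length(runs) < 2L)
    stop("h-CLAT evaluation requires at least two independent runs",
         call. = FALSE)
  for (r in runs)
    if (!inherits(r, "hclat_run"))
      stop("all elements of runs must be hclat_run objects", call. = FALSE)
  grid <- runs[[1L]]$cd86_rfi$concentration
  for (r in runs[-1L])
    if (!isTRUE(all.equal(grid, r$cd86_rfi$concentration)))
      stop("all runs must share one concentration grid", call. = FALSE)

  marker_ec <- function(marker, threshold) {
    qual <- vapply(runs, .hclat_run_qualifies, logical(1L),
                   marker = marker, threshold = threshold)
    if (sum(qual) < 2L)
      return(list(positive = FALSE, ec = NA_real_, at_lowest = FALSE))
    sel <- runs[qual]
    rfi_mat <- vapply(sel, function(r) r[[marker]]$response, numeric(length(grid)))
    viab_mat <- vapply(sel, function(r) r$viability$response, numeric(length(grid)))
    gm_rfi <- exp(rowMeans(log(pmax(rfi_mat, 1e-9))))
    gm_viab <- exp(rowMeans(log(pmax(viab_mat, 1e-9))))
    keep <- gm_viab >= 50
    if (sum(keep) < 2L)
      return(list(positive = TRUE, ec = NA_real_, at_lowest = FALSE))
    s <- dose_response(grid[keep], gm_rfi[keep], unit = "ug/mL",
                       kind = "rfi_percent")
    ec <- crossing_concentration(s, threshold, "up", "log")
    at_lowest <- is.na(ec) && gm_rfi[keep][1L] > threshold
    list(positive = TRUE, ec = ec, at_lowest = at_lowest)
  }

  cd86 <- marker_ec("cd86_rfi", 150)
  cd54 <- marker_ec("cd54_rfi", 200)
  ecs <- c(cd86$ec, cd54$ec)
  mit <- if (all(is.na(ecs))) NA_real_ else min(ecs, na.rm = TRUE)

  structure(list(ec150 = cd86$ec, ec200 = cd54$ec, mit = mit,
                 positive = cd86$positive || cd54$positive,
                 cd86_positive = cd86$positive, cd54_positive = cd54$positive,
                 positive_at_lowest = cd86$at_lowest || cd54$at_lowest,
                 runs_used = length(runs)),
            class = "hclat_result")
}

#' @export
print.hclat_result <- function(x, ...) {
  cat("h-CLAT result (", x$runs_used, " runs)\n", sep = "")
  cat(sprintf("  EC150 (CD86): %s   EC200 (CD54): %s   MIT: %s ug/mL\n",
              format(signif(x$ec150, 3)), format(signif(x$ec200, 3)),
              format(signif(x$mit, 3))))
  cat(sprintf("  Call: %s%s\n", if (x$positive) "POSITIVE" else "NEGATIVE",
              if (x$positive_at_lowest) " (induction at lowest dose)" else ""))
  invisible(x)
}
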