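# Documented CSV schemas (all plain text, one row per record):
#   dpra.csv:         chemical, replicate, peptide {cys,lys}, area_sample,
#                     area_control, coeluted
#   keratinosens.csv: chemical, plate, repetition, conc_uM, fold_induction,
#                     viability_pct
#   hclat.csv:        chemical, run, conc_ug_ml, cd86_rfi, cd54_rfi,
#                     viability_pct
#   llna_studies.csv: chemical, study_id, vehicle, conc_pct, si, source,
#                     plus one logical column per checklist flag
#   training_table.csv: chemical, avg_lys_cys, mit, imax, ec3, split

.check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s is missing columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Read raw assay and study tables
#'
#' Thin, schema-validating readers for the package's documented CSV formats.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame.
#' @name read_assay_csv
NULL

#' @rdname read_assay_csv
#' @export
read_dpra_csv <- function(path) {
  .check_columns(utils::read.csv(path),
                 c("chemical", "replicate", "peptide", "area_sample",
                   "area_control", "coeluted"), "dpra.csv")
}

#' @rdname read_assay_csv
#' @export
read_keratinosens_csv <- function(path) {
  .check_columns(utils::read.csv(path),
                 c("chemical", "plate", "repetition", "conc_uM",
                   "fold_induction", "viability_pct"), "keratinosens.csv")
}

#' @rdname read_assay_csv
#' @export
read_hclat_csv <- function(path) {
  .check_columns(utils::read.csv(path),
                 c("chemical", "run", "conc_ug_ml", "cd86_rfi", "cd54_rfi",
                   "viability_pct"), "hclat.csv")
}

#' @rdname read_assay_csv
#' @export
read_llna_csv <- function(path) {
  .check_columns(utils::read.csv(path),
                 c("chemical", "study_id", "vehicle", "conc_pct", "si"),
                 "llna_studies.csv")
}

#' @rdname read_assay_csv
#' @export
read_training_table <- function(path) {
  df <- .check_columns(utils::read.csv(path),
                       c("chemical", "avg_lys_cys", "mit", "ec3"),
                       "training_table.csv")
  if (any(df$ec3 <= 0)) stop("training EC3 values must be positive",
                             call. = FALSE)
  df
}

#' Evaluate all three assays from raw tables
#'
#' Runs the endpoint calculators over long-format raw tables (as read by the
#' `read_*_csv` readers or produced by [generate_assay_fixtures()]) and
#' collects one endpoint row per chemical: DPRA Avg.Lys.Cys and reactivity
#' call, KeratinoSens Imax/EC1.5 and call, h-CLAT MIT and call. Replicate
#' DPRA rows are averaged per peptide; replicate KeratinoSens plates are
#' averaged per concentration.
#'
#' @param dpra,keratinosens,hclat Data frames in the documented schemas.
#' @param dpra_fallback_cys_only When a chemical's lysine peptide co-elutes,
#'   use its cysteine depletion as the Avg.Lys.Cys surrogate fed to the DAs
#'   (flagged in the output); default `TRUE`.
#' @return Data frame with one row per chemical: `chemical`, `avg_lys_cys`,
#'   `dpra_positive`, `dpra_class`, `dpra_model`, `imax`, `ec15`,
#'   `ks_positive`, `mit`, `hclat_positive`, `dpra_surrogate` (logical).
#' @export
assay_endpoints <- function(dpra, keratinosens, hclat,
                            dpra_fallback_cys_only = TRUE) {
  chems <- unique(dpra$chemical)
  rows <- lapply(chems, function(chem) {
    d <- dpra[dpra$chemical == chem, ]
    dep <- vapply(c("cys", "lys"), function(pep) {
      p <- d[d$peptide == pep, ]
      if (nrow(p) == 0L || any(p$coeluted)) return(NA_real_)
      mean(percent_depletion(p$area_sample, p$area_control))
    }, numeric(1L))
    dres <- dpra_evaluate(dep[["cys"]], dep[["lys"]])
    avg <- dres$avg_lys_cys
    surrogate <- FALSE
    if (is.na(avg) && dpra_fallback_cys_only) {
      avg <- dres$cys_depletion  # cysteine-only surrogate for the DA input
      surrogate <- TRUE
    }

    k <- keratinosens[keratinosens$chemical == chem, ]
    ks <- NULL
    if (nrow(k) > 0L) {
      agg <- stats::aggregate(cbind(fold_induction, viability_pct) ~ conc_uM,
                              data = k, FUN = mean)
      agg <- agg[order(agg$conc_uM), ]
      ks <- keratinosens_evaluate(
        dose_response(agg$conc_uM, agg$fold_induction, "uM", "fold_induction"),
        dose_response(agg$conc_uM, agg$viability_pct, "uM",
                      "viability_percent"))
    }

    h <- hclat[hclat$chemical == chem, ]
    hc <- NULL
    if (nrow(h) > 0L) {
      runs <- lapply(split(h, h$run), function(r) {
        r <- r[order(r$conc_ug_ml), ]
        hclat_run(
          dose_response(r$conc_ug_ml, r$cd86_rfi, "ug/mL", "rfi_percent"),
          dose_response(r$conc_ug_ml, r$cd54_rfi, "ug/mL", "rfi_percent"),
          dose_response(r$conc_ug_ml, r$viability_pct, "ug/mL",
                        "viability_percent"))
      })
      hc <- hclat_evaluate(unname(runs))
    }

    data.frame(chemical = chem, avg_lys_cys = avg,
               dpra_positive = dres$positive,
               dpra_class = dres$reactivity_class,
               dpra_model = dres$model_used,
               imax = if (is.null(ks)) NA_real_ else ks$imax,
               ec15 = if (is.null(ks)) NA_real_ else ks$ec15,
               ks_positive = if (is.null(ks)) NA else ks$positive,
               mit = if (is.null(hc)) NA_real_ else hc$mit,
               hclat_positive = if (is.null(hc)) NA else hc$positive,
               dpra_surrogate = surrogate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build per-chemical reference EC3 values from an LLNA study table
#'
#' Converts the long study table into [llna_study] objects (deduplicating
#' studies with identical chemical and stimulation-index vectors), screens
#' each against the acceptability checklist, estimates EC3 per study,
#' applies the extrapolation screen, and aggregates under both approaches.
#'
#' @param llna Data frame in the `llna_studies.csv` schema; checklist-flag
#'   columns are optional and default to `TRUE`.
#' @param preferred_vehicles Vehicles eligible for Approach 1.
#' @return Data frame with one row per chemical: `chemical`, `a1_ec3`,
#'   `a1_low`, `a1_high`, `a1_n`, `a1_ghs`, `a2_ec3`, `a2_low`, `a2_high`,
#'   `a2_n`, `a2_ghs`, `n_studies`, `n_accepted`.
#' @export
llna_reference <- function(llna, preferred_vehicles = c("acetone", "AOO")) {
  flag_cols <- intersect(llna_checklist_flags(), names(llna))
  rows <- lapply(unique(llna$chemical), function(chem) {
    tab <- llna[llna$chemical == chem, ]
    studies <- lapply(split(tab, tab$study_id), function(s) {
      s <- s[order(s$conc_pct), ]
      flags <- if (length(flag_cols))
        stats::setNames(as.logical(s[1L, flag_cols]), flag_cols) else NULL
      llna_study(chem, s$conc_pct, s$si,
                 vehicle = as.character(s$vehicle[1L]), flags = flags,
                 source = if ("source" %in% names(s))
                   as.character(s$source[1L]) else "",
                 study_id = as.character(s$study_id[1L]))
    })
    # drop duplicated studies (same chemical, same SI vector)
    keys <- vapply(studies, function(s)
      paste(signif(s$series$response, 6), collapse = ","), character(1L))
    studies <- studies[!duplicated(keys)]

    ests <- lapply(studies, function(s) {
      scr <- checklist_screen(s)
      est <- ec3_from_study(s)
      est <- ryan_screen(est, s)
      if (!scr$accepted) {
        est$rejection_reasons <- unique(c(est$rejection_reasons,
                                          "checklist_fail"))
        est$accepted <- FALSE
      }
      est
    })
    acc <- vapply(ests, function(e) e$accepted && !e$negative, logical(1L))

    a1 <- tryCatch(approach1_select(studies, ests, preferred_vehicles),
                   error = function(e) NULL)
    a2 <- tryCatch(approach2_aggregate(
      vapply(ests[acc], `[[`, numeric(1L), "value")),
      error = function(e) NULL)
    g <- function(ref, f) if (is.null(ref)) NA else ref[[f]]
    data.frame(chemical = chem,
               a1_ec3 = g(a1, "mean"), a1_low = g(a1, "ci_low"),
               a1_high = g(a1, "ci_high"), a1_n = g(a1, "n_studies"),
               a1_ghs = if (is.null(a1)) NA_character_ else a1$ghs_class,
               a2_ec3 = g(a2, "mean"), a2_low = g(a2, "ci_low"),
               a2_high = g(a2, "ci_high"), a2_n = g(a2, "n_studies"),
               a2_ghs = if (is.null(a2)) NA_character_ else a2$ghs_class,
               n_studies = length(studies), n_accepted = sum(acc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
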