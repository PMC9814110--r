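#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Either a
#' directory of input CSVs (`input_dir`, expecting `dpra.csv`,
#' `keratinosens.csv`, `hclat.csv`, `llna_studies.csv`,
#' `training_table.csv`) or a simulation request (`simulate = TRUE`, with
#' `sim_spec`) must be supplied. Configurations can also be stored as YAML
#' and read with [read_run_config()].
#'
#' @param output_dir Directory for artifacts (created if absent).
#' @param simulate Generate all inputs synthetically (default `TRUE`).
#' @param sim_spec A [synthetic_spec()] used when simulating.
#' @param input_dir Directory containing the input CSVs when not simulating.
#' @param variants Model variants to fit (`"D_hC"`, `"D_hC_KS"`).
#' @param n_runs Ensemble size per variant.
#' @param iterations Training epochs per run.
#' @param seed Master seed for the whole run.
#' @param n_llna_studies Studies simulated per evaluation chemical.
#' @param n_eval_chemicals Number of held-out chemicals carried through the
#'   full endpoint -> prediction -> reference comparison when simulating.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(output_dir = tempfile("sensda_run_"),
                       simulate = TRUE, sim_spec = synthetic_spec(),
                       input_dir = NULL,
                       variants = c("D_hC", "D_hC_KS"),
                       n_runs = 100L, iterations = 10000L, seed = 1L,
                       n_llna_studies = 5L, n_eval_chemicals = 6L) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (!simulate) {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("input_dir must exist when simulate = FALSE", call. = FALSE)
  }
  structure(list(output_dir = output_dir, simulate = simulate,
                 sim_spec = sim_spec, input_dir = input_dir,
                 variants = variants, n_runs = as.integer(n_runs),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 n_llna_studies = as.integer(n_llna_studies),
                 n_eval_chemicals = as.integer(n_eval_chemicals)),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys mirror the [run_config()]
#'   arguments (simulation spec fields under `sim_spec`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y$sim_spec
  y$sim_spec <- if (is.null(spec_args)) synthetic_spec() else
    do.call(synthetic_spec, spec_args)
  do.call(run_config, y)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

#' Run the full defined-approach pipeline
#'
#' Orchestrates the stages end to end: (1) obtain inputs (simulated with
#' known truth, or read from `input_dir`); (2) derive assay endpoints per
#' chemical; (3) curate LLNA reference EC3 values under Approaches 1 and 2;
#' (4) fit the requested ensemble variants on the training table and predict
#' EC3 for every evaluation chemical; (5) compare predictions with
#' references (GHS concordance, RMSE/MAE, dose per area). All randomness
#' derives from the master seed, so a rerun with the same configuration is
#' bit-identical. Artifacts written to `output_dir`: `endpoints.csv`,
#' `reference.csv`, `predictions.csv`, `metrics.json`, `manifest.json` and,
#' when simulating, the generated input CSVs plus `truth.json`.
#'
#' @param config A [run_config()].
#' @return An object of class `"potency_report"`: list with `endpoints`,
#'   `reference`, `predictions`, `metrics`, `concordance`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  inputs <- stage("input", {
    if (config$simulate) .simulate_inputs(config) else .load_inputs(config)
  })

  endpoints <- stage("endpoints",
    assay_endpoints(inputs$dpra, inputs$keratinosens, inputs$hclat))

  reference <- stage("reference", llna_reference(inputs$llna))

  predictions <- stage("predict", {
    rows <- list()
    for (v in config$variants) {
      fit <- ann_da(inputs$training, variant = v, n_runs = config$n_runs,
                    seed = child_seed(config$seed, paste0("fit_", v)),
                    iterations = config$iterations)
      newdata <- endpoints
      if (v == "D_hC_KS" && any(is.na(newdata$imax)))
        stop("variant D_hC_KS requires an imax endpoint for every chemical")
      pred <- predict(fit, newdata)
      rows[[v]] <- data.frame(chemical = endpoints$chemical, variant = v,
                              mean_ec3 = pred$mean_ec3, ci_low = pred$ci_low,
                              ci_high = pred$ci_high,
                              n_runs = config$n_runs,
                              ghs_class = ghs_classify(pred$mean_ec3),
                              dose_per_area =
                                ec3_to_dose_per_area(pred$mean_ec3),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  metrics <- stage("evaluate", {
    out <- list()
    for (v in config$variants) {
      pv <- predictions[predictions$variant == v, ]
      m <- merge(pv, reference, by = "chemical")
      for (appr in c("a1", "a2")) {
        ref_col <- paste0(appr, "_ec3")
        ok <- !is.na(m[[ref_col]])
        if (any(ok))
          out[[paste(v, toupper(appr), sep = "_")]] <- list(
            rmse = rmse(m$mean_ec3[ok], m[[ref_col]][ok]),
            mae = mae(m$mean_ec3[ok], m[[ref_col]][ok]),
            n = sum(ok))
      }
    }
    out
  })

  conc <- stage("evaluate", {
    out <- list()
    for (v in config$variants) {
      pv <- predictions[predictions$variant == v, ]
      pred_cls <- stats::setNames(pv$ghs_class, pv$chemical)
      ref_cls <- stats::setNames(reference$a2_ghs, reference$chemical)
      out[[v]] <- tryCatch(concordance(pred_cls, ref_cls),
                           error = function(e) NULL)
    }
    out
  })

  report <- structure(list(endpoints = endpoints, reference = reference,
                           predictions = predictions, metrics = metrics,
                           concordance = conc, config = config,
                           truth = inputs$truth),
                      class = "potency_report")

  stage("write", {
    od <- config$output_dir
    utils::write.csv(endpoints, file.path(od, "endpoints.csv"),
                     row.names = FALSE)
    utils::write.csv(reference, file.path(od, "reference.csv"),
                     row.names = FALSE)
    utils::write.csv(predictions, file.path(od, "predictions.csv"),
                     row.names = FALSE)
    .write_json(metrics, file.path(od, "metrics.json"))
    cfg <- config
    cfg$sim_spec <- unclass(cfg$sim_spec)
    .write_json(list(package = "sensda",
                     version = as.character(utils::packageVersion("sensda")),
                     seed = config$seed, config = unclass(cfg)),
                file.path(od, "manifest.json"))
  })
  report
}

# simulate every input the pipeline needs, with truth retained
.simulate_inputs <- function(config) {
  spec <- config$sim_spec
  training <- generate_training_table(spec)

  # evaluation chemicals: reuse held-out test chemicals with known truth
  test_rows <- training[training$split == "test", ]
  n_eval <- min(config$n_eval_chemicals, nrow(test_rows))
  eval_tab <- test_rows[seq_len(n_eval), ]

  truth <- data.frame(chemical = eval_tab$chemical,
                      cys_depletion = eval_tab$avg_lys_cys,
                      lys_depletion = eval_tab$avg_lys_cys,
                      ks_ec15 = pmax(2, 4 * eval_tab$mit),
                      ks_imax = pmax(2, eval_tab$imax + 1),
                      cv75 = 2 * eval_tab$mit,
                      mit = eval_tab$mit,
                      solvent = "PBS",
                      true_ec3 = 10^eval_tab$log10_ec3_true,
                      stringsAsFactors = FALSE)
  fixtures <- generate_assay_fixtures(truth, spec)

  llna_rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(config$n_llna_studies)) {
      st <- simulate_llna_study(
        truth$true_ec3[i], spec,
        study_seed = child_seed(config$seed, sprintf("llna_%d_%d", i, j)),
        chemical = truth$chemical[i])
      llna_rows[[length(llna_rows) + 1L]] <- data.frame(
        chemical = st$chemical, study_id = paste0(st$chemical, "_", j),
        vehicle = st$vehicle, conc_pct = st$series$concentration,
        si = st$series$response, source = st$source)
    }
  }
  llna <- do.call(rbind, llna_rows)

  od <- config$output_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fixtures$dpra, file.path(od, "dpra.csv"), row.names = FALSE)
  utils::write.csv(fixtures$keratinosens, file.path(od, "keratinosens.csv"),
                   row.names = FALSE)
  utils::write.csv(fixtures$hclat, file.path(od, "hclat.csv"),
                   row.names = FALSE)
  utils::write.csv(llna, file.path(od, "llna_studies.csv"), row.names = FALSE)
  utils::write.csv(training, file.path(od, "training_table.csv"),
                   row.names = FALSE)
  .write_json(truth, file.path(od, "truth.json"))

  list(dpra = fixtures$dpra, keratinosens = fixtures$keratinosens,
       hclat = fixtures$hclat, llna = llna, training = training,
       truth = truth)
}

.load_inputs <- function(config) {
  d <- config$input_dir
  list(dpra = read_dpra_csv(file.path(d, "dpra.csv")),
       keratinosens = read_keratinosens_csv(file.path(d, "keratinosens.csv")),
       hclat = read_hclat_csv(file.path(d, "hclat.csv")),
       llna = read_llna_csv(file.path(d, "llna_studies.csv")),
       training = read_training_table(file.path(d, "training_table.csv")),
       truth = NULL)
}

#' @export
print.potency_report <- function(x, ...) {
  cat("sensda potency report\n")
  cat(sprintf("  %d chemicals evaluated, variants: %s\n",
              length(unique(x$predictions$chemical)),
              paste(x$config$variants, collapse = ", ")))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-12s RMSE %.3g  MAE %.3g  (n = %d)\n", nm, m$rmse, m$mae,
                m$n))
  }
  for (nm in names(x$concordance))
    if (!is.null(x$concordance[[nm]]))
      cat(sprintf("  %s GHS concordance: %d/%d\n", nm,
                  x$concordance[[nm]]$agreement, x$concordance[[nm]]$n))
  invisible(x)
}
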