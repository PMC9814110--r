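# Synthetic ground-truth generators. Every input the pipeline consumes can be
# produced here with known truth: DA training tables linking endpoint vectors
# to EC3, LLNA dose-response studies crossing SI = 3 at a known concentration,
# and raw per-assay fixtures that the endpoint calculators invert back to
# their targets.

# deterministic child seed for a named stream, so adding a generator never
# perturbs an existing one; kept well below 2^31
child_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 10007 + h) %% 2147483629) + 1L
}

#' Specification of a synthetic study population
#'
#' Defines the conditions under which synthetic chemicals are generated: the
#' range of true potencies, the monotone links from potency to each assay
#' endpoint, per-endpoint noise, and the LLNA simulation settings. Defaults
#' emulate the isothiazolinone-like regime: true log10 EC3 uniform on
#' [-3, 1.3] (EC3 from 0.001% to 20%), DPRA depletion declining with log10
#' EC3 through the 50-55% band, h-CLAT MIT spanning roughly 0.2-20 ug/mL,
#' and KeratinoSens Imax in the low single digits.
#'
#' @param n_chemicals Number of synthetic chemicals (default 80).
#' @param seed Master seed; all generators derive named child streams.
#' @param log10_ec3_range True log10 EC3 drawn uniformly on this interval.
#' @param link List of link parameters: `depletion_slope` (`a`),
#'   `depletion_mid` (`m`) for `100 / (1 + 10^(a (x - m)))`; `mit_slope`
#'   (`b`), `mit_intercept` (`c`) for `10^(b x + c)`; `imax_gain` (`d`) for
#'   `1 + d (1 - x / max(x-range))`.
#' @param noise_sd_log List of noise levels: `depletion` (additive percent
#'   sd), `mit`, `imax`, `ec3` (log10 sd of multiplicative noise).
#' @param llna List: `grid_mult` (dose grid as multiples of the study EC3
#'   centre), `hill` (Hill coefficient of the SI curve), `cv_log` (log10 sd
#'   of inter-study EC3 variability), `si_noise_log` (log10 sd of
#'   multiplicative SI measurement noise).
#' @param train_fraction Fraction of chemicals tagged `"train"`
#'   (default 0.75).
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_chemicals = 80L, seed = 1L,
                           log10_ec3_range = c(-3, 1.3),
                           link = list(depletion_slope = 0.35,
                                       depletion_mid = 0,
                                       mit_slope = 0.5, mit_intercept = 0.7,
                                       imax_gain = 1.5),
                           noise_sd_log = list(depletion = 5, mit = 0.2,
                                               imax = 0.2, ec3 = 0.2),
                           llna = list(grid_mult = c(0.25, 0.5, 1, 2, 4),
                                       hill = 1.5, cv_log = 0.2,
                                       si_noise_log = 0.02),
                           train_fraction = 0.75) {
  stopifnot(n_chemicals >= 4L, diff(log10_ec3_range) > 0,
            all(unlist(noise_sd_log) >= 0), llna$hill > 0,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_chemicals = as.integer(n_chemicals), seed = as.integer(seed),
                 log10_ec3_range = log10_ec3_range, link = link,
                 noise_sd_log = noise_sd_log, llna = llna,
                 train_fraction = train_fraction),
            class = "synthetic_spec")
}

# noiseless endpoint links (exported for oracle use in tests via :::)
.link_depletion <- function(x, link)
  100 / (1 + 10^(link$depletion_slope * (x - link$depletion_mid)))
.link_mit <- function(x, link)
  10^(link$mit_slope * x + link$mit_intercept)
.link_imax <- function(x, link, xmax)
  pmax(1, 1 + link$imax_gain * (1 - x / xmax))

#' Generate a synthetic DA training table
#'
#' Draws true log10 EC3 values uniformly over the specified range, maps them
#' through the monotone endpoint links with per-endpoint noise, and tags a
#' 75/25 train/test split. The observed `ec3` column carries multiplicative
#' lognormal noise around the true value. Deterministic given the spec's
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `chemical`, `avg_lys_cys`, `mit`, `imax`,
#'   `ec3`, `log10_ec3_true`, `split`.
#' @export
generate_training_table <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_chemicals
  link <- spec$link
  ns <- spec$noise_sd_log
  set.seed(child_seed(spec$seed, "training"))
  x <- stats::runif(n, spec$log10_ec3_range[1L], spec$log10_ec3_range[2L])
  xmax <- spec$log10_ec3_range[2L]

  dep <- .link_depletion(x, link) + stats::rnorm(n, 0, ns$depletion)
  dep <- pmin(100, pmax(0.5, dep))
  mit <- .link_mit(x, link) * 10^stats::rnorm(n, 0, ns$mit)
  imax <- pmax(1, 1 + (.link_imax(x, link, xmax) - 1) *
                 10^stats::rnorm(n, 0, ns$imax))
  ec3 <- 10^(x + stats::rnorm(n, 0, ns$ec3))

  n_train <- round(spec$train_fraction * n)
  split <- rep("test", n)
  split[sample.int(n, n_train)] <- "train"

  data.frame(chemical = sprintf("SYN%03d", seq_len(n)),
             avg_lys_cys = dep, mit = mit, imax = imax, ec3 = ec3,
             log10_ec3_true = x, split = split,
             stringsAsFactors = FALSE)
}

#' Simulate one LLNA study with a known EC3
#'
#' The study's own EC3 is the chemical's true EC3 perturbed by lognormal
#' inter-study variability; the stimulation index follows
#' `SI(c) = 1 + 2 (c / EC3_i)^h`, which equals 3 exactly at `c = EC3_i`, and
#' is evaluated on a dose grid centred on the study EC3 with optional
#' multiplicative measurement noise. Checklist flags default to all `TRUE`
#' and can be corrupted individually to exercise the acceptability screen.
#'
#' @param true_ec3 True EC3 in percent (positive).
#' @param spec A [synthetic_spec()] supplying the `llna` settings.
#' @param study_seed Integer seed for this study's draws.
#' @param chemical Chemical id recorded in the study.
#' @param failed_flags Character vector of checklist flags to set `FALSE`.
#' @return An [llna_study].
#' @export
simulate_llna_study <- function(true_ec3, spec = synthetic_spec(),
                                study_seed = 1L, chemical = "SYN001",
                                failed_flags = character()) {
  stopifnot(is.finite(true_ec3), true_ec3 > 0)
  ll <- spec$llna
  set.seed(study_seed)
  ec3_i <- true_ec3 * 10^stats::rnorm(1L, 0, ll$cv_log)
  conc <- sort(ec3_i * ll$grid_mult)
  conc <- pmin(conc, 100)
  conc <- conc[!duplicated(conc)]
  si <- 1 + 2 * (conc / ec3_i)^ll$hill
  if (ll$si_noise_log > 0)
    si <- si * 10^stats::rnorm(length(si), 0, ll$si_noise_log)
  flags <- NULL
  if (length(failed_flags))
    flags <- stats::setNames(rep(FALSE, length(failed_flags)), failed_flags)
  study <- llna_study(chemical, conc, si, vehicle = "AOO", flags = flags,
                      source = "synthetic", study_id = paste0("sim", study_seed))
  study$true_ec3 <- ec3_i
  study
}

#' Generate raw assay fixtures reproducing target endpoint values
#'
#' For each chemical in `truth`, emits raw-format records for the three
#' assays whose endpoint calculators recover the stated targets: DPRA HPLC
#' peak areas reproducing the target depletions; a 12-point twofold
#' KeratinoSens dilution series whose Hill-shaped induction curve crosses
#' 1.5-fold at the target EC1.5; and two h-CLAT runs on the 1.2-fold dose
#' series whose viability crosses 75% at the target CV75 and whose CD86 RFI
#' crosses 150% at the target MIT. A target MIT below the lowest dose of the
#' series yields a run that is positive at the lowest concentration with an
#' undefined crossing; such fixtures are flagged `infeasible_mit`.
#'
#' @param truth Data frame with columns `chemical`, `cys_depletion`,
#'   `lys_depletion`, `ks_ec15` (uM), `ks_imax` (> 1.5), `cv75` (ug/mL),
#'   `mit` (ug/mL), `solvent` (`"PBS"`/`"DMSO"`).
#' @param spec A [synthetic_spec()] (reserved for noise settings; fixtures
#'   are deterministic).
#' @return List of class `"assay_fixtures"` with data frames `dpra`,
#'   `keratinosens`, `hclat` matching the documented CSV schemas, and
#'   `flags` (per-chemical feasibility notes).
#' @export
generate_assay_fixtures <- function(truth, spec = synthetic_spec()) {
  need <- c("chemical", "cys_depletion", "lys_depletion", "ks_ec15",
            "ks_imax", "cv75", "mit", "solvent")
  miss <- setdiff(need, names(truth))
  if (length(miss))
    stop("truth is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  dpra_rows <- list(); ks_rows <- list(); hclat_rows <- list()
  flags <- character(0)

  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    chem <- tr$chemical

    # DPRA: control area 1000, sample area set to give the target depletion
    for (pep in c("cys", "lys")) {
      dep <- tr[[paste0(pep, "_depletion")]]
      coel <- is.na(dep)
      dpra_rows[[length(dpra_rows) + 1L]] <- data.frame(
        chemical = chem, replicate = 1L, peptide = pep,
        area_sample = if (coel) NA_real_ else 1000 * (1 - dep / 100),
        area_control = 1000, coeluted = coel)
    }

    # KeratinoSens: 12 twofold dilutions; Hill curve through 1.5 at ks_ec15
    if (tr$ks_imax <= 1.5)
      stop("ks_imax must exceed 1.5 to place an EC1.5", call. = FALSE)
    start <- max(2000, tr$ks_ec15 * 8)
    conc <- start / 2^(11:0)
    h <- 2
    K <- tr$ks_ec15 * (2 * (tr$ks_imax - 1) - 1)^(1 / h)
    fold <- 1 + (tr$ks_imax - 1) * conc^h / (conc^h + K^h)
    viab <- 100 - 10 * (conc / max(conc))  # mild cytotoxicity, stays > 70
    ks_rows[[length(ks_rows) + 1L]] <- data.frame(
      chemical = chem, plate = 1L, repetition = 1L,
      conc_uM = conc, fold_induction = fold, viability_pct = viab)

    # h-CLAT: two runs on the 1.2-fold series from CV75
    doses <- sort(hclat_dose_series(tr$cv75, tr$solvent))
    viab_run <- 100 / (1 + (doses / tr$cv75)^3 / 3)  # = 75 at CV75
    cd86 <- 100 + 50 * (doses / tr$mit)^2            # = 150 at MIT
    cd54 <- 100 + 30 * pmin((doses / tr$mit)^2, 2)   # stays below 200
    if (tr$mit < min(doses))
      flags <- c(flags, sprintf("%s: infeasible_mit (below lowest dose)", chem))
    if (tr$mit > max(doses))
      flags <- c(flags, sprintf("%s: infeasible_mit (above dose-series cap)", chem))
    for (run in 1:2)
      hclat_rows[[length(hclat_rows) + 1L]] <- data.frame(
        chemical = chem, run = run, conc_ug_ml = doses,
        cd86_rfi = cd86, cd54_rfi = cd54, viability_pct = viab_run)
  }

  structure(list(dpra = do.call(rbind, dpra_rows),
                 keratinosens = do.call(rbind, ks_rows),
                 hclat = do.call(rbind, hclat_rows),
                 flags = flags),
            class = "assay_fixtures")
}
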