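#' Dose-response series
#'
#' Light container for an ordered concentration-response series, the common
#' currency of all interpolation-based endpoints (EC1.5, CV75, EC150, EC200,
#' EC3). Concentrations must be strictly increasing and positive; responses
#' are paired one-to-one.
#'
#' @param concentration Numeric vector of positive, strictly increasing
#'   concentrations.
#' @param response Numeric vector of responses, same length.
#' @param unit Concentration unit tag: `"uM"`, `"ug/mL"` or `"pct"` (% w/v).
#' @param kind Response kind: one of `"fold_induction"`, `"viability_percent"`,
#'   `"rfi_percent"`, `"depletion_percent"`, `"stimulation_index"`.
#' @return An object of class `"dose_response"`: a list with elements
#'   `concentration`, `response`, `unit`, `kind`.
#' @examples
#' dose_response(c(125, 250, 500, 1000), c(1.0, 1.2, 1.6, 2.4),
#'               unit = "uM", kind = "fold_induction")
#' @export
dose_response <- function(concentration, response,
                          unit = c("uM", "ug/mL", "pct"),
                          kind = c("fold_induction", "viability_percent",
                                   "rfi_percent", "depletion_percent",
                                   "stimulation_index")) {
  unit <- match.arg(unit)
  kind <- match.arg(kind)
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) < 2L)
    stop("a dose-response series needs at least 2 concentrations", call. = FALSE)
  if (length(response) != length(concentration))
    stop("concentration and response must have the same length", call. = FALSE)
  if (anyNA(concentration) || anyNA(response))
    stop("concentration and response must be complete (no NA)", call. = FALSE)
  if (any(concentration <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing", call. = FALSE)
  if (kind %in% c("viability_percent", "rfi_percent") && any(response < 0))
    stop("percent responses must be non-negative", call. = FALSE)
  structure(list(concentration = concentration, response = response,
                 unit = unit, kind = kind),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response series (%s, %d concentrations in %s)\n",
              x$kind, length(x$concentration), x$unit))
  print(data.frame(concentration = x$concentration, response = x$response),
        row.names = FALSE)
  invisible(x)
}

as_dose_response <- function(x, unit, kind) {
  if (inherits(x, "dose_response")) return(x)
  dose_response(x[[1L]], x[[2L]], unit = unit, kind = kind)
}

#' Lowest concentration at which a response series crosses a threshold
#'
#' Shared interpolator behind EC1.5 (KeratinoSens), CV75, EC150 and EC200
#' (h-CLAT). The series is treated as a piecewise-linear function of
#' concentration, either on the arithmetic scale or on log10 concentration
#' (the conventional scale for serially diluted in vitro series). The lowest
#' concentration at which the interpolant crosses `threshold` in the stated
#' direction is returned; a response exactly equal to the threshold at a
#' tested concentration returns that concentration. With no crossing the
#' result is `NA` -- "no crossing" is a value, not an error.
#'
#' For non-monotone series several crossings can exist; the lowest
#' concentration wins, which is the conservative (most potent) convention.
#' A series that already sits beyond the threshold at its lowest tested
#' concentration has no crossing within the tested range and returns `NA`
#' (callers flag this case, e.g. "positive at lowest dose").
#'
#' @param series A [dose_response] object (or a list/data.frame whose first
#'   two columns are concentration and response).
#' @param threshold Finite numeric threshold on the response scale.
#' @param direction `"up"` for crossings from below, `"down"` for crossings
#'   from above (e.g. viability falling through 75%).
#' @param scale `"log"` (default) interpolates linearly in log10
#'   concentration; `"linear"` in arithmetic concentration.
#' @return The crossing concentration, or `NA_real_` if none.
#' @examples
#' s <- dose_response(c(10, 20), c(1, 2), unit = "uM", kind = "fold_induction")
#' crossing_concentration(s, 1.5, "up", "linear")  # 15
#' @export
crossing_concentration <- function(series, threshold,
                                   direction = c("up", "down"),
                                   scale = c("log", "linear")) {
  direction <- match.arg(direction)
  scale <- match.arg(scale)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (!inherits(series, "dose_response"))
    series <- as_dose_response(series, unit = "uM", kind = "fold_induction")
  conc <- series$concentration
  resp <- series$response
  x <- if (scale == "log") log10(conc) else conc

  hit <- function(i) conc[i]
  if (direction == "up") {
    if (resp[1L] == threshold) return(hit(1L))
    for (i in seq_len(length(conc) - 1L)) {
      a <- resp[i]; b <- resp[i + 1L]
      if (a < threshold && b >= threshold) {
        if (b == threshold) return(hit(i + 1L))
        xc <- x[i] + (threshold - a) / (b - a) * (x[i + 1L] - x[i])
        return(if (scale == "log") 10^xc else xc)
      }
    }
  } else {
    if (resp[1L] == threshold) return(hit(1L))
    for (i in seq_len(length(conc) - 1L)) {
      a <- resp[i]; b <- resp[i + 1L]
      if (a > threshold && b <= threshold) {
        if (b == threshold) return(hit(i + 1L))
        xc <- x[i] + (threshold - a) / (b - a) * (x[i + 1L] - x[i])
        return(if (scale == "log") 10^xc else xc)
      }
    }
  }
  NA_real_
}
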