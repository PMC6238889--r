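#' Configuration of the counterfactual ("no walking") curve model
#'
#' The per-person counterfactual diurnal glucose curve is a smooth baseline
#' plus three postprandial excursions, anchored so that its time average
#' equals the estimated average glucose (eAG) for the person's HbA1c under
#' the linear eAG convention (mg/dl = 28.7 x HbA1c - 46.7).
#'
#' @param meal_times Minutes-since-midnight of the three meals
#'   (default 08:00, 12:00, 18:00).
#' @param peak_width Gaussian width of each postprandial excursion, minutes.
#' @param peak_amplitude Excursion amplitude (mg/dl) at the low end of the
#'   supported HbA1c range (5.9).
#' @param amplitude_slope Additional amplitude (mg/dl) per percentage point
#'   of HbA1c above 5.9; higher-HbA1c days swing harder.
#' @param eag_slope,eag_intercept Coefficients of the linear HbA1c to
#'   mean-glucose mapping (mg/dl per percent, mg/dl).
#' @return An object of class `curve_config`.
#' @export
#' @examples
#' cfg <- curve_config()
#' cfg$meal_times
curve_config <- function(meal_times = c(480, 720, 1080),
                         peak_width = 45,
                         peak_amplitude = 40,
                         amplitude_slope = 10,
                         eag_slope = 28.7,
                         eag_intercept = -46.7) {
  if (any(meal_times < 0 | meal_times >= 1440)) {
    stopf("meal_times must lie in [0, 1440)", class = "glywalk_bad_config")
  }
  if (peak_amplitude < 0 || amplitude_slope < 0 || peak_width <= 0) {
    stopf("amplitudes must be >= 0 and peak_width > 0", class = "glywalk_bad_config")
  }
  if (eag_slope <= 0) {
    stopf("eag_slope must be > 0", class = "glywalk_bad_config")
  }
  structure(list(meal_times = meal_times, peak_width = peak_width,
                 peak_amplitude = peak_amplitude,
                 amplitude_slope = amplitude_slope,
                 eag_slope = eag_slope, eag_intercept = eag_intercept),
            class = "curve_config")
}

A1C_MIN <- 5.9
A1C_MAX <- 10.1

# unit meal-excursion shape on arbitrary times (vectorised over t)
meal_shape <- function(t, config) {
  s <- numeric(length(t))
  for (m in config$meal_times) {
    s <- s + exp(-0.5 * ((t - m) / config$peak_width)^2)
  }
  s
}

eag <- function(hba1c, config) {
  config$eag_slope * hba1c + config$eag_intercept
}

#' Build the counterfactual diurnal glucose curve for one HbA1c value
#'
#' Returns the modelled 24-hour "no walking" glucose trajectory on the fixed
#' 15-minute grid. The curve's time mean equals the estimated average glucose
#' for the given HbA1c exactly; meal-associated rises appear at the
#' configured meal times and their amplitude grows with HbA1c.
#'
#' @param hba1c HbA1c in percent, within [5.9, 10.1] (the supported range).
#' @param config A [curve_config()].
#' @return Object of class `diurnal_curve` with elements `hba1c`, `times`
#'   (minutes since midnight) and `values` (glucose, mg/dl).
#' @export
#' @examples
#' crv <- build_curve(7.0)
#' mean(crv$values)  # 154.2 = 28.7 * 7 - 46.7
build_curve <- function(hba1c, config = curve_config()) {
  if (!is.numeric(hba1c) || length(hba1c) != 1L || !is.finite(hba1c)) {
    stopf("hba1c must be a single finite number", class = "glywalk_bad_a1c")
  }
  if (hba1c < A1C_MIN || hba1c > A1C_MAX) {
    stopf("hba1c = %g is outside the supported range [%.1f, %.1f]",
          hba1c, A1C_MIN, A1C_MAX, class = "glywalk_bad_a1c")
  }
  times <- glucose_grid()
  shp <- meal_shape(times, config)
  amp <- config$peak_amplitude + config$amplitude_slope * (hba1c - A1C_MIN)
  # centre the excursions so the grid mean is the eAG exactly
  values <- eag(hba1c, config) + amp * (shp - mean(shp))
  if (any(values <= 0)) {
    stopf("configuration yields non-positive glucose values",
          class = "glywalk_bad_config")
  }
  structure(list(hba1c = hba1c, times = times, values = values,
                 config = config),
            class = "diurnal_curve")
}

#' Area under a glucose curve by the 15-minute rectangle rule
#'
#' The AUC of a day-long curve sampled at 15-minute intervals is the sum of
#' the 96 values multiplied by 15, in mg/dl x min. This is the rectangle
#' rule on the left-closed grid, and is exact for the package's convention
#' (no trapezoid correction).
#'
#' @param x A `diurnal_curve` or a numeric vector of 96 glucose values.
#' @return AUC in mg/dl x min.
#' @export
#' @examples
#' curve_auc(rep(100, 96))  # 144000
curve_auc <- function(x) {
  v <- if (inherits(x, "diurnal_curve")) x$values else x
  if (!is.numeric(v) || length(v) != GRID_N || !all(is.finite(v))) {
    stopf("curve must be %d finite glucose values", GRID_N,
          class = "glywalk_invalid_curve")
  }
  sum(v) * GRID_STEP
}

#' The full bank of supported curves (HbA1c 5.9 to 10.1, step 0.1)
#'
#' @param config A [curve_config()].
#' @return Named list mapping HbA1c strings ("5.9" ... "10.1") to 96-value
#'   glucose vectors.
#' @export
curve_bank <- function(config = curve_config()) {
  a1c <- seq(59L, 101L) / 10
  bank <- lapply(a1c, function(a) build_curve(a, config)$values)
  names(bank) <- sprintf("%.1f", a1c)
  bank
}

#' Export / import a curve bank as JSON
#'
#' The bank is stored as a JSON object mapping HbA1c strings to arrays of 96
#' glucose values, so precomputed curves can be shared with other tools.
#'
#' @param bank A list as returned by [curve_bank()].
#' @param path File path.
#' @return `read_curve_bank()` returns the bank; `write_curve_bank()` the
#'   path, invisibly.
#' @export
write_curve_bank <- function(bank, path) {
  jsonlite::write_json(bank, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_curve_bank
#' @export
read_curve_bank <- function(path) {
  bank <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(bank, as.numeric)
}

#' @export
print.diurnal_curve <- function(x, ...) {
  cat(sprintf("Diurnal glucose curve (HbA1c %.1f%%)\n", x$hba1c))
  cat(sprintf("  96 points, 15-min grid; mean %.1f mg/dl, range [%.1f, %.1f]\n",
              mean(x$values), min(x$values), max(x$values)))
  cat(sprintf("  AUC %.0f mg/dl x min\n", curve_auc(x)))
  invisible(x)
}

#' @export
plot.diurnal_curve <- function(x, ...) {
  plot(x$times / 60, x$values, type = "l", lwd = 2,
       xlab = "Hour of day", ylab = "Glucose (mg/dl)",
       main = sprintf("Counterfactual curve, HbA1c %.1f%%", x$hba1c), ...)
  abline(v = x$config$meal_times / 60, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
as.data.frame.diurnal_curve <- function(x, ...) {
  data.frame(time_min = x$times, glucose_mgdl = x$values)
}
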