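#' A participant-drawn glucose trajectory
#'
#' Drawings start at or after 9 AM (the walk in the drawing prompt starts at
#' 9 AM) and consist of ordered time/glucose points. Times need not fall on
#' the 15-minute grid; they are resampled at splice time.
#'
#' @param time_min Times in minutes since midnight, strictly increasing,
#'   within [540, 1440).
#' @param glucose_mgdl Finite glucose values (mg/dl), same length.
#' @return Object of class `drawn_trajectory` (a data frame).
#' @export
#' @examples
#' drawn_trajectory(c(540, 720, 1080), c(150, 120, 130))
drawn_trajectory <- function(time_min = numeric(), glucose_mgdl = numeric()) {
  if (length(time_min) != length(glucose_mgdl)) {
    stopf("time and glucose vectors must have equal length",
          class = "glywalk_bad_drawing")
  }
  if (length(time_min)) {
    if (any(!is.finite(time_min)) || any(!is.finite(glucose_mgdl))) {
      stopf("drawn points must be finite", class = "glywalk_bad_drawing")
    }
    if (any(diff(time_min) <= 0)) {
      stopf("drawn times must be strictly increasing",
            class = "glywalk_bad_drawing")
    }
    if (time_min[1] < 540 || time_min[length(time_min)] >= 1440) {
      stopf("drawn times must lie in [540, 1440)", class = "glywalk_bad_drawing")
    }
  }
  structure(data.frame(time_min = as.numeric(time_min),
                       glucose_mgdl = as.numeric(glucose_mgdl)),
            class = c("drawn_trajectory", "data.frame"))
}

#' Splice a drawing onto the counterfactual day
#'
#' Reconstructs the full-day glucose sequence a drawing implies: grid points
#' before 9 AM take the counterfactual values; points within the drawn span
#' are linearly resampled from the drawn points; points after the last drawn
#' point are interpolated linearly from the last drawn value to the
#' counterfactual's midnight value (its period-boundary value at 00:00). If
#' the drawing starts after 9 AM, values in between are interpolated from
#' the counterfactual's 9 AM value to the first drawn point.
#'
#' @param drawing A [drawn_trajectory()].
#' @param counterfactual A `diurnal_curve`.
#' @return Numeric vector of 96 glucose values on the grid.
#' @export
splice_drawing <- function(drawing, counterfactual) {
  if (!inherits(drawing, "drawn_trajectory")) {
    drawing <- drawn_trajectory(drawing$time_min, drawing$glucose_mgdl)
  }
  if (nrow(drawing) == 0L) {
    stopf("drawing has no points; an empty drawing cannot be scored",
          class = "glywalk_empty_drawing")
  }
  if (!inherits(counterfactual, "diurnal_curve")) {
    stopf("counterfactual must be a diurnal_curve", class = "glywalk_bad_input")
  }
  times <- counterfactual$times
  cf <- counterfactual$values
  midnight_value <- cf[1]       # period boundary: the curve's 00:00 level
  knots_x <- drawing$time_min
  knots_y <- drawing$glucose_mgdl
  if (knots_x[1] > 540) {
    knots_x <- c(540, knots_x)
    knots_y <- c(cf[match(540, times)], knots_y)
  }
  knots_x <- c(knots_x, 1440)
  knots_y <- c(knots_y, midnight_value)
  out <- cf
  post <- times >= 540
  out[post] <- approx(knots_x, knots_y, xout = times[post])$y
  out
}

#' Score a drawing as an outcome-expectancy measure
#'
#' The drawn AUC is the rectangle-rule AUC of the spliced full-day sequence;
#' the AUC decrease is the counterfactual AUC minus the drawn AUC, stored
#' with expected improvements positive.
#'
#' @inheritParams splice_drawing
#' @return Object of class `expectancy_measure` with `drawn_auc`,
#'   `auc_decrease` (both mg/dl x min) and `min_spliced` (mg/dl, used by the
#'   outlier rule).
#' @export
#' @examples
#' cf <- build_curve(7.3)
#' d <- drawn_trajectory(cf$times[cf$times >= 540],
#'                       cf$values[cf$times >= 540] - 10)
#' expectancy(d, cf)$auc_decrease  # 10 mg/dl below for 15 h
expectancy <- function(drawing, counterfactual) {
  spliced <- splice_drawing(drawing, counterfactual)
  drawn_auc <- curve_auc(spliced)
  structure(list(drawn_auc = drawn_auc,
                 auc_decrease = curve_auc(counterfactual) - drawn_auc,
                 min_spliced = min(spliced)),
            class = "expectancy_measure")
}

#' Outlier rule for extreme drawings
#'
#' A drawing is flagged when the magnitude of its implied AUC change exceeds
#' a threshold, or when the spliced sequence implies non-positive glucose.
#' The published study excluded extreme drawings by human-coder consensus;
#' this reproducible rule stands in for that judgement and its threshold is
#' configurable.
#'
#' @param threshold Absolute AUC-decrease threshold in mg/dl x min
#'   (default 50,000).
#' @return Object of class `outlier_rule`.
#' @export
outlier_rule <- function(threshold = 50000) {
  if (threshold <= 0) stopf("threshold must be > 0", class = "glywalk_bad_config")
  structure(list(threshold = threshold), class = "outlier_rule")
}

#' Flag an extreme drawing
#'
#' @param measure An `expectancy_measure`, or a numeric vector of AUC
#'   decreases (in which case only the threshold part of the rule applies).
#' @param rule An [outlier_rule()].
#' @return Logical.
#' @export
flag_outlier <- function(measure, rule = outlier_rule()) {
  if (inherits(measure, "expectancy_measure")) {
    return(abs(measure$auc_decrease) > rule$threshold ||
             measure$min_spliced <= 0)
  }
  if (!is.numeric(measure) || any(!is.finite(measure))) {
    stopf("measure must be finite", class = "glywalk_bad_input")
  }
  abs(measure) > rule$threshold
}

#' Read / write a drawing
#'
#' Drawings interchange as two-column CSV (`time_min`, `glucose_mgdl`) or as
#' a JSON object of two arrays.
#'
#' @param drawing A [drawn_trajectory()].
#' @param path File path; format inferred from the extension (`.csv` or
#'   `.json`).
#' @return `read_drawing()` returns a `drawn_trajectory`;
#'   `write_drawing()` the path, invisibly.
#' @export
write_drawing <- function(drawing, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(time_min = drawing$time_min,
                              glucose_mgdl = drawing$glucose_mgdl),
                         path, digits = NA)
  } else {
    write.csv(as.data.frame(unclass(drawing)), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_drawing
#' @export
read_drawing <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    drawn_trajectory(x$time_min, x$glucose_mgdl)
  } else {
    x <- read.csv(path)
    drawn_trajectory(x$time_min, x$glucose_mgdl)
  }
}

#' @export
print.expectancy_measure <- function(x, ...) {
  cat(sprintf("Outcome expectancy: drawn AUC %.0f, AUC decrease %.0f mg/dl x min\n",
              x$drawn_auc, x$auc_decrease))
  invisible(x)
}
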