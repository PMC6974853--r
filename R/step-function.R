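#' Right-continuous step functions for survival curves and cumulative hazards
#'
#' Light container used throughout the package for Kaplan-Meier curves and
#' Breslow cumulative hazards: a value at time 0 and a new value after each
#' knot. Survivor functions start at 1 and are nonincreasing; cumulative
#' hazards start at 0 and are nondecreasing.
#'
#' @param knots strictly increasing event times
#' @param values function value attained at (and after) each knot
#' @param initial value on `[0, knots[1])`
#' @param type `"survival"` or `"cumhaz"`; checked monotonicity differs
#' @return an object of class `step_function`
#' @export
step_function <- function(knots, values, initial, type = c("survival", "cumhaz")) {
  type <- match.arg(type)
  knots <- as.numeric(knots)
  values <- as.numeric(values)
  if (length(knots) != length(values))
    stop("knots and values must have equal length")
  if (length(knots) && any(diff(knots) <= 0))
    stop("knots must be strictly increasing")
  vals <- c(initial, values)
  if (type == "survival") {
    if (abs(initial - 1) > 1e-12) stop("survivor function must start at 1")
    if (any(diff(vals) > 1e-12) || any(vals < -1e-12) || any(vals > 1 + 1e-12))
      stop("survivor function values must be nonincreasing in [0, 1]")
  } else {
    if (any(diff(vals) < -1e-12))
      stop("cumulative hazard must be nondecreasing")
  }
  structure(list(knots = knots, values = values, initial = initial, type = type),
            class = "step_function")
}

#' Evaluate a step function
#'
#' @param sf a [step_function]
#' @param t times (vector)
#' @param left if `TRUE`, return the left limit at each `t` (value just
#'   before `t`), used e.g. for censoring weights `G(t-)`
#' @return numeric vector of the same length as `t`
#' @export
step_eval <- function(sf, t, left = FALSE) {
  stopifnot(inherits(sf, "step_function"))
  idx <- findInterval(t, sf$knots, left.open = left)
  c(sf$initial, sf$values)[idx + 1L]
}

#' Median crossing time of a survivor-type step function
#'
#' Smallest knot at which the curve reaches 0.5 or less; `NA` when the curve
#' never crosses 0.5 (e.g. heavy late censoring).
#' @param sf a [step_function]
#' @return a single time or `NA`
#' @export
step_median <- function(sf) {
  i <- which(sf$values <= 0.5)
  if (!length(i)) return(NA_real_)
  sf$knots[min(i)]
}

#' @export
print.step_function <- function(x, ...) {
  cat(sprintf("step_function (%s): %d knots on [%.4g, %.4g], range [%.4g, %.4g]\n",
              x$type, length(x$knots),
              if (length(x$knots)) min(x$knots) else NA,
              if (length(x$knots)) max(x$knots) else NA,
              min(c(x$initial, x$values)), max(c(x$initial, x$values))))
  invisible(x)
}
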