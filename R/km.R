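#' Kaplan-Meier survivor curve
#'
#' Product-limit estimator over the observed event times; ties at a time are
#' handled by a single simultaneous factor. Thin wrapper around
#' [survival::survfit()] returning the package's [step_function] container.
#'
#' @param times positive follow-up times
#' @param status event indicator (1 event, 0 censored)
#' @return a [step_function] of type `"survival"` with knots at event times
#' @export
km_estimate <- function(times, status) {
  if (!length(times)) stop("empty input")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(status %in% c(0, 1))) stop("status must be binary")
  fit <- survival::survfit(survival::Surv(times, status) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  step_function(fit$time[keep], fit$surv[keep], 1, "survival")
}

#' Censoring survivor curve (reverse Kaplan-Meier)
#'
#' Kaplan-Meier with the censoring indicator as the event; estimates the
#' censoring distribution `G(t)`. Its median crossing time is the standard
#' "median follow-up" summary.
#'
#' @inheritParams km_estimate
#' @return list with `curve` (a [step_function]) and `median` (median
#'   follow-up, `NA` if the curve never reaches 0.5)
#' @export
censoring_km <- function(times, status) {
  curve <- km_estimate(times, 1 - status)
  list(curve = curve, median = step_median(curve))
}
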