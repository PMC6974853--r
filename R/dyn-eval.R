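# Dynamic performance of landmark predictions: window-restricted Harrell
# concordance, IPCW Brier prediction-error against a conditional KM null,
# and cumulative/dynamic time-dependent AUC. The score-level workhorses are
# exported so any risk score can be evaluated; the fit-level wrappers score
# subjects with x'beta_LM(s) + gamma(s) from a fitted supermodel.

#' Window-restricted concordance at one landmark
#'
#' Harrell-type concordance among subjects at risk at `s`, using only pairs
#' whose earlier event time falls inside the window `(s, s+w]`: for every
#' event at `t_i` in the window, comparable partners are subjects still
#' under observation beyond `t_i`; a pair is concordant when the event case
#' carries the higher risk score. Ties in score count 1/2.
#'
#' @param time,status follow-up and event indicator for the full cohort
#' @param score risk score (higher = riskier)
#' @param s landmark
#' @param w window width
#' @return list with `concordant` (tie-corrected count), `pairs`, and
#'   `cindex` (`NA` when no usable pairs)
#' @export
window_cindex <- function(time, status, score, s, w) {
  at <- time > s
  time <- time[at]; status <- status[at]; score <- score[at]
  ev <- which(status == 1 & time <= s + w)
  conc <- 0; pairs <- 0
  for (i in ev) {
    comp <- time > time[i]
    npair <- sum(comp)
    if (!npair) next
    conc <- conc + sum(score[i] > score[comp]) + 0.5 * sum(score[i] == score[comp])
    pairs <- pairs + npair
  }
  list(concordant = conc, pairs = pairs,
       cindex = if (pairs > 0) conc / pairs else NA_real_)
}

#' IPCW Brier score at the window horizon, at one landmark
#'
#' Among subjects at risk at `s`, the mean inverse-probability-of-censoring
#' weighted squared difference between the window death indicator
#' `1{T <= s+w}` and the predicted probability: subjects observed to die by
#' the horizon get weight `G(s)/G(T-)`, subjects still under observation at
#' the horizon get `G(s)/G(s+w)`, subjects censored inside the window get
#' weight 0. `G` is the censoring survivor curve of the full cohort; the
#' `G(s)` numerator conditions it on being uncensored at the landmark.
#'
#' @inheritParams window_cindex
#' @param prob predicted window death probabilities (recycled if scalar)
#' @param G censoring [step_function] (see [censoring_km()])
#' @return the Brier score (single number)
#' @export
window_brier <- function(time, status, prob, s, w, G) {
  at <- time > s
  time <- time[at]; status <- status[at]
  prob <- rep_len(prob, length(at))[at]
  hor <- s + w
  Gs <- step_eval(G, s)
  Ghor <- step_eval(G, hor)
  died <- status == 1 & time <= hor
  alive <- time > hor
  if (any(alive) && Ghor <= 0)
    stop("censoring survivor function is zero at the horizon; ",
         "IPCW weights inestimable at s = ", format(s))
  wt <- numeric(length(time))
  if (any(died)) {
    Gt <- step_eval(G, time[died], left = TRUE)
    if (any(Gt <= 0))
      stop("censoring survivor function is zero before an event; ",
           "IPCW weights inestimable at s = ", format(s))
    wt[died] <- Gs / Gt
  }
  if (any(alive)) wt[alive] <- Gs / Ghor
  D <- as.numeric(died)
  mean(wt * (D - prob)^2)
}

#' IPCW cumulative/dynamic AUC at the window horizon, at one landmark
#'
#' Probability that a case (event in `(s, s+w]`) carries a higher risk
#' score than a control (survives beyond `s+w`), among subjects at risk at
#' `s`, with inverse-probability-of-censoring weights; score ties count 1/2.
#'
#' @inheritParams window_brier
#' @return list with `auc` (`NA` when no cases or no controls), `n_cases`,
#'   `n_controls`
#' @export
window_auc <- function(time, status, score, s, w, G) {
  at <- time > s
  time <- time[at]; status <- status[at]; score <- score[at]
  hor <- s + w
  cases <- which(status == 1 & time <= hor)
  controls <- which(time > hor)
  if (!length(cases) || !length(controls))
    return(list(auc = NA_real_, n_cases = length(cases),
                n_controls = length(controls)))
  Gs <- step_eval(G, s)
  Gt <- step_eval(G, time[cases], left = TRUE)
  Ghor <- step_eval(G, hor)
  if (Ghor <= 0 || any(Gt <= 0))
    stop("censoring survivor function is zero inside the window; ",
         "IPCW weights inestimable at s = ", format(s))
  wi <- Gs / Gt
  # the control weight G(s)/G(s+w) is constant, so it cancels in the ratio
  num <- 0
  for (k in seq_along(cases)) {
    sc <- score[cases[k]]
    num <- num + wi[k] * (sum(sc > score[controls]) +
                            0.5 * sum(sc == score[controls]))
  }
  list(auc = num / (sum(wi) * length(controls)),
       n_cases = length(cases), n_controls = length(controls))
}

# risk scores x'beta_LM(s) + gamma(s) for every cohort row at landmark s
landmark_scores <- function(fit, cohort, s) {
  X <- as.matrix(as.data.frame(cohort)[, fit$covariates, drop = FALSE])
  blm <- vapply(fit$covariates, function(cv)
    beta_lm(fit, s, covariate = cv)$estimate, numeric(1))
  sc <- drop(X %*% blm)
  if (fit$kind == "proportional") sc <- sc + gamma_at(fit, s)$estimate
  sc
}

#' Dynamic concordance curve
#'
#' [window_cindex()] at every landmark of the design, scoring subjects with
#' `x' beta_LM(s) + gamma(s)`. The per-landmark value pools all usable
#' pairs across event times in the window; the summary averages the
#' per-landmark values with equal weights (default) or with window event
#' counts, and the fully pooled ratio is reported as well. Landmarks
#' without usable pairs are `NA` and excluded from summaries.
#'
#' @param fit a `dl_supermodel`
#' @param cohort data frame with `time`, `status` and the fit's covariates
#' @param design a [landmark_design] (default: the fit's)
#' @param weights `"equal"` or `"events"` for the summary average
#' @return list with `per_landmark` (data frame `s`, `cindex`, `pairs`,
#'   `events`), `mean_c`, `pooled_c`
#' @export
dynamic_cindex <- function(fit, cohort, design = fit$design,
                           weights = c("equal", "events")) {
  weights <- match.arg(weights)
  df <- as.data.frame(cohort)
  res <- lapply(design$grid, function(s) {
    ci <- window_cindex(df$time, df$status, landmark_scores(fit, df, s),
                        s, design$w)
    nev <- sum(df$time > s & df$status == 1 & df$time <= s + design$w)
    data.frame(s = s, cindex = ci$cindex, concordant = ci$concordant,
               pairs = ci$pairs, events = nev)
  })
  per <- do.call(rbind, res)
  ok <- !is.na(per$cindex)
  wts <- if (weights == "equal") rep(1, sum(ok)) else per$events[ok]
  list(per_landmark = per,
       mean_c = sum(per$cindex[ok] * wts) / sum(wts),
       pooled_c = sum(per$concordant[ok]) / sum(per$pairs[ok]))
}

#' Dynamic prediction-error (Brier) curves
#'
#' [window_brier()] at every landmark, for the model's
#' [dynamic_death_probability()] and for the Kaplan-Meier null (the
#' conditional KM window death probability `1 - S(s+w)/S(s)`, one number
#' for everyone). Censoring weights come from the reverse-KM curve of the
#' full cohort.
#'
#' @inheritParams dynamic_cindex
#' @return data frame with `s`, `brier_model`, `brier_null`
#' @export
prediction_error_curve <- function(fit, cohort, design = fit$design) {
  df <- as.data.frame(cohort)
  G <- censoring_km(df$time, df$status)$curve
  S <- km_estimate(df$time, df$status)
  X <- as.matrix(df[, fit$covariates, drop = FALSE])
  out <- lapply(design$grid, function(s) {
    p_model <- dynamic_death_probability(fit, X, s)
    p_null <- 1 - step_eval(S, s + design$w) / step_eval(S, s)
    data.frame(s = s,
               brier_model = window_brier(df$time, df$status, p_model,
                                          s, design$w, G),
               brier_null = window_brier(df$time, df$status, p_null,
                                         s, design$w, G))
  })
  do.call(rbind, out)
}

#' Dynamic time-dependent AUC curve
#'
#' [window_auc()] at every landmark with the fit's risk scores.
#'
#' @inheritParams dynamic_cindex
#' @return data frame with `s`, `auc`, `n_cases`, `n_controls`
#' @export
dynamic_auc <- function(fit, cohort, design = fit$design) {
  df <- as.data.frame(cohort)
  G <- censoring_km(df$time, df$status)$curve
  out <- lapply(design$grid, function(s) {
    a <- window_auc(df$time, df$status, landmark_scores(fit, df, s),
                    s, design$w, G)
    data.frame(s = s, auc = a$auc, n_cases = a$n_cases,
               n_controls = a$n_controls)
  })
  do.call(rbind, out)
}

#' All dynamic evaluation curves in one table
#'
#' Convenience wrapper returning the per-landmark `cindex`, `brier_model`,
#' `brier_null` and `auc` columns side by side, plus the concordance
#' summaries as attributes `mean_c` and `pooled_c`.
#'
#' @inheritParams dynamic_cindex
#' @return data frame of class `dl_dyncurves`
#' @export
dynamic_evaluation <- function(fit, cohort, design = fit$design) {
  ci <- dynamic_cindex(fit, cohort, design)
  pe <- prediction_error_curve(fit, cohort, design)
  au <- dynamic_auc(fit, cohort, design)
  out <- data.frame(s = ci$per_landmark$s,
                    cindex = ci$per_landmark$cindex,
                    brier_model = pe$brier_model,
                    brier_null = pe$brier_null,
                    auc = au$auc)
  attr(out, "mean_c") <- ci$mean_c
  attr(out, "pooled_c") <- ci$pooled_c
  class(out) <- c("dl_dyncurves", "data.frame")
  out
}
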