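#' Fit a Cox proportional hazards model
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with
#' step-halving (convergence when the relative log-likelihood change falls
#' below `1e-9`, at most 100 iterations). Supports delayed entry
#' (left truncation) through `entry`, and an optional cluster id for a
#' sandwich (robust) covariance. The Breslow baseline cumulative hazard,
#' Schoenfeld residuals and per-row score residuals are returned with the
#' fit.
#'
#' @param cohort data frame with `time`, `status` and covariate columns
#' @param columns covariate columns to use (default: all columns except
#'   `id`, `time`, `status`)
#' @param entry optional per-row entry times (default 0)
#' @param cluster optional grouping vector for the robust covariance
#' @return object of class `dl_coxfit`: coefficients `beta`, model-based
#'   covariance `var`, robust covariance `var_robust` (when `cluster`
#'   given, else equal to the independence sandwich), `baseline_cumhaz`
#'   ([step_function]), `loglik` (null, final), counts `n`/`nevent`,
#'   design-column means `xbar`, and residuals
#' @export
fit_cox <- function(cohort, columns = NULL, entry = NULL, cluster = NULL) {
  df <- as.data.frame(cohort)
  if (is.null(columns)) columns <- cohort_columns(df)
  miss <- setdiff(columns, names(df))
  if (length(miss)) stop("columns not in cohort: ", paste(miss, collapse = ", "))
  if (sum(df$status == 1) < 1) stop("no events in the data; cannot fit")
  X <- as.matrix(df[, columns, drop = FALSE])
  if (ncol(X)) {
    qd <- qr(scale(X, center = TRUE, scale = FALSE))
    if (qd$rank < ncol(X)) {
      bad <- columns[qd$pivot[(qd$rank + 1):ncol(X)]]
      stop("design matrix is rank deficient; collinear columns: ",
           paste(bad, collapse = ", "))
    }
  }
  eng <- cox_engine(entry, df$time, df$status, X, strata = NULL,
                    cluster = cluster)
  structure(list(beta = stats::setNames(eng$beta, columns),
                 var = eng$var, var_robust = eng$var_robust,
                 baseline_cumhaz = eng$baselines[[1]],
                 loglik = eng$loglik, iter = eng$iter, score = eng$score,
                 n = eng$n, nevent = eng$nevent,
                 columns = columns,
                 xbar = colMeans(X),
                 schoenfeld = eng$schoenfeld,
                 score_resid = eng$score_resid),
            class = "dl_coxfit")
}

#' @export
print.dl_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Breslow): n=%d, events=%d, loglik %.4f -> %.4f (%d iter)\n",
              x$n, x$nevent, x$loglik[1], x$loglik[2], x$iter))
  if (length(x$beta)) {
    se <- sqrt(diag(x$var))
    print(data.frame(coef = x$beta, HR = exp(x$beta), se = se,
                     z = x$beta / se,
                     p = 2 * stats::pnorm(-abs(x$beta / se))))
  }
  invisible(x)
}

#' Prognostic index
#'
#' Centered linear predictor `PI_i = (X_i - Xbar)' beta_hat` with `Xbar` the
#' sample mean of the design columns of `cohort`; by construction the sample
#' mean of PI is zero to floating precision.
#'
#' @param cohort data frame carrying the fit's covariate columns
#' @param fit a [fit_cox()] result
#' @return numeric vector, one PI per row of `cohort`
#' @export
prognostic_index <- function(cohort, fit) {
  df <- as.data.frame(cohort)
  miss <- setdiff(fit$columns, names(df))
  if (length(miss))
    stop("cohort lacks fit columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(df[, fit$columns, drop = FALSE])
  drop(sweep(X, 2, colMeans(X)) %*% fit$beta)
}

#' Proportional-hazards (time-varying effect) test
#'
#' Scaled-Schoenfeld-residual score test in the Grambsch-Therneau form with
#' the identity time transform: regresses the Schoenfeld residuals on the
#' (centered) event times and tests the slope. With `u = sum_k (t_k -
#' tbar) s_k`, the global statistic is `d u' I^{-1} u / sum (t_k - tbar)^2`
#' on `p` df; the per-column statistic is `d (I^{-1} u)_j^2 / ((I^{-1})_jj
#' sum (t_k - tbar)^2)` on 1 df.
#'
#' @param fit a converged [fit_cox()] result
#' @param column a covariate name for the single-coefficient test; `NULL`
#'   gives the global test
#' @return list with `statistic`, `df`, `p_value` and the per-column `table`
#' @export
tv_effect_test <- function(fit, column = NULL) {
  if (fit$nevent < 2) stop("need at least 2 events for the PH test")
  sres <- fit$schoenfeld$resid
  g <- fit$schoenfeld$time
  gc <- g - mean(g)
  ssg <- sum(gc^2)
  if (ssg <= 0) stop("degenerate event times; PH test undefined")
  d <- nrow(sres)
  V <- fit$var
  u <- drop(crossprod(sres, gc))
  Vu <- drop(V %*% u)
  per <- d * Vu^2 / (diag(V) * ssg)
  tab <- data.frame(column = fit$columns, statistic = per, df = 1,
                    p_value = stats::pchisq(per, 1, lower.tail = FALSE))
  if (!is.null(column)) {
    j <- match(column, fit$columns)
    if (is.na(j)) stop("unknown column: ", column)
    return(list(statistic = per[j], df = 1,
                p_value = tab$p_value[j], table = tab))
  }
  glob <- d * sum(u * Vu) / ssg
  p <- length(u)
  list(statistic = glob, df = p,
       p_value = stats::pchisq(glob, p, lower.tail = FALSE), table = tab)
}

#' Predicted survival curves from a Cox fit
#'
#' `S(t | x) = exp(-H0(t) exp(x' beta))` with the fitted Breslow baseline.
#' `survival_at_pi()` re-references the baseline to the covariate mean so
#' curves can be requested directly at prognostic-index values (PI = 0 is
#' the mean-covariate patient).
#'
#' @param fit a [fit_cox()] result
#' @param newx covariate vector (or matrix, one row per profile) on the
#'   design scale
#' @param times evaluation times
#' @return matrix of survival probabilities, `length(times)` rows, one
#'   column per profile
#' @export
predict_survival <- function(fit, newx, times) {
  H0 <- step_eval(fit$baseline_cumhaz, times)
  newx <- if (is.null(dim(newx))) matrix(newx, nrow = 1) else as.matrix(newx)
  lp <- drop(newx %*% fit$beta)
  outer(H0, exp(lp), function(h, r) exp(-h * r))
}

#' @rdname predict_survival
#' @param pi_values prognostic-index values at which curves are wanted
#' @export
survival_at_pi <- function(fit, pi_values, times) {
  H0c <- step_eval(fit$baseline_cumhaz, times) * exp(sum(fit$xbar * fit$beta))
  outer(H0c, exp(pi_values), function(h, r) exp(-h * r))
}
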