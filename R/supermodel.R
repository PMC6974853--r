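#' Fit the stratified landmark supermodel
#'
#' The stratified supermodel `h(t | X, s) = h0(t | s) exp(X beta_LM(s))`
#' with `beta_LM(s) = sum_j theta_j f_j(s)` is a stratified Cox model on
#' the super dataset: risk sets are formed within each landmark stratum
#' only, and one coefficient is estimated per (covariate x f_j) column.
#' Because a subject contributes rows to many strata, the default
#' covariance is the sandwich estimator clustered on subject id; the
#' model-based inverse information is also returned. Per-stratum Breslow
#' baseline cumulative hazards are computed at the fitted coefficients.
#'
#' @param data a `dl_superdata` from [build_landmark_dataset()], or a
#'   cohort data frame (then `design` must be given and the super dataset
#'   is built on the fly)
#' @param design a [landmark_design]; defaults to the superdata's
#' @param columns covariate columns (defaults to the superdata's)
#' @return object of class `dl_supermodel` with `kind = "stratified"`,
#'   coefficients `theta` (named `cov.fj`), covariances `var` (model-based)
#'   and `var_robust` (subject-clustered sandwich, the default for
#'   inference), per-stratum `baselines`, the `design`, and fit metadata
#' @export
fit_stratified_supermodel <- function(data, design = NULL, columns = NULL) {
  sd <- as_superdata(data, design, columns)
  design <- attr(sd, "design")
  columns <- attr(sd, "covariates")
  check_stratum_events(sd)
  fcols <- superdata_fcols(columns, length(design$f_basis))
  X <- as.matrix(sd[, fcols, drop = FALSE])
  skey <- factor(sd$stratum_s, levels = unique(design$grid))
  eng <- cox_engine(sd$entry, sd$exit, sd$status, X,
                    strata = skey, cluster = sd$id)
  new_supermodel(kind = "stratified", eng = eng, fcols = fcols,
                 gcols = character(0), design = design, columns = columns,
                 n_subjects = length(unique(sd$id)), n_rows = nrow(sd))
}

#' Fit the proportional-baselines landmark supermodel
#'
#' The proportional-baselines supermodel `h(t | X, s) = h0(t) exp(X
#' beta_LM(s) + gamma(s))`, with `gamma(s) = sum_j gamma_j g_j(s)` and
#' `g_j(s_1) = 0` so the single baseline is anchored at the first landmark.
#' It is fit as one unstratified partial likelihood over the stacked
#' landmark rows with delayed entry: a row for landmark `s` is at risk in
#' `(s, exit]`, so each subject at risk at an event time contributes once
#' per stratum containing it, exactly the n_is-records construction. With
#' a single landmark the `g` columns are identically zero and are dropped;
#' the fit then coincides with the stratified one.
#'
#' @inheritParams fit_stratified_supermodel
#' @return a `dl_supermodel` with `kind = "proportional"`, coefficients
#'   `theta` and `gamma`, robust and model-based covariances, and the
#'   single Breslow baseline referenced to `s_1`
#' @export
fit_proportional_supermodel <- function(data, design = NULL, columns = NULL) {
  sd <- as_superdata(data, design, columns)
  design <- attr(sd, "design")
  columns <- attr(sd, "covariates")
  check_stratum_events(sd)
  g1 <- drop(eval_basis(design$g_basis, design$grid[1]))
  if (any(abs(g1) > 1e-10))
    stop("identifiability: every g_j must vanish at the first landmark s_1 = ",
         format(design$grid[1]))
  fcols <- superdata_fcols(columns, length(design$f_basis))
  gcols <- paste0("g", seq_along(design$g_basis))
  if (length(unique(design$grid)) == 1L) gcols <- character(0)
  X <- as.matrix(sd[, c(fcols, gcols), drop = FALSE])
  eng <- cox_engine(sd$entry, sd$exit, sd$status, X,
                    strata = NULL, cluster = sd$id)
  new_supermodel(kind = "proportional", eng = eng, fcols = fcols,
                 gcols = gcols, design = design, columns = columns,
                 n_subjects = length(unique(sd$id)), n_rows = nrow(sd))
}

as_superdata <- function(data, design, columns) {
  if (inherits(data, "dl_superdata")) {
    if (!is.null(design)) attr(data, "design") <- design
    return(data)
  }
  if (is.null(design)) stop("a landmark_design is required to build the super dataset")
  build_landmark_dataset(data, design, columns)
}

check_stratum_events <- function(sd) {
  ev <- tapply(sd$status, sd$stratum_s, sum)
  bad <- names(ev)[ev == 0]
  if (length(bad))
    stop("stratum without events at landmark(s): ", paste(bad, collapse = ", "))
}

new_supermodel <- function(kind, eng, fcols, gcols, design, columns,
                           n_subjects, n_rows) {
  cf <- stats::setNames(eng$beta, c(fcols, gcols))
  structure(list(kind = kind,
                 theta = cf[fcols],
                 gamma = cf[gcols],
                 coef = cf,
                 var = eng$var, var_robust = eng$var_robust,
                 loglik = eng$loglik, iter = eng$iter,
                 baselines = eng$baselines,
                 design = design, covariates = columns,
                 fcols = fcols, gcols = gcols,
                 n = n_subjects, n_rows = n_rows,
                 nevent = eng$nevent),
            class = "dl_supermodel")
}

#' @export
print.dl_supermodel <- function(x, ...) {
  cat(sprintf("%s landmark supermodel: %d subjects, %d stacked rows, %d window events\n",
              x$kind, x$n, x$n_rows, x$nevent))
  cat(sprintf("  w=%g, %d landmarks; loglik %.4f (%d iter)\n",
              x$design$w, length(x$design$grid), x$loglik[2], x$iter))
  print(supermodel_table(x))
  invisible(x)
}

#' Coefficient table in the two-part landmark layout
#'
#' One row per (covariate, time function) coefficient, with the landmark
#' main-effect (`gamma`) rows appended for the proportional-baselines fit:
#' columns `part`, `covariate`, `time_function`, `coefficient`, `se`
#' (robust by default).
#'
#' @param fit a `dl_supermodel`
#' @param robust use the cluster-robust covariance for SEs
#' @return data frame
#' @export
supermodel_table <- function(fit, robust = TRUE) {
  V <- if (robust) fit$var_robust else fit$var
  se <- sqrt(diag(V))
  nf <- length(fit$design$f_basis)
  rows <- data.frame(
    part = fit$kind,
    covariate = rep(fit$covariates, each = nf),
    time_function = rep(fit$design$f_labels, times = length(fit$covariates)),
    coefficient = as.numeric(fit$theta),
    se = se[seq_along(fit$fcols)])
  if (length(fit$gcols)) {
    rows <- rbind(rows, data.frame(
      part = fit$kind, covariate = "gamma(s)",
      time_function = fit$design$g_labels,
      coefficient = as.numeric(fit$gamma),
      se = se[length(fit$fcols) + seq_along(fit$gcols)]))
  }
  rows
}

#' Landmark-varying coefficient with pointwise confidence interval
#'
#' Reconstructs `beta_LM(s) = sum_j theta_j f_j(s)` for one covariate, with
#' variance `f(s)' Cov(theta) f(s)` (robust covariance by default) and a
#' pointwise 95% CI; `exp(beta_LM(s))` is the dynamic hazard ratio.
#' Requests beyond the fitted grid are honoured but carry a warning and an
#' `extrapolated` flag.
#'
#' @param fit a `dl_supermodel`
#' @param s landmark values
#' @param covariate covariate name (default: the fit's single covariate)
#' @param robust use the cluster-robust covariance
#' @param level confidence level
#' @return data frame with `s`, `estimate`, `se`, `lower`, `upper`, `hr`,
#'   `extrapolated`
#' @export
beta_lm <- function(fit, s, covariate = NULL, robust = TRUE, level = 0.95) {
  if (is.null(covariate)) {
    if (length(fit$covariates) != 1L)
      stop("specify `covariate` for a multi-covariate fit")
    covariate <- fit$covariates
  }
  if (!covariate %in% fit$covariates) stop("unknown covariate: ", covariate)
  nf <- length(fit$design$f_basis)
  cols <- paste0(covariate, ".f", seq_len(nf))
  idx <- match(cols, names(fit$coef))
  F <- eval_basis(fit$design$f_basis, s)
  V <- (if (robust) fit$var_robust else fit$var)[idx, idx, drop = FALSE]
  est <- drop(F %*% fit$coef[idx])
  se <- sqrt(pmax(rowSums((F %*% V) * F), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  outside <- s > max(fit$design$grid) + 1e-9 | s < min(fit$design$grid) - 1e-9
  if (any(outside))
    warning("beta_lm evaluated outside the fitted landmark grid; extrapolation")
  data.frame(s = s, estimate = est, se = se,
             lower = est - z * se, upper = est + z * se,
             hr = exp(est), extrapolated = outside)
}

#' Landmark main effect gamma(s) with confidence interval
#'
#' `gamma(s) = sum_j gamma_j g_j(s)` of the proportional-baselines fit;
#' by construction `gamma(s_1) = 0` and `exp(gamma(s_1)) = 1` exactly.
#'
#' @inheritParams beta_lm
#' @return data frame with `s`, `estimate`, `se`, `lower`, `upper`,
#'   `exp_gamma`
#' @export
gamma_at <- function(fit, s, robust = TRUE, level = 0.95) {
  if (fit$kind != "proportional")
    stop("gamma(s) is defined only for the proportional-baselines supermodel")
  if (!length(fit$gcols))
    return(data.frame(s = s, estimate = 0, se = 0, lower = 0, upper = 0,
                      exp_gamma = 1))
  idx <- match(fit$gcols, names(fit$coef))
  G <- eval_basis(fit$design$g_basis, s)
  V <- (if (robust) fit$var_robust else fit$var)[idx, idx, drop = FALSE]
  est <- drop(G %*% fit$coef[idx])
  se <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(s = s, estimate = est, se = se,
             lower = est - z * se, upper = est + z * se,
             exp_gamma = exp(est))
}

#' Breslow baseline cumulative hazard of a landmark stratum
#'
#' For stratified fits, the stratum-`s` baseline (increments `d_t /
#' sum_{at risk in stratum} exp(x beta_LM(s))` at each event time, summed);
#' for proportional fits the single pooled baseline anchored at `s_1`.
#'
#' @param fit a `dl_supermodel`
#' @param s landmark identifying the stratum (ignored for proportional fits)
#' @return a [step_function] of type `"cumhaz"`
#' @export
breslow_baseline <- function(fit, s = NULL) {
  if (fit$kind == "proportional") return(fit$baselines[[1]])
  if (is.null(s)) stop("stratified fits need a stratum landmark s")
  key <- match_landmark(fit$design$grid, s)
  fit$baselines[[as.character(factor(key, levels = unique(fit$design$grid)))]]
}

match_landmark <- function(grid, s) {
  j <- which(abs(grid - s) < 1e-8)
  if (!length(j)) stop("unknown stratum: s = ", format(s),
                       " is not a landmark of the fitted grid")
  grid[j[1]]
}

#' Dynamic probability of dying within the sliding window
#'
#' The landmark prediction `F_w(s | x) = 1 - exp(-[H0(s+w) - H0(s)]
#' exp(x beta_LM(s) + gamma(s)))`: coefficients (and `gamma`) are evaluated
#' at the landmark `s` and held fixed over the whole window `(s, s+w]` —
#' the landmark convention. Stratified fits use the stratum-`s` baseline
#' (so `s` must be a grid point); proportional fits use the single
#' baseline at any `s` inside `[s_1, s_L]`.
#'
#' @param fit a `dl_supermodel`
#' @param x covariate vector (one value per fit covariate), or a matrix
#'   with one row per subject
#' @param s landmark value(s)
#' @return matrix of probabilities, `length(s)` rows by `nrow(x)` columns
#'   (dropped to a vector when one dimension is 1)
#' @export
dynamic_death_probability <- function(fit, x, s) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(fit$covariates))
    stop("x must supply one value per fit covariate")
  w <- fit$design$w
  lo <- min(fit$design$grid) - 1e-9
  hi <- max(fit$design$grid) + 1e-9
  if (any(s < lo | s > hi))
    stop("landmark s outside the fitted grid [",
         format(min(fit$design$grid)), ", ", format(max(fit$design$grid)), "]")
  out <- matrix(NA_real_, length(s), nrow(x))
  for (k in seq_along(s)) {
    sk <- s[k]
    bl <- if (fit$kind == "stratified") breslow_baseline(fit, sk)
          else fit$baselines[[1]]
    dH <- step_eval(bl, sk + w) - step_eval(bl, sk)
    blm <- vapply(fit$covariates, function(cv)
      beta_lm(fit, sk, covariate = cv)$estimate, numeric(1))
    lp <- drop(x %*% blm)
    if (fit$kind == "proportional") lp <- lp + gamma_at(fit, sk)$estimate
    out[k, ] <- 1 - exp(-dH * exp(lp))
  }
  if (length(s) == 1L || nrow(x) == 1L) drop(out) else out
}

#' Per-landmark ("crude") Cox fits
#'
#' Fits a separate Cox model inside every landmark stratum of a super
#' dataset — the estimates the stratified supermodel smooths over `s`.
#'
#' @param sd a `dl_superdata`
#' @return data frame with one row per (landmark, covariate): `s`,
#'   `covariate`, `estimate`, `se`
#' @export
crude_landmark_fits <- function(sd) {
  design <- attr(sd, "design")
  columns <- attr(sd, "covariates")
  out <- lapply(unique(design$grid), function(s) {
    sub <- sd[abs(sd$stratum_s - s) < 1e-12, , drop = FALSE]
    fit <- fit_cox(data.frame(time = sub$exit, status = sub$status,
                              sub[, columns, drop = FALSE],
                              check.names = FALSE),
                   columns = columns)
    data.frame(s = s, covariate = columns,
               estimate = as.numeric(fit$beta),
               se = sqrt(diag(fit$var)))
  })
  do.call(rbind, out)
}
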