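#' Configuration for a full landmark analysis
#'
#' Exactly one of `preset`/`input_csv` selects the cohort: the `"table1"`
#' preset simulates the registry-style cohort (see [table1_design()]),
#' `input_csv` loads and validates an existing cohort file. The default
#' landmark design is `w = 5` years, landmarks `0, 0.1, ..., 3`, and the
#' polynomial bases `f = {1, s/3, (s/3)^2}`, `g = {s/3, (s/3)^2}`; the
#' model covariate is the prognostic index computed from `pi_columns`.
#'
#' @param preset `"table1"` or `NULL`
#' @param input_csv path to a cohort CSV or `NULL`
#' @param n,seed cohort size and seed for the preset
#' @param design a [landmark_design]
#' @param pi_columns covariate subset for the prognostic index (default:
#'   all covariates)
#' @param out_dir output directory for tables and figures
#' @param evaluate compute the dynamic evaluation curves
#' @param figures write pdf figures next to their CSV twins
#' @return object of class `dl_config`
#' @export
analysis_config <- function(preset = "table1", input_csv = NULL,
                            n = 550, seed = 1L,
                            design = landmark_design(),
                            pi_columns = NULL,
                            out_dir = "results",
                            evaluate = TRUE, figures = TRUE) {
  if (is.null(preset) == is.null(input_csv))
    stop("exactly one of preset / input_csv must be given")
  if (!is.null(preset)) preset <- match.arg(preset, "table1")
  stopifnot(inherits(design, "landmark_design"))
  structure(list(preset = preset, input_csv = input_csv, n = n,
                 seed = as.integer(seed), design = design,
                 pi_columns = pi_columns, out_dir = out_dir,
                 evaluate = isTRUE(evaluate), figures = isTRUE(figures)),
            class = "dl_config")
}

#' Run the full landmark analysis
#'
#' End-to-end driver: obtain the cohort (simulate the preset or load the
#' CSV), summarize the covariates, fit the all-covariate Cox model, compute
#' the prognostic index and screen it for a time-varying effect, build the
#' landmark super dataset with PI as the covariate, fit the stratified and
#' proportional-baselines supermodels, and (optionally) evaluate them
#' dynamically. Every table is written as CSV under `config$out_dir`; each
#' figure has a CSV twin so no number exists only in a plot. Deterministic
#' given the seed.
#'
#' @param config an [analysis_config()]
#' @return invisibly, a list with the cohort, fits, curves and the paths of
#'   everything written
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "dl_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }

  # --- cohort ---------------------------------------------------------
  if (!is.null(config$preset)) {
    design_sim <- table1_design(n = config$n, seed = config$seed)
    cohort <- generate_cohort(design_sim)
  } else {
    cohort <- validate_cohort_csv(config$input_csv)
  }
  covs <- cohort_columns(cohort)
  message(sprintf("cohort: n=%d, events=%d (%.1f%%)", nrow(cohort),
                  sum(cohort$status), 100 * mean(cohort$status)))
  emit(covariate_summary(cohort), "table1_summary")

  # --- KM / censoring curves ------------------------------------------
  km <- km_estimate(cohort$time, cohort$status)
  ck <- censoring_km(cohort$time, cohort$status)
  message(sprintf("median follow-up (reverse KM): %.2f years", ck$median))
  emit(data.frame(time = km$knots, survival = km$values), "km_survival")
  emit(data.frame(time = ck$curve$knots, censoring_survival = ck$curve$values),
       "km_censoring")

  # --- Cox model, PI, PH screen ---------------------------------------
  fit0 <- fit_cox(cohort, columns = covs)
  se <- sqrt(diag(fit0$var))
  emit(data.frame(term = fit0$columns, coef = fit0$beta, hr = exp(fit0$beta),
                  se = se, p_value = 2 * stats::pnorm(-abs(fit0$beta / se))),
       "cox_hr_table")
  pi_cols <- if (is.null(config$pi_columns)) covs else config$pi_columns
  fit_pi_src <- if (identical(sort(pi_cols), sort(covs))) fit0
                else fit_cox(cohort, columns = pi_cols)
  PI <- prognostic_index(cohort, fit_pi_src)
  picoh <- data.frame(id = cohort$id, time = cohort$time,
                      status = cohort$status, PI = PI)
  fit_pi <- fit_cox(picoh, columns = "PI")
  tv <- tv_effect_test(fit_pi, column = "PI")
  message(sprintf("PI: mean=%.2e sd=%.3f; PH test on PI: chi2=%.3f p=%.4f",
                  mean(PI), stats::sd(PI), tv$statistic, tv$p_value))
  emit(data.frame(pi_mean = mean(PI), pi_sd = stats::sd(PI),
                  tv_statistic = tv$statistic, tv_p_value = tv$p_value),
       "pi_summary")

  # --- survival curves at PI quantiles (mean, +/- 1 and 2 sd) ---------
  tgrid <- seq(0, max(cohort$time), length.out = 201)[-1]
  pis <- stats::sd(PI) * c(-2, -1, 0, 1, 2)
  Smat <- survival_at_pi(fit_pi, pis, tgrid)
  colnames(Smat) <- c("pi_m2sd", "pi_m1sd", "pi_mean", "pi_p1sd", "pi_p2sd")
  emit(data.frame(time = tgrid, Smat, km = step_eval(km, tgrid)),
       "cox_survival_by_pi")

  # --- landmark supermodels on PI -------------------------------------
  sdat <- build_landmark_dataset(picoh, config$design, columns = "PI")
  fit_str <- fit_stratified_supermodel(sdat)
  fit_pro <- fit_proportional_supermodel(sdat)
  message(sprintf("supermodels fitted: %d stacked rows, %d window events",
                  fit_str$n_rows, fit_str$nevent))
  emit(rbind(supermodel_table(fit_str), supermodel_table(fit_pro)),
       "supermodel_coefficients")

  # --- dynamic death probabilities and landmark effects ---------------
  grid <- config$design$grid
  pset <- stats::sd(PI) * c(-1, 0, 1)
  dpr <- dynamic_death_probability(fit_pro, matrix(pset, ncol = 1), grid)
  dpr <- matrix(dpr, nrow = length(grid))
  colnames(dpr) <- c("pi_m1sd", "pi_mean", "pi_p1sd")
  emit(data.frame(s = grid, dpr), "dynamic_death_prob")

  eff <- beta_lm(fit_str, grid, covariate = "PI")
  gam <- gamma_at(fit_pro, grid)
  crude <- crude_landmark_fits(sdat)
  emit(data.frame(s = grid,
                  beta_lm = eff$estimate, lower = eff$lower, upper = eff$upper,
                  hr = eff$hr,
                  crude = crude$estimate, crude_se = crude$se,
                  gamma = gam$estimate, exp_gamma = gam$exp_gamma,
                  gamma_lower = gam$lower, gamma_upper = gam$upper),
       "landmark_effects")

  curves <- NULL
  if (config$evaluate) {
    curves <- dynamic_evaluation(fit_pro, picoh)
    message(sprintf("dynamic C: mean over landmarks %.3f, pooled %.3f",
                    attr(curves, "mean_c"), attr(curves, "pooled_c")))
    emit(cbind(as.data.frame(curves),
               mean_c = attr(curves, "mean_c"),
               pooled_c = attr(curves, "pooled_c")),
         "evaluation_curves")
  }

  if (config$figures) paths <- c(paths, write_figures(config$out_dir))

  manifest <- list(package_version = as.character(utils::packageVersion("dynland")),
                   r_version = R.version.string,
                   seed = config$seed,
                   preset = config$preset, input_csv = config$input_csv,
                   n = nrow(cohort),
                   design = list(w = config$design$w,
                                 grid = range(config$design$grid),
                                 landmarks = length(config$design$grid)),
                   outputs = basename(paths))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(cohort = cohort, pi = PI, cox = fit0, cox_pi = fit_pi,
                 tv_test = tv, superdata = sdat,
                 stratified = fit_str, proportional = fit_pro,
                 curves = curves, paths = paths))
}

#' Covariate summary in registry-table layout
#'
#' Counts and percentages per design column (continuous columns get mean
#' and SD instead).
#' @param cohort a cohort data frame
#' @return data frame with `variable`, `summary`
#' @export
covariate_summary <- function(cohort) {
  covs <- cohort_columns(cohort)
  rows <- lapply(covs, function(cl) {
    x <- cohort[[cl]]
    if (all(x %in% c(0, 1))) {
      data.frame(variable = cl,
                 summary = sprintf("%d (%.2f%%)", sum(x), 100 * mean(x)))
    } else {
      data.frame(variable = cl,
                 summary = sprintf("%.2f (%.2f)", mean(x), stats::sd(x)))
    }
  })
  do.call(rbind, c(list(data.frame(variable = "n",
                                   summary = as.character(nrow(cohort)))),
                   rows))
}

# render the standard figures from the CSV twins already on disk
write_figures <- function(out_dir) {
  written <- character(0)
  fig <- function(plot, name) {
    p <- file.path(out_dir, paste0(name, ".pdf"))
    grDevices::pdf(p, width = 7, height = 5)
    print(plot)
    grDevices::dev.off()
    written <<- c(written, p)
  }
  rd <- function(name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  km <- rd("km_survival"); ck <- rd("km_censoring")
  if (!is.null(km) && !is.null(ck)) {
    df <- rbind(data.frame(time = km$time, value = km$survival,
                           curve = "survival"),
                data.frame(time = ck$time, value = ck$censoring_survival,
                           curve = "censoring"))
    fig(ggplot2::ggplot(df, ggplot2::aes(time, value, linetype = curve)) +
          ggplot2::geom_step() + ggplot2::ylim(0, 1) +
          ggplot2::labs(x = "years", y = "probability",
                        title = "Survival and censoring (reverse KM) curves"),
        "fig_km")
  }
  dp <- rd("dynamic_death_prob")
  if (!is.null(dp)) {
    long <- stats::reshape(dp, direction = "long",
                           varying = names(dp)[-1], v.names = "prob",
                           timevar = "profile", times = names(dp)[-1])
    fig(ggplot2::ggplot(long, ggplot2::aes(s, prob, colour = profile)) +
          ggplot2::geom_line() +
          ggplot2::labs(x = "landmark s (years)",
                        y = "P(death within w years | alive at s)",
                        title = "Dynamic window death probabilities"),
        "fig_dynamic_death_prob")
  }
  le <- rd("landmark_effects")
  if (!is.null(le)) {
    fig(ggplot2::ggplot(le, ggplot2::aes(s, beta_lm)) +
          ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                               alpha = 0.2) +
          ggplot2::geom_line() +
          ggplot2::geom_point(ggplot2::aes(y = crude), shape = 1) +
          ggplot2::labs(x = "landmark s (years)", y = "beta_LM(s)",
                        title = "Landmark effect of the prognostic index"),
        "fig_landmark_effects")
  }
  ev <- rd("evaluation_curves")
  if (!is.null(ev)) {
    fig(ggplot2::ggplot(ev, ggplot2::aes(s, cindex)) + ggplot2::geom_line() +
          ggplot2::ylim(0, 1) +
          ggplot2::labs(x = "landmark s (years)", y = "dynamic C-index",
                        title = "Dynamic concordance"),
        "fig_dynamic_cindex")
    df <- rbind(data.frame(s = ev$s, brier = ev$brier_model, model = "landmark"),
                data.frame(s = ev$s, brier = ev$brier_null, model = "KM null"))
    fig(ggplot2::ggplot(df, ggplot2::aes(s, brier, linetype = model)) +
          ggplot2::geom_line() +
          ggplot2::labs(x = "landmark s (years)", y = "prediction error",
                        title = "Dynamic prediction-error (Brier) curves"),
        "fig_prediction_error")
  }
  written
}
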