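#' Simulate a survival cohort
#'
#' Draws covariates i.i.d. from the design's marginal specifications, event
#' times from the specified baseline hazard scaled by `exp(X'beta(t))`
#' (inverse-transform sampling; piecewise inversion when the effect profile
#' is step or linear-decay), and independent censoring times; the observed
#' time is the minimum and `status` records whether the event was seen.
#' Continuous covariates are centred at their design mean inside the
#' generating linear predictor, so the baseline hazard describes an average
#' subject; the stored column is on the original scale (or standardized if
#' the spec says so).
#'
#' All randomness flows from `design$seed` through one generator stream in a
#' fixed order (covariates, then event draws, then censoring draws), so a
#' fixed seed reproduces the cohort bit for bit and censoring never reuses
#' event-time random numbers.
#'
#' @param design a [simulation_design]
#' @return a `data.frame` of class `dl_cohort` with columns `id`, `time`
#'   (years), `status` (1 event / 0 censored) and one column per design-coded
#'   covariate; the design and generating truth are attached as attributes.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(design$seed)
  n <- design$n

  # covariates, in design order
  Xraw <- list()
  Xgen <- list()   # columns as they enter the generating linear predictor
  for (spec in design$covariates) {
    if (spec$kind == "continuous") {
      x <- stats::rnorm(n, spec$mean, spec$sd)
      stored <- if (spec$coding == "standardized") (x - spec$mean) / spec$sd else x
      Xraw[[spec$name]] <- stored
      Xgen[[spec$name]] <- if (spec$coding == "standardized") stored else x - spec$mean
    } else {
      lev <- sample(seq_along(spec$levels), n, replace = TRUE,
                    prob = spec$probabilities)
      for (j in seq_along(spec$levels)[-1]) {
        nm <- paste(spec$name, spec$levels[j], sep = ".")
        Xraw[[nm]] <- Xgen[[nm]] <- as.numeric(lev == j)
      }
    }
  }
  X <- if (length(Xgen)) do.call(cbind, Xgen) else matrix(0, n, 0)

  tev <- draw_event_times(X, design)
  E_unif <- stats::runif(n)                    # censoring-type draw
  C_unif <- stats::runif(n)                    # uniform-censoring draw
  if (is.null(design$censoring)) {
    cens <- rep(Inf, n)
  } else {
    cs <- design$censoring
    cens <- ifelse(E_unif < cs$p_uniform, C_unif * cs$c_max, cs$c_admin)
    cens <- pmin(cens, cs$c_admin)
  }
  time <- pmin(tev, cens)
  status <- as.integer(tev <= cens)
  out <- data.frame(id = seq_len(n), time = time, status = status)
  for (nm in names(Xraw)) out[[nm]] <- Xraw[[nm]]
  attr(out, "design") <- design
  class(out) <- c("dl_cohort", "data.frame")
  out
}

# cumulative baseline hazard and its inverse
baseline_cumhaz_fun <- function(baseline) {
  if (baseline$dist == "exponential") {
    list(H = function(t) baseline$rate * t,
         Hinv = function(h) h / baseline$rate)
  } else {
    list(H = function(t) (t / baseline$scale)^baseline$shape,
         Hinv = function(h) baseline$scale * h^(1 / baseline$shape))
  }
}

# piecewise-constant effect profile: interval breaks and per-interval beta
effect_intervals <- function(design) {
  p <- length(design$true_beta)
  prof <- design$beta_time_profile
  if (is.null(prof) || prof$type == "constant")
    return(list(breaks = Inf, betas = matrix(design$true_beta, ncol = p)))
  if (prof$type == "step") {
    return(list(breaks = c(prof$tau, Inf),
                betas = rbind(design$true_beta, prof$beta2)))
  }
  # linear-decay: beta(t) = beta * max(1 - t/tau, 0), discretised on a fine
  # grid (midpoint rule) so piecewise-exponential inversion stays exact
  m <- 512L
  edges <- seq(0, prof$tau, length.out = m + 1L)
  mids <- (edges[-1] + edges[-(m + 1L)]) / 2
  betas <- outer(1 - mids / prof$tau, design$true_beta)
  list(breaks = c(edges[-1], Inf), betas = rbind(betas, 0 * design$true_beta))
}

# inverse-transform event times under a piecewise-constant effect profile
draw_event_times <- function(X, design) {
  n <- nrow(X)
  bl <- baseline_cumhaz_fun(design$baseline)
  iv <- effect_intervals(design)
  K <- length(iv$breaks)
  E <- stats::rexp(n)
  if (ncol(X) == 0) {
    lp <- matrix(0, n, K)
  } else {
    lp <- X %*% t(iv$betas)
  }
  lower <- c(0, iv$breaks[-K])
  dH0 <- bl$H(iv$breaks) - bl$H(lower)        # last entry Inf
  tev <- rep(NA_real_, n)
  cum <- rep(0, n)
  remaining <- rep(TRUE, n)
  for (k in seq_len(K)) {
    incr <- dH0[k] * exp(lp[, k])
    hit <- remaining & (cum + incr >= E)
    if (any(hit)) {
      need <- (E[hit] - cum[hit]) / exp(lp[hit, k])
      tev[hit] <- bl$Hinv(bl$H(lower[k]) + need)
      remaining[hit] <- FALSE
    }
    cum <- cum + ifelse(is.finite(incr), incr, 0)
    if (!any(remaining)) break
  }
  tev
}

#' Simulate a cohort with a step time-varying effect
#'
#' Convenience wrapper around [generate_cohort()] for the step profile
#' `beta(t) = beta1` for `t < tau`, `beta2` for `t >= tau`: event times come
#' from exact piecewise-exponential inversion so the true hazard ratio
#' changes at `tau`. The truth `(beta1, beta2, tau)` travels with the cohort
#' in its attributes.
#'
#' @param design a [simulation_design]; its `true_beta` is `beta1`
#' @param beta2 coefficient vector after `tau` (defaults to the design's
#'   step profile if already present)
#' @param tau change point, `> 0`
#' @return a `dl_cohort` (see [generate_cohort()])
#' @export
generate_tv_cohort <- function(design, beta2 = NULL, tau = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(design$beta_time_profile) ||
      design$beta_time_profile$type != "step") {
    if (is.null(beta2) || is.null(tau))
      stop("invalid design: step profile needs beta2 and tau")
    if (tau <= 0) stop("invalid design: tau must be positive")
    design$beta_time_profile <- list(type = "step",
                                     beta2 = rep_len(beta2, length(design$true_beta)),
                                     tau = tau)
  }
  out <- generate_cohort(design)
  attr(out, "tv_truth") <- list(beta1 = design$true_beta,
                                beta2 = design$beta_time_profile$beta2,
                                tau = design$beta_time_profile$tau)
  out
}

#' Write / read the cohort CSV schema
#'
#' Columns: `id`, `time`, `status`, then one column per design-coded
#' covariate; header mandatory, times written with full precision.
#' @param cohort a cohort data frame
#' @param path file path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$time <- signif(df$time, 10)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate and load a cohort CSV
#'
#' Checks the schema (`id`, `time`, `status`, covariate columns), strict
#' positivity of times, binary status and absence of missing cells,
#' reporting offending row numbers.
#'
#' @param path CSV file path
#' @return a `dl_cohort` data frame
#' @export
validate_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("id", "time", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort CSV missing columns: ", paste(miss, collapse = ", "))
  probs <- character(0)
  na_rows <- which(!stats::complete.cases(df))
  if (length(na_rows))
    probs <- c(probs, paste0("missing values in rows ", paste(na_rows, collapse = ", ")))
  bad_t <- which(!is.na(df$time) & df$time <= 0)
  if (length(bad_t))
    probs <- c(probs, paste0("nonpositive time in rows ", paste(bad_t, collapse = ", ")))
  bad_s <- which(!is.na(df$status) & !(df$status %in% c(0, 1)))
  if (length(bad_s))
    probs <- c(probs, paste0("non-binary status in rows ", paste(bad_s, collapse = ", ")))
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(nonnum))
    probs <- c(probs, paste0("non-numeric columns: ", paste(nonnum, collapse = ", ")))
  if (length(probs))
    stop("invalid cohort CSV:\n  ", paste(probs, collapse = "\n  "))
  class(df) <- c("dl_cohort", "data.frame")
  df
}

# covariate (design) columns of a cohort
cohort_columns <- function(cohort) {
  setdiff(names(cohort), c("id", "time", "status"))
}
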