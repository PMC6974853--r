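# shared fixtures and independent oracles (deliberately naive code paths)

# three-subject cohort used for super-dataset enumeration
toy3_cohort <- function() {
  data.frame(id = c("A", "B", "C"),
             time = c(1.5, 2.5, 4.0),
             status = c(1L, 0L, 1L))
}

# small two-stratum cohort with one covariate; both strata contain events
# under grid {0, 1}, w = 2
toy_super_cohort <- function() {
  data.frame(id = 1:5,
             time = c(0.5, 1.5, 2.5, 3.0, 4.0),
             status = c(1L, 1L, 0L, 1L, 0L),
             x = c(1.2, -0.4, 0.8, -1.0, 0.3))
}

toy_super_design <- function() {
  landmark_design(w = 2, grid = c(0, 1),
                  f_basis = list(function(s) rep(1, length(s)),
                                 function(s) s),
                  f_labels = c("constant", "linear"),
                  g_basis = list(function(s) s),
                  g_labels = "linear")
}

# written Breslow (pseudo-)partial log-likelihood, direct double loop;
# strata = NULL gives the pooled delayed-entry likelihood
naive_logpl <- function(beta, entry, exit, status, X, strata = NULL) {
  lp <- drop(as.matrix(X) %*% beta)
  w <- exp(lp)
  ll <- 0
  for (i in which(status == 1)) {
    t <- exit[i]
    risk <- entry < t & exit >= t
    if (!is.null(strata)) risk <- risk & strata == strata[i]
    ll <- ll + lp[i] - log(sum(w[risk]))
  }
  ll
}

# exhaustive grid search followed by local refinement of the written
# pseudo-likelihood; independent of the package's Newton fitter
oracle_maximize <- function(fn, p, lim = 2.5, step = 0.25) {
  grid <- as.matrix(expand.grid(rep(list(seq(-lim, lim, by = step)), p)))
  vals <- apply(grid, 1, fn)
  start <- grid[which.max(vals), ]
  opt <- stats::optim(start, fn, method = "BFGS",
                      control = list(fnscale = -1, reltol = 1e-14, maxit = 500))
  opt$par
}

# exhaustive-pair Harrell concordance among subjects at risk at s with the
# earlier event inside (s, s+w]
enum_cindex <- function(time, status, score, s = 0, w = Inf) {
  keep <- time > s
  time <- time[keep]; status <- status[keep]; score <- score[keep]
  conc <- 0; pairs <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (status[i] != 1 || time[i] > s + w) next
    if (time[j] <= time[i]) next
    pairs <- pairs + 1
    conc <- conc + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  list(cindex = if (pairs) conc / pairs else NA_real_, pairs = pairs)
}

# quick single-covariate exponential cohort
quick_cohort <- function(n, beta = 0.8, rate = 0.15, seed = 1,
                         censoring = list(c_admin = 9, c_max = 10, p_uniform = 0.6)) {
  d <- simulation_design(
    n = n,
    covariates = list(cov_spec("x", "continuous", mean = 0, sd = 1)),
    true_beta = beta,
    baseline = list(dist = "exponential", rate = rate),
    censoring = censoring, seed = seed)
  generate_cohort(d)
}

# PI pipeline on a single-covariate cohort: returns list(picoh, superdata)
pi_pipeline <- function(cohort, design = landmark_design()) {
  f0 <- fit_cox(cohort, columns = "x")
  picoh <- data.frame(id = cohort$id, time = cohort$time,
                      status = cohort$status,
                      PI = prognostic_index(cohort, f0))
  list(picoh = picoh,
       superdata = build_landmark_dataset(picoh, design, columns = "PI"))
}
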