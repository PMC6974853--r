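test_that("product-limit estimator matches hand and analytic computations", {
  # no events: flat at 1
  flat <- km_estimate(c(2, 3, 5), c(0, 0, 0))
  expect_equal(step_eval(flat, c(0, 1, 10)), c(1, 1, 1))
  # hand product-limit: (1,2,3) with (1,1,0)
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(step_eval(km, c(1, 2, 3)), c(2 / 3, 1 / 3, 1 / 3))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("censoring curve is the reverse KM and carries the follow-up median", {
  allev <- censoring_km(c(1, 2, 3), c(1, 1, 1))
  expect_equal(step_eval(allev$curve, c(0.5, 2, 5)), c(1, 1, 1))
  ck <- censoring_km(c(1, 2, 3), c(0, 0, 1))
  expect_equal(ck$curve$knots, c(1, 2))   # drops at censoring times only
  # reverse product-limit by hand: 2/3, then 2/3 * 1/2
  expect_equal(step_eval(ck$curve, c(1, 2)), c(2 / 3, 1 / 3))
  expect_equal(ck$median, 2)
  # classical identity on tie-free data: S_km * G_km = empirical at-risk
  set.seed(5)
  t <- sort(rexp(40)); s <- rbinom(40, 1, 0.5)
  S <- km_estimate(t, s); G <- censoring_km(t, s)$curve
  frac_after <- sapply(t, function(u) mean(t > u))
  expect_equal(step_eval(S, t) * step_eval(G, t), frac_after, tolerance = 1e-12)
})

test_that("partial likelihood maximization matches written-likelihood and coxph oracles", {
  # symmetry: two groups with identical time/status patterns
  sym <- data.frame(time = c(1, 2, 1, 2), status = c(1, 0, 1, 0),
                    x = c(0, 0, 1, 1))
  expect_equal(unname(fit_cox(sym, "x")$beta), 0, tolerance = 1e-9)

  # 3-subject written likelihood PL(b) = [1/(2+e^b)] * [e^b/(1+e^b)]
  toy <- data.frame(time = c(1, 2, 3), status = c(1, 1, 0), x = c(0, 1, 0))
  logpl <- function(b) -log(2 + exp(b)) + b - log(1 + exp(b))
  oracle <- optimize(logpl, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(fit_cox(toy, "x")$beta), oracle, tolerance = 1e-6)

  # random right-censored data with delayed entry against survival::coxph
  library(survival)
  co <- quick_cohort(300, beta = 0.6, seed = 12)
  co$z <- rbinom(300, 1, 0.4)
  f <- fit_cox(co, c("x", "z"))
  cf <- coxph(Surv(time, status) ~ x + z, data = co, ties = "breslow")
  expect_equal(unname(f$beta), unname(coef(cf)), tolerance = 1e-7)
  expect_lt(max(abs(f$var - vcov(cf))), 1e-10)
  expect_lt(max(abs(f$score)), 1e-6)   # first-order condition
  bh <- basehaz(cf, centered = FALSE)
  expect_lt(max(abs(step_eval(f$baseline_cumhaz, bh$time) - bh$hazard)), 1e-6)

  entry <- runif(300, 0, 0.5); keep <- co$time > entry
  f2 <- fit_cox(co[keep, ], c("x", "z"), entry = entry[keep])
  cf2 <- coxph(Surv(entry[keep], co$time[keep], co$status[keep]) ~ x + z,
               data = co[keep, ], ties = "breslow")
  expect_equal(unname(f2$beta), unname(coef(cf2)), tolerance = 1e-7)

  # error contracts
  expect_error(fit_cox(data.frame(time = 1:3, status = c(0, 0, 0), x = 1:3), "x"),
               "no events")
  co$x2 <- 2 * co$x
  expect_error(fit_cox(co, c("x", "x2")), "x2")
})

test_that("constant-effect recovery at n = 5000", {
  d <- simulation_design(
    n = 5000,
    covariates = list(cov_spec("x1", "continuous", mean = 0, sd = 1),
                      cov_spec("x2", "continuous", mean = 0, sd = 1)),
    true_beta = c(0.5, -0.3),
    baseline = list(dist = "exponential", rate = 0.15),
    censoring = list(c_admin = 10, c_max = 12, p_uniform = 0.5),
    seed = 21)
  f <- fit_cox(generate_cohort(d))
  se <- sqrt(diag(f$var))
  expect_lt(abs(f$beta[["x1"]] - 0.5), 3 * se[1])
  expect_lt(abs(f$beta[["x2"]] + 0.3), 3 * se[2])
})

test_that("prognostic index is centered, zero at the mean, and linear in beta", {
  co <- generate_cohort(table1_design(n = 500, seed = 2))
  f <- fit_cox(co)
  PI <- prognostic_index(co, f)
  expect_lt(abs(mean(PI)), 1e-10)
  # a subject sitting exactly at the design-column mean has PI = 0:
  # x = (0, 2, 1) puts the third subject at the sample mean
  mini <- data.frame(time = c(1, 2, 3), status = c(1, 1, 0), x = c(0, 2, 1))
  fm <- fit_cox(mini, "x")
  expect_equal(prognostic_index(mini, fm)[3], 0)
  # linearity: doubling beta doubles every PI
  f2 <- f; f2$beta <- 2 * f$beta
  expect_equal(prognostic_index(co, f2), 2 * PI, tolerance = 1e-12)
  expect_error(prognostic_index(co[, 1:4], f), "lacks fit columns")
})

test_that("PH screen agrees with survival's residual path and detects step effects", {
  library(survival)
  co <- quick_cohort(400, beta = 0.7, seed = 31)
  f <- fit_cox(co, "x")
  tv <- tv_effect_test(f, "x")
  # same statistic recomputed from coxph's Schoenfeld residuals + covariance
  cf <- coxph(Surv(time, status) ~ x, data = co, ties = "breslow")
  sr <- resid(cf, type = "schoenfeld")
  g <- as.numeric(names(sr)); gc <- g - mean(g)
  u <- sum(gc * sr)
  stat_oracle <- length(sr) * vcov(cf)[1, 1] * u^2 / sum(gc^2)
  expect_equal(tv$statistic, stat_oracle, tolerance = 1e-8)

  # power: step effect beta 1.2 -> 0 at tau = 2, n = 1000
  hits <- 0
  for (r in 1:100) {
    d <- simulation_design(
      n = 1000, covariates = list(cov_spec("x", "continuous", mean = 0, sd = 1)),
      true_beta = 1.2, baseline = list(dist = "exponential", rate = 0.2),
      censoring = list(c_admin = 8, c_max = 10, p_uniform = 0.3),
      seed = 4000 + r)
    ct <- generate_tv_cohort(d, beta2 = 0, tau = 2)
    p <- tv_effect_test(fit_cox(ct, "x"), "x")$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 80)

  # null behaviour: covariate permuted against outcome gives uniform p
  ps <- numeric(200)
  for (r in 1:200) {
    co0 <- quick_cohort(300, beta = 0.8, seed = 7000 + r)
    co0$x <- sample(co0$x)
    ps[r] <- tv_effect_test(fit_cox(co0, "x"), "x")$p_value
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("predicted survival curves respect the PI ordering and KM anchor", {
  co <- quick_cohort(800, beta = 1, seed = 14)
  f <- fit_cox(co, "x")
  PI <- prognostic_index(co, f)
  tt <- c(1, 2, 4, 6)
  S <- survival_at_pi(f, sd(PI) * c(-1, 0, 1), tt)
  expect_true(all(diff(t(S)) <= 1e-12))  # higher PI, lower survival
  expect_true(all(S >= 0 & S <= 1))
  # mean-PI curve sits near the model-free KM curve for a fair model
  km <- km_estimate(co$time, co$status)
  expect_lt(max(abs(S[, 2] - step_eval(km, tt))), 0.1)
})
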