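FAMILY_EXAMPLES <- list(
  exponential = list(rate = 0.05),
  weibull = list(shape = 1.3, scale = 40),
  gamma = list(shape = 2, rate = 0.05),
  generalized_gamma = list(mu = 3.5, sigma = 0.8, Q = 1.0),
  gompertz = list(shape = 0.05, rate = 0.01),
  lognormal = list(meanlog = 3.5, sdlog = 1.6),
  loglogistic = list(shape = 1.5, scale = 38))

test_that("survivor functions hit their closed-form anchors", {
  ln <- surv_model("lognormal", meanlog = 3.827, sdlog = 1.727)
  expect_equal(surv_prob(ln, exp(3.827)), 0.5)
  ll <- surv_model("loglogistic", shape = 1.012, scale = 38.350)
  expect_equal(surv_prob(ll, 38.350), 0.5)
  for (fam in names(FAMILY_EXAMPLES)) {
    m <- do.call(surv_model, c(list(fam), FAMILY_EXAMPLES[[fam]]))
    expect_identical(surv_prob(m, 0), 1)
    expect_error(surv_prob(m, -1), "non-negative")
    # S non-increasing on a grid
    s <- surv_prob(m, seq(0, 500, by = 0.5))
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
    # quantile inverts the survivor function (where S is still positive)
    tt <- c(1, 10, 50)
    expect_equal(surv_quantile(m, surv_prob(m, tt)), tt, tolerance = 1e-6)
  }
  expect_error(surv_model("lognormal", meanlog = 1, sdlog = -1), "positive")
})

test_that("densities integrate to one", {
  for (fam in names(FAMILY_EXAMPLES)) {
    m <- do.call(surv_model, c(list(fam), FAMILY_EXAMPLES[[fam]]))
    total <- integrate(function(t) surv_dens(m, t), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("exponential MLE matches the events-over-exposure closed form", {
  m <- surv_model("exponential", rate = 0.05)
  ipd <- simulate_ipd(m, 3000, accrual_months = 0, study_months = Inf,
                      dropout_rate = 0, seed = 5)
  fit <- fit_parametric(ipd, "exponential")
  oracle_rate <- sum(ipd$event) / sum(ipd$time)
  expect_equal(fit$model$pars$rate, oracle_rate, tolerance = 1e-4)
  expect_lt(abs(fit$model$pars$rate - 0.05), 3 * 0.05 / sqrt(3000))
  expect_true(fit$converged)
  # censored data uses events over total exposure too
  ipd2 <- simulate_ipd(m, 3000, seed = 6)
  fit2 <- fit_parametric(ipd2, "exponential")
  expect_equal(fit2$model$pars$rate, sum(ipd2$event) / sum(ipd2$time),
               tolerance = 1e-4)
})

test_that("AIC and BIC obey their definitions on every report", {
  ipd <- simulate_ipd(surv_model("lognormal", meanlog = 3.5, sdlog = 1.6),
                      300, seed = 7)
  for (fam in c("exponential", "weibull", "lognormal")) {
    f <- fit_parametric(ipd, fam)
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$loglik)
  }
  f <- fit_parametric(ipd, "exponential")
  expect_equal(f$aic - f$bic, 2 - log(f$n))  # single-parameter identity
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  # scaled-down recovery sweep: mean estimate over replicates within 5%
  reps <- 6; n <- 3000
  for (fam in names(FAMILY_EXAMPLES)) {
    tru <- unlist(FAMILY_EXAMPLES[[fam]])
    est <- matrix(0, reps, length(tru))
    for (r in seq_len(reps)) {
      ipd <- simulate_ipd(do.call(surv_model, c(list(fam), FAMILY_EXAMPLES[[fam]])),
                          n, accrual_months = 0, study_months = Inf,
                          dropout_rate = 0, seed = 100 + r)
      est[r, ] <- unlist(fit_parametric(ipd, fam)$model$pars)
    }
    bias <- colMeans(est) / tru - 1
    expect_true(all(abs(bias) < 0.05),
                label = paste0(fam, " bias: ",
                               paste(signif(bias, 2), collapse = ", ")))
  }
})

test_that("AIC selection identifies the generating family", {
  m <- surv_model("lognormal", meanlog = 3.501, sdlog = 1.598)
  wins <- 0; reps <- 20
  for (r in seq_len(reps)) {
    ipd <- simulate_ipd(m, 1000, accrual_months = 0, study_months = 120,
                        dropout_rate = 0.002, seed = 200 + r)
    f_ln <- fit_parametric(ipd, "lognormal")
    f_ex <- fit_parametric(ipd, "exponential")
    if (f_ln$aic < f_ex$aic) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.95)
  # full seven-family selection lands on the log-normal in the modal case
  picks <- character(5)
  for (r in 1:5) {
    ipd <- simulate_ipd(m, 1000, accrual_months = 0, study_months = 120,
                        dropout_rate = 0.002, seed = 300 + r)
    picks[r] <- select_best_fit(fit_all_families(ipd))$model$family
  }
  expect_equal(names(which.max(table(picks))), "lognormal")
})

test_that("select_best_fit applies the documented tie-breaks", {
  mk <- function(ll, n, k) psmcea:::new_surv_fit(
    surv_model("exponential", rate = 1), loglik = ll, n = n, k = k)
  a <- mk(-50, 100, 1); b <- mk(-45, 100, 1)  # aic 102 vs 92
  expect_equal(select_best_fit(list(a, b))$aic, b$aic)
  # equal AIC -> lower BIC wins
  a <- mk(-50, 100, 1)                       # aic 102, bic 104.6
  b <- mk(-49, 100, 2); b$aic <- a$aic       # force tie, bic 107.2 vs 104.6
  expect_equal(select_best_fit(list(b, a))$bic, a$bic)
  # disagreement flag when AIC- and BIC-best differ
  a <- mk(-50, 1000, 1)                       # aic 102, bic 106.9
  b <- mk(-48.5, 1000, 2)                     # aic 101, bic 110.8
  expect_true(attr(select_best_fit(list(a, b)), "disagreement"))
  c1 <- mk(-50, 100, 1); c2 <- mk(-50, 200, 1)
  expect_error(select_best_fit(list(c1, c2)), "mismatched n")
})

test_that("Royston-Parmar splines nest the Weibull and track the truth", {
  m <- surv_model("lognormal", meanlog = 3.827, sdlog = 1.727)
  ipd <- simulate_ipd(m, 1500, accrual_months = 0, study_months = 150,
                      dropout_rate = 0.002, seed = 42)
  wb <- fit_parametric(ipd, "weibull")
  rp0 <- fit_rp_spline(ipd, internal_knots = 0)
  expect_equal(rp0$loglik, wb$loglik, tolerance = 1e-4)
  rp1 <- fit_rp_spline(ipd, internal_knots = 1)
  expect_gte(rp1$loglik, wb$loglik - 1e-6)  # nested-model dominance
  tt <- seq(1, 120, by = 1)
  expect_lt(max(abs(surv_prob(rp1$model, tt) - surv_prob(m, tt))), 0.05)
  expect_error(fit_rp_spline(ipd[1:5, ], 1), "at least 10 events")
  expect_error(fit_rp_spline(ipd, 5), "internal_knots")
})

test_that("degenerate inputs are rejected", {
  all_cens <- data.frame(time = 1:20, event = 0)
  expect_error(fit_parametric(all_cens, "exponential"), "at least 2 events")
  expect_error(fit_parametric(data.frame(time = -1, event = 1), "weibull"),
               "non-negative")
})
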