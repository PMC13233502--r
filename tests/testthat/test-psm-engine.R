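test_that("state occupancies conserve the cohort at every cycle", {
  mods <- base_models_tbl()
  for (arm in list(c("pfs_ven", "os_ven"), c("pfs_pbo", "os_pbo"))) {
    tr <- psm_trace(mods[[arm[1]]], mods[[arm[2]]])
    expect_equal(nrow(tr), 421)  # 35 years of monthly cycles + baseline
    expect_true(all(abs(tr$occ_pfs + tr$occ_pd + tr$occ_dead - 1) < 1e-12))
    expect_true(all(tr$occ_pfs >= 0 & tr$occ_pfs <= 1))
    expect_true(all(diff(tr$occ_dead) >= 0))
    expect_equal(tr$occ_pfs[1], 1)
    expect_equal(sum(tr$new_deaths), tr$occ_dead[nrow(tr)], tolerance = 1e-9)
  }
})

test_that("fraction dead at the horizon matches the printed extrapolations", {
  # direct evaluation of the fitted survivor functions at 420 months:
  # a tenth of the cohort is still alive under these heavy-tailed fits
  mods <- base_models_tbl()
  tr_v <- psm_trace(mods$pfs_ven, mods$os_ven)
  tr_p <- psm_trace(mods$pfs_pbo, mods$os_pbo)
  expect_equal(tail(tr_v$occ_dead, 1), 1 - surv_prob(mods$os_ven, 420))
  expect_gt(tail(tr_v$occ_dead, 1), 0.85)
  expect_gt(tail(tr_p$occ_dead, 1), 0.85)
  expect_lt(tail(tr_v$occ_dead, 1), 0.95)
})

test_that("identical PFS and OS curves leave the PD state empty", {
  m <- surv_model("lognormal", meanlog = 3.5, sdlog = 1.6)
  tr <- psm_trace(m, m, horizon_years = 10)
  expect_true(all(tr$occ_pd == 0))
})

test_that("near-immortal OS gives the closed-form PD occupancy", {
  s_os <- surv_model("exponential", rate = 1e-12)
  s_pfs <- surv_model("exponential", rate = 0.05)
  tr <- psm_trace(s_pfs, s_os, horizon_years = 10)
  expect_true(all(tr$occ_dead < 1e-9))
  expect_equal(tr$occ_pd, 1 - exp(-0.05 * tr$time), tolerance = 1e-6)
})

test_that("accrual conserves time with no discounting and full utility", {
  s1 <- surv_model("exponential", rate = 1e-12)
  tr <- psm_trace(s1, s1, horizon_years = 10)
  res <- accrue(tr, cost = rep(0, 120), u_pfs = 1, u_pd = 1,
                annual_discount = 0)
  expect_equal(res$ly, 10, tolerance = 1e-6)
  expect_equal(res$qaly, 10, tolerance = 1e-6)
})

test_that("exponential life expectancy approaches 1/lambda", {
  lambda <- 0.2                       # per year
  m <- surv_model("exponential", rate = lambda / 12)
  tr <- psm_trace(m, m, horizon_years = 20 / lambda)
  res <- accrue(tr, rep(0, nrow(tr) - 1), 1, 1, annual_discount = 0)
  expect_equal(res$ly, 1 / lambda, tolerance = 1e-3)
})

test_that("discounting strictly shrinks every accumulator", {
  mods <- base_models_tbl()
  tr <- psm_trace(mods$pfs_ven, mods$os_ven)
  cost <- rep(100, nrow(tr) - 1)
  r0 <- accrue(tr, cost, 0.827, 0.68, annual_discount = 0)
  r5 <- accrue(tr, cost, 0.827, 0.68, annual_discount = 0.05)
  expect_lt(r5$ly, r0$ly)
  expect_lt(r5$qaly, r0$qaly)
  expect_lt(r5$cost, r0$cost)
  expect_lte(r5$ly, r5$ly_undisc)
  expect_lte(r5$qaly, r5$ly)  # utilities are below one
})

test_that("life-years match continuous quadrature of the OS curve", {
  mods <- base_models_tbl()
  for (nm in c("os_ven", "os_pbo")) {
    tr <- psm_trace(mods[[nm]], mods[[nm]])
    res <- accrue(tr, rep(0, 420), 1, 1, annual_discount = 0)
    expect_equal(res$ly, oracle_ly(mods[[nm]], 420), tolerance = 5e-3)
  }
  # and for the PFS curves used as standalone survivor functions
  for (nm in c("pfs_ven", "pfs_pbo")) {
    tr <- psm_trace(mods[[nm]], mods[[nm]])
    res <- accrue(tr, rep(0, 420), 1, 1, annual_discount = 0)
    expect_equal(res$ly, oracle_ly(mods[[nm]], 420), tolerance = 5e-3)
  }
})

test_that("halving the cycle length moves results by less than half a percent", {
  for (co in c("china", "us")) {
    p <- default_parameters(co)
    full <- evaluate_ce(p, co, cycle_months = 1)
    half <- evaluate_ce(p, co, cycle_months = 0.5)
    for (arm in c("ven", "pbo")) {
      expect_lt(abs(half[[arm]]$ly / full[[arm]]$ly - 1), 0.005)
      expect_lt(abs(half[[arm]]$qaly / full[[arm]]$qaly - 1), 0.005)
      expect_lt(abs(half[[arm]]$cost / full[[arm]]$cost - 1), 0.005)
    }
  }
})

test_that("the ICER is currency-invariant up to exact scaling", {
  p <- default_parameters("china")
  base <- evaluate_ce(p, "china")
  c_rows <- p$category %in% psmcea:::COST_CATEGORIES
  p2 <- p
  p2$base[c_rows] <- p2$base[c_rows] * 7.1217
  p2$low[c_rows] <- p2$low[c_rows] * 7.1217
  p2$high[c_rows] <- p2$high[c_rows] * 7.1217
  scaled <- evaluate_ce(p2, "china")
  expect_equal(scaled$icer, base$icer * 7.1217, tolerance = 1e-9)
  expect_equal(scaled$dqaly, base$dqaly, tolerance = 1e-12)
})

test_that("icer() handles ratios, dominance and zero QALY differences", {
  expect_equal(icer(list(cost = 200, qaly = 2), list(cost = 100, qaly = 1)), 100)
  expect_equal(icer(list(cost = 100, qaly = 2), list(cost = 200, qaly = 1)),
               "dominant")
  expect_equal(icer(list(cost = 200, qaly = 1), list(cost = 100, qaly = 2)),
               "dominated")
  expect_equal(icer(list(cost = 200, qaly = 1), list(cost = 100, qaly = 1)), Inf)
  # arithmetic on the published rounded table cells lands within 1.5%
  # of the published unrounded-accumulator ratio
  rounded <- icer(list(cost = 131805.05, qaly = 4.53),
                  list(cost = 48991.09, qaly = 3.89))
  expect_equal(rounded, 82813.96 / 0.64, tolerance = 1e-9)
  expect_lt(abs(rounded / 128183.93 - 1), 0.015)
})

test_that("accrual rejects invalid schedules", {
  m <- surv_model("exponential", rate = 0.05)
  tr <- psm_trace(m, m, horizon_years = 1)
  expect_error(accrue(tr, rep(-1, 12), 1, 1), "negative")
  expect_error(accrue(tr, rep(1, 5), 1, 1), "length")
  expect_error(accrue(tr, rep(1, 12), 1.2, 0.5), "\\[0, 1\\]")
})
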