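#' Scenario specification and execution
#'
#' A scenario is a set of overrides on the base configuration: price
#' multipliers on drug acquisition costs, an alternative horizon, an
#' alternative utility set, or alternative fitted survival models. The four
#' published scenario families are shorter horizons (10/20 years), the
#' venetoclax price grid (80/60/40/20% of list price), flexible
#' (Royston-Parmar) survival models, and alternative utilities
#' (PFS 0.843, PD 0.743).
#'
#' @param label Scenario label.
#' @param price_multipliers Named numeric vector of non-negative multipliers
#'   applied to drug price rows, e.g. `c(venetoclax = 0.2)`; names must be
#'   drugs in the price list (`ibrutinib`, `venetoclax`, `rituximab`,
#'   `bendamustine`).
#' @param horizon_years Optional horizon override.
#' @param utilities Optional list with elements `u_pfs` (applied to both
#'   arms) and/or `u_pd`.
#' @param survival Optional survival-model override as in [evaluate_ce()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label = "scenario", price_multipliers = NULL,
                          horizon_years = NULL, utilities = NULL,
                          survival = NULL) {
  if (!is.null(price_multipliers)) {
    if (is.null(names(price_multipliers)) || any(price_multipliers < 0))
      stop("price_multipliers must be a named, non-negative vector")
  }
  structure(list(label = label, price_multipliers = price_multipliers,
                 horizon_years = horizon_years, utilities = utilities,
                 survival = survival), class = "scenario_spec")
}

apply_scenario <- function(params, spec) {
  for (drug in names(spec$price_multipliers))
    params <- scale_param(params, paste0("cost_", drug),
                          spec$price_multipliers[[drug]])
  if (!is.null(spec$utilities$u_pfs)) {
    params <- set_param(params, "u_pfs_ven", spec$utilities$u_pfs)
    params <- set_param(params, "u_pfs_pbo", spec$utilities$u_pfs)
  }
  if (!is.null(spec$utilities$u_pd))
    params <- set_param(params, "u_pd", spec$utilities$u_pd)
  params
}

#' Run one scenario
#'
#' Applies the overrides and re-runs the full deterministic pipeline;
#' optionally also a seeded PSA reporting the acceptance probability at the
#' country threshold.
#'
#' @param country `"china"` or `"us"`.
#' @param spec A [scenario_spec()].
#' @param params Base parameter table.
#' @param psa_n Number of PSA draws (0 = deterministic only).
#' @param seed Seed for the optional PSA.
#' @param ... Passed to [evaluate_ce()].
#' @return A `ce_result`; when `psa_n > 0` it carries an `acceptability`
#'   element (probability cost-effective at the country threshold).
#' @export
run_scenario <- function(country = c("china", "us"), spec = scenario_spec(),
                         params = default_parameters(country),
                         psa_n = 0, seed = 1, ...) {
  country <- match.arg(country)
  stopifnot(inherits(spec, "scenario_spec"))
  p <- apply_scenario(params, spec)
  args <- list(...)
  if (!is.null(spec$horizon_years)) args$horizon_years <- spec$horizon_years
  res <- do.call(evaluate_ce,
                 c(list(p, country, survival = spec$survival), args))
  res$label <- spec$label
  if (psa_n > 0)
    res$acceptability <- psa_probability(
      do.call(psa, c(list(country, p, n = psa_n, seed = seed), args)))
  res
}

#' The published scenario grid for one country
#'
#' Base case, 10- and 20-year horizons, the venetoclax price ladder and the
#' alternative utility set, as one tidy table.
#'
#' @inheritParams run_scenario
#' @return Data frame with one row per scenario: label, per-arm cost/LY/
#'   QALY of the intervention arm, and the ICER.
#' @export
scenario_table <- function(country = c("china", "us"),
                           params = default_parameters(country), ...) {
  country <- match.arg(country)
  specs <- c(list(scenario_spec("base case")),
             lapply(c(10, 20), function(h)
               scenario_spec(paste0(h, "-year horizon"), horizon_years = h)),
             lapply(c(0.8, 0.6, 0.4, 0.2), function(m)
               scenario_spec(sprintf("%d%% price of venetoclax", m * 100),
                             price_multipliers = c(venetoclax = m))),
             list(scenario_spec("alternative utilities",
                                utilities = list(u_pfs = 0.843, u_pd = 0.743))))
  do.call(rbind, lapply(specs, function(s) {
    r <- run_scenario(country, s, params, ...)
    data.frame(scenario = s$label, cost_ven = r$ven$cost, ly_ven = r$ven$ly,
               qaly_ven = r$ven$qaly, cost_pbo = r$pbo$cost,
               icer = if (is.numeric(r$icer)) r$icer else NA)
  }))
}

#' Alternative-utility scenario
#'
#' Re-runs both countries with PFS utility 0.843 (both arms) and PD utility
#' 0.743.
#'
#' @param countries Countries to run.
#' @param ... Passed to [evaluate_ce()].
#' @return Named list of `ce_result` objects.
#' @export
alternative_utility_scenario <- function(countries = c("china", "us"), ...) {
  spec <- scenario_spec("alternative utilities",
                        utilities = list(u_pfs = 0.843, u_pd = 0.743))
  res <- lapply(countries, function(co) run_scenario(co, spec, ...))
  names(res) <- countries
  res
}

#' Flexible-model scenario: Royston-Parmar refits
#'
#' Re-estimates all four survival curves as Royston-Parmar splines on
#' synthetic individual patient data simulated from the base-case fits
#' (the trial's source coordinates are not published, so this scenario
#' characterises model-choice uncertainty rather than reproducing any
#' specific published row), then re-runs the pipeline.
#'
#' @inheritParams run_scenario
#' @param internal_knots Internal knots for each spline fit.
#' @param n_sim Subjects per simulated curve.
#' @return A `ce_result` with the refitted models attached as `survival`.
#' @export
flexible_model_scenario <- function(country = c("china", "us"),
                                    params = default_parameters(country),
                                    internal_knots = 1, n_sim = 500,
                                    seed = 1, ...) {
  country <- match.arg(country)
  mods <- base_survival_models(params)
  refit <- list()
  k <- 0
  for (a in c("ven", "pbo")) {
    refit[[a]] <- list()
    for (ep in c("pfs", "os")) {
      k <- k + 1
      ipd <- simulate_ipd(mods[[a]][[ep]], n_sim, seed = seed + k)
      refit[[a]][[ep]] <- fit_rp_spline(ipd, internal_knots)$model
    }
  }
  res <- run_scenario(country, scenario_spec("flexible parametric models",
                                             survival = refit),
                      params, ...)
  res$survival <- refit
  res
}

#' Price-reduction threshold search
#'
#' Bisection on a common price multiplier applied to the selected drugs,
#' seeking either the multiplier at which the deterministic ICER equals the
#' willingness-to-pay threshold, or the one at which a seeded PSA gives a
#' 50% probability of cost-effectiveness. The criterion is monotone in the
#' multiplier (drug spending is linear in price), which the search asserts
#' via its bracket.
#'
#' @param country `"china"` or `"us"`.
#' @param drugs Drugs sharing the multiplier (default both ibrutinib and
#'   venetoclax).
#' @param criterion `"icer_equals_wtp"` (deterministic) or
#'   `"psa_probability_half"`.
#' @param params Base parameter table.
#' @param n PSA draws per evaluation (PSA criterion).
#' @param seed Seed reused for every PSA evaluation so the criterion is a
#'   deterministic function of the multiplier.
#' @param tol Bisection tolerance on the multiplier.
#' @param ... Passed to [evaluate_ce()].
#' @return The multiplier in `[0, 1]`, or `NA` with attribute
#'   `status = "unattainable"` when even free drugs do not meet the
#'   criterion. Attribute `criterion_value` reports the achieved ICER or
#'   probability.
#' @export
price_threshold <- function(country = c("china", "us"),
                            drugs = c("ibrutinib", "venetoclax"),
                            criterion = c("icer_equals_wtp",
                                          "psa_probability_half"),
                            params = default_parameters(country),
                            n = 1000, seed = 1, tol = 1e-3, ...) {
  country <- match.arg(country)
  criterion <- match.arg(criterion)
  wtp <- country_setting(country, params)$wtp
  mult <- setNames(rep(1, length(drugs)), drugs)
  # gap(m) < 0 means the criterion is met at multiplier m; gap is
  # non-decreasing in m
  gap <- function(m) {
    p <- apply_scenario(params, scenario_spec(price_multipliers = mult * m))
    if (criterion == "icer_equals_wtp") {
      ic <- evaluate_ce(p, country, ...)$icer
      if (identical(ic, "dominant")) -Inf else ic - wtp
    } else {
      0.5 - psa_probability(psa(country, p, n = n, seed = seed, ...), wtp)
    }
  }
  g1 <- gap(1)
  if (g1 <= 0) {
    out <- 1
    attr(out, "criterion_value") <- g1
    return(out)
  }
  g0 <- gap(0)
  if (g0 > 0) {
    out <- NA_real_
    attr(out, "status") <- "unattainable"
    return(out)
  }
  lo <- 0; hi <- 1
  repeat {
    mid <- (lo + hi) / 2
    g <- gap(mid)
    if (criterion == "psa_probability_half" && abs(g) < 0.01) break
    if (g > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) { mid <- (lo + hi) / 2; g <- gap(mid) }
    if (hi - lo < tol) break
  }
  out <- mid
  attr(out, "criterion_value") <- if (criterion == "icer_equals_wtp")
    g + wtp else 0.5 - g
  out
}
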