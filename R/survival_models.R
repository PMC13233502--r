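#' Parametric survival models
#'
#' Light-weight survival model objects used by the partitioned survival
#' engine. A `surv_model` is a family name plus a named parameter vector in
#' the standard survival-analysis parameterization, chosen so that the
#' published fitted parameters are directly interpretable: the log-normal
#' uses `meanlog`/`sdlog` on log-months, and the log-logistic uses
#' `S(t) = 1 / (1 + (t/scale)^shape)` so that `scale` is the median survival
#' in months. Time is in months throughout.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gamma"`,
#'   `"generalized_gamma"`, `"gompertz"`, `"lognormal"`, `"loglogistic"`,
#'   `"rp_spline"`.
#' @param ... Named parameters for the family (see Details).
#' @details Parameter names by family: exponential `rate`; weibull
#'   `shape, scale`; gamma `shape, rate`; generalized_gamma `mu, sigma, Q`
#'   (location-scale-shape form, `Q -> 0` recovering the log-normal);
#'   gompertz `shape, rate`; lognormal `meanlog, sdlog`; loglogistic
#'   `shape, scale`; rp_spline `gamma` (spline coefficients) and `knots`
#'   (log-time knot locations including the boundary knots).
#' @return An object of class `surv_model`.
#' @export
#' @examples
#' m <- surv_model("lognormal", meanlog = 3.827, sdlog = 1.727)
#' surv_prob(m, exp(3.827))  # 0.5 at the median
surv_model <- function(family, ...) {
  family <- match.arg(family, SURV_FAMILIES)
  pars <- list(...)
  need <- SURV_PARS[[family]]
  if (!all(need %in% names(pars)))
    stop(family, " model needs parameters: ", paste(need, collapse = ", "))
  pos <- intersect(names(pars), SURV_POSITIVE[[family]])
  bad <- vapply(pars[pos], function(x) any(x <= 0), logical(1))
  if (any(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(pos[bad], collapse = ", "))
  structure(list(family = family, pars = pars), class = "surv_model")
}

SURV_FAMILIES <- c("exponential", "weibull", "gamma", "generalized_gamma",
                   "gompertz", "lognormal", "loglogistic", "rp_spline")

SURV_PARS <- list(
  exponential = "rate", weibull = c("shape", "scale"),
  gamma = c("shape", "rate"), generalized_gamma = c("mu", "sigma", "Q"),
  gompertz = c("shape", "rate"), lognormal = c("meanlog", "sdlog"),
  loglogistic = c("shape", "scale"), rp_spline = c("gamma", "knots"))

SURV_POSITIVE <- list(
  exponential = "rate", weibull = c("shape", "scale"),
  gamma = c("shape", "rate"), generalized_gamma = "sigma",
  gompertz = "rate", lognormal = "sdlog",
  loglogistic = c("shape", "scale"), rp_spline = character(0))

# flexsurv distribution codes for the seven standard families
FLEXSURV_DIST <- c(exponential = "exp", weibull = "weibull", gamma = "gamma",
                   generalized_gamma = "gengamma", gompertz = "gompertz",
                   lognormal = "lnorm", loglogistic = "llogis")

# flexsurv parameter names -> ours (same order as fit$res rows)
FLEXSURV_PARS <- list(
  exponential = c(rate = "rate"),
  weibull = c(shape = "shape", scale = "scale"),
  gamma = c(shape = "shape", rate = "rate"),
  generalized_gamma = c(mu = "mu", sigma = "sigma", Q = "Q"),
  gompertz = c(shape = "shape", rate = "rate"),
  lognormal = c(meanlog = "meanlog", sdlog = "sdlog"),
  loglogistic = c(shape = "shape", scale = "scale"))

#' @export
print.surv_model <- function(x, ...) {
  p <- x$pars[setdiff(names(x$pars), "knots")]
  cat("<surv_model> ", x$family, ": ",
      paste(names(p), vapply(p, function(v) paste(signif(v, 5), collapse = ","),
                             ""), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Survivor function, density and censored log-likelihood
#'
#' `surv_prob()` evaluates `S(t)`; `surv_dens()` the density `f(t)`;
#' `surv_loglik()` the right-censored log-likelihood
#' `sum(event * log f(t) + (1 - event) * log S(t))`.
#'
#' @param model A [surv_model()].
#' @param t Time(s) in months, `t >= 0`.
#' @return Numeric vector of the same length as `t`.
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "surv_model"))
  if (any(t < 0)) stop("survival time must be non-negative")
  p <- model$pars
  out <- switch(model$family,
    exponential = exp(-p$rate * t),
    weibull = exp(-(t / p$scale)^p$shape),
    gamma = stats::pgamma(t, shape = p$shape, rate = p$rate, lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = p$mu, sigma = p$sigma,
                                            Q = p$Q, lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = p$shape, rate = p$rate,
                                   lower.tail = FALSE),
    lognormal = stats::plnorm(t, p$meanlog, p$sdlog, lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / p$scale)^p$shape),
    rp_spline = flexsurv::psurvspline(t, gamma = p$gamma, knots = p$knots,
                                      scale = "hazard", lower.tail = FALSE))
  out[t == 0] <- 1
  out
}

#' @rdname surv_prob
#' @export
surv_dens <- function(model, t) {
  stopifnot(inherits(model, "surv_model"))
  p <- model$pars
  switch(model$family,
    exponential = stats::dexp(t, p$rate),
    weibull = stats::dweibull(t, p$shape, p$scale),
    gamma = stats::dgamma(t, shape = p$shape, rate = p$rate),
    generalized_gamma = flexsurv::dgengamma(t, mu = p$mu, sigma = p$sigma, Q = p$Q),
    gompertz = flexsurv::dgompertz(t, shape = p$shape, rate = p$rate),
    lognormal = stats::dlnorm(t, p$meanlog, p$sdlog),
    loglogistic = flexsurv::dllogis(t, shape = p$shape, scale = p$scale),
    rp_spline = flexsurv::dsurvspline(t, gamma = p$gamma, knots = p$knots,
                                      scale = "hazard"))
}

#' @rdname surv_prob
#' @param time,event Follow-up times (months) and event indicators
#'   (1 = event, 0 = censored).
#' @export
surv_loglik <- function(model, time, event) {
  sum(ifelse(event == 1, log(surv_dens(model, time)),
             log(surv_prob(model, time))))
}

#' Inverse survivor function (quantiles of the event-time distribution)
#'
#' Returns `t` such that `S(t) = s`. Used by the synthetic-data generator
#' for inverse-CDF sampling.
#'
#' @param model A [surv_model()].
#' @param s Survival probabilities in (0, 1].
#' @return Times in months.
#' @export
surv_quantile <- function(model, s) {
  stopifnot(inherits(model, "surv_model"), all(s > 0 & s <= 1))
  p <- model$pars
  switch(model$family,
    exponential = -log(s) / p$rate,
    weibull = p$scale * (-log(s))^(1 / p$shape),
    gamma = stats::qgamma(s, shape = p$shape, rate = p$rate, lower.tail = FALSE),
    generalized_gamma = flexsurv::qgengamma(s, mu = p$mu, sigma = p$sigma,
                                            Q = p$Q, lower.tail = FALSE),
    gompertz = flexsurv::qgompertz(s, shape = p$shape, rate = p$rate,
                                   lower.tail = FALSE),
    lognormal = stats::qlnorm(s, p$meanlog, p$sdlog, lower.tail = FALSE),
    loglogistic = p$scale * (1 / s - 1)^(1 / p$shape),
    rp_spline = flexsurv::qsurvspline(s, gamma = p$gamma, knots = p$knots,
                                      scale = "hazard", lower.tail = FALSE))
}

#' Maximum-likelihood fit of a parametric family to right-censored data
#'
#' Fits one of the seven standard families by maximizing the right-censored
#' log-likelihood (via [flexsurv::flexsurvreg()]) and reports the fit with
#' AIC and BIC. Non-convergence is flagged on the report, not silently
#' ignored.
#'
#' @param data A data frame with columns `time` (months) and `event`
#'   (1 = event, 0 = censored), as produced by [simulate_ipd()] or
#'   [reconstruct_ipd()].
#' @param family One of the seven standard family names (not `rp_spline`;
#'   see [fit_rp_spline()]).
#' @return An object of class `surv_fit`: list with elements `model`
#'   ([surv_model()]), `loglik`, `aic`, `bic`, `n`, `k`, `converged`.
#' @export
fit_parametric <- function(data, family) {
  family <- match.arg(family, setdiff(SURV_FAMILIES, "rp_spline"))
  check_ipd(data)
  if (sum(data$event == 1) < 2)
    stop("need at least 2 events to fit a parametric model")
  fit <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = data,
                               dist = FLEXSURV_DIST[[family]])
  est <- fit$res[, "est"]
  pars <- as.list(unname(est))
  names(pars) <- names(FLEXSURV_PARS[[family]])
  model <- do.call(surv_model, c(list(family = family), pars))
  new_surv_fit(model, loglik = fit$loglik, n = nrow(data), k = fit$npars,
               converged = is.null(fit$opt$convergence) ||
                 fit$opt$convergence == 0)
}

new_surv_fit <- function(model, loglik, n, k, converged = TRUE) {
  structure(list(model = model, loglik = loglik,
                 aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik,
                 n = n, k = k, converged = converged),
            class = "surv_fit")
}

#' @export
print.surv_fit <- function(x, ...) {
  cat(sprintf("<surv_fit> %s  loglik %.3f  AIC %.2f  BIC %.2f  (n=%d, k=%d%s)\n",
              x$model$family, x$loglik, x$aic, x$bic, x$n, x$k,
              if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' Fit all seven standard families
#'
#' @inheritParams fit_parametric
#' @return Named list of `surv_fit` objects.
#' @export
fit_all_families <- function(data) {
  fams <- setdiff(SURV_FAMILIES, "rp_spline")
  fits <- lapply(fams, function(f) {
    tryCatch(fit_parametric(data, f), error = function(e) NULL)
  })
  names(fits) <- fams
  Filter(Negate(is.null), fits)
}

#' Select the best-fitting model by AIC, then BIC
#'
#' Picks the report with the lowest AIC; ties are broken by lowest BIC, then
#' fewest parameters. When the AIC-best and BIC-best models disagree the
#' returned report carries `disagreement = TRUE` so the analyst can inspect
#' the extrapolations visually.
#'
#' @param reports A list of `surv_fit` objects fitted to the same dataset.
#' @return The selected `surv_fit`, with attribute `disagreement`.
#' @export
select_best_fit <- function(reports) {
  stopifnot(length(reports) >= 1)
  n <- vapply(reports, `[[`, numeric(1), "n")
  if (length(unique(n)) != 1L)
    stop("fit reports come from different datasets (mismatched n)")
  aic <- vapply(reports, `[[`, numeric(1), "aic")
  bic <- vapply(reports, `[[`, numeric(1), "bic")
  k <- vapply(reports, `[[`, numeric(1), "k")
  best <- order(aic, bic, k)[1]
  out <- reports[[best]]
  attr(out, "disagreement") <- best != order(bic, aic, k)[1]
  out
}

#' Royston-Parmar spline fit on the log-cumulative-hazard scale
#'
#' Restricted cubic spline for `log(-log S(t))` against `log t`
#' (proportional-hazards scale) maximizing the right-censored likelihood,
#' via [flexsurv::flexsurvspline()]. Boundary knots sit at the extreme
#' uncensored log event times and internal knots at event-time quantiles.
#' With zero internal knots the model coincides with the Weibull.
#'
#' @inheritParams fit_parametric
#' @param internal_knots Number of internal knots, 0 to 3.
#' @return A `surv_fit` whose model has family `"rp_spline"`.
#' @export
fit_rp_spline <- function(data, internal_knots = 1) {
  check_ipd(data)
  if (!internal_knots %in% 0:3)
    stop("internal_knots must be 0, 1, 2 or 3")
  n_events <- sum(data$event == 1)
  if (n_events < 10)
    stop("need at least 10 events for a spline fit; have ", n_events)
  fit <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ 1, data = data,
                                  k = internal_knots, scale = "hazard")
  model <- surv_model("rp_spline", gamma = unname(fit$res[, "est"]),
                      knots = fit$knots)
  new_surv_fit(model, loglik = fit$loglik, n = nrow(data), k = fit$npars,
               converged = is.null(fit$opt$convergence) ||
                 fit$opt$convergence == 0)
}

check_ipd <- function(data) {
  if (!all(c("time", "event") %in% names(data)))
    stop("IPD needs columns `time` and `event`")
  if (any(!is.finite(data$time)) || any(data$time < 0))
    stop("IPD times must be finite and non-negative")
  if (!all(data$event %in% c(0, 1)))
    stop("IPD event flags must be 0 or 1")
  invisible(data)
}

#' The four fitted base-case survival models
#'
#' Builds the fitted extrapolation models from a parameter table: log-normal
#' OS and PFS for the ibrutinib+venetoclax arm, log-logistic OS and
#' log-normal PFS for the ibrutinib+placebo arm.
#'
#' @param params A `ce_params` table (default: bundled values, which are
#'   country-invariant).
#' @return Nested list `list(ven = list(pfs, os), pbo = list(pfs, os))` of
#'   [surv_model()] objects.
#' @export
base_survival_models <- function(params = default_parameters("china")) {
  g <- function(nm) param_value(params, nm)
  list(
    ven = list(
      pfs = surv_model("lognormal", meanlog = g("pfs_ven_meanlog"),
                       sdlog = g("pfs_ven_sdlog")),
      os = surv_model("lognormal", meanlog = g("os_ven_meanlog"),
                      sdlog = g("os_ven_sdlog"))),
    pbo = list(
      pfs = surv_model("lognormal", meanlog = g("pfs_pbo_meanlog"),
                       sdlog = g("pfs_pbo_sdlog")),
      os = surv_model("loglogistic", shape = g("os_pbo_shape"),
                      scale = g("os_pbo_scale"))))
}
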