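#' One-way (deterministic) sensitivity analysis
#'
#' Re-runs the full two-arm pipeline with each parameter set to its low and
#' then its high bound, all other inputs at base case, and records the ICER
#' at both endpoints. Rows are ordered by descending span for tornado
#' plotting. Parameters without a usable range (the fitted survival
#' parameters, zero risks) are skipped unless explicitly requested, in
#' which case they contribute a zero span.
#'
#' @param country `"china"` or `"us"`.
#' @param params Base parameter table.
#' @param parameters Optional character vector restricting the analysis;
#'   names absent from the table are an error.
#' @param ... Passed to [evaluate_ce()].
#' @return Data frame with columns `parameter`, `base`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`, sorted by descending span. The
#'   base-case ICER is attached as attribute `icer_base`.
#' @export
owsa <- function(country = c("china", "us"),
                 params = default_parameters(country),
                 parameters = NULL, ...) {
  country <- match.arg(country)
  if (is.null(parameters)) {
    rows <- owsa_rows(params)
  } else {
    rows <- match(parameters, params$name)
    if (anyNA(rows))
      stop("parameter(s) absent from the model: ",
           paste(parameters[is.na(rows)], collapse = ", "))
  }
  base_icer <- evaluate_ce(params, country, ...)$icer
  one <- function(i, value) {
    p <- params
    p$base[i] <- value
    r <- evaluate_ce(p, country, ...)$icer
    if (is.numeric(r)) r else NA_real_
  }
  res <- do.call(rbind, lapply(rows, function(i) {
    lo <- if (is.na(params$low[i])) params$base[i] else params$low[i]
    hi <- if (is.na(params$high[i])) params$base[i] else params$high[i]
    il <- if (lo == params$base[i]) base_icer else one(i, lo)
    ih <- if (hi == params$base[i]) base_icer else one(i, hi)
    data.frame(parameter = params$name[i], base = params$base[i],
               low = lo, high = hi, icer_low = il, icer_high = ih,
               span = abs(ih - il))
  }))
  res <- res[order(-res$span), ]
  rownames(res) <- NULL
  attr(res, "icer_base") <- base_icer
  res
}

#' Probabilistic sensitivity analysis
#'
#' Samples every distribution-labelled parameter from its moment-matched
#' gamma (costs, body surface area) or beta (probabilities, utilities)
#' distribution — standard deviations derived by [derive_sd()] — and
#' re-evaluates both arms per draw with the shared sampled vector. The
#' fitted survival parameters are labelled fixed and are not sampled, so
#' state occupancy is computed once and reused. Infeasible beta targets are
#' rejected at setup, before any draw is taken.
#'
#' @inheritParams owsa
#' @param n Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed; the same seed reproduces the draws exactly.
#' @param ... Passed to [evaluate_ce()].
#' @return Data frame of class `psa_result` with one row per draw: `draw`,
#'   `cost_ven`, `qaly_ven`, `cost_pbo`, `qaly_pbo`, `dcost`, `dqaly`.
#'   Attributes: `wtp`, `seed`, `sampled` (the draw matrix of sampled
#'   parameter values).
#' @export
psa <- function(country = c("china", "us"),
                params = default_parameters(country),
                n = 1000, seed = 1, ...) {
  country <- match.arg(country)
  stopifnot(n >= 1)
  rows <- sampled_rows(params)
  setup <- lapply(rows, function(i) {
    sd <- derive_sd(params$base[i], params$low[i], params$high[i])
    if (params$dist[i] == "gamma")
      c(list(dist = "gamma"), as.list(gamma_from_moments(params$base[i], sd)))
    else
      c(list(dist = "beta"), as.list(beta_from_moments(params$base[i], sd)))
  })
  set.seed(seed)
  draws <- vapply(setup, function(s) {
    if (s$dist == "gamma") stats::rgamma(n, shape = s$shape, rate = s$rate)
    else stats::rbeta(n, s$shape1, s$shape2)
  }, numeric(n))
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, params$name[rows]))
  dots <- list(...)
  horizon <- if (is.null(dots$horizon_years)) 35 else dots$horizon_years
  cm <- if (is.null(dots$cycle_months)) 1 else dots$cycle_months
  traces <- base_traces(params, horizon, cm)
  out <- vector("list", n)
  for (d in seq_len(n)) {
    p <- params
    p$base[rows] <- draws[d, ]
    r <- do.call(evaluate_ce, c(list(p, country, traces = traces), dots))
    out[[d]] <- c(r$ven$cost, r$ven$qaly, r$pbo$cost, r$pbo$qaly,
                  r$dcost, r$dqaly)
  }
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("cost_ven", "qaly_ven", "cost_pbo", "qaly_pbo",
                  "dcost", "dqaly")
  res <- cbind(draw = seq_len(n), res)
  attr(res, "wtp") <- country_setting(country, params)$wtp
  attr(res, "seed") <- seed
  attr(res, "sampled") <- draws
  class(res) <- c("psa_result", "data.frame")
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws whose
#' incremental net monetary benefit `wtp * dqaly - dcost` is non-negative.
#'
#' @param draws A [psa()] result.
#' @param wtp_grid Vector of willingness-to-pay values (USD/QALY).
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 3e5, by = 5e3)) {
  stopifnot(nrow(draws) > 0)
  prob <- vapply(wtp_grid, function(w) mean(w * draws$dqaly - draws$dcost >= 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' @rdname ceac
#' @param wtp A single willingness-to-pay threshold (defaults to the
#'   country threshold attached to the PSA result).
#' @return `psa_probability()` returns a single acceptance probability.
#' @export
psa_probability <- function(draws, wtp = attr(draws, "wtp")) {
  mean(wtp * draws$dqaly - draws$dcost >= 0)
}
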