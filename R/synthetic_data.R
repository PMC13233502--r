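#' Simulate right-censored survival data
#'
#' Draws event times from a parametric survival model by inverse-CDF
#' sampling and censors them by the minimum of an administrative cut-off
#' (uniform staggered accrual against a fixed study end) and exponential
#' dropout. The defaults emulate a trial-like follow-up in which roughly
#' half of the overall-survival records are still censored at the data cut-off, the
#' immature-follow-up regime in which the extrapolation actually operates.
#'
#' @param model A [surv_model()] generating the event times.
#' @param n Number of subjects.
#' @param accrual_months Length of the uniform accrual window; each
#'   subject's administrative censoring time is `study_months` minus their
#'   entry time. `0` puts everyone at full follow-up.
#' @param study_months Administrative cut-off measured from the start of
#'   accrual. Use `Inf` (with `dropout_rate = 0`) for uncensored data.
#' @param dropout_rate Exponential dropout hazard per month.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return Data frame with columns `time` (months) and `event`.
#' @export
#' @examples
#' ipd <- simulate_ipd(surv_model("lognormal", meanlog = 3.827, sdlog = 1.727),
#'                     n = 200, seed = 1)
#' mean(ipd$event)
simulate_ipd <- function(model, n, accrual_months = 24, study_months = 66,
                         dropout_rate = 0.002, seed = NULL) {
  stopifnot(inherits(model, "surv_model"), n >= 1,
            accrual_months >= 0, dropout_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  t_event <- surv_quantile(model, stats::runif(n))
  entry <- if (accrual_months > 0) stats::runif(n, 0, accrual_months) else rep(0, n)
  t_admin <- pmax(study_months - entry, 0)
  t_drop <- if (dropout_rate > 0) stats::rexp(n, dropout_rate) else rep(Inf, n)
  t_cens <- pmin(t_admin, t_drop)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Build a digitized-KM fixture from individual patient data
#'
#' Computes the exact Kaplan-Meier step coordinates of a dataset, optionally
#' perturbs the survival ordinates by uniform noise of half-width
#' `digitizer_noise` (emulating graph-digitizer precision) with monotonicity
#' restored by a running minimum, and tabulates the number at risk on the
#' supplied grid. The result feeds [reconstruct_ipd()] for round-trip
#' validation.
#'
#' @param data Data frame with `time` and `event` columns.
#' @param risk_times Time grid (months) for the number-at-risk table; must
#'   contain at least two values spanning the follow-up.
#' @param digitizer_noise Half-width of the uniform ordinate perturbation.
#' @param seed Optional seed for the perturbation.
#' @return A [km_digitized()] object.
#' @export
make_km_fixture <- function(data, risk_times = seq(0, 66, by = 6),
                            digitizer_noise = 0, seed = NULL) {
  check_ipd(data)
  if (nrow(data) == 0) stop("empty dataset")
  km <- km_curve(data)
  pts <- km[km$n_event > 0 | km$time == 0, c("time", "surv")]
  if (digitizer_noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- stats::runif(nrow(pts), -digitizer_noise, digitizer_noise)
    noise[pts$time == 0] <- 0
    pts$surv <- pmin(cummin(pmax(pts$surv + noise, 0)), 1)
  }
  risk_times <- sort(unique(risk_times))
  n_risk <- vapply(risk_times, function(t) sum(data$time >= t), numeric(1))
  keep <- n_risk > 0 | risk_times <= max(data$time)
  km_digitized(points = pts,
               risk_table = data.frame(time = risk_times[keep],
                                       n_risk = n_risk[keep]),
               total_events = sum(data$event))
}
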