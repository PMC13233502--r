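#' State occupancy of the three-state partitioned survival model
#'
#' Partitions the cohort among progression-free (PFS), progressed (PD) and
#' dead at every cycle boundary directly from the two survival curves:
#' `occ_pfs = min(S_PFS, S_OS)`, `occ_pd = max(0, S_OS - S_PFS)`,
#' `occ_dead = 1 - S_OS`. The clamp resolves any crossing of the
#' extrapolated curves so that PD occupancy is never negative. Incident
#' fractions are boundary first differences: `new_deaths` is the increase
#' in dead occupancy and `new_progressors` the decrease in PFS occupancy
#' (floored at zero), i.e. all exits from the progression-free state.
#'
#' @param s_pfs,s_os [surv_model()] objects for progression-free and overall
#'   survival (time in months).
#' @param horizon_years Simulation horizon in years (default 35).
#' @param cycle_months Cycle length in months (default 1).
#' @return A data frame of class `psm_trace` with one row per cycle boundary
#'   (cycle 0 .. N): `cycle`, `time` (months), `occ_pfs`, `occ_pd`,
#'   `occ_dead`, `new_deaths`, `new_progressors`.
#' @export
#' @examples
#' mods <- base_survival_models()
#' tr <- psm_trace(mods$ven$pfs, mods$ven$os)
#' tail(tr$occ_dead, 1)  # fraction dead at 35 years
psm_trace <- function(s_pfs, s_os, horizon_years = 35, cycle_months = 1) {
  stopifnot(horizon_years > 0, cycle_months > 0)
  n_cycles <- round(horizon_years * 12 / cycle_months)
  t <- (0:n_cycles) * cycle_months
  S_pfs <- surv_prob(s_pfs, t)
  S_os <- surv_prob(s_os, t)
  occ_pfs <- pmin(S_pfs, S_os)
  occ_dead <- 1 - S_os
  occ_pd <- pmax(0, S_os - occ_pfs)
  out <- data.frame(
    cycle = 0:n_cycles, time = t,
    occ_pfs = occ_pfs, occ_pd = occ_pd, occ_dead = occ_dead,
    new_deaths = c(0, pmax(0, diff(occ_dead))),
    new_progressors = c(0, pmax(0, -diff(occ_pfs))))
  attr(out, "cycle_months") <- cycle_months
  class(out) <- c("psm_trace", "data.frame")
  out
}

#' Per-cycle state occupancy used for accrual
#'
#' With half-cycle correction the occupancy attributed to cycle `k` is the
#' trapezoid average of the boundary values at `k - 1` and `k`; without it,
#' the end-of-cycle value is used.
#'
#' @param trace A [psm_trace()].
#' @param half_cycle Logical; apply the trapezoid (half-cycle) correction.
#' @return Data frame with one row per cycle (1 .. N): `time` (end of
#'   cycle, months), `pfs`, `pd`, `alive`.
#' @export
cycle_occupancy <- function(trace, half_cycle = TRUE) {
  n <- nrow(trace) - 1L
  at_end <- function(x) x[-1L]
  avg <- function(x) (x[-1L] + x[-(n + 1L)]) / 2
  f <- if (half_cycle) avg else at_end
  data.frame(time = trace$time[-1L],
             pfs = f(trace$occ_pfs), pd = f(trace$occ_pd),
             alive = f(trace$occ_pfs + trace$occ_pd))
}

#' Discounted accrual of costs, life-years and QALYs over a trace
#'
#' Sums per-cycle quantities with discount factor `(1 + r)^(-t/12)` anchored
#' at the end-of-cycle time `t` in months. Life-years and QALYs use the
#' cycle occupancies of [cycle_occupancy()]; one month counts exactly 1/12
#' year. The first-cycle QALY lump (adverse-event disutility) is subtracted
#' at the first cycle's discount factor.
#'
#' @param trace A [psm_trace()].
#' @param cost Per-cycle undiscounted total cost vector (length = number of
#'   cycles), already occupancy-weighted (see [build_schedules()]).
#' @param u_pfs,u_pd State utilities in `[0, 1]`.
#' @param qaly_loss_cycle1 QALY decrement (years) charged in the first cycle.
#' @param annual_discount Annual discount rate (e.g. 0.05).
#' @param half_cycle Logical; trapezoid occupancy correction.
#' @return List with `cost`, `ly`, `qaly` (discounted), plus undiscounted
#'   `ly_undisc` and `qaly_undisc`.
#' @export
accrue <- function(trace, cost, u_pfs, u_pd, qaly_loss_cycle1 = 0,
                   annual_discount = 0, half_cycle = TRUE) {
  stopifnot(inherits(trace, "psm_trace"))
  n <- nrow(trace) - 1L
  if (length(cost) != n)
    stop("cost schedule length ", length(cost), " != number of cycles ", n)
  if (any(cost < -1e-9)) stop("negative entries in the cost schedule")
  if (u_pfs < 0 || u_pd < 0 || u_pfs > 1 || u_pd > 1)
    stop("utilities must lie in [0, 1]")
  if (annual_discount < 0) stop("discount rate must be non-negative")
  occ <- cycle_occupancy(trace, half_cycle)
  cm <- attr(trace, "cycle_months")
  disc <- (1 + annual_discount)^(-occ$time / 12)
  yrs <- cm / 12
  ly_cycle <- occ$alive * yrs
  q_cycle <- (occ$pfs * u_pfs + occ$pd * u_pd) * yrs
  list(cost = sum(cost * disc),
       ly = sum(ly_cycle * disc),
       qaly = sum(q_cycle * disc) - qaly_loss_cycle1 * disc[1],
       ly_undisc = sum(ly_cycle),
       qaly_undisc = sum(q_cycle) - qaly_loss_cycle1)
}

#' Incremental cost-effectiveness ratio
#'
#' `icer(a, b)` compares strategy `a` against comparator `b` on unrounded
#' accumulators. Returns the ratio `(cost_a - cost_b) / (qaly_a - qaly_b)`,
#' the sentinel string `"dominant"` when `a` is cheaper and more effective,
#' `"dominated"` when costlier and less effective, or a signed infinity when
#' the QALY difference is exactly zero.
#'
#' @param a,b Lists with `cost` and `qaly` elements (as from [accrue()]).
#' @return Numeric ICER (USD/QALY) or a sentinel.
#' @export
#' @examples
#' icer(list(cost = 200, qaly = 2), list(cost = 100, qaly = 1))  # 100
icer <- function(a, b) {
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  if (dc < 0 && dq > 0) return("dominant")
  if (dc > 0 && dq < 0) return("dominated")
  if (dq == 0) return(sign(dc) * Inf)
  dc / dq
}
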