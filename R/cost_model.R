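#' Country setting
#'
#' Bundles a country's discount rate, willingness-to-pay threshold, body
#' surface area, price list, disease-management schedule and vial/tablet
#' strengths from a parameter table.
#'
#' @param country `"china"` or `"us"`.
#' @param params A `ce_params` table for that country (see
#'   [default_parameters()]).
#' @return A list of class `country_setting`.
#' @details Pricing conventions follow the published price list: ibrutinib
#'   is priced per day on the 560 mg daily dose in both countries;
#'   venetoclax per tablet (100 mg in China, 20 mg in the US) with whole
#'   tablets billed per day; bendamustine and rituximab per vial (25/70 mg
#'   and 100 mg) with vials rounded up per administration day.
#' @export
country_setting <- function(country = c("china", "us"),
                            params = default_parameters(country)) {
  country <- match.arg(country)
  g <- function(nm) param_value(params, nm)
  ae <- AE_NAMES
  out <- list(
    name = country,
    annual_discount = g("discount"),
    wtp = g("wtp"),
    bsa = g("bsa"),
    ibrutinib_daily = g("cost_ibrutinib"),
    venetoclax_tab = g("cost_venetoclax"),
    venetoclax_tab_mg = if (country == "china") 100 else 20,
    rituximab_vial = g("cost_rituximab"),
    rituximab_vial_mg = 100,
    bendamustine_vial = g("cost_bendamustine"),
    bendamustine_vial_mg = if (country == "china") 25 else 70,
    pet_ct = g("cost_pet_ct"),
    end_of_life = g("cost_end_of_life"),
    ae_costs = vapply(paste0("cost_ae_", ae), g, numeric(1)))
  names(out$ae_costs) <- ae
  if (country == "china") {
    out$mgmt_tiers <- c(y0_2 = g("mgmt_y0_2"), y3_5 = g("mgmt_y3_5"),
                        y6_plus = g("mgmt_y6_plus"))
  } else {
    out$mgmt_state <- c(pfs = g("mgmt_pfs"), pd = g("mgmt_pd"))
  }
  class(out) <- "country_setting"
  out
}

AE_NAMES <- c("anemia", "neutropenia", "pneumonia", "thrombocytopenia",
              "leukopenia", "atrial_fibrillation")

#' Treatment-arm specification
#'
#' One strategy's survival models, regimen, adverse-event profile,
#' utilities and subsequent-therapy uptake. `"ven"` is ibrutinib plus
#' venetoclax (5-week ramp to 400 mg daily, capped at 24 months), `"pbo"`
#' ibrutinib plus placebo (no acquisition cost for the placebo).
#'
#' @param arm `"ven"` or `"pbo"`.
#' @param params A `ce_params` table.
#' @param survival Optional list with `pfs` and `os` [surv_model()] objects
#'   overriding the fitted base-case models (used by the flexible-model
#'   scenario).
#' @return A list of class `arm_spec`.
#' @export
arm_spec <- function(arm = c("ven", "pbo"), params = default_parameters("china"),
                     survival = NULL) {
  arm <- match.arg(arm)
  g <- function(nm) param_value(params, nm)
  if (is.null(survival)) survival <- base_survival_models(params)[[arm]]
  risks <- vapply(paste0("risk_", AE_NAMES, "_", arm), g, numeric(1))
  dus <- vapply(paste0("du_", AE_NAMES), g, numeric(1))
  names(risks) <- names(dus) <- AE_NAMES
  structure(list(
    label = if (arm == "ven") "ibrutinib + venetoclax" else "ibrutinib + placebo",
    arm = arm,
    s_pfs = survival$pfs, s_os = survival$os,
    has_venetoclax = arm == "ven",
    u_pfs = g(paste0("u_pfs_", arm)), u_pd = g("u_pd"),
    ae_risks = risks, ae_disutilities = dus,
    subsequent_proportion = g(paste0("subsequent_", arm))),
    class = "arm_spec")
}

DAYS_PER_CYCLE_MONTH <- 365.25 / 12  # days per one-month cycle
VEN_RAMP_MG <- c(20, 50, 100, 200, 400)  # weekly ramp doses, mg/day
VEN_STOP_DAY <- 24 * 365.25 / 12         # 2-year cap on venetoclax

# cumulative venetoclax tablets from day 0 to `day` (whole tablets per day,
# ramp weeks 1-5 then 400 mg/day until the 24-month cap)
ven_cum_tablets <- function(day, tab_mg) {
  tabs_per_day <- ceiling(VEN_RAMP_MG / tab_mg)
  breaks <- c(0, 7, 14, 21, 28, VEN_STOP_DAY)
  rates <- c(tabs_per_day, 0)  # rate beyond the cap is zero
  cum_at_break <- cumsum(c(0, rates[1:5] * diff(breaks)))
  idx <- findInterval(day, breaks, rightmost.closed = FALSE)
  idx <- pmin(idx, 6)
  cum_at_break[idx] + rates[pmin(idx, 6)] * (pmin(day, VEN_STOP_DAY) - breaks[idx]) *
    (day > 0)
}

#' Drug acquisition cost per cycle while progression-free
#'
#' Per person remaining in the PFS state: daily ibrutinib cost times days in
#' the cycle, plus the venetoclax component for cycles starting before the
#' 24-month cap, with the 5-week ramp (20/50/100/200/400 mg daily) billed as
#' whole tablets per day.
#'
#' @param arm An [arm_spec()].
#' @param country A [country_setting()].
#' @param cycle_index Cycle number(s), 1-based.
#' @param cycle_months Cycle length in months.
#' @return USD per person-in-PFS for each requested cycle.
#' @export
drug_cost_per_cycle <- function(arm, country, cycle_index, cycle_months = 1) {
  stopifnot(all(cycle_index >= 1))
  days <- cycle_months * DAYS_PER_CYCLE_MONTH
  ibr <- country$ibrutinib_daily * days
  if (!arm$has_venetoclax) return(rep(ibr, length(cycle_index)))
  d0 <- (cycle_index - 1) * days
  d1 <- cycle_index * days
  tabs <- ven_cum_tablets(d1, country$venetoclax_tab_mg) -
    ven_cum_tablets(d0, country$venetoclax_tab_mg)
  ibr + tabs * country$venetoclax_tab
}

#' Cost of one bendamustine-rituximab cycle
#'
#' Bendamustine 90 mg/m2 on each of two days and rituximab 375 mg/m2 on one
#' day per 4-week cycle, with vials rounded up per administration day.
#'
#' @param country A [country_setting()].
#' @return USD per treated 4-week cycle.
#' @export
#' @examples
#' br_cycle_cost(country_setting("china"))  # 2089.43 at BSA 1.72
br_cycle_cost <- function(country) {
  stopifnot(country$bsa > 0)
  bend_vials <- ceiling(90 * country$bsa / country$bendamustine_vial_mg)
  rit_vials <- ceiling(375 * country$bsa / country$rituximab_vial_mg)
  bend_vials * 2 * country$bendamustine_vial + rit_vials * country$rituximab_vial
}

#' Expected subsequent-therapy cost per incident progressor
#'
#' The subsequent-therapy uptake fraction times six cycles of
#' bendamustine-rituximab, charged as a lump to each cycle's new
#' progressors (the engine discounts it at the event time).
#'
#' @inheritParams br_cycle_cost
#' @param arm An [arm_spec()].
#' @return USD per incident progressor.
#' @export
subsequent_therapy_lump <- function(arm, country) {
  arm$subsequent_proportion * 6 * br_cycle_cost(country)
}

#' First-cycle adverse-event burden
#'
#' Expected cost and QALY loss from grade >= 3 adverse events with incidence
#' above 5% in either arm: sum over events of risk times cost, and risk
#' times disutility for one month's duration. Both are charged once, in the
#' first cycle.
#'
#' @inheritParams subsequent_therapy_lump
#' @return List with `cost` (USD) and `qaly_loss` (years).
#' @export
ae_lump <- function(arm, country) {
  list(cost = sum(arm$ae_risks * country$ae_costs),
       qaly_loss = sum(arm$ae_risks * arm$ae_disutilities) / 12)
}

#' Assemble the engine's per-cycle cost schedule for one arm
#'
#' Combines drug acquisition (weighted by PFS occupancy), disease
#' management (China: calendar-time tiers applied to all alive states; US:
#' state-specific), PET-CT scans (one at model entry and one per incident
#' progressor), end-of-life cost per incident death, the subsequent-therapy
#' lump per incident progressor, and the first-cycle adverse-event lump.
#'
#' @param arm An [arm_spec()].
#' @param country A [country_setting()].
#' @param trace A [psm_trace()] for this arm's survival models.
#' @param half_cycle Logical; must match the engine's accrual setting so
#'   occupancy weighting is consistent.
#' @return List with `cost` (undiscounted per-cycle totals), `u_pfs`,
#'   `u_pd`, `qaly_loss_cycle1`.
#' @export
build_schedules <- function(arm, country, trace, half_cycle = TRUE) {
  stopifnot(inherits(trace, "psm_trace"))
  occ <- cycle_occupancy(trace, half_cycle)
  n <- nrow(occ)
  cm <- attr(trace, "cycle_months")
  drug <- drug_cost_per_cycle(arm, country, seq_len(n), cm) * occ$pfs
  if (country$name == "china") {
    yrs_since_entry <- (occ$time - cm) / 12  # years completed at cycle start
    tier <- ifelse(yrs_since_entry < 3, country$mgmt_tiers[["y0_2"]],
                   ifelse(yrs_since_entry < 6, country$mgmt_tiers[["y3_5"]],
                          country$mgmt_tiers[["y6_plus"]]))
    mgmt <- tier * occ$alive * (cm / 1)
  } else {
    mgmt <- (country$mgmt_state[["pfs"]] * occ$pfs +
               country$mgmt_state[["pd"]] * occ$pd) * (cm / 1)
  }
  new_dead <- trace$new_deaths[-1L]
  new_prog <- trace$new_progressors[-1L]
  pet <- country$pet_ct * new_prog
  pet[1] <- pet[1] + country$pet_ct  # baseline staging scan at entry
  eol <- country$end_of_life * new_dead
  subs <- subsequent_therapy_lump(arm, country) * new_prog
  ae <- ae_lump(arm, country)
  cost <- drug + mgmt + pet + eol + subs
  cost[1] <- cost[1] + ae$cost
  list(cost = cost, u_pfs = arm$u_pfs, u_pd = arm$u_pd,
       qaly_loss_cycle1 = ae$qaly_loss)
}
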