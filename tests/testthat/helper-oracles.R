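# Independent oracles used across the suite; deliberately naive
# implementations that share no code with the package internals.

# hand-rolled product-limit estimator
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = 0, surv = 1)
  for (t in ut) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# step-function lookup on a (time, surv) frame
oracle_surv_at <- function(km, t) {
  vapply(t, function(x) km$surv[max(which(km$time <= x))], numeric(1))
}

# discounted restricted life expectancy by adaptive quadrature
oracle_ly <- function(model, horizon_months, rate = 0) {
  stats::integrate(function(t) surv_prob(model, t) * (1 + rate)^(-t / 12),
                   0, horizon_months, rel.tol = 1e-9,
                   subdivisions = 500L)$value / 12
}

base_models_tbl <- function() {
  list(
    os_ven = surv_model("lognormal", meanlog = 3.827, sdlog = 1.727),
    pfs_ven = surv_model("lognormal", meanlog = 3.501, sdlog = 1.598),
    os_pbo = surv_model("loglogistic", shape = 1.012, scale = 38.350),
    pfs_pbo = surv_model("lognormal", meanlog = 2.960, sdlog = 1.512))
}

# minimal valid one-row parameter table for loader edge cases
param_row <- function(name = "x", country = "china", category = "drug_cost",
                      base = 1, low = NA, high = NA, dist = "fixed",
                      units = "USD", source = "test") {
  data.frame(name = name, country = country, category = category,
             base = base, low = low, high = high, dist = dist,
             units = units, source = source)
}
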