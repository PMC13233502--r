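#' Parameter tables
#'
#' The model is driven by a flat parameter table with one row per input:
#' unit drug prices, disease-management costs, adverse-event costs and risks,
#' utilities and disutilities, body surface area, discount rate,
#' willingness-to-pay threshold and the fitted survival-model parameters.
#' Each row carries its base-case value, the low/high range used by the
#' one-way sensitivity analysis, and the distribution family (`gamma`,
#' `beta` or `fixed`) used by the probabilistic sensitivity analysis.
#'
#' @section Schema:
#' `name` (identifier, unique within a country), `country`
#' (`"china"`, `"us"` or `"both"`), `category` (one of `drug_cost`,
#' `management_cost`, `ae_cost`, `ae_risk`, `utility`, `disutility`,
#' `one_off_cost`, `bsa`, `discount`, `proportion`, `survival`, `threshold`),
#' `base`, `low`, `high` (numeric; `NA` range means the row is never varied),
#' `dist`, `units`, `source`.
#'
#' @name parameters
NULL

PARAM_COLUMNS <- c("name", "country", "category", "base", "low", "high",
                   "dist", "units", "source")

PROB_CATEGORIES <- c("ae_risk", "utility", "disutility", "proportion")
COST_CATEGORIES <- c("drug_cost", "management_cost", "ae_cost", "one_off_cost")

#' Read a parameter table from CSV
#'
#' Reads and validates a parameter table in the documented schema. Rows are
#' checked for duplicate `(name, country)` pairs, `low <= base <= high` where
#' a range is present, probabilities/utilities in `[0, 1]` and non-negative
#' costs. Violations are rejected with the offending row named.
#'
#' @param source Path to a CSV file (UTF-8, dot decimal) or a connection.
#' @return A `data.frame` of class `ce_params`.
#' @seealso [default_parameters()] for the bundled tables.
#' @export
#' @examples
#' p <- default_parameters("china")
#' p[p$name == "cost_venetoclax", "base"]
load_parameter_table <- function(source) {
  tbl <- utils::read.csv(source, stringsAsFactors = FALSE)
  if (nrow(tbl) == 0L) {
    warning("parameter table is empty: ", paste(source, collapse = ""))
    tbl <- tbl[, intersect(PARAM_COLUMNS, names(tbl)), drop = FALSE]
    class(tbl) <- c("ce_params", "data.frame")
    return(tbl)
  }
  missing_cols <- setdiff(PARAM_COLUMNS, names(tbl))
  if (length(missing_cols))
    stop("parameter table lacks columns: ", paste(missing_cols, collapse = ", "))
  tbl <- tbl[, PARAM_COLUMNS]
  validate_parameters(tbl)
}

validate_parameters <- function(tbl) {
  key <- paste(tbl$name, tbl$country)
  if (anyDuplicated(key))
    stop("duplicate parameter rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  for (col in c("base", "low", "high"))
    tbl[[col]] <- as.numeric(tbl[[col]])
  if (anyNA(tbl$base))
    stop("missing base value for: ",
         paste(tbl$name[is.na(tbl$base)], collapse = ", "))
  has_range <- !is.na(tbl$low) & !is.na(tbl$high)
  bad <- has_range & !(tbl$low <= tbl$base & tbl$base <= tbl$high)
  if (any(bad))
    stop("range does not bracket base for: ", paste(tbl$name[bad], collapse = ", "))
  pr <- tbl$category %in% PROB_CATEGORIES
  bad <- pr & (tbl$base < 0 | tbl$base > 1 |
                 (has_range & (tbl$low < 0 | tbl$high > 1)))
  if (any(bad))
    stop("probability/utility outside [0, 1] for: ",
         paste(tbl$name[bad], collapse = ", "))
  co <- tbl$category %in% COST_CATEGORIES
  if (any(co & tbl$base < 0))
    stop("negative cost for: ", paste(tbl$name[co & tbl$base < 0], collapse = ", "))
  class(tbl) <- c("ce_params", "data.frame")
  tbl
}

#' Bundled base-case parameter tables
#'
#' Returns the full published parameter set for one country: the rows common
#' to both settings (survival-model parameters, adverse-event risks,
#' utilities, disutilities, subsequent-therapy proportions) bound to the
#' country-specific price list, management schedule, body surface area,
#' discount rate and willingness-to-pay threshold.
#'
#' @param country `"china"` or `"us"`.
#' @return A `ce_params` data frame.
#' @export
default_parameters <- function(country = c("china", "us")) {
  country <- match.arg(country)
  common <- load_parameter_table(
    system.file("extdata", "params_common.csv", package = "psmcea"))
  local <- load_parameter_table(
    system.file("extdata", paste0("params_", country, ".csv"), package = "psmcea"))
  validate_parameters(rbind(as.data.frame(common), as.data.frame(local)))
}

#' Look up or modify a parameter value
#'
#' @param params A `ce_params` table.
#' @param name Parameter name.
#' @return `param_value()` returns the base value; `set_param()` and
#'   `scale_param()` return the modified table.
#' @export
param_value <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  params$base[i]
}

#' @rdname param_value
#' @param value Replacement base value.
#' @export
set_param <- function(params, name, value) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  params$base[i] <- value
  params
}

#' @rdname param_value
#' @param mult Non-negative multiplier applied to `base`, `low` and `high`,
#'   so that downstream sensitivity analyses see the rescaled price.
#' @export
scale_param <- function(params, name, mult) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  if (mult < 0) stop("price multiplier must be non-negative")
  params[i, c("base", "low", "high")] <- params[i, c("base", "low", "high")] * mult
  params
}

#' Standard deviation implied by a sensitivity range
#'
#' Ranges in the parameter table are either 95% confidence intervals, for
#' which `sd = (high - low) / 3.92`, or plus/minus 20% of the base value, for
#' which `sd = 0.10 * base`. A range whose endpoints sit at 80% and 120% of
#' the base (to 0.5% relative precision) is treated as the latter.
#'
#' @param base Base-case value.
#' @param low,high Range endpoints. Both must be present.
#' @return The standard deviation used for moment matching.
#' @export
#' @examples
#' derive_sd(22.07, 17.66, 26.48)  # +-20% range -> 2.207
#' derive_sd(0.824, 0.767, 0.867)  # CI range -> (0.867 - 0.767)/3.92
derive_sd <- function(base, low = NA, high = NA) {
  if (is.na(base)) stop("cannot derive an SD: base value missing")
  if (is.na(low) || is.na(high))
    stop("cannot derive an SD: parameter has no low/high range")
  tol <- 5e-3
  pm20 <- base > 0 &&
    abs(low / base - 0.8) < tol && abs(high / base - 1.2) < tol
  if (pm20) 0.10 * base else (high - low) / 3.92
}

#' Moment matching for PSA distributions
#'
#' `gamma_from_moments()` solves shape `= mean^2 / sd^2` and rate
#' `= mean / sd^2`; `beta_from_moments()` solves
#' `alpha = mean * (mean (1 - mean) / sd^2 - 1)` and
#' `beta = (1 - mean) * (mean (1 - mean) / sd^2 - 1)`. Both return a
#' distribution whose first two moments equal the inputs.
#'
#' @param mean,sd Target mean and standard deviation (`sd > 0`; for the beta
#'   case `0 < mean < 1` and `sd^2 < mean (1 - mean)`).
#' @return Named numeric vector: `c(shape, rate)` or `c(shape1, shape2)`.
#' @export
#' @examples
#' gamma_from_moments(22.07, 2.207)  # shape 100
#' beta_from_moments(0.5, 0.1)       # alpha = beta = 12
gamma_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("gamma moment matching needs mean > 0")
  if (!is.finite(sd) || sd <= 0) stop("gamma moment matching needs sd > 0")
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' @rdname gamma_from_moments
#' @export
beta_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta moment matching needs 0 < mean < 1")
  if (!is.finite(sd) || sd <= 0) stop("beta moment matching needs sd > 0")
  if (sd^2 >= mean * (1 - mean))
    stop("beta moment matching infeasible: sd^2 >= mean*(1-mean)")
  nu <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# Rows eligible for probabilistic sampling: a gamma/beta distribution label,
# a usable range, and a non-degenerate base (a zero-risk beta is degenerate
# and stays fixed, as do the survival parameters and the discount rate).
sampled_rows <- function(params) {
  which(params$dist %in% c("gamma", "beta") &
          !is.na(params$low) & !is.na(params$high) &
          params$high > params$low &
          params$base > 0)
}

# Rows eligible for one-way variation: any finite non-degenerate range.
owsa_rows <- function(params) {
  which(!is.na(params$low) & !is.na(params$high) & params$high > params$low)
}
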