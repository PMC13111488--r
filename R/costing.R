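#' Discounting and timing specification
#'
#' Global time parameters of the model: the annual discount rate, the model
#' horizon, and the year at which rescue fixed-appliance therapy is booked.
#' Interceptive treatment starts at model year 0 (around ages 8-10);
#' comprehensive fixed-appliance therapy for initial failures and for
#' relapses starts around ages 14-16, i.e. about 5 years later, within an
#' 8-year horizon.
#'
#' @param annual_rate Annual discount rate, `0 <= rate < 1` (default 0.03).
#' @param horizon_years Model horizon in years (default 8).
#' @param follow_up_start_year Year at which rescue fixed-appliance treatment
#'   starts for initial failures and failed partial successes (default 5).
#' @param relapse_start_year Year at which rescue treatment starts after a
#'   relapse of an initially successful treatment (default
#'   `follow_up_start_year`).
#' @return A list of class `"discount_spec"`.
#' @export
discount_spec <- function(annual_rate = 0.03, horizon_years = 8,
                          follow_up_start_year = 5,
                          relapse_start_year = follow_up_start_year) {
  if (!is_number(annual_rate) || annual_rate < 0 || annual_rate >= 1) {
    validation_error("annual_rate", "must satisfy 0 <= rate < 1")
  }
  if (!is_number(horizon_years) || horizon_years < 0) {
    validation_error("horizon_years", "must be >= 0")
  }
  for (nm in c("follow_up_start_year", "relapse_start_year")) {
    val <- get(nm)
    if (!is_number(val) || val < 0 || val > horizon_years) {
      validation_error(nm, sprintf("must lie in [0, horizon_years = %g]", horizon_years))
    }
  }
  structure(
    list(
      annual_rate = annual_rate,
      horizon_years = horizon_years,
      follow_up_start_year = follow_up_start_year,
      relapse_start_year = relapse_start_year
    ),
    class = "discount_spec"
  )
}

#' Discount factor for a future year
#'
#' `(1 + rate)^(-year)`: the present-value weight of a cost incurred `year`
#' years after model start.
#'
#' @param year Years after model start, `>= 0` (vectorised).
#' @param rate Annual discount rate, `0 <= rate < 1`.
#' @return Discount factor(s) in `(0, 1]`, strictly decreasing in `year`
#'   when `rate > 0`.
#' @examples
#' discount_factor(6, 0.03) # 1.03^-6
#' @export
discount_factor <- function(year, rate = 0.03) {
  if (any(!is.finite(year)) || any(year < 0)) validation_error("year", "must be >= 0")
  if (!is_number(rate) || rate < 0 || rate >= 1) validation_error("rate", "must satisfy 0 <= rate < 1")
  (1 + rate)^(-year)
}

#' Present value of a future amount
#'
#' @param amount Amount in EUR, `>= 0` (vectorised).
#' @param year Years after model start.
#' @param rate Annual discount rate.
#' @return `amount * discount_factor(year, rate)`.
#' @export
present_value <- function(amount, year, rate = 0.03) {
  if (any(!is.finite(amount)) || any(amount < 0)) validation_error("amount", "must be >= 0")
  amount * discount_factor(year, rate)
}

#' Assemble a treatment cost from resource-use components
#'
#' Total direct cost = materials + professional fees + overhead +
#' visits x chair-time per visit x personnel rate. This mirrors how
#' per-treatment totals are compiled from unit costs and observed resource
#' use (visit counts and durations) in an administrative costing exercise.
#'
#' @param materials,professional_fees,overhead Fixed cost components (EUR).
#' @param n_visits Number of visits.
#' @param chair_time_per_visit Chair time per visit, minutes.
#' @param personnel_rate Personnel cost per chair minute (EUR/min).
#' @return Total cost in EUR.
#' @examples
#' assemble_cost(100, 200, 50, n_visits = 10, chair_time_per_visit = 30, personnel_rate = 1)
#' @export
assemble_cost <- function(materials = 0, professional_fees = 0, overhead = 0,
                          n_visits = 0, chair_time_per_visit = 0,
                          personnel_rate = 0) {
  comp <- c(
    materials = materials, professional_fees = professional_fees,
    overhead = overhead, n_visits = n_visits,
    chair_time_per_visit = chair_time_per_visit, personnel_rate = personnel_rate
  )
  for (nm in names(comp)) {
    if (!is_number(comp[[nm]]) || comp[[nm]] < 0) {
      validation_error(nm, "cost components must be single non-negative numbers")
    }
  }
  materials + professional_fees + overhead +
    n_visits * chair_time_per_visit * personnel_rate
}

#' Convert Swedish krona to euro
#'
#' Applied at input time only; all model arithmetic is in EUR. The default
#' rate is the 2024 average exchange rate, 1 SEK = 0.0875 EUR.
#'
#' @param amount_sek Amount in SEK, `>= 0` (vectorised).
#' @param rate EUR per SEK (default 0.0875).
#' @return Amount in EUR.
#' @export
sek_to_eur <- function(amount_sek, rate = 0.0875) {
  if (any(!is.finite(amount_sek)) || any(amount_sek < 0)) {
    validation_error("amount_sek", "must be >= 0")
  }
  if (!is_number(rate) || rate <= 0) validation_error("rate", "must be > 0")
  amount_sek * rate
}
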