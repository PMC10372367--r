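#' Per-state annual utility and disability weights
#'
#' Utilities must be non-increasing in myopia severity and disability
#' weights non-decreasing; both lie in [0, 1]. QALYs accrue as occupancy x
#' utility per annual cycle; DALYs as occupancy x disability weight
#' (prevalence-based years-lived-with-disability accrual; the model has no
#' mortality, hence no years-of-life-lost term).
#'
#' @param utility Named or ordered numeric vector of length 4 (state order
#'   NON_MYOPIA, LOW, MODERATE, HIGH).
#' @param disability_weight Same shape as `utility`.
#' @return A `list` of class `mpc_payoffs`.
#' @export
payoff_schedule <- function(utility, disability_weight) {
  utility <- as.numeric(utility)
  disability_weight <- as.numeric(disability_weight)
  if (length(utility) != 4L || length(disability_weight) != 4L) {
    stop("utility and disability_weight must each have 4 entries",
         call. = FALSE)
  }
  if (any(utility < 0 | utility > 1) ||
      any(disability_weight < 0 | disability_weight > 1)) {
    stop("payoff weights must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(utility) > 1e-12)) {
    stop("utilities must be non-increasing with myopia severity",
         call. = FALSE)
  }
  if (any(diff(disability_weight) < -1e-12)) {
    stop("disability weights must be non-decreasing with myopia severity",
         call. = FALSE)
  }
  structure(list(utility = setNames(utility, myopia_states()),
                 disability_weight = setNames(disability_weight,
                                              myopia_states())),
            class = "mpc_payoffs")
}

#' Unit costs of one setting (2021 USD, societal perspective)
#'
#' Direct costs arise inside the hospital (examination, correction and
#' follow-up) and outside it (transport, food, accommodation); indirect
#' costs are family working-time loss accompanying visits. Health education
#' and school screening are program costs per student(-test) per year.
#'
#' @param health_education List with `traditional` and `digital` per-student
#'   annual program costs.
#' @param school_screening Cost per administered school vision test.
#' @param hospital_examination List with `direct_hospital`, `direct_outside`,
#'   `indirect` cost per confirmatory visit.
#' @param treatment List with the same three components per treated
#'   child-year (spectacles, follow-up).
#' @param classification Optional named list flagging each line `"capital"`
#'   or `"recurrent"` (both are aggregated identically).
#' @return A `list` of class `mpc_costs` with pre-summed `examination_total`
#'   and `treatment_total` bundles.
#' @export
cost_schedule <- function(health_education, school_screening,
                          hospital_examination, treatment,
                          classification = NULL) {
  vals <- c(unlist(health_education), school_screening,
            unlist(hospital_examination), unlist(treatment))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all costs must be finite and non-negative", call. = FALSE)
  }
  structure(list(health_education = health_education,
                 school_screening = school_screening,
                 hospital_examination = hospital_examination,
                 treatment = treatment,
                 examination_total = sum(unlist(hospital_examination)),
                 treatment_total = sum(unlist(treatment)),
                 classification = classification),
            class = "mpc_costs")
}

#' Macro-economic context
#'
#' @param exchange_rate_cny_per_usd 2021 average exchange rate (6.45 CNY per
#'   USD).
#' @param cost_adjustment_rate Annual rate used to bring older cost data to
#'   2021 (0.05).
#' @param discount_rate Annual discount rate applied to costs, QALYs and
#'   DALYs (default 0.05; 0 disables discounting).
#' @param national_gdp_per_capita,urbanization_rate,urban_rural_income_ratio
#'   National 2021 context ($12,551, 0.65, 2.5). The setting-level GDPs are
#'   direct inputs of [setting_context()]; these three are carried for
#'   reporting.
#' @param half_cycle_correction Logical; apply a half weight to the first
#'   and last age points (default `FALSE`).
#' @return A `list` of class `mpc_economy`.
#' @export
economy_context <- function(exchange_rate_cny_per_usd = 6.45,
                            cost_adjustment_rate = 0.05,
                            discount_rate = 0.05,
                            national_gdp_per_capita = 12551,
                            urbanization_rate = 0.65,
                            urban_rural_income_ratio = 2.5,
                            half_cycle_correction = FALSE) {
  if (exchange_rate_cny_per_usd <= 0) {
    stop("exchange rate must be positive", call. = FALSE)
  }
  for (r in c(cost_adjustment_rate, discount_rate)) {
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)", call. = FALSE)
  }
  structure(list(exchange_rate_cny_per_usd = exchange_rate_cny_per_usd,
                 cost_adjustment_rate = cost_adjustment_rate,
                 discount_rate = discount_rate,
                 national_gdp_per_capita = national_gdp_per_capita,
                 urbanization_rate = urbanization_rate,
                 urban_rural_income_ratio = urban_rural_income_ratio,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "mpc_economy")
}

#' Convert Chinese yuan to US dollars
#'
#' @param amount_cny Non-negative amount in CNY.
#' @param rate CNY per USD (default the 2021 average, 6.45).
#' @return Amount in USD.
#' @examples
#' convert_currency(6.45)   # 1
#' @export
convert_currency <- function(amount_cny, rate = 6.45) {
  if (any(amount_cny < 0)) stop("amount must be non-negative", call. = FALSE)
  if (rate <= 0) stop("exchange rate must be positive", call. = FALSE)
  amount_cny / rate
}

#' Bring a cost forward to a later price year
#'
#' @param cost Cost in USD at `from_year` prices.
#' @param from_year,to_year Integer years, `to_year >= from_year`.
#' @param rate Annual adjustment rate (default 0.05).
#' @return `cost * (1 + rate)^(to_year - from_year)`.
#' @examples
#' inflate_cost(100, 2019, 2021)   # 110.25
#' @export
inflate_cost <- function(cost, from_year, to_year, rate = 0.05) {
  if (to_year < from_year) {
    stop("to_year must not precede from_year (no deflation)", call. = FALSE)
  }
  cost * (1 + rate)^(to_year - from_year)
}

#' WHO cost-effectiveness thresholds from per-capita GDP
#'
#' Interventions costing less than 1x per-capita GDP per QALY gained or DALY
#' averted are highly cost-effective; between 1x and 3x, cost-effective;
#' above 3x, not cost-effective.
#'
#' @param gdp_per_capita Per-capita GDP in USD (positive).
#' @return Named numeric vector `c(highly_cost_effective = gdp,
#'   cost_effective = 3 * gdp)`.
#' @examples
#' compute_thresholds(10167)   # 10167, 30501
#' @export
compute_thresholds <- function(gdp_per_capita) {
  if (!is.numeric(gdp_per_capita) || gdp_per_capita <= 0) {
    stop("gdp_per_capita must be positive", call. = FALSE)
  }
  c(highly_cost_effective = gdp_per_capita,
    cost_effective = 3 * gdp_per_capita)
}

# Discount weights over the 13 age points (age 6 undiscounted).
discount_weights <- function(discount_rate, half_cycle = FALSE) {
  w <- (1 + discount_rate)^(-(MODEL_AGES - 6L))
  if (half_cycle) {
    w[1L] <- w[1L] / 2
    w[length(w)] <- w[length(w)] / 2
  }
  w
}

# Expected per-person event flows in one cycle, given state occupancy.
# Returns fractions of the cohort screened / examined / treated and the
# per-person cycle cost.
cycle_flows <- function(occ, strategy, costs) {
  cas <- strategy$cascade
  myo <- sum(occ[2:4])
  non <- occ[[1L]]
  screened <- cas$coverage
  true_pos <- myo * cas$sensitivity * cas$coverage
  false_pos <- non * (1 - cas$specificity) * cas$coverage
  examined <- (true_pos + false_pos) * cas$referral_compliance
  treated <- true_pos * cas$referral_compliance * cas$spectacle_compliance
  edu_cost <- switch(strategy$education_channel,
                     none = 0,
                     traditional = costs$health_education$traditional,
                     digital = costs$health_education$digital)
  cost <- edu_cost +
    screened * costs$school_screening +
    examined * costs$examination_total +
    treated * costs$treatment_total
  list(screened = screened, examined = examined, treated = treated,
       cost = cost)
}

#' Accrue discounted cost, QALY and DALY totals over a cohort trace
#'
#' QALY(total) = sum over ages of discount(age) x sum over states of
#' occupancy x utility; DALYs likewise with disability weights; costs sum
#' the discounted expected event costs of the screening/referral/treatment
#' cascade plus health-education program costs. `discount(age) =
#' (1 + discount_rate)^-(age - 6)`.
#'
#' @param trace An `mpc_trace` from [run_cohort()], or any data frame with
#'   columns `age, p_non, p_low, p_mod, p_high`.
#' @param payoffs An [payoff_schedule()].
#' @param costs A [cost_schedule()].
#' @param economy An [economy_context()].
#' @param strategy The `mpc_strategy` whose cascade generated the trace
#'   (needed to price screening/examination/treatment events).
#' @return Named list with per-person `cost`, `qaly`, `daly` and the
#'   per-cycle breakdown data frame.
#' @export
accrue_outcomes <- function(trace, payoffs, costs, economy, strategy) {
  stopifnot(inherits(payoffs, "mpc_payoffs"), inherits(costs, "mpc_costs"),
            inherits(economy, "mpc_economy"),
            inherits(strategy, "mpc_strategy"))
  occ <- as.matrix(trace[, c("p_non", "p_low", "p_mod", "p_high")])
  if (nrow(occ) != length(MODEL_AGES)) {
    stop("trace must contain all ", length(MODEL_AGES), " age points",
         call. = FALSE)
  }
  w <- discount_weights(economy$discount_rate, economy$half_cycle_correction)
  qaly_c <- as.numeric(occ %*% payoffs$utility) * w
  daly_c <- as.numeric(occ %*% payoffs$disability_weight) * w
  cost_c <- vapply(seq_len(nrow(occ)), function(i) {
    cycle_flows(occ[i, ], strategy, costs)$cost
  }, numeric(1)) * w
  breakdown <- data.frame(age = trace$age, cost = cost_c, qaly = qaly_c,
                          daly = daly_c)
  list(cost = sum(cost_c), qaly = sum(qaly_c), daly = sum(daly_c),
       cycles = breakdown)
}
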