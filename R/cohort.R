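#' Advance a cohort distribution by one annual cycle
#'
#' Left-multiplies the occupancy row vector by the (row-stochastic, age
#' matched) transition matrix and increments the age.
#'
#' @param dist An `mpc_dist` at some age in 6..17.
#' @param matrix An `mpc_tmat` whose `age` equals the distribution's age.
#' @return The `mpc_dist` one year later.
#' @examples
#' d6 <- baseline_distribution("rural")
#' m6 <- transition_matrix(progression_matrix(0.10, 0.05, 0.02), age = 6)
#' advance_cohort(d6, m6)
#' @export
advance_cohort <- function(dist, matrix) {
  stopifnot(inherits(dist, "mpc_dist"), inherits(matrix, "mpc_tmat"))
  age <- attr(dist, "age")
  if (age >= 18L) {
    stop("cohort is at the terminal age (18); no further cycles",
         call. = FALSE)
  }
  if (attr(matrix, "age") != age) {
    stop("matrix age (", attr(matrix, "age"), ") does not match ",
         "distribution age (", age, ")", call. = FALSE)
  }
  occ <- as.numeric(unclass(dist) %*% unclass(matrix))
  health_state_distribution(occ, age + 1L)
}

#' Run the 13-point Markov cohort simulation for one setting and strategy
#'
#' Simulates the closed cohort from age 6 to age 18 (13 age points, 12
#' annual transitions). At each age the natural-history matrix is modified
#' by the strategy's interventions ([apply_strategy()]), the cohort is
#' advanced, and discounted per-person cost, QALY and DALY payoffs accrue at
#' every age point. The run is fully deterministic given the parameter set.
#'
#' @param setting Setting name (`"rural"`/`"urban"`) or an `mpc_setting`.
#' @param strategy Strategy name (e.g. `"DIGITAL"`) or an `mpc_strategy`.
#' @param params Full parameter set (see [read_params()],
#'   [mpc_reference_params()]).
#' @return A data frame of class `mpc_trace` with one row per age and
#'   columns `age, p_non, p_low, p_mod, p_high, cost, qaly, daly, cum_cost,
#'   cum_qaly, cum_daly` (per person, discounted), plus attributes
#'   `setting`, `strategy`, `discount_rate`, `cohort_size`, `provenance`.
#' @examples
#' \donttest{
#' params <- mpc_reference_params()
#' tr <- run_cohort("rural", "SCHOOL_SCREENING", params)
#' tail(tr, 1)
#' }
#' @export
run_cohort <- function(setting, strategy, params) {
  setting <- resolve_setting(params, setting)
  strategy <- resolve_strategy(params, setting, strategy)
  mats <- natural_matrices(params, setting$name)
  payoffs <- resolve_payoffs(params, setting$name)
  costs <- resolve_costs(params, setting$name)
  economy <- resolve_economy(params)

  dist <- setting$baseline_distribution
  occ <- matrix(NA_real_, nrow = length(MODEL_AGES), ncol = N_STATES,
                dimnames = list(NULL, c("p_non", "p_low", "p_mod", "p_high")))
  occ[1L, ] <- unclass(dist)
  for (i in seq_along(6:17)) {
    eff <- apply_strategy(mats[[as.character(5L + i)]], strategy, setting)
    dist <- advance_cohort(dist, eff)
    occ[i + 1L, ] <- unclass(dist)
  }

  trace <- data.frame(age = MODEL_AGES, occ)
  acc <- accrue_outcomes(trace, payoffs, costs, economy, strategy)
  trace$cost <- acc$cycles$cost
  trace$qaly <- acc$cycles$qaly
  trace$daly <- acc$cycles$daly
  trace$cum_cost <- cumsum(trace$cost)
  trace$cum_qaly <- cumsum(trace$qaly)
  trace$cum_daly <- cumsum(trace$daly)
  structure(trace,
            setting = setting$name, strategy = strategy$name,
            discount_rate = economy$discount_rate,
            cohort_size = setting$cohort_size,
            provenance = params$meta$provenance,
            class = c("mpc_trace", "data.frame"))
}

#' Myopia prevalence trajectory of a cohort trace
#'
#' @param trace An `mpc_trace` from [run_cohort()].
#' @return Data frame with `age`, `total_myopia` (1 - non-myopia occupancy)
#'   and the per-state prevalences, all as fractions. Under the
#'   irreversibility convention total and high-myopia prevalence are
#'   non-decreasing in age.
#' @export
prevalence_trajectory <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("age", "p_non", "p_low", "p_mod", "p_high") %in%
                  names(trace)))
  data.frame(age = trace$age,
             total_myopia = 1 - trace$p_non,
             low = trace$p_low, moderate = trace$p_mod, high = trace$p_high)
}

#' Per-person totals of a cohort trace
#'
#' @param trace An `mpc_trace`.
#' @return Named list `cost`, `qaly`, `daly` (per person, discounted) plus
#'   `age18_total_myopia` and `age18_high_myopia` prevalences (fractions).
#' @export
trace_totals <- function(trace) {
  n <- nrow(trace)
  list(cost = trace$cum_cost[n], qaly = trace$cum_qaly[n],
       daly = trace$cum_daly[n],
       age18_total_myopia = 1 - trace$p_non[n],
       age18_high_myopia = trace$p_high[n])
}

#' Export a cohort trace as CSV
#'
#' Writes the standard trace columns (comma-separated, `.` decimal, header
#' row) preceded by `#`-prefixed metadata lines recording setting, strategy,
#' discount rate and parameter provenance.
#'
#' @param trace An `mpc_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "mpc_trace"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "# myopiaCEA trace | setting=%s | strategy=%s | discount_rate=%s | params=%s",
    attr(trace, "setting"), attr(trace, "strategy"),
    format(attr(trace, "discount_rate")),
    attr(trace, "provenance") %||% "unlabelled"), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @export
print.mpc_trace <- function(x, ...) {
  cat("<cohort trace: ", attr(x, "setting"), " / ", attr(x, "strategy"),
      ", discount ", attr(x, "discount_rate"), ">\n", sep = "")
  if (!is.null(attr(x, "provenance"))) {
    cat("  parameters: ", attr(x, "provenance"), "\n", sep = "")
  }
  print(as.data.frame(lapply(as.data.frame(x), round, 5)))
  invisible(x)
}
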