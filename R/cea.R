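#' Per-strategy outcome summary
#'
#' @param strategy Strategy name.
#' @param cost,qaly,daly Per-person discounted totals.
#' @param cohort_size Scaling population (default 100,000); per-cohort
#'   values are per-person values times `cohort_size` exactly.
#' @return One-row data frame of class `mpc_outcome`.
#' @export
strategy_outcome <- function(strategy, cost, qaly, daly, cohort_size = 1e5) {
  out <- data.frame(strategy = as.character(strategy), cost = cost,
                    qaly = qaly, daly = daly,
                    cost_per_cohort = cost * cohort_size,
                    qaly_per_cohort = qaly * cohort_size,
                    daly_per_cohort = daly * cohort_size)
  class(out) <- c("mpc_outcome", "data.frame")
  out
}

#' Incremental cost per unit of effect
#'
#' @param incremental_cost Incremental cost (USD).
#' @param incremental_effect Incremental effect (QALYs gained or DALYs
#'   averted). Zero effect yields a signed-infinity sentinel (`Inf` when the
#'   cost is positive, `-Inf` when negative, `0` when both are zero).
#' @return The exact quotient, sign preserved.
#' @examples
#' compute_ratio(4700000, 745)   # 6308.725
#' @export
compute_ratio <- function(incremental_cost, incremental_effect) {
  if (incremental_effect == 0) {
    return(if (incremental_cost == 0) 0 else sign(incremental_cost) * Inf)
  }
  incremental_cost / incremental_effect
}

#' Classify a cost-effectiveness ratio against WHO GDP thresholds
#'
#' @param ratio USD per QALY gained or per DALY averted. `NA` for reference
#'   strategies returns `NA`.
#' @param gdp_per_capita Setting per-capita GDP (USD).
#' @param worse_effect Logical; `TRUE` when the strategy produced less
#'   effect than its comparator (a negative ratio then means dominated, not
#'   cost-saving).
#' @return One of `"highly_cost_effective"` (< 1x GDP), `"cost_effective"`
#'   (1x to 3x GDP), `"not_cost_effective"` (> 3x GDP), `"dominated"`.
#' @examples
#' classify_ratio(10707, 13856)   # highly_cost_effective
#' classify_ratio(11301, 10167)   # cost_effective
#' classify_ratio(37446, 10167)   # not_cost_effective
#' @export
classify_ratio <- function(ratio, gdp_per_capita, worse_effect = FALSE) {
  if (is.na(ratio)) return(NA_character_)
  th <- compute_thresholds(gdp_per_capita)
  if (worse_effect || (ratio < 0)) return("dominated")
  if (ratio < th[["highly_cost_effective"]]) return("highly_cost_effective")
  if (ratio <= th[["cost_effective"]]) return("cost_effective")
  "not_cost_effective"
}

# Strict dominance: strategy i is dominated if some j has cost <= and
# effect >= with at least one strict (ties: equal cost & effect -> the later
# row is flagged "duplicate").
flag_strict_dominance <- function(cost, effect) {
  n <- length(cost)
  flag <- rep("none", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (cost[j] == cost[i] && effect[j] == effect[i]) {
        if (j < i) flag[i] <- "duplicate"
        next
      }
      if (cost[j] <= cost[i] && effect[j] >= effect[i]) flag[i] <- "dominated"
    }
  }
  flag
}

#' Incremental cost-effectiveness analysis with extended dominance
#'
#' Strategies are sorted by ascending cost; strictly dominated strategies
#' (weakly cheaper and weakly more effective alternative exists, one strict)
#' are flagged, then extended dominance is applied iteratively: a strategy
#' whose incremental ratio against the previous surviving strategy exceeds
#' that of the next surviving strategy is removed from the frontier.
#' Surviving strategies form the efficiency frontier with strictly
#' increasing cost, effect and sequential ratios. Dominated strategies stay
#' in the table with their (possibly negative) ratios for transparency, but
#' are excluded from comparator chains.
#'
#' @param outcomes Data frame with columns `strategy`, `cost` and the chosen
#'   effect column (rows from [strategy_outcome()] may be `rbind`ed).
#' @param gdp_per_capita Setting GDP for threshold classification (optional;
#'   `NA` skips classification).
#' @param effect `"qaly"` (more is better; ratios are ICURs) or `"daly"`
#'   (fewer is better; effect enters as DALYs averted and ratios are ICERs).
#' @return Data frame of class `mpc_cea`: the input sorted by cost with
#'   `incr_cost`, `incr_effect`, `icer`, `dominance`
#'   (`none`/`dominated`/`extended_dominated`/`duplicate`), `comparator`,
#'   `classification`. `icer` is full precision; round only for display.
#' @examples
#' t1 <- data.frame(strategy = c("SCREEN", "TRAD", "DIGITAL"),
#'                  cost = c(171, 218, 324),
#'                  qaly = c(9.57764, 9.58509, 9.59448))
#' incremental_analysis(t1, gdp_per_capita = 10167, effect = "qaly")
#' @export
incremental_analysis <- function(outcomes, gdp_per_capita = NA,
                                 effect = c("qaly", "daly")) {
  effect <- match.arg(effect)
  outcomes <- as.data.frame(outcomes)
  if (nrow(outcomes) < 2L) {
    stop("incremental analysis needs at least 2 strategies", call. = FALSE)
  }
  if (anyDuplicated(outcomes$strategy)) {
    stop("strategy names must be distinct", call. = FALSE)
  }
  eff_raw <- outcomes[[effect]]
  if (is.null(eff_raw)) stop("outcomes lack column '", effect, "'",
                             call. = FALSE)
  # effect on a "more is better" scale
  eff_gain <- if (effect == "daly") -eff_raw else eff_raw

  ord <- order(outcomes$cost, eff_gain)
  tab <- outcomes[ord, , drop = FALSE]
  gain <- eff_gain[ord]

  tab$dominance <- flag_strict_dominance(tab$cost, gain)

  # iterative extended dominance on the surviving chain
  repeat {
    alive <- which(tab$dominance == "none")
    if (length(alive) < 3L) break
    icers <- diff(tab$cost[alive]) / diff(gain[alive])
    worse <- which(diff(icers) < 0)
    if (!length(worse)) break
    # middle strategy of the first decreasing ICER pair is extended dominated
    tab$dominance[alive[worse[1L] + 1L]] <- "extended_dominated"
  }

  # comparator chain over survivors; dominated rows compared to the previous
  # survivor for transparency
  tab$incr_cost <- NA_real_
  tab$incr_effect <- NA_real_
  tab$icer <- NA_real_
  tab$comparator <- NA_character_
  last_alive <- NA_integer_
  for (i in seq_len(nrow(tab))) {
    if (!is.na(last_alive)) {
      tab$incr_cost[i] <- tab$cost[i] - tab$cost[last_alive]
      tab$incr_effect[i] <- gain[i] - gain[last_alive]
      tab$icer[i] <- compute_ratio(tab$incr_cost[i], tab$incr_effect[i])
      tab$comparator[i] <- tab$strategy[last_alive]
      if (is.infinite(tab$icer[i]) && tab$incr_cost[i] > 0 &&
          tab$dominance[i] == "none") {
        tab$dominance[i] <- "dominated"
      }
    }
    if (tab$dominance[i] == "none") last_alive <- i
  }

  tab$classification <- vapply(seq_len(nrow(tab)), function(i) {
    if (is.na(tab$icer[i])) return(NA_character_)
    if (tab$dominance[i] != "none") return("dominated")
    if (is.na(gdp_per_capita)) return(NA_character_)
    classify_ratio(tab$icer[i], gdp_per_capita,
                   worse_effect = tab$incr_effect[i] < 0)
  }, character(1))

  rownames(tab) <- NULL
  structure(tab, effect = effect, gdp_per_capita = gdp_per_capita,
            class = c("mpc_cea", "data.frame"))
}

#' @export
print.mpc_cea <- function(x, ...) {
  eff <- attr(x, "effect")
  cat("<incremental ", if (identical(eff, "qaly")) "cost-utility" else
    "cost-effectiveness", " analysis (effect: ", eff, ")>\n", sep = "")
  df <- as.data.frame(x)
  df$icer <- ifelse(is.na(df$icer), NA,
                    formatC(round(df$icer), format = "d", big.mark = ","))
  print(df)
  invisible(x)
}

#' Efficiency frontier of a CEA table
#'
#' @param cea An `mpc_cea` table.
#' @return The subset of rows with `dominance == "none"`, in cost order.
#' @export
cea_frontier <- function(cea) {
  as.data.frame(cea)[cea$dominance == "none", , drop = FALSE]
}

#' Export a CEA table as CSV plus a JSON summary
#'
#' CSV mirrors the base-case table layout (cost, effect, incrementals,
#' ratio, dominance, classification) with full-precision machine-readable
#' numbers; the JSON carries the same rows plus the effect measure and GDP
#' used.
#'
#' @param cea An `mpc_cea` table.
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
write_cea <- function(cea, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(cea, "mpc_cea"))
  if (!is.null(path_csv)) {
    write.csv(as.data.frame(cea), path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(effect = attr(cea, "effect"),
           gdp_per_capita = attr(cea, "gdp_per_capita"),
           table = as.data.frame(cea)),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(list(csv = path_csv, json = path_json))
}

#' Sequential incremental comparison in table order
#'
#' The published base-case table compares every strategy to the previous
#' row regardless of dominance (dominance is flagged separately). This
#' helper reproduces that convention: incrementals and ratios of each row
#' against its predecessor, in the order given.
#'
#' @param outcomes Data frame with `strategy`, `cost` and the effect column,
#'   in presentation order (typically ascending cost).
#' @param effect `"qaly"` (ratios per QALY gained) or `"daly"` (per DALY
#'   averted).
#' @param scale Multiplier applied to incremental columns (e.g. `1e5` for
#'   per-100,000 presentation; ratios are scale invariant).
#' @return The input with `incr_cost`, `incr_effect`, `ratio` columns
#'   (first row `NA`).
#' @examples
#' bc <- published_base_case()
#' sequential_increments(bc[bc$setting == "rural",
#'                          c("strategy", "cost", "qaly")], scale = 1e5)
#' @export
sequential_increments <- function(outcomes, effect = c("qaly", "daly"),
                                  scale = 1) {
  effect <- match.arg(effect)
  outcomes <- as.data.frame(outcomes)
  eff <- outcomes[[effect]]
  gain <- if (effect == "daly") -eff else eff
  n <- nrow(outcomes)
  outcomes$incr_cost <- c(NA, diff(outcomes$cost)) * scale
  outcomes$incr_effect <- c(NA, diff(gain)) * scale
  outcomes$ratio <- c(NA_real_, vapply(seq_len(n)[-1], function(i) {
    compute_ratio(outcomes$cost[i] - outcomes$cost[i - 1L],
                  gain[i] - gain[i - 1L])
  }, numeric(1)))
  outcomes$comparator <- c(NA_character_, outcomes$strategy[-n])
  outcomes
}
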