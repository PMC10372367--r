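# One-way (tornado) sensitivity, probabilistic sensitivity analysis with
# beta/gamma parameter distributions, CEAC construction, and the
# perfect-compliance subgroup scenarios.

#' Build a perfect-compliance variant of the digital strategy
#'
#' @param params Parameter set.
#' @param setting Setting name.
#' @param fields Cascade field(s) set to 1.0: any of `"outdoor_compliance"`,
#'   `"coverage"`, `"spectacle_compliance"`, `"referral_compliance"`.
#' @param base Strategy to perfect (default `"DIGITAL"`).
#' @return An `mpc_strategy` named `<base>+perfect:<fields>`.
#' @export
perfect_compliance_variant <- function(params, setting, fields,
                                       base = "DIGITAL") {
  allowed <- c("outdoor_compliance", "coverage", "spectacle_compliance",
               "referral_compliance")
  bad <- setdiff(fields, allowed)
  if (length(bad)) {
    stop("unknown compliance field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  strat <- resolve_strategy(params, setting, base)
  for (f in fields) strat$cascade[[f]] <- 1
  strat$name <- paste0(base, "+perfect:", paste(fields, collapse = "+"))
  strat
}

#' Subgroup scenarios: perfect compliance along the cascade
#'
#' Reproduces the subgroup analysis layout: starting from the traditional
#' strategy, perfect-compliance variants of the digital strategy are formed
#' in the order outdoor activity, vision-test coverage, spectacles, hospital
#' examination, and each row is compared to the previous row. By default
#' each variant perfects a single field with the others at base case
#' (`mode = "single"`, which matches the published table's cost and DALY
#' patterns); `mode = "cumulative"` accumulates the perfections instead.
#'
#' @param params Parameter set.
#' @param setting Setting name.
#' @param fields Ordered compliance fields (default the published order).
#' @param mode `"single"` or `"cumulative"`.
#' @return Data frame of class `mpc_subgroup`: per-person `cost` and `daly`
#'   per variant, sequential `incr_cost`, `incr_daly_averted`, `icer`,
#'   `classification` against the setting's thresholds.
#' @export
subgroup_scenarios <- function(params, setting,
                               fields = c("outdoor_compliance", "coverage",
                                          "spectacle_compliance",
                                          "referral_compliance"),
                               mode = c("single", "cumulative")) {
  mode <- match.arg(mode)
  labels <- c(outdoor_compliance = "PERFECT_OUTDOOR",
              coverage = "PERFECT_COVERAGE",
              spectacle_compliance = "PERFECT_SPECTACLES",
              referral_compliance = "PERFECT_HOSPITAL")
  strategies <- list(TRADITIONAL = resolve_strategy(params, setting,
                                                    "TRADITIONAL"))
  for (i in seq_along(fields)) {
    f <- if (mode == "cumulative") fields[seq_len(i)] else fields[i]
    v <- perfect_compliance_variant(params, setting, f)
    strategies[[unname(labels[fields[i]])]] <- v
  }
  setting_ctx <- resolve_setting(params, setting)
  rows <- lapply(names(strategies), function(nm) {
    tot <- trace_totals(run_cohort(setting, strategies[[nm]], params))
    data.frame(variant = nm, cost = tot$cost, daly = tot$daly)
  })
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  tab$incr_cost <- c(NA, diff(tab$cost))
  tab$incr_daly_averted <- c(NA, -diff(tab$daly))
  tab$icer <- c(NA_real_, vapply(2:n, function(i) {
    compute_ratio(tab$incr_cost[i], tab$incr_daly_averted[i])
  }, numeric(1)))
  tab$comparator <- c(NA_character_, tab$variant[-n])
  tab$classification <- c(NA_character_, vapply(2:n, function(i) {
    classify_ratio(tab$icer[i], setting_ctx$gdp_per_capita,
                   worse_effect = tab$incr_daly_averted[i] < 0)
  }, character(1)))
  structure(tab, setting = setting_ctx$name, mode = mode,
            row.names = seq_len(n),
            class = c("mpc_subgroup", "data.frame"))
}

# ---- one-way sensitivity ---------------------------------------------------

# Deterministic headline ratio for a parameter bundle: ICUR (or ICER) of
# `strategy` vs `comparator` in `setting`.
bundle_ratio <- function(params, setting, strategy = "DIGITAL",
                         comparator = "TRADITIONAL", effect = "qaly") {
  t1 <- trace_totals(run_cohort(setting, comparator, params))
  t2 <- trace_totals(run_cohort(setting, strategy, params))
  eff <- if (effect == "qaly") t2$qaly - t1$qaly else t1$daly - t2$daly
  compute_ratio(t2$cost - t1$cost, eff)
}

#' One-way sensitivity of the headline ratio to one parameter
#'
#' Re-runs the full deterministic pipeline with the parameter at
#' `base * (1 - fraction)` and `base * (1 + fraction)`, everything else at
#' base case. Perturbed probabilities leaving [0, 1] are clipped with a
#' warning.
#'
#' @param params Parameter set.
#' @param path Dotted scalar parameter path, e.g.
#'   `"costs.rural.school_screening"` or
#'   `"strategies.rural.DIGITAL.cascade.coverage"`.
#' @param fraction Bound fraction, 0.10 or 0.20 (0 allowed for checking).
#' @param setting,strategy,comparator,effect Define the reported ratio
#'   (default: digital vs traditional ICUR).
#' @return One-row data frame: `param, base, low, high, ratio_low,
#'   ratio_high, range`.
#' @export
one_way <- function(params, path, fraction = 0.10, setting = "rural",
                    strategy = "DIGITAL", comparator = "TRADITIONAL",
                    effect = c("qaly", "daly")) {
  effect <- match.arg(effect)
  if (!fraction %in% c(0, 0.10, 0.20)) {
    stop("bound fraction must be 0, 0.10 or 0.20", call. = FALSE)
  }
  base <- param_get(params, path)
  is_prob <- !startsWith(path, "costs.")
  bound_value <- function(mult) {
    v <- base * mult
    if (is_prob && (v < 0 || v > 1)) {
      warning("perturbed value ", format(v), " for ", path,
              " clipped to [0, 1]", call. = FALSE)
      v <- min(max(v, 0), 1)
    }
    v
  }
  ratio_at <- function(v) {
    bundle_ratio(param_set(params, path, v), setting, strategy, comparator,
                 effect)
  }
  lo_v <- bound_value(1 - fraction)
  hi_v <- bound_value(1 + fraction)
  lo <- ratio_at(lo_v)
  hi <- ratio_at(hi_v)
  data.frame(param = path, base = base, low = lo_v, high = hi_v,
             ratio_low = lo, ratio_high = hi, range = abs(hi - lo))
}

#' Tornado analysis over a set of parameters
#'
#' Applies [one_way()] to each path with the conventional bound fractions
#' (10 percent for probabilities and weights, 20 percent for costs) and
#' orders the result by descending ratio range.
#'
#' @param params Parameter set.
#' @param paths Character vector of dotted parameter paths; defaults to the
#'   main cascade compliances, effect multipliers and unit-cost lines of the
#'   chosen setting.
#' @param setting,strategy,comparator,effect As in [one_way()].
#' @return Data frame of one-way rows sorted by `range`, class
#'   `mpc_tornado`.
#' @export
tornado <- function(params, paths = NULL, setting = "rural",
                    strategy = "DIGITAL", comparator = "TRADITIONAL",
                    effect = c("qaly", "daly")) {
  effect <- match.arg(effect)
  if (is.null(paths)) {
    paths <- c(
      sprintf("strategies.%s.DIGITAL.cascade.%s", setting,
              c("coverage", "sensitivity", "referral_compliance",
                "spectacle_compliance", "outdoor_compliance")),
      sprintf("strategies.%s.DIGITAL.effects.%s", setting,
              c("onset", "progression")),
      sprintf("strategies.%s.DIGITAL.education_exposure", setting),
      sprintf("costs.%s.school_screening", setting),
      sprintf("costs.%s.health_education.digital", setting),
      sprintf("costs.%s.hospital_examination.direct_hospital", setting),
      sprintf("costs.%s.treatment.direct_hospital", setting))
  }
  rows <- lapply(paths, function(p) {
    f <- if (startsWith(p, "costs.")) 0.20 else 0.10
    one_way(params, p, f, setting, strategy, comparator, effect)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  structure(out, setting = setting, effect = effect,
            class = c("mpc_tornado", "data.frame"))
}

#' Empirical percentile interval
#'
#' Linear interpolation between order statistics (the standard "type 7"
#' quantile rule), stated in all output metadata.
#'
#' @param samples Numeric vector with at least 2 values.
#' @param q_low,q_high Quantile levels (defaults 0.025 and 0.975).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' percentile_interval(1:100)   # 3.475 97.525
#' @export
percentile_interval <- function(samples, q_low = 0.025, q_high = 0.975) {
  if (length(samples) < 2L) {
    stop("percentile interval needs at least 2 samples", call. = FALSE)
  }
  q <- quantile(samples, c(q_low, q_high), type = 7, names = FALSE)
  c(low = q[1L], high = q[2L])
}

# ---- probabilistic sensitivity analysis ------------------------------------

#' PSA configuration
#'
#' Parameter distributions follow the conventional assignment: beta for
#' bounded quantities (transition probabilities, compliances, test
#' characteristics, effect multipliers, utilities, disability weights) with
#' the effective sample size `beta_ess` (alpha + beta = ess, mean = base
#' value), gamma for costs with coefficient of variation `gamma_cv` (mean =
#' base value). Moment matching reproduces the base value as the mean
#' exactly. `beta_ess = Inf` together with `gamma_cv = 0` gives degenerate
#' (variance zero) distributions.
#'
#' @param iterations Monte-Carlo iterations (default 10000).
#' @param seed Integer RNG seed.
#' @param beta_ess Effective sample size of beta distributions (default
#'   100).
#' @param gamma_cv Coefficient of variation of gamma distributions (default
#'   0.2).
#' @return List of class `mpc_psa_config`.
#' @export
psa_config <- function(iterations = 10000L, seed = 1L, beta_ess = 100,
                       gamma_cv = 0.2) {
  stopifnot(iterations >= 1, beta_ess > 0, gamma_cv >= 0)
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 beta_ess = beta_ess, gamma_cv = gamma_cv),
            class = "mpc_psa_config")
}

draw_beta <- function(n, mean, ess) {
  if (any(mean <= 0 | mean >= 1)) {
    stop("beta moment matching infeasible for base value ", mean,
         " (must be strictly inside (0, 1))", call. = FALSE)
  }
  if (!is.finite(ess)) return(rep(mean, n))
  rbeta(n, mean * ess, (1 - mean) * ess)
}

draw_gamma <- function(n, mean, cv) {
  if (mean < 0) stop("gamma moment matching infeasible for negative base",
                     call. = FALSE)
  if (cv == 0 || mean == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape / mean)
}

#' Probabilistic sensitivity analysis
#'
#' Jointly resamples all model parameters of one setting (transition
#' probabilities, cascade compliances and test characteristics, effect
#' multipliers, payoff weights, unit costs) and re-runs the three base
#' strategies per draw; parameters shared between strategies use a single
#' draw so strategies stay correlated. Reproducible given the seed.
#'
#' @param params Base-case parameter set.
#' @param setting Setting name.
#' @param config A [psa_config()].
#' @param wtp Willingness-to-pay used for the headline cost-effectiveness
#'   probability (default the setting's 3x-GDP threshold).
#' @param wtp_grid Grid for the acceptability curve (default 101 evenly
#'   spaced points from 0 to 4x GDP).
#' @param effect `"qaly"` (net monetary benefit uses QALYs; default) or
#'   `"daly"` (uses DALYs averted).
#' @return List of class `mpc_psa`: `draws` (iteration x strategy cost/
#'   qaly/daly), `ce_probability` at `wtp`, `ceac` (wtp x strategy
#'   probability matrix, rows summing to 1), `percentiles` (2.5/97.5 of
#'   cost, QALY, DALY per strategy), and the configuration metadata.
#' @export
run_psa <- function(params, setting, config = psa_config(), wtp = NULL,
                    wtp_grid = NULL, effect = c("qaly", "daly")) {
  effect <- match.arg(effect)
  setting_ctx <- resolve_setting(params, setting)
  s <- setting_ctx$name
  if (is.null(wtp)) wtp <- 3 * setting_ctx$gdp_per_capita
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 4 * setting_ctx$gdp_per_capita, length.out = 101L)
  }
  n <- config$iterations
  set.seed(config$seed)

  ages <- as.character(6:17)
  tr <- params$transitions[[s]]
  base_onset <- vapply(ages, function(a) tr[[a]]$onset, numeric(1))
  base_p1 <- vapply(ages, function(a) tr[[a]]$low_to_mod, numeric(1))
  base_p2 <- vapply(ages, function(a) tr[[a]]$mod_to_high, numeric(1))
  strat <- lapply(setNames(BASE_STRATEGIES, BASE_STRATEGIES),
                  function(st) params$strategies[[s]][[st]])
  pay <- params$payoffs[[s]]
  costs <- params$costs[[s]]
  w <- discount_weights(params$economics$discount_rate,
                        isTRUE(params$economics$half_cycle_correction))

  db <- function(m) vapply(m, function(v) draw_beta(n, v, config$beta_ess),
                           numeric(n))
  dg <- function(m) vapply(m, function(v) draw_gamma(n, v, config$gamma_cv),
                           numeric(n))
  D <- list(
    onset = db(base_onset), p1 = db(base_p1), p2 = db(base_p2),
    coverage = db(strat$DIGITAL$cascade$coverage),
    sens = db(strat$DIGITAL$cascade$sensitivity),
    spec = db(strat$DIGITAL$cascade$specificity),
    outdoor = db(strat$DIGITAL$cascade$outdoor_compliance),
    m_out = db(strat$DIGITAL$effects$onset),
    m_prog = db(strat$DIGITAL$effects$progression),
    ref = vapply(strat, function(x) db(x$cascade$referral_compliance),
                 numeric(n)),
    spect = vapply(strat, function(x) db(x$cascade$spectacle_compliance),
                   numeric(n)),
    du = db(1 - unlist(pay$utility)[2:4]),
    dw = db(unlist(pay$disability_weight)[2:4]),
    uc = dg(c(edu_t = costs$health_education$traditional,
              edu_d = costs$health_education$digital,
              screen = costs$school_screening,
              exam = sum(unlist(costs$hospital_examination)),
              treat = sum(unlist(costs$treatment))))
  )
  exposure <- vapply(strat, function(x) x$education_exposure, numeric(1))
  channel <- vapply(strat, function(x) x$education_channel, character(1))
  baseline <- as.numeric(unlist(params$settings[[s]]$baseline))

  draws <- array(NA_real_, dim = c(n, 3L, 3L),
                 dimnames = list(NULL, BASE_STRATEGIES,
                                 c("cost", "qaly", "daly")))
  for (i in seq_len(n)) {
    du <- sort(D$du[i, ])                # enforce severity ordering
    dwt <- sort(D$dw[i, ])
    u_full <- c(1, 1 - du)
    dw_full <- c(0, dwt)
    for (k in seq_along(BASE_STRATEGIES)) {
      st <- BASE_STRATEGIES[k]
      f_on <- 1 - exposure[st] * D$outdoor[i] * (1 - D$m_out[i])
      reach <- D$coverage[i] * D$sens[i] * D$ref[i, st] * D$spect[i, st]
      occ <- raw_occupancy(baseline, D$onset[i, ], D$p1[i, ], D$p2[i, ],
                           f_on, 1 - reach * (1 - D$m_prog[i]))
      myo <- rowSums(occ[, 2:4, drop = FALSE])
      tp <- myo * D$sens[i] * D$coverage[i]
      fp <- occ[, 1L] * (1 - D$spec[i]) * D$coverage[i]
      edu <- switch(channel[st], none = 0,
                    traditional = D$uc[i, "edu_t"],
                    digital = D$uc[i, "edu_d"])
      cost <- sum(w * (edu + D$coverage[i] * D$uc[i, "screen"] +
                         (tp + fp) * D$ref[i, st] * D$uc[i, "exam"] +
                         tp * D$ref[i, st] * D$spect[i, st] *
                         D$uc[i, "treat"]))
      draws[i, k, ] <- c(cost, sum(w * (occ %*% u_full)),
                         sum(w * (occ %*% dw_full)))
    }
  }

  eff_mat <- if (effect == "qaly") draws[, , "qaly"] else -draws[, , "daly"]
  cost_mat <- draws[, , "cost"]
  winner_at <- function(tau) {
    nmb <- eff_mat * tau - cost_mat
    max.col(nmb, ties.method = "first")
  }
  ce_prob <- tabulate(winner_at(wtp), 3L) / n
  names(ce_prob) <- BASE_STRATEGIES
  ceac <- t(vapply(wtp_grid, function(tau) tabulate(winner_at(tau), 3L) / n,
                   numeric(3)))
  colnames(ceac) <- BASE_STRATEGIES
  ceac <- data.frame(wtp = wtp_grid, ceac, check.names = FALSE)

  percentiles <- do.call(rbind, lapply(BASE_STRATEGIES, function(st) {
    do.call(rbind, lapply(c("cost", "qaly", "daly"), function(o) {
      pi <- percentile_interval(draws[, st, o])
      data.frame(strategy = st, outcome = o, p2.5 = pi[["low"]],
                 p97.5 = pi[["high"]], mean = mean(draws[, st, o]))
    }))
  }))

  structure(list(draws = draws, ce_probability = ce_prob, wtp = wtp,
                 ceac = ceac, percentiles = percentiles,
                 effect = effect, config = config,
                 setting = s, quantile_rule = "type 7 (linear interpolation)",
                 provenance = params$meta$provenance),
            class = "mpc_psa")
}

#' @export
print.mpc_psa <- function(x, ...) {
  cat("<PSA: ", x$setting, ", ", x$config$iterations, " iterations, seed ",
      x$config$seed, ">\n", sep = "")
  cat("P(most cost-effective) at WTP $", format(x$wtp, big.mark = ","),
      " per ", toupper(x$effect), ":\n", sep = "")
  print(round(x$ce_probability, 4))
  print(x$percentiles, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Export PSA artifacts as CSV
#'
#' Writes the per-iteration draws and/or the acceptability curve, each with
#' a metadata header line embedding seed, iteration count and quantile
#' rule.
#'
#' @param psa An `mpc_psa` result.
#' @param draws_path,ceac_path Output paths (`NULL` to skip).
#' @return Invisible list of paths.
#' @export
write_psa_csv <- function(psa, draws_path = NULL, ceac_path = NULL) {
  meta <- sprintf("# myopiaCEA PSA | setting=%s | iterations=%d | seed=%d | quantiles=%s | params=%s",
                  psa$setting, psa$config$iterations, psa$config$seed,
                  psa$quantile_rule, psa$provenance %||% "unlabelled")
  if (!is.null(draws_path)) {
    long <- do.call(rbind, lapply(BASE_STRATEGIES, function(st) {
      data.frame(iteration = seq_len(dim(psa$draws)[1L]), strategy = st,
                 cost = psa$draws[, st, "cost"],
                 qaly = psa$draws[, st, "qaly"],
                 daly = psa$draws[, st, "daly"])
    }))
    con <- file(draws_path, "wt"); writeLines(meta, con)
    write.csv(long, con, row.names = FALSE); close(con)
  }
  if (!is.null(ceac_path)) {
    con <- file(ceac_path, "wt"); writeLines(meta, con)
    write.csv(psa$ceac, con, row.names = FALSE); close(con)
  }
  invisible(list(draws = draws_path, ceac = ceac_path))
}
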