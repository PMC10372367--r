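#' Screening and referral cascade of a management strategy
#'
#' Every strategy screens schoolchildren with a non-cycloplegic vision test
#' (imperfect sensitivity/specificity). Children who screen positive may
#' attend a confirmatory hospital examination (referral compliance), and
#' confirmed myopes may take up correction (spectacle compliance). Health
#' education additionally promotes outdoor activity among all students,
#' independent of screening result.
#'
#' @param coverage Fraction of students receiving the school vision test per
#'   annual cycle (base case 0.918).
#' @param sensitivity,specificity Test characteristics of the non-cycloplegic
#'   school test against cycloplegic refraction.
#' @param referral_compliance Fraction of screen-positives attending the
#'   hospital examination.
#' @param spectacle_compliance Fraction of confirmed myopes complying with
#'   correction/treatment.
#' @param outdoor_compliance Fraction of students complying with promoted
#'   outdoor activity when reached by health education (base case 0.838).
#' @return A `list` of class `mpc_cascade`.
#' @export
screening_cascade <- function(coverage = 0.918,
                              sensitivity = 0.90,
                              specificity = 0.95,
                              referral_compliance = 0.353,
                              spectacle_compliance = 0.36,
                              outdoor_compliance = 0.838) {
  x <- list(coverage = coverage, sensitivity = sensitivity,
            specificity = specificity,
            referral_compliance = referral_compliance,
            spectacle_compliance = spectacle_compliance,
            outdoor_compliance = outdoor_compliance)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("cascade field '", nm, "' must be a single value in [0, 1]",
           call. = FALSE)
    }
  }
  class(x) <- "mpc_cascade"
  x
}

#' Intervention effect on transition probabilities
#'
#' An effect is a multiplicative factor in (0, 1] applied to the targeted
#' transition probabilities of children actually reached by the
#' intervention; interventions never worsen progression in this model.
#'
#' @param applies_to Either `"onset"` (NON_MYOPIA -> LOW, delivered by
#'   outdoor-activity promotion through health education) or `"progression"`
#'   (within-myopia transitions, delivered by treatment through the screening
#'   cascade).
#' @param multiplier Transition-probability multiplier in (0, 1] among the
#'   reached.
#' @param label Free-text intervention label.
#' @return A `list` of class `mpc_effect`.
#' @export
intervention_effect <- function(applies_to = c("onset", "progression"),
                                multiplier, label = applies_to) {
  applies_to <- match.arg(applies_to)
  if (!is.numeric(multiplier) || length(multiplier) != 1L ||
      is.na(multiplier) || multiplier <= 0 || multiplier > 1) {
    stop("effect multiplier must be a single value in (0, 1]", call. = FALSE)
  }
  structure(list(applies_to = applies_to, multiplier = multiplier,
                 label = label[[1L]]),
            class = "mpc_effect")
}

#' Define a myopia management strategy
#'
#' The three base strategies share the school vision test but differ in the
#' health-education channel and in compliance along the cascade:
#' `SCHOOL_SCREENING` (screening and referral only, no education),
#' `TRADITIONAL` (posters/brochures/activities education) and `DIGITAL`
#' (WeChat/SMS education, highest compliance). Perfect-compliance variants
#' used in subgroup analyses carry their parent's name plus a suffix.
#'
#' @param name Strategy name.
#' @param cascade A [screening_cascade()].
#' @param effects List of [intervention_effect()] objects (may be empty, in
#'   which case the strategy follows natural history).
#' @param education_channel One of `"none"`, `"traditional"`, `"digital"`.
#' @param education_exposure Fraction of students reached by the education
#'   channel (0 when `education_channel == "none"`).
#' @return A `list` of class `mpc_strategy`.
#' @export
strategy_definition <- function(name, cascade, effects = list(),
                                education_channel = c("none", "traditional",
                                                      "digital"),
                                education_exposure = 0) {
  education_channel <- match.arg(education_channel)
  stopifnot(inherits(cascade, "mpc_cascade"))
  if (length(effects) && !all(vapply(effects, inherits, TRUE, "mpc_effect"))) {
    stop("effects must be a list of intervention_effect objects", call. = FALSE)
  }
  if (!is.numeric(education_exposure) || education_exposure < 0 ||
      education_exposure > 1) {
    stop("education_exposure must lie in [0, 1]", call. = FALSE)
  }
  if (education_channel == "none" && education_exposure > 0) {
    stop("education_exposure must be 0 when there is no education channel",
         call. = FALSE)
  }
  structure(list(name = as.character(name)[[1L]], cascade = cascade,
                 effects = effects, education_channel = education_channel,
                 education_exposure = education_exposure),
            class = "mpc_strategy")
}

#' @export
print.mpc_strategy <- function(x, ...) {
  cat("<strategy ", x$name, ", education: ", x$education_channel, ">\n",
      sep = "")
  str(x$cascade[], give.attr = FALSE)
  invisible(x)
}

#' Define a rural or urban setting context
#'
#' @param name `"rural"` or `"urban"`.
#' @param baseline_distribution [health_state_distribution()] at age 6.
#'   Published baselines: rural low/moderate/high 4.83/0.07/0.09 percent;
#'   urban 12.56/0.19/0.25 percent.
#' @param gdp_per_capita Per-capita GDP in 2021 USD (rural 10,167; urban
#'   13,856), used for WHO willingness-to-pay thresholds.
#' @param cohort_size Cohort size for per-100,000-style scaling (default
#'   100,000; 0 is allowed, per-person outputs remain defined).
#' @return A `list` of class `mpc_setting`.
#' @export
setting_context <- function(name, baseline_distribution, gdp_per_capita,
                            cohort_size = 1e5) {
  stopifnot(inherits(baseline_distribution, "mpc_dist"))
  if (attr(baseline_distribution, "age") != 6L) {
    stop("baseline distribution must be at age 6", call. = FALSE)
  }
  if (!is.numeric(gdp_per_capita) || gdp_per_capita <= 0) {
    stop("gdp_per_capita must be positive", call. = FALSE)
  }
  if (!is.numeric(cohort_size) || cohort_size < 0) {
    stop("cohort_size must be non-negative", call. = FALSE)
  }
  structure(list(name = as.character(name)[[1L]],
                 baseline_distribution = baseline_distribution,
                 gdp_per_capita = gdp_per_capita,
                 cohort_size = cohort_size),
            class = "mpc_setting")
}

# Reach of each effect route through the cascade. Treatment effects require
# the full screening cascade (test -> positive -> hospital -> uptake);
# education-delivered outdoor activity reaches students regardless of screen
# result.
effect_reach <- function(strategy, applies_to) {
  cas <- strategy$cascade
  if (applies_to == "onset") {
    r <- strategy$education_exposure * cas$outdoor_compliance
  } else {
    r <- cas$coverage * cas$sensitivity * cas$referral_compliance *
      cas$spectacle_compliance
  }
  if (r < 0 || r > 1) {
    stop("effect reach ", format(r), " outside [0, 1]", call. = FALSE)
  }
  r
}

#' Apply a strategy's interventions to a natural-history matrix
#'
#' Each targeted transition probability `p` becomes
#' `p * (1 - reach * (1 - multiplier))`: the reached fraction of the cohort
#' progresses at `p * multiplier`, the rest at `p`. For treatment
#' (progression) effects `reach = coverage x sensitivity x
#' referral_compliance x spectacle_compliance`; for education-delivered
#' outdoor activity (onset) `reach = education_exposure x
#' outdoor_compliance`. The diagonal absorbs the change so the matrix stays
#' row-stochastic.
#'
#' @param matrix An `mpc_tmat` natural-history matrix for one age.
#' @param strategy An `mpc_strategy`.
#' @param setting An `mpc_setting` (carried for interface symmetry; reach
#'   does not depend on it beyond the strategy's own setting-specific
#'   compliances).
#' @return The effective `mpc_tmat` for the same age.
#' @examples
#' nat <- transition_matrix(progression_matrix(0.10, 0.05, 0.02), age = 8)
#' dig <- strategy_definition(
#'   "DIGITAL", screening_cascade(),
#'   effects = list(intervention_effect("onset", 0.6),
#'                  intervention_effect("progression", 0.85)),
#'   education_channel = "digital", education_exposure = 0.9)
#' apply_strategy(nat, dig)
#' @export
apply_strategy <- function(matrix, strategy, setting = NULL) {
  stopifnot(inherits(matrix, "mpc_tmat"), inherits(strategy, "mpc_strategy"))
  m <- unclass(matrix)
  age <- attr(matrix, "age")
  for (eff in strategy$effects) {
    reach <- effect_reach(strategy, eff$applies_to)
    factor <- 1 - reach * (1 - eff$multiplier)
    if (eff$applies_to == "onset") {
      idx <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))
    } else {
      idx <- rbind(c(2L, 3L), c(2L, 4L), c(3L, 4L))
    }
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1L]; j <- idx[k, 2L]
      delta <- m[i, j] * (1 - factor)
      m[i, j] <- m[i, j] - delta
      m[i, i] <- m[i, i] + delta
    }
  }
  transition_matrix(m, age)
}
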