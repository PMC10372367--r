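#' Health states of the myopia progression model
#'
#' The cohort model tracks four mutually exclusive refractive states defined
#' on cycloplegic spherical equivalent (SE, diopters): non-myopia
#' (SE > -0.5 D), low myopia (-3.00 < SE <= -0.50), moderate myopia
#' (-6.00 < SE <= -3.00), and high myopia (SE <= -6.00). The four SE
#' intervals partition the real line.
#'
#' @return Character vector of the four state labels, ordered from least to
#'   most myopic.
#' @examples
#' myopia_states()
#' @export
myopia_states <- function() {
  c("NON_MYOPIA", "LOW", "MODERATE", "HIGH")
}

#' SE interval boundaries of each health state
#'
#' @return A data frame with one row per state giving the half-open spherical
#'   equivalent interval `(se_lower, se_upper]` in diopters (non-myopia is
#'   open below at -0.5 D and unbounded above).
#' @examples
#' state_se_ranges()
#' @export
state_se_ranges <- function() {
  data.frame(
    state = myopia_states(),
    se_lower = c(-0.5, -3.0, -6.0, -Inf),
    se_upper = c(Inf, -0.5, -3.0, -6.0)
  )
}

N_STATES <- 4L
MODEL_AGES <- 6:18       # 13 age points, 12 annual transitions
MYOPIC <- c("LOW", "MODERATE", "HIGH")

#' Construct a health-state distribution at one age
#'
#' @param occupancy Numeric vector of length 4 (fractions of the cohort in
#'   NON_MYOPIA, LOW, MODERATE, HIGH). Must be non-negative and sum to 1
#'   within 1e-9. Names, if present, must match [myopia_states()].
#' @param age Integer age in years, between 6 and 18.
#' @return An object of class `mpc_dist`: a named numeric vector with an
#'   `age` attribute.
#' @examples
#' health_state_distribution(c(0.9501, 0.0483, 0.0007, 0.0009), age = 6)
#' @export
health_state_distribution <- function(occupancy, age) {
  occupancy <- as.numeric(occupancy)
  if (length(occupancy) != N_STATES) {
    stop("occupancy must have exactly ", N_STATES, " elements", call. = FALSE)
  }
  if (any(occupancy < -1e-12) || any(occupancy > 1 + 1e-12)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancies must sum to 1 (got ", format(sum(occupancy), digits = 12),
         ")", call. = FALSE)
  }
  age <- as.integer(age)
  if (length(age) != 1L || is.na(age) || age < 6L || age > 18L) {
    stop("age must be a single integer in [6, 18]", call. = FALSE)
  }
  names(occupancy) <- myopia_states()
  structure(occupancy, age = age, class = "mpc_dist")
}

#' @export
print.mpc_dist <- function(x, ...) {
  cat("<health-state distribution, age ", attr(x, "age"), ">\n", sep = "")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Total myopia prevalence of a distribution
#'
#' @param dist An `mpc_dist` object (or plain 4-vector in state order).
#' @return `1 - P(NON_MYOPIA)` as a fraction.
#' @export
total_myopia <- function(dist) {
  unname(1 - dist[[1L]])
}

#' Construct and validate an annual transition matrix
#'
#' Rows index the state at the start of the cycle, columns the state at the
#' end; each row must sum to 1 within 1e-9 with entries in [0, 1]. Under the
#' irreversibility convention the model enforces that no probability mass
#' moves toward a less myopic state (the lower triangle is zero): refractive
#' error does not regress.
#'
#' @param mat 4x4 numeric matrix of annual transition probabilities.
#' @param age Integer age (years) at the start of the transition, in 6..17.
#' @return An object of class `mpc_tmat` (the validated matrix with an `age`
#'   attribute and dimnames set to the state labels).
#' @examples
#' transition_matrix(progression_matrix(0.10, 0.05, 0.02), age = 6)
#' @export
transition_matrix <- function(mat, age) {
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(N_STATES, N_STATES))) {
    stop("transition matrix must be 4x4", call. = FALSE)
  }
  if (any(mat < -1e-12) || any(mat > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(mat)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad)) {
    stop("transition matrix row ", bad[1L], " (", myopia_states()[bad[1L]],
         ") sums to ", format(rs[bad[1L]], digits = 12), ", not 1",
         call. = FALSE)
  }
  if (any(mat[lower.tri(mat)] > 1e-12)) {
    stop("transitions toward less myopic states are forbidden ",
         "(lower triangle must be zero)", call. = FALSE)
  }
  age <- as.integer(age)
  if (length(age) != 1L || is.na(age) || age < 6L || age > 17L) {
    stop("transition age must be a single integer in [6, 17]", call. = FALSE)
  }
  dimnames(mat) <- list(myopia_states(), myopia_states())
  structure(mat, age = age, class = "mpc_tmat")
}

#' Build a one-step-progression matrix from three annual probabilities
#'
#' Convenience constructor for the natural-history structure used throughout:
#' onset moves NON_MYOPIA to LOW, progression moves LOW to MODERATE and
#' MODERATE to HIGH; HIGH is absorbing and no state skipping occurs within a
#' single annual cycle.
#'
#' @param onset Annual probability of myopia onset (NON_MYOPIA -> LOW).
#' @param low_to_mod Annual probability LOW -> MODERATE.
#' @param mod_to_high Annual probability MODERATE -> HIGH.
#' @return A plain 4x4 matrix (wrap with [transition_matrix()] to validate
#'   and attach an age).
#' @export
progression_matrix <- function(onset, low_to_mod, mod_to_high) {
  p <- c(onset = onset, low_to_mod = low_to_mod, mod_to_high = mod_to_high)
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop("transition probability '", names(p)[bad[1L]], "' (",
         format(p[bad[1L]]), ") must lie in [0, 1]", call. = FALSE)
  }
  m <- diag(4)
  m[1, 1] <- 1 - onset;      m[1, 2] <- onset
  m[2, 2] <- 1 - low_to_mod; m[2, 3] <- low_to_mod
  m[3, 3] <- 1 - mod_to_high; m[3, 4] <- mod_to_high
  m
}
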