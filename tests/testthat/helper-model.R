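# Shared fixtures, built in code. The packaged surrogate set is loaded once;
# small hand-rolled parameter sets support the cheaper unit tests.

ref_params <- mpc_reference_params()

# A tiny, fully hand-specified parameter set (identical transitions at all
# ages) used where the packaged fixture would be overkill.
toy_params <- local({
  p <- generate_initial_guess(seed = 1)
  for (s in c("rural", "urban")) {
    for (a in as.character(6:17)) {
      p$transitions[[s]][[a]] <- list(onset = 0.10, low_to_mod = 0.05,
                                      mod_to_high = 0.02)
    }
  }
  validate_params(p)
  p
})

# Independent step-by-step oracle: dense matrix products on the 4-vector,
# written without any package machinery.
oracle_occupancy <- function(baseline, matrices) {
  out <- matrix(NA_real_, length(matrices) + 1L, 4L)
  v <- baseline
  out[1L, ] <- v
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    v <- c(sum(v * m[, 1]), sum(v * m[, 2]), sum(v * m[, 3]), sum(v * m[, 4]))
    out[i + 1L, ] <- v
  }
  out
}

# Brute-force efficiency frontier straight from the definition: a strategy
# is off the frontier iff some convex combination of two other strategies
# (including the degenerate single-strategy mixes) costs no more and yields
# no less effect, with at least one strict. The feasible mixing weights form
# an interval computed analytically — no sweep logic shared with the
# implementation.
oracle_frontier <- function(cost, gain) {
  n <- length(cost)
  lam_interval <- function(a, b) {
    # all lambda in [0,1] with lambda*a <= b
    if (abs(a) < 1e-14) { if (b >= -1e-14) c(0, 1) else c(1, 0) }
    else if (a > 0) c(0, min(1, b / a))
    else c(max(0, b / a), 1)
  }
  dominated <- vapply(seq_len(n), function(i) {
    for (j in seq_len(n)) for (k in j:n) {
      if (j == i || k == i) next
      ic <- lam_interval(cost[j] - cost[k], cost[i] - cost[k])
      ig <- lam_interval(-(gain[j] - gain[k]), -(gain[i] - gain[k]))
      lo <- max(ic[1L], ig[1L]); hi <- min(ic[2L], ig[2L])
      if (lo > hi) next
      for (lam in unique(c(lo, (lo + hi) / 2, hi))) {
        cm <- lam * cost[j] + (1 - lam) * cost[k]
        gm <- lam * gain[j] + (1 - lam) * gain[k]
        if (cm <= cost[i] + 1e-12 && gm >= gain[i] - 1e-12 &&
            (cm < cost[i] - 1e-9 || gm > gain[i] + 1e-9)) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  which(!dominated)
}
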