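# Surrogate parameter generation and calibration.

test_that("initial guesses are seed-deterministic and structurally valid", {
  g1 <- generate_initial_guess(seed = 7)
  g2 <- generate_initial_guess(seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_initial_guess(seed = 8)
  expect_false(identical(g1$transitions, g3$transitions))
  expect_silent(validate_params(g1))
  # baseline is an input, not fitted: reproduced exactly
  expect_identical(unlist(g1$settings$rural$baseline),
                   c(0.9501, 0.0483, 0.0007, 0.0009))
  # onset curve rises to its peak before declining
  onset <- vapply(as.character(6:17),
                  function(a) g1$transitions$rural[[a]]$onset, numeric(1))
  peak <- which.max(onset)
  expect_true(all(diff(onset[1:peak]) >= 0))
})

test_that("calibration recovers outputs of a known generating set
          (round trip at the output level)", {
  gen <- generate_initial_guess(seed = 3)
  # targets produced by running the generating set through the pipeline
  synth_targets <- calibration_targets()
  for (s in c("rural", "urban")) {
    tots <- lapply(c(SCHOOL_SCREENING = "SCHOOL_SCREENING",
                     TRADITIONAL = "TRADITIONAL", DIGITAL = "DIGITAL"),
                   function(st) trace_totals(run_cohort(s, st, gen)))
    synth_targets[[s]]$age18_total <- vapply(tots, `[[`,
                                             numeric(1),
                                             "age18_total_myopia")
    synth_targets[[s]]$high_reduction <-
      tots$SCHOOL_SCREENING$age18_high_myopia -
      tots$DIGITAL$age18_high_myopia
    synth_targets[[s]]$cost <- vapply(tots, `[[`, numeric(1), "cost")
    synth_targets[[s]]$qaly <- vapply(tots, `[[`, numeric(1), "qaly")
    synth_targets[[s]]$daly <- vapply(tots, `[[`, numeric(1), "daly")
    outdoor <- perfect_compliance_variant(gen, s, "outdoor_compliance")
    synth_targets[[s]]$cost_outdoor <-
      trace_totals(run_cohort(s, outdoor, gen))$cost
    synth_targets[[s]]$soft_cost[] <- NA_real_
  }
  res <- calibrate(synth_targets, generate_initial_guess(seed = 12),
                   control = list(maxit = 120))
  rep <- calibration_report(res$params, synth_targets)
  expect_true(rep$converged)
})

test_that("targets violating the strategy ordering are rejected", {
  tg <- calibration_targets()
  tg$rural$age18_total["DIGITAL"] <- 0.95  # above screening: inconsistent
  expect_error(calibrate(tg, generate_initial_guess()), "ordering invariant")
})

test_that("the shipped fixture carries the surrogate provenance label and
          propagates it to derived artifacts", {
  expect_identical(ref_params$meta$provenance,
                   "calibrated surrogate, not original appendix values")
  tr <- run_cohort("rural", "DIGITAL", ref_params)
  expect_identical(attr(tr, "provenance"), ref_params$meta$provenance)
  psa <- run_psa(ref_params, "rural", psa_config(iterations = 2, seed = 1))
  expect_identical(psa$provenance, ref_params$meta$provenance)
})

test_that("the fit report recomputes every anchor class from the fixture", {
  rep <- calibration_report(ref_params)
  expect_true(rep$converged)
  tb <- rep$table
  expect_setequal(unique(tb$setting), c("rural", "urban"))
  # every target family present for both settings
  expect_identical(sum(grepl("age18_total", tb$target)), 6L)
  expect_identical(sum(grepl("high_myopia_reduction", tb$target)), 2L)
  expect_identical(sum(grepl("cost_per_person", tb$target)), 8L)
  expect_identical(sum(grepl("qaly_per_person", tb$target)), 6L)
  expect_identical(sum(grepl("daly_per_person", tb$target)), 6L)
})

test_that("fixture runs are bit-stable across repeated executions", {
  t1 <- run_cohort("urban", "TRADITIONAL", ref_params)
  t2 <- run_cohort("urban", "TRADITIONAL", ref_params)
  expect_identical(t1, t2)
})

test_that("the scenario bundle assembles presentation tables with sequential
          per-100,000 incrementals", {
  bundle <- suppressWarnings(make_scenario_bundle(ref_params))
  expect_identical(bundle$provenance, ref_params$meta$provenance)
  tq <- bundle$base_case$rural$table_qaly
  expect_identical(tq$strategy,
                   c("SCHOOL_SCREENING", "TRADITIONAL", "DIGITAL"))
  # sequential incrementals recompute from the full-precision outcomes
  oc <- bundle$base_case$rural$outcomes
  expect_equal(tq$incr_cost[2], (oc$cost[2] - oc$cost[1]) * 1e5,
               tolerance = 1e-9)
  expect_equal(tq$incr_effect[3], (oc$qaly[3] - oc$qaly[2]) * 1e5,
               tolerance = 1e-9)
  expect_identical(nrow(bundle$subgroup$urban), 5L)
  expect_identical(names(bundle$traces$rural),
                   c("SCHOOL_SCREENING", "TRADITIONAL", "DIGITAL"))
})
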