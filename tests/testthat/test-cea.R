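# Incremental cost-utility / cost-effectiveness analysis, dominance,
# threshold classification.

test_that("compute_ratio is an exact signed quotient with infinity sentinel", {
  expect_equal(compute_ratio(4700000, 745), 4700000 / 745)
  expect_equal(round(compute_ratio(4700000, 745)), 6309)
  expect_equal(compute_ratio(0, 7), 0)
  expect_equal(compute_ratio(100, 8), 12.5)
  expect_equal(compute_ratio(-50, 10), -5)
  expect_identical(compute_ratio(10, 0), Inf)
  expect_identical(compute_ratio(-10, 0), -Inf)
  expect_identical(compute_ratio(0, 0), 0)
})

test_that("GDP-multiple classification matches the published calls", {
  expect_identical(classify_ratio(10707, 13856), "highly_cost_effective")
  expect_identical(classify_ratio(11301, 10167), "cost_effective")
  expect_identical(classify_ratio(37446, 10167), "not_cost_effective")
  expect_identical(classify_ratio(41814, 13856), "not_cost_effective")
  expect_identical(classify_ratio(-19891, 10167, worse_effect = TRUE),
                   "dominated")
  # boundaries: 1x is cost-effective (WHO: "one to three times"), 3x included
  expect_identical(classify_ratio(10167, 10167), "cost_effective")
  expect_identical(classify_ratio(30501, 10167), "cost_effective")
  expect_identical(classify_ratio(30501.01, 10167), "not_cost_effective")
})

test_that("incremental analysis on the published per-person values matches
          the printed rural incrementals", {
  bc <- published_base_case()
  rural <- bc[bc$setting == "rural", c("strategy", "cost", "qaly", "daly")]
  cea <- incremental_analysis(rural, gdp_per_capita = 10167, effect = "qaly")
  expect_identical(cea$dominance, rep("none", 3))
  # per-100,000 incrementals from printed per-person values
  expect_equal(round(cea$incr_cost * 1e5), c(NA, 4700000, 10600000))
  expect_equal(round(cea$incr_effect * 1e5), c(NA, 745, 939))
  expect_equal(round(cea$icer[2]), 6309)
  expect_identical(cea$comparator, c(NA, "SCHOOL_SCREENING", "TRADITIONAL"))
  # traditional sits below 1x GDP; digital between 1x and 3x
  expect_identical(cea$classification[2:3],
                   c("highly_cost_effective", "cost_effective"))

  cead <- incremental_analysis(rural, gdp_per_capita = 10167, effect = "daly")
  expect_equal(round(cead$incr_effect * 1e5), c(NA, 373, 284))
})

test_that("strict dominance, duplicates and zero-effect sentinels are flagged", {
  two <- data.frame(strategy = c("A", "B"), cost = c(10, 10),
                    qaly = c(5, 5))
  cea <- incremental_analysis(two, effect = "qaly")
  expect_identical(cea$dominance, c("none", "duplicate"))
  expect_equal(cea$incr_cost[2], 0)
  expect_equal(cea$incr_effect[2], 0)

  tie <- data.frame(strategy = c("A", "B"), cost = c(10, 12), qaly = c(5, 5))
  ceat <- incremental_analysis(tie, effect = "qaly")
  expect_identical(ceat$dominance[2], "dominated")
  expect_identical(ceat$icer[2], Inf)

  expect_error(incremental_analysis(two[1, ], effect = "qaly"),
               "at least 2")
  expect_error(incremental_analysis(rbind(two, two), effect = "qaly"),
               "distinct")
})

test_that("extended dominance yields an increasing-ICER frontier", {
  # classic textbook pattern: B has a higher ICER vs A than C does
  tab <- data.frame(strategy = c("A", "B", "C"),
                    cost = c(100, 200, 250),
                    qaly = c(1.0, 1.01, 1.10))
  cea <- incremental_analysis(tab, effect = "qaly")
  expect_identical(cea$dominance, c("none", "extended_dominated", "none"))
  front <- cea_frontier(cea)
  expect_identical(front$strategy, c("A", "C"))
  icers <- front$icer[!is.na(front$icer)]
  expect_true(all(diff(c(0, icers)) > 0))
})

test_that("frontier equals the brute-force convex-combination oracle", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    tab <- data.frame(strategy = LETTERS[1:n],
                      cost = runif(n, 50, 500),
                      qaly = runif(n, 9.0, 9.6))
    cea <- incremental_analysis(tab, effect = "qaly")
    got <- sort(cea$strategy[cea$dominance == "none"])
    ord <- oracle_frontier(tab$cost, tab$qaly)
    expect_identical(got, sort(tab$strategy[ord]))
    # frontier invariants: strictly increasing cost, effect, sequential ICER
    fr <- cea_frontier(cea)
    expect_true(all(diff(fr$cost) > 0))
    expect_true(all(diff(fr$qaly) > 0))
    seq_icer <- fr$icer[!is.na(fr$icer)]
    if (length(seq_icer) > 1) expect_true(all(diff(seq_icer) > 0))
  }
})

test_that("ratios are identical per person and per 100,000", {
  bc <- published_base_case()
  rural <- bc[bc$setting == "rural", c("strategy", "cost", "qaly")]
  per_person <- incremental_analysis(rural, effect = "qaly")
  scaled <- rural
  scaled$cost <- scaled$cost * 1e5
  scaled$qaly <- scaled$qaly * 1e5
  per_cohort <- incremental_analysis(scaled, effect = "qaly")
  expect_equal(per_person$icer, per_cohort$icer, tolerance = 1e-12)
})

test_that("negative ratios are reported, not suppressed", {
  tab <- data.frame(strategy = c("A", "B"), cost = c(100, 150),
                    daly = c(0.05, 0.06))  # B costs more, averts fewer
  cea <- incremental_analysis(tab, gdp_per_capita = 10167, effect = "daly")
  expect_identical(cea$dominance[2], "dominated")
  expect_true(is.finite(cea$icer[2]) && cea$icer[2] < 0)
  expect_identical(cea$classification[2], "dominated")
})
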