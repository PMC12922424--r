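test_that("scenario-year cost keeps N integer and arm populations fractional", {
  s1 <- scenario1_fixture()
  costs <- setNames(s1$unit_costs$cost_qar[s1$unit_costs$year == 2024],
                    s1$unit_costs$arm_id[s1$unit_costs$year == 2024])
  out <- scenario_annual_cost(173, c(abma = 0.20, cdk_mix = 0.80), costs)
  expect_equal(out$total, 29890060, tolerance = 1e-6)
  expect_equal(sum(out$arm_costs), out$total, tolerance = 1e-12)

  expect_identical(scenario_annual_cost(0, c(a = 1), c(a = 5000))$total, 0)
  expect_identical(scenario_annual_cost(50, c(a = 1), c(a = 5000))$total,
                   50 * 5000)
  expect_error(scenario_annual_cost(10, c(a = 0.5, b = 0.5), c(a = 1)), "b")
  expect_error(scenario_annual_cost(10, c(a = 0.6, b = 0.6),
                                    c(a = 1, b = 1)), "sum to 1")
  # zero-share arms do not require a cost entry
  expect_identical(
    scenario_annual_cost(10, c(a = 1, b = 0), c(a = 100))$total, 1000)
})

test_that("baseline annual cost reduces to N times the blended basket rate", {
  s1 <- scenario1_fixture()
  expect_equal(baseline_annual_cost(173, 2024, s1), 31124763,
               tolerance = 1e-6)
  s2 <- scenario2_fixture()
  expect_equal(baseline_annual_cost(173, 2024, s2), 27102920,
               tolerance = 1e-6)
  expect_equal(baseline_annual_cost(173, 2024, s2) / 173,
               27102920 / 173, tolerance = 1e-9)
  bad <- s1
  bad$baseline$shares <- bad$baseline$shares[bad$baseline$shares$year !=
                                               2026, ]
  expect_error(baseline_annual_cost(191, 2026, bad), "2026")
})

test_that("incremental impact follows the projected-minus-baseline sign", {
  expect_identical(incremental_impact(29890060, 31124763), -1234703)
  expect_identical(incremental_impact(42, 42), 0)
  expect_identical(incremental_impact(27893201, 27102920), 790281)
})

test_that("per-patient impact is integer QAR, ties away from zero", {
  expect_identical(per_patient_impact(-1234703, 173), -7137)
  expect_identical(per_patient_impact(790281, 173), 4568)
  expect_identical(per_patient_impact(0, 99), 0)
  expect_identical(per_patient_impact(301, 2), 151)
  expect_identical(per_patient_impact(-301, 2), -151)
  expect_error(per_patient_impact(1, 0), "> 0")
})

test_that("cumulative impact is the exact sum of yearly incrementals", {
  inc <- c(-1234703, -1944658, -2726339, -3578320, -4517729)
  expect_identical(cumulative_impact(inc), -14001749)
  expect_identical(cumulative_impact(tibble::tibble(incremental = inc)),
                   -14001749)
  expect_identical(cumulative_impact(-7), -7)
  expect_identical(cumulative_impact(c(5, -3, -2)), 0)
  expect_error(cumulative_impact(numeric()), "no rows")
})

test_that("affordability bands split at 0, T and (1 + tolerance) T", {
  th <- affordability_threshold(302172, override_value = 453822,
                                tolerance_fraction = 0.10)
  t_eff <- effective_threshold(th)
  expect_identical(assess_affordability(4568, th), "affordable")
  expect_identical(assess_affordability(-7137, th), "saving")
  expect_identical(assess_affordability(0, th), "saving")
  expect_identical(assess_affordability(t_eff, th), "affordable")
  expect_identical(assess_affordability(t_eff * 1.05, th), "borderline")
  expect_identical(assess_affordability(t_eff * 1.10, th), "borderline")
  expect_identical(assess_affordability(t_eff * 1.2, th), "unacceptable")
})

test_that("identity scenarios produce exactly zero impact", {
  s <- tiny_spec(s_proj = c(0.3, 0.3, 0.3), baseline_new_share = 0.3)
  res <- run_budget_impact(s)
  expect_identical(res$rows$incremental, c(0, 0, 0))
  expect_identical(res$cumulative, 0)
  expect_identical(unique(res$rows$affordability), "saving")
})

test_that("equal unit costs across arms neutralise any share shift", {
  s <- tiny_spec(s_proj = c(0.1, 0.9), cost_new = 120000, cost_old = 120000)
  res <- run_budget_impact(s)
  expect_equal(res$rows$incremental, c(0, 0), tolerance = 1e-9)
})

test_that("yearly impact is linear in the intervention share", {
  grid <- seq(0, 1, by = 0.1)
  c_new <- 111111
  c_old <- 173000
  n <- 137
  inc <- vapply(grid, function(s) {
    run_budget_impact(tiny_spec(s_proj = s, cost_new = c_new,
                                cost_old = c_old,
                                base_count = n))$rows$incremental
  }, numeric(1))
  # brute-force recomputation from first principles
  expect_equal(inc, n * grid * (c_new - c_old), tolerance = 1e-9)
  slopes <- diff(inc) / diff(grid)
  expect_lt(diff(range(slopes)) / abs(mean(slopes)), 1e-9)
})

test_that("cheaper intervention means cumulative impact falls as uptake rises", {
  set.seed(41)
  for (i in 1:10) {
    h <- sample(3:6, 1)
    s <- sort(runif(h, 0.05, 0.8))
    c_new <- runif(1, 5e4, 1e5)
    c_old <- c_new + runif(1, 1e3, 1e5)
    base <- run_budget_impact(tiny_spec(s, c_new, c_old))$cumulative
    bump <- pmin(s + runif(h, 0, 0.15), 1)
    bumped <- run_budget_impact(tiny_spec(bump, c_new, c_old))$cumulative
    expect_lte(bumped, base)
  }
})

test_that("recomputed fixture cells agree with the printed tables", {
  rep1 <- fixture_consistency(scenario1_fixture(), printed_table_cells(1))
  rep2 <- fixture_consistency(scenario2_fixture(), printed_table_cells(2))
  expect_true(rep1$pass)
  expect_true(rep2$pass)
  expect_lte(rep1$max_rel_dev, 1e-4)
  expect_lte(rep2$max_rel_dev, 1e-4)
  expect_true(rep1$per_patient_exact)
  expect_true(rep2$per_patient_exact)
})

test_that("result tables and CSV export mirror the published layout", {
  res <- run_budget_impact(scenario1_fixture())
  tab <- result_table(res)
  expect_identical(nrow(tab), 5L)
  expect_true(all(c("year", "n", "cost_abma", "cost_cdk_mix",
                    "projected_total", "baseline_total", "incremental",
                    "per_patient", "affordability") %in% names(tab)))
  expect_identical(unique(tab$affordability), "saving")

  path <- withr::local_tempfile(fileext = ".csv")
  write_result_csv(res, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 6L)
  # re-summing the yearly rows reproduces the cumulative line
  expect_identical(sum(back$incremental[1:5]), back$incremental[6])
})
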