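# Small two-arm model builder used across tests: one intervention arm "new"
# with projected uptake s_proj, one comparator "old" carrying the baseline.
tiny_spec <- function(s_proj = c(0.2, 0.4),
                      cost_new = 100000, cost_old = 150000,
                      base_count = 100, base_year = 2024,
                      incidence = 0.05, dropout = 0,
                      rounding = "nearest_half_away_from_zero",
                      baseline_new_share = 0) {
  horizon <- length(s_proj)
  years <- seq.int(base_year, length.out = horizon)
  cost_new <- rep_len(cost_new, horizon)
  cost_old <- rep_len(cost_old, horizon)
  model_spec(
    population = population_model(base_year, base_count, incidence, dropout,
                                  horizon, rounding_policy = rounding),
    arms = list(treatment_arm("new", role = "intervention"),
                treatment_arm("old", role = "comparator_mix")),
    unit_costs = unit_cost_table(tibble::tibble(
      arm_id = rep(c("new", "old"), each = horizon),
      year = rep(years, 2),
      cost_qar = c(cost_new, cost_old))),
    baseline = market_share_trajectory("baseline", tibble::tibble(
      year = rep(years, 2),
      arm_id = rep(c("new", "old"), each = horizon),
      share = c(rep(baseline_new_share, horizon),
                rep(1 - baseline_new_share, horizon)))),
    projected = market_share_trajectory("projected", tibble::tibble(
      year = rep(years, 2),
      arm_id = rep(c("new", "old"), each = horizon),
      share = c(s_proj, 1 - s_proj))),
    threshold = affordability_threshold(302172, override_value = 453822),
    name = "tiny test model")
}

# printed yearly columns of the two shipped scenario tables, deduplicated to
# one row per year
printed_year_rows <- function(scenario) {
  cells <- printed_table_cells(scenario)
  dplyr::distinct(cells, year, n, baseline_total, scenario_total,
                  incremental, per_patient)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1)), tol)
}
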