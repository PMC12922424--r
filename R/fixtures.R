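# Printed cells of the published five-year CDK4/6-inhibitor budget impact
# tables for Qatar (QAR). One row per (year, arm); year-level columns are
# repeated on each arm row. These cells are the source from which the fixture
# unit costs are back-derived.

scenario1_printed <- function() {
  tibble::tibble(
    scenario = "scenario1",
    year = rep(2024:2028, each = 2),
    n = rep(c(173, 182, 191, 201, 211), each = 2),
    baseline_total = rep(c(31124763, 32681001, 34363178, 36081336, 37961416),
                         each = 2),
    scenario_total = rep(c(29890060, 30736344, 31636839, 32503017, 33443687),
                         each = 2),
    incremental = rep(c(-1234703, -1944658, -2726339, -3578320, -4517729),
                      each = 2),
    per_patient = rep(c(-7137, -10685, -14274, -17803, -21411), each = 2),
    arm_id = rep(c("abma", "cdk_mix"), times = 5),
    role = rep(c("intervention", "comparator_mix"), times = 5),
    share = c(0.20, 0.80, 0.30, 0.70, 0.40, 0.60, 0.50, 0.50, 0.60, 0.40),
    arm_cost = c(4990249, 24899810, 7859643, 22876701, 11018932, 20617907,
                 14462348, 18040668, 18259121, 15184566))
}

scenario2_printed <- function() {
  tibble::tibble(
    scenario = "scenario2",
    year = rep(2024:2028, each = 2),
    n = rep(c(173, 182, 191, 201, 211), each = 2),
    baseline_total = rep(c(27102920, 28458066, 29922877, 31419021, 33056163),
                         each = 2),
    scenario_total = rep(c(27893201, 29564460, 31377055, 33403974, 35626479),
                         each = 2),
    incremental = rep(c(790281, 1106393, 1454178, 1984953, 2570316),
                      each = 2),
    per_patient = rep(c(4568, 6079, 7613, 9875, 12182), each = 2),
    arm_id = rep(c("abma_ribo", "plbo_mix"), times = 5),
    role = rep(c("intervention", "comparator_mix"), times = 5),
    share = c(0.30, 0.70, 0.40, 0.60, 0.50, 0.50, 0.65, 0.35, 0.80, 0.20),
    arm_cost = c(8921157, 18972044, 12489620, 17074840, 16415617, 14961439,
                 22407317, 10996657, 29015247, 6611233))
}

#' Printed budget-impact table cells
#'
#' The year-by-arm cells of the two published scenario tables (QAR):
#' scenario 1 is abemaciclib replacing the palbociclib/ribociclib/standard
#' care mix up to 60% uptake; scenario 2 is abemaciclib plus ribociclib
#' jointly reaching 80%. Returned long, one row per (year, arm), with the
#' year-level totals repeated on each arm row. The same cells ship as CSV
#' under `system.file("extdata", package = "bimpact")`.
#'
#' @param scenario 1 or 2.
#' @return A tibble of printed cells.
#' @seealso [derive_unit_costs()], [fixture_consistency()]
#' @export
printed_table_cells <- function(scenario) {
  switch(as.character(scenario),
         "1" = scenario1_printed(),
         "2" = scenario2_printed(),
         abort_bia("scenario must be 1 or 2"))
}

#' Back-derive per-patient unit costs from printed table cells
#'
#' Inverts the engine's arithmetic `arm_cost = N * share * c` to recover the
#' per-arm per-year unit costs behind a printed table: `c = arm_cost /
#' (share * N)`, and for the baseline basket `c = baseline_total / N`.
#'
#' Published cells are rounded to integer QAR, which leaves them internally
#' inconsistent by +/-1 QAR (arm cells need not sum exactly to the printed
#' scenario total). With `reconcile = "totals"` (the fixture default) the
#' comparator-mix arm's cost is derived from the residual
#' `scenario_total - sum(other arm cells)` instead of from its own cell, so
#' that recomputed scenario totals and per-patient integers reproduce the
#' printed ones exactly; `"none"` applies the plain per-cell division.
#'
#' @param rows A printed-cells tibble as from [printed_table_cells()].
#' @param baseline_arm_id Arm id under which to store the derived baseline
#'   basket cost (default `"std_care"`).
#' @param reconcile `"totals"` or `"none"`.
#' @return A [unit_cost_table()] covering every table arm plus the baseline
#'   basket arm.
#' @export
#' @examples
#' derive_unit_costs(printed_table_cells(1), reconcile = "none")
derive_unit_costs <- function(rows, baseline_arm_id = "std_care",
                              reconcile = c("totals", "none")) {
  reconcile <- match.arg(reconcile)
  bad <- rows$share == 0 & rows$arm_cost != 0
  if (any(bad)) {
    abort_bia(paste0("zero share with nonzero printed cost in year ",
                     paste(rows$year[bad], collapse = ", ")))
  }
  per_arm <- purrr::map_dfr(split(rows, rows$year), function(d) {
    cost <- d$arm_cost / (d$share * d$n)
    if (reconcile == "totals") {
      resid <- which(d$role == "comparator_mix")
      if (length(resid) > 1) {
        abort_bia("'totals' reconciliation needs at most one comparator_mix
                   arm per year")
      }
      if (length(resid) == 1) {
        cost[resid] <- (d$scenario_total[resid] - sum(d$arm_cost[-resid])) /
          (d$share[resid] * d$n[resid])
      }
    }
    tibble::tibble(arm_id = d$arm_id, year = d$year, cost_qar = cost)
  })
  base <- dplyr::distinct(rows, .data$year, .data$n, .data$baseline_total)
  unit_cost_table(dplyr::bind_rows(
    per_arm,
    tibble::tibble(arm_id = baseline_arm_id, year = base$year,
                   cost_qar = base$baseline_total / base$n)))
}

fixture_population <- function() {
  population_model(base_year = 2024, base_count = 173,
                   incidence_rate = 0.10, dropout_rate = 0.05,
                   horizon_years = 5)
}

fixture_threshold <- function() {
  # the published analysis prints an adopted threshold of QAR 453,822, which
  # the formula 1.5 x 302,172 does not exactly reproduce; the printed value
  # wins via override_value
  affordability_threshold(gdp_per_capita = 302172, multiplier = 1.5,
                          override_value = 453822, tolerance_fraction = 0.10)
}

build_fixture <- function(cells, int_label, comp_label, base_label, name,
                          uptake_override = NULL) {
  ids <- unique(cells$arm_id)
  roles <- cells$role[match(ids, cells$arm_id)]
  int_id <- ids[roles == "intervention"]
  comp_id <- ids[roles == "comparator_mix"]
  years <- unique(cells$year)
  int_share <- cells$share[cells$arm_id == int_id]
  if (!is.null(uptake_override)) int_share <- uptake_override
  arms <- list(
    treatment_arm(int_id, int_label, "intervention"),
    treatment_arm(comp_id, comp_label, "comparator_mix"),
    treatment_arm("std_care", base_label, "comparator_mix"))
  projected <- market_share_trajectory("projected", tibble::tibble(
    year = rep(years, times = 2),
    arm_id = rep(c(int_id, comp_id), each = length(years)),
    share = c(int_share, 1 - int_share)))
  baseline <- market_share_trajectory("baseline (current mix)",
    tibble::tibble(year = years, arm_id = "std_care", share = 1))
  model_spec(population = fixture_population(), arms = arms,
             unit_costs = derive_unit_costs(cells),
             baseline = baseline, projected = projected,
             threshold = fixture_threshold(),
             currency = currency_settings(), name = name)
}

#' Scenario-1 fixture: abemaciclib displacing the CDK4/6 mix
#'
#' Ready-to-run model of the published first scenario: 173 patients in 2024
#' growing at 5%/year net, abemaciclib uptake rising over
#' palbociclib/ribociclib/standard care, unit costs back-derived from the
#' printed table ([derive_unit_costs()]), threshold QAR 453,822.
#'
#' @param uptake `"table"` (default) uses the published table's shares
#'   20/30/40/50/60%; `"methods"` uses the narrative trajectory
#'   10/20/35/50/60% described alongside the model, which conflicts with the
#'   table and does not reproduce its cells.
#' @return A `bia_model_spec`.
#' @export
#' @examples
#' run_budget_impact(scenario1_fixture())
scenario1_fixture <- function(uptake = c("table", "methods")) {
  uptake <- match.arg(uptake)
  build_fixture(
    scenario1_printed(),
    int_label = "ABMA", comp_label = "PLBO/RIBO/Other Tx",
    base_label = "Current treatment mix",
    name = "CDK4/6 BIA scenario 1 (ABMA to 60%)",
    uptake_override = if (uptake == "methods")
      c(0.10, 0.20, 0.35, 0.50, 0.60))
}

#' Scenario-2 fixture: abemaciclib and ribociclib jointly to 80%
#'
#' Ready-to-run model of the published second scenario: abemaciclib plus
#' ribociclib taken as one intervention basket expanding to 80% of the
#' market over palbociclib/other treatment.
#'
#' @param uptake `"table"` (default) uses the published table's shares
#'   30/40/50/65/80%; `"methods"` uses the narrative 40/50/60/70/80%
#'   trajectory, which conflicts with the table.
#' @return A `bia_model_spec`.
#' @export
#' @examples
#' run_budget_impact(scenario2_fixture())
scenario2_fixture <- function(uptake = c("table", "methods")) {
  uptake <- match.arg(uptake)
  build_fixture(
    scenario2_printed(),
    int_label = "ABMA & RIBO", comp_label = "PLBO/Other Tx",
    base_label = "Current treatment mix",
    name = "CDK4/6 BIA scenario 2 (ABMA & RIBO to 80%)",
    uptake_override = if (uptake == "methods")
      c(0.40, 0.50, 0.60, 0.70, 0.80))
}

#' Check a fixture against its printed table cells
#'
#' Re-runs the budget engine on `spec` and compares every recomputed cell
#' (baseline total, arm costs, scenario total, incremental, per-patient)
#' with the printed value.
#'
#' @param spec A fixture `bia_model_spec`.
#' @param rows The printed cells the fixture was derived from.
#' @param max_rel_tol Pass threshold on the maximum relative deviation
#'   (default 1e-4).
#' @return A `bia_fixture_report`: list with `cells` (tibble: `year`,
#'   `cell`, `printed`, `recomputed`, `abs_dev`, `rel_dev`),
#'   `max_rel_dev`, `per_patient_exact`, and `pass`.
#' @export
fixture_consistency <- function(spec, rows, max_rel_tol = 1e-4) {
  res <- run_budget_impact(spec)
  cells <- purrr::map_dfr(seq_len(nrow(res$rows)), function(i) {
    yr <- res$rows$year[i]
    pr <- rows[rows$year == yr, , drop = FALSE]
    arm_cells <- purrr::map_dfr(seq_len(nrow(pr)), function(j) {
      tibble::tibble(cell = paste0("arm_cost:", pr$arm_id[j]),
                     printed = pr$arm_cost[j],
                     recomputed = res$rows$arm_costs[[i]][[pr$arm_id[j]]])
    })
    dplyr::bind_rows(
      tibble::tibble(cell = c("baseline_total", "scenario_total",
                              "incremental", "per_patient"),
                     printed = c(pr$baseline_total[1],
                                 pr$scenario_total[1],
                                 pr$incremental[1],
                                 pr$per_patient[1]),
                     recomputed = c(res$rows$baseline_total[i],
                                    res$rows$projected_total[i],
                                    res$rows$incremental[i],
                                    res$rows$per_patient[i])),
      arm_cells) |>
      dplyr::mutate(year = yr, .before = 1)
  })
  cells$abs_dev <- abs(cells$recomputed - cells$printed)
  cells$rel_dev <- cells$abs_dev / pmax(abs(cells$printed), 1)
  pp <- cells[cells$cell == "per_patient", , drop = FALSE]
  report <- list(cells = cells,
                 max_rel_dev = max(cells$rel_dev),
                 per_patient_exact = all(pp$recomputed == pp$printed),
                 pass = max(cells$rel_dev) <= max_rel_tol)
  structure(report, class = "bia_fixture_report")
}

#' @export
print.bia_fixture_report <- function(x, ...) {
  cat("<bia_fixture_report> max relative deviation ",
      format(x$max_rel_dev, digits = 3),
      if (x$pass) " (PASS)" else " (FAIL)",
      "; per-patient cells ",
      if (x$per_patient_exact) "exact" else "NOT exact", "\n", sep = "")
  worst <- x$cells[order(-x$cells$rel_dev), ][1:min(3, nrow(x$cells)), ]
  print(worst)
  invisible(x)
}

#' Generate a synthetic model spec with analytically known results
#'
#' Draws a random but reproducible two-scenario budget impact model: a base
#' cohort with compounding net growth, one intervention arm and
#' `n_arms - 1` comparator arms with positive per-patient costs that drift
#' by year, a monotone intervention uptake trajectory, and a baseline made
#' of the comparator arms at fixed weights. The expected result is computed
#' in closed form, independently of the budget engine:
#' `incremental(t) = N(t) * s(t) * (c_int(t) - c_blend(t))`.
#'
#' @param seed Integer seed; the same seed always yields the same spec and
#'   ground truth.
#' @param n_arms Total arms including the intervention (>= 2, default 2).
#' @param horizon Horizon in years (default 5).
#' @param cost_range Range per-patient annual base costs are drawn from
#'   (QAR, default 50,000--250,000).
#' @param growth_range Range the net growth rate is drawn from (default
#'   0--0.10).
#' @return A list with `spec` (a `bia_model_spec`) and `truth` (list with
#'   `rows`: tibble of `year`, `n`, `projected_total`, `baseline_total`,
#'   `incremental`; and `cumulative`).
#' @export
#' @examples
#' gt <- generate_synthetic_spec(seed = 1)
#' all.equal(run_budget_impact(gt$spec)$cumulative, gt$truth$cumulative)
generate_synthetic_spec <- function(seed, n_arms = 2, horizon = 5,
                                    cost_range = c(5e4, 2.5e5),
                                    growth_range = c(0, 0.10)) {
  stopifnot(n_arms >= 2, horizon >= 1, cost_range[1] > 0,
            diff(cost_range) >= 0, growth_range[1] >= -0.5)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  base_year <- 2024L
  years <- seq.int(base_year, length.out = horizon)
  base_count <- sample(50:500, 1)
  g <- stats::runif(1, growth_range[1], growth_range[2])
  dropout <- stats::runif(1, 0, min(0.05, 1 - max(g, 0)))
  incidence <- g + dropout

  int_id <- "new_tx"
  comp_ids <- paste0("comp", seq_len(n_arms - 1))
  ids <- c(int_id, comp_ids)

  # per-arm base cost with up to +/-3%/year multiplicative drift
  costs <- purrr::map_dfr(ids, function(a) {
    base_cost <- stats::runif(1, cost_range[1], cost_range[2])
    drift <- cumprod(c(1, 1 + stats::runif(horizon - 1, -0.03, 0.03)))
    tibble::tibble(arm_id = a, year = years, cost_qar = base_cost * drift)
  })

  # monotone nondecreasing intervention uptake, comparators at fixed weights
  s <- sort(stats::runif(horizon, 0.05, 0.95))
  w <- stats::runif(n_arms - 1)
  w <- w / sum(w)

  projected <- market_share_trajectory("projected", dplyr::bind_rows(
    tibble::tibble(year = years, arm_id = int_id, share = s),
    purrr::map_dfr(seq_along(comp_ids), function(j)
      tibble::tibble(year = years, arm_id = comp_ids[j],
                     share = (1 - s) * w[j]))))
  baseline <- market_share_trajectory("baseline", purrr::map_dfr(
    seq_along(comp_ids), function(j)
      tibble::tibble(year = years, arm_id = comp_ids[j], share = w[j])))

  spec <- model_spec(
    population = population_model(base_year, base_count, incidence, dropout,
                                  horizon),
    arms = c(list(treatment_arm(int_id, "new treatment", "intervention")),
             lapply(comp_ids, function(a)
               treatment_arm(a, paste("comparator", a), "comparator_mix"))),
    unit_costs = unit_cost_table(costs),
    baseline = baseline, projected = projected,
    threshold = affordability_threshold(302172),
    name = paste0("synthetic model (seed ", seed, ")"))

  # closed-form ground truth, independent of the engine's evaluation loop
  n <- numeric(horizon)
  n[1] <- base_count
  if (horizon > 1) for (i in 2:horizon) n[i] <- round_half_away(n[i - 1] * (1 + g))
  cost_of <- function(a, yr) costs$cost_qar[costs$arm_id == a &
                                              costs$year == yr]
  truth_rows <- purrr::map_dfr(seq_along(years), function(i) {
    yr <- years[i]
    c_int <- cost_of(int_id, yr)
    c_blend <- sum(w * vapply(comp_ids, cost_of, numeric(1), yr = yr))
    n_i <- n[i]
    tibble::tibble(year = yr, n = n_i,
                   projected_total = n_i * (s[i] * c_int +
                                              (1 - s[i]) * c_blend),
                   baseline_total = n_i * c_blend,
                   incremental = n_i * s[i] * (c_int - c_blend))
  })
  list(spec = spec,
       truth = list(rows = truth_rows,
                    cumulative = sum(truth_rows$incremental)))
}
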