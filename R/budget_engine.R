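#' Total annual cost of one scenario-year
#'
#' Each arm's cost is `N * share * unit_cost`. The year-level patient count N
#' is an integer, but arm-level populations stay fractional (`share * N`):
#' budget totals are money, not headcounts, and a 20% share of 173 patients
#' costs exactly 34.6 patient-years of treatment.
#'
#' @param n Integer patient count for the year.
#' @param shares Named numeric vector of arm shares summing to 1.
#' @param costs Named numeric vector of per-patient annual costs (QAR)
#'   covering every arm with positive share.
#' @return A list with `arm_costs` (named QAR vector) and `total` (QAR).
#' @export
scenario_annual_cost <- function(n, shares, costs) {
  if (abs(sum(shares) - 1) > 1e-9) {
    abort_bia(paste0("shares must sum to 1, got ", sum(shares)))
  }
  pos <- names(shares)[shares > 0]
  missing <- setdiff(pos, names(costs))
  if (length(missing)) {
    abort_bia(paste0("no unit cost for positive-share arm(s): ",
                     paste(missing, collapse = ", ")))
  }
  arm_costs <- vapply(names(shares), function(a) {
    if (shares[[a]] > 0) n * shares[[a]] * costs[[a]] else 0
  }, numeric(1))
  list(arm_costs = arm_costs, total = sum(arm_costs))
}

trajectory_shares <- function(trajectory, year) {
  d <- trajectory$shares[trajectory$shares$year == year, , drop = FALSE]
  if (nrow(d) == 0) {
    abort_bia(paste0("trajectory '", trajectory$scenario_name,
                     "' has no shares for year ", year))
  }
  stats::setNames(d$share, d$arm_id)
}

year_costs <- function(spec, year) {
  d <- spec$unit_costs[spec$unit_costs$year == year, , drop = FALSE]
  stats::setNames(d$cost_qar, d$arm_id)
}

#' Baseline ("current scenario") total cost for one year
#'
#' Evaluates [scenario_annual_cost()] under the spec's baseline trajectory.
#'
#' @param n Integer patient count for the year.
#' @param year Calendar year.
#' @param spec A `bia_model_spec`.
#' @return Total baseline cost in QAR.
#' @export
baseline_annual_cost <- function(n, year, spec) {
  scenario_annual_cost(n, trajectory_shares(spec$baseline, year),
                       year_costs(spec, year))$total
}

#' Incremental budget impact of one year
#'
#' Projected-scenario total minus baseline total; negative values are
#' savings, matching the sign convention of published budget-impact tables.
#'
#' @param projected_total,baseline_total Yearly totals in QAR.
#' @return Incremental impact in QAR.
#' @export
#' @examples
#' incremental_impact(29890060, 31124763)  # -1234703
incremental_impact <- function(projected_total, baseline_total) {
  projected_total - baseline_total
}

#' Per-patient incremental impact
#'
#' @param incremental Yearly incremental impact in QAR.
#' @param n Patients in that year (> 0).
#' @return QAR per patient, rounded to the nearest integer (ties away from
#'   zero).
#' @export
#' @examples
#' per_patient_impact(-1234703, 173)  # -7137
per_patient_impact <- function(incremental, n) {
  if (!is.finite(n) || n <= 0) abort_bia("n must be > 0")
  round_half_away(incremental / n)
}

#' Cumulative budget impact
#'
#' @param rows A result row tibble with an `incremental` column, or a bare
#'   numeric vector of yearly incrementals.
#' @return The exact sum of yearly incremental impacts, in QAR.
#' @export
cumulative_impact <- function(rows) {
  inc <- if (is.data.frame(rows)) rows$incremental else rows
  if (length(inc) == 0) abort_bia("no rows to accumulate")
  sum(inc)
}

#' Classify a per-patient impact against the affordability threshold
#'
#' With effective threshold T and tolerance band f: `saving` if the impact is
#' <= 0; `affordable` if 0 < impact <= T; `borderline` if T < impact <=
#' (1 + f) T; `unacceptable` above that.
#'
#' @param per_patient Per-patient yearly incremental impact (QAR).
#' @param threshold An [affordability_threshold()].
#' @return One of `"saving"`, `"affordable"`, `"borderline"`,
#'   `"unacceptable"` (character, vectorised over `per_patient`).
#' @export
#' @examples
#' assess_affordability(4568, affordability_threshold(302172,
#'                      override_value = 453822))  # "affordable"
assess_affordability <- function(per_patient, threshold) {
  t_eff <- effective_threshold(threshold)
  if (!is.finite(t_eff) || t_eff <= 0) {
    abort_bia("effective threshold must be > 0")
  }
  upper <- (1 + threshold$tolerance_fraction) * t_eff
  ifelse(per_patient <= 0, "saving",
         ifelse(per_patient <= t_eff, "affordable",
                ifelse(per_patient <= upper, "borderline", "unacceptable")))
}

#' Run a full budget impact analysis
#'
#' Projects the population, evaluates the baseline and projected scenarios
#' for every horizon year, and derives incremental, per-patient and
#' cumulative impacts plus affordability categories. No discounting or
#' inflation adjustment is applied: budget impact is reported in nominal
#' per-year money, and any price drift belongs in the per-year unit costs.
#'
#' @param spec A validated `bia_model_spec`.
#' @return A `bia_result`: list with `rows` (tibble: `year`, `n`,
#'   `arm_costs` list-column of named QAR vectors, `projected_total`,
#'   `baseline_total`, `incremental`, `per_patient`, `affordability`),
#'   `cumulative` (QAR), `cumulative_usd`, `spec_digest`, and `name`.
#' @seealso [result_table()], [write_result_csv()], [one_way_analysis()]
#' @export
#' @examples
#' res <- run_budget_impact(scenario1_fixture())
#' res$cumulative  # about -14.0 million QAR over five years
run_budget_impact <- function(spec) {
  proj <- project_population(spec$population)
  rows <- purrr::map_dfr(seq_len(nrow(proj$counts)), function(i) {
    yr <- proj$counts$year[i]
    n <- proj$counts$n[i]
    costs <- year_costs(spec, yr)
    p <- scenario_annual_cost(n, trajectory_shares(spec$projected, yr), costs)
    b <- scenario_annual_cost(n, trajectory_shares(spec$baseline, yr), costs)
    inc <- incremental_impact(p$total, b$total)
    tibble::tibble(
      year = yr, n = n, arm_costs = list(p$arm_costs),
      projected_total = p$total, baseline_total = b$total,
      incremental = inc,
      per_patient = per_patient_impact(inc, n),
      affordability = assess_affordability(per_patient_impact(inc, n),
                                           spec$threshold))
  })
  cum <- cumulative_impact(rows)
  structure(list(rows = rows, cumulative = cum,
                 cumulative_usd = convert_currency(cum, spec$currency),
                 spec_digest = spec_digest(spec), name = spec$name),
            class = "bia_result")
}

#' @export
print.bia_result <- function(x, ...) {
  cat("<bia_result> ", x$name, " [spec ", x$spec_digest, "]\n", sep = "")
  print(result_table(x))
  cat("cumulative budget impact: QAR",
      format(round_half_away(x$cumulative), big.mark = ","),
      sprintf("(USD %s)\n", format(x$cumulative_usd, big.mark = ",")))
  invisible(x)
}

#' Flatten a budget impact result to a wide table
#'
#' One row per year with one `cost_<arm_id>` column per arm, mirroring the
#' layout of published budget-impact tables (year, N, arm costs, scenario
#' totals, incremental, per-patient, affordability). All QAR amounts are
#' rounded to integer QAR.
#'
#' @param result A `bia_result`.
#' @return A tibble.
#' @export
result_table <- function(result) {
  arm_wide <- purrr::map_dfr(result$rows$arm_costs, function(ac)
    tibble::as_tibble(as.list(round_half_away(ac))))
  names(arm_wide) <- paste0("cost_", names(arm_wide))
  dplyr::bind_cols(
    result$rows[c("year", "n")], arm_wide,
    tibble::tibble(
      projected_total = round_half_away(result$rows$projected_total),
      baseline_total = round_half_away(result$rows$baseline_total),
      incremental = round_half_away(result$rows$incremental),
      per_patient = result$rows$per_patient,
      affordability = result$rows$affordability))
}

#' Write a budget impact result as CSV
#'
#' Writes the [result_table()] rows plus a final `cumulative` line whose
#' `incremental` column is the cumulative impact.
#'
#' @param result A `bia_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  tab <- result_table(result)
  cum_row <- tab[1, ]
  cum_row[1, ] <- NA
  cum_row$year <- NA_integer_
  cum_row$incremental <- round_half_away(result$cumulative)
  cum_row$affordability <- "cumulative"
  utils::write.csv(dplyr::bind_rows(tab, cum_row), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Export a budget impact result as JSON
#'
#' @param result A `bia_result`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
result_json <- function(result, path = NULL) {
  payload <- list(name = result$name, spec_digest = result$spec_digest,
                  rows = result_table(result),
                  cumulative = round_half_away(result$cumulative),
                  cumulative_usd = result$cumulative_usd)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
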