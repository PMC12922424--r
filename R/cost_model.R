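#' Per-patient annual cost from bottom-up components
#'
#' Sums drug acquisition (`drug_cost_per_cycle * cycles_per_year`) with the
#' annual laboratory, imaging, cardiac-monitoring, outpatient-visit and
#' hospitalisation components of one patient-year of treatment.
#'
#' @param breakdown A [cost_breakdown()].
#' @return QAR per patient per year.
#' @export
#' @examples
#' annual_cost_from_components(cost_breakdown(
#'   drug_cost_per_cycle = 10000, cycles_per_year = 13,
#'   lab_cost_per_year = 2000, imaging_cost_per_year = 5000,
#'   cardiac_monitoring_per_year = 500,
#'   outpatient_visit_cost_per_year = 3000,
#'   hospitalisation_cost_per_year = 1000))  # 141500
annual_cost_from_components <- function(breakdown) {
  if (!inherits(breakdown, "bia_cost_breakdown")) {
    breakdown <- do.call(cost_breakdown, as.list(breakdown))
  }
  breakdown$drug_cost_per_cycle * breakdown$cycles_per_year +
    breakdown$lab_cost_per_year + breakdown$imaging_cost_per_year +
    breakdown$cardiac_monitoring_per_year +
    breakdown$outpatient_visit_cost_per_year +
    breakdown$hospitalisation_cost_per_year
}

#' Blended per-patient cost over an arm mixture
#'
#' Share-weighted mean unit cost, used to price a comparator basket (for
#' example a palbociclib/ribociclib/standard-care mix) at one rate.
#'
#' @param weights Named numeric vector of arm weights summing to 1.
#' @param costs Named numeric vector of per-patient annual costs covering
#'   every weighted arm.
#' @return Blended QAR per patient per year.
#' @export
#' @examples
#' blended_unit_cost(c(a = 0.5, b = 0.5), c(a = 100, b = 200))  # 150
blended_unit_cost <- function(weights, costs) {
  if (abs(sum(weights) - 1) > 1e-9) {
    abort_bia(paste0("weights must sum to 1, got ", sum(weights)))
  }
  missing <- setdiff(names(weights), names(costs))
  if (length(missing)) {
    abort_bia(paste0("no cost supplied for arm(s): ",
                     paste(missing, collapse = ", ")))
  }
  sum(weights * costs[names(weights)])
}

#' Look up a per-patient annual cost
#'
#' @param table A [unit_cost_table()].
#' @param arm_id Arm identifier.
#' @param year Calendar year.
#' @return QAR per patient per year.
#' @export
unit_cost <- function(table, arm_id, year) {
  hit <- table$arm_id == arm_id & table$year == year
  if (!any(hit)) {
    abort_bia(paste0("no unit cost for arm '", arm_id, "' in year ", year))
  }
  table$cost_qar[which(hit)[1]]
}

#' Read a unit-cost table from CSV
#'
#' @param path CSV with columns `arm_id`, `year`, `cost_qar`.
#' @return A [unit_cost_table()].
#' @export
read_unit_costs <- function(path) {
  unit_cost_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a unit-cost table to CSV
#'
#' Costs are written with 2 decimal places.
#'
#' @param table A [unit_cost_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_unit_costs <- function(table, path) {
  out <- as.data.frame(table)
  out$cost_qar <- sprintf("%.2f", out$cost_qar)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
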