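#' Define a one-way sensitivity axis
#'
#' An axis names one model parameter to perturb and the levels to perturb it
#' by. Two targets are supported:
#'
#' * `arm_unit_cost` with `perturbation_kind = "multiplicative_factor"`:
#'   each level `f` multiplies the selected arms' per-patient costs by
#'   `(1 + f)` within `scenario_scope`.
#' * `uptake_trajectory` with `perturbation_kind =
#'   "additive_percentage_points"`: each level (a fraction, e.g. `0.10` for
#'   +10 percentage points) is added to the intervention arm's share in every
#'   year of the projected trajectory, with the comparator arms absorbing the
#'   complement in proportion to their shares.
#'
#' @param axis_id Short identifier for reports.
#' @param target `"arm_unit_cost"` or `"uptake_trajectory"`.
#' @param levels Ordered numeric vector of perturbation magnitudes (nonempty).
#' @param arm_selector Character vector of arm ids (cost axes only; default
#'   all arms).
#' @param scenario_scope `"both"` (default), `"projected_only"` or
#'   `"baseline_only"` — which scenario's costs a cost axis touches.
#' @param perturbation_kind Defaults to the kind matching `target`.
#' @return A `bia_axis` list.
#' @seealso [perturb_spec()], [one_way_analysis()]
#' @export
sensitivity_axis <- function(axis_id,
                             target = c("arm_unit_cost", "uptake_trajectory"),
                             levels,
                             arm_selector = NULL,
                             scenario_scope = c("both", "projected_only",
                                                "baseline_only"),
                             perturbation_kind = NULL) {
  target <- match.arg(target)
  scenario_scope <- match.arg(scenario_scope)
  default_kind <- if (target == "arm_unit_cost") "multiplicative_factor"
                  else "additive_percentage_points"
  perturbation_kind <- perturbation_kind %||% default_kind
  if (!perturbation_kind %in% c("multiplicative_factor",
                                "additive_percentage_points")) {
    abort_bia("unknown perturbation_kind")
  }
  if (length(levels) == 0 || !all(is.finite(levels))) {
    abort_bia(paste0("axis '", axis_id, "' needs a nonempty finite levels",
                     " vector"))
  }
  structure(list(axis_id = axis_id, target = target,
                 arm_selector = arm_selector,
                 scenario_scope = scenario_scope,
                 perturbation_kind = perturbation_kind,
                 levels = as.numeric(levels)),
            class = "bia_axis")
}

arms_in_trajectory <- function(trajectory) {
  unique(trajectory$shares$arm_id[trajectory$shares$share > 0])
}

perturb_costs <- function(spec, axis, level) {
  sel <- axis$arm_selector %||% arm_ids(spec)
  unknown <- setdiff(sel, arm_ids(spec))
  if (length(unknown)) {
    abort_bia(paste0("axis '", axis$axis_id, "' selects undefined arm(s): ",
                     paste(unknown, collapse = ", ")))
  }
  if (axis$scenario_scope != "both") {
    scoped <- if (axis$scenario_scope == "projected_only") spec$projected
              else spec$baseline
    other <- if (axis$scenario_scope == "projected_only") spec$baseline
             else spec$projected
    sel <- intersect(sel, arms_in_trajectory(scoped))
    shared <- intersect(sel, arms_in_trajectory(other))
    if (length(shared)) {
      abort_bia(paste0(
        "axis '", axis$axis_id, "': arm(s) ", paste(shared, collapse = ", "),
        " appear in both scenarios; a one-sided scenario_scope is ",
        "ill-defined because unit costs are shared per (arm, year)"))
    }
  }
  hit <- spec$unit_costs$arm_id %in% sel
  spec$unit_costs$cost_qar[hit] <- spec$unit_costs$cost_qar[hit] * (1 + level)
  spec
}

perturb_uptake <- function(spec, axis, level) {
  ids <- arm_ids(spec)
  roles <- vapply(spec$arms, `[[`, character(1), "role")
  int_arm <- ids[roles == "intervention"]
  if (length(int_arm) != 1) {
    abort_bia("uptake perturbation needs exactly one intervention arm")
  }
  sh <- spec$projected$shares
  for (yr in unique(sh$year)) {
    in_year <- sh$year == yr
    i_int <- which(in_year & sh$arm_id == int_arm)
    if (length(i_int) != 1) {
      abort_bia(paste0("projected trajectory lacks an intervention share in ",
                       yr))
    }
    s_new <- sh$share[i_int] + level
    if (s_new < -1e-9 || s_new > 1 + 1e-9) {
      abort_bia(paste0("axis '", axis$axis_id, "': year ", yr,
                       " intervention share ", format(s_new),
                       " falls outside [0, 1]"))
    }
    s_new <- min(max(s_new, 0), 1)
    i_comp <- which(in_year & sh$arm_id != int_arm)
    comp_old <- sh$share[i_comp]
    comp_total <- 1 - s_new
    comp_new <- if (sum(comp_old) > 0) comp_old / sum(comp_old) * comp_total
                else rep(comp_total / length(comp_old), length(comp_old))
    sh$share[i_int] <- s_new
    sh$share[i_comp] <- comp_new
  }
  spec$projected$shares <- sh
  spec
}

#' Apply one perturbation level to a model spec
#'
#' Returns a modified copy; the input spec is never mutated. A cost factor of
#' 0 or an uptake shift of 0 returns a spec equivalent to the input.
#'
#' @param spec A `bia_model_spec`.
#' @param axis A [sensitivity_axis()].
#' @param level One perturbation magnitude from the axis.
#' @return A perturbed, revalidated `bia_model_spec`.
#' @export
#' @examples
#' up <- sensitivity_axis("uptake", "uptake_trajectory", levels = 0.10)
#' perturb_spec(scenario1_fixture(), up, 0.10)
perturb_spec <- function(spec, axis, level) {
  out <- switch(axis$target,
                arm_unit_cost = perturb_costs(spec, axis, level),
                uptake_trajectory = perturb_uptake(spec, axis, level))
  v <- validate_model_spec(out)
  if (nrow(v) > 0) {
    abort_bia(paste0("axis '", axis$axis_id, "' level ", level,
                     " produced an invalid spec: ", v$message[1]))
  }
  out
}

#' One-way (deterministic) sensitivity analysis
#'
#' Re-runs the budget engine once per axis x level, one parameter perturbed
#' at a time, plus once for the unperturbed base case. Probabilistic
#' sensitivity analysis is out of scope.
#'
#' @param spec A `bia_model_spec`.
#' @param axes List of [sensitivity_axis()] objects (nonempty).
#' @return A `bia_spider`: list with `base` (the base-case `bia_result`) and
#'   `entries` (tibble: `axis_id`, `level`, `result` list-column).
#' @seealso [spider_series()]
#' @export
one_way_analysis <- function(spec, axes) {
  if (inherits(axes, "bia_axis")) axes <- list(axes)
  if (length(axes) == 0) abort_bia("at least one sensitivity axis is required")
  base <- run_budget_impact(spec)
  entries <- purrr::map_dfr(axes, function(ax) {
    purrr::map_dfr(ax$levels, function(lv) {
      tibble::tibble(axis_id = ax$axis_id, level = lv,
                     result = list(run_budget_impact(
                       perturb_spec(spec, ax, lv))))
    })
  })
  structure(list(base = base, entries = entries), class = "bia_spider")
}

#' @export
print.bia_spider <- function(x, ...) {
  cat("<bia_spider> ", nrow(x$entries), " perturbed runs over ",
      length(unique(x$entries$axis_id)), " axis/axes + base case\n", sep = "")
  print(spider_series(x))
  invisible(x)
}

#' Long-format spider-plot series
#'
#' One row per (axis, level, outcome). Levels are sorted and the base case is
#' included for every axis at level 0, so each axis traces a line through the
#' origin of the spider plot.
#'
#' @param dataset A [one_way_analysis()] result.
#' @param outcome `"cumulative"` (default) and/or `"by_year"`.
#' @return A tibble with columns `axis_id`, `level`, `year`
#'   (`"cumulative"` or the calendar year as character), `value_qar`.
#' @export
spider_series <- function(dataset, outcome = "cumulative") {
  outcome <- match.arg(outcome, c("cumulative", "by_year"),
                       several.ok = TRUE)
  if (nrow(dataset$entries) == 0) abort_bia("empty spider dataset")
  one <- function(axis_id, level, result) {
    parts <- list()
    if ("cumulative" %in% outcome) {
      parts$cum <- tibble::tibble(axis_id = axis_id, level = level,
                                  year = "cumulative",
                                  value_qar = result$cumulative)
    }
    if ("by_year" %in% outcome) {
      parts$yr <- tibble::tibble(axis_id = axis_id, level = level,
                                 year = as.character(result$rows$year),
                                 value_qar = result$rows$incremental)
    }
    dplyr::bind_rows(parts)
  }
  rows <- purrr::pmap_dfr(dataset$entries, one)
  base_rows <- purrr::map_dfr(unique(dataset$entries$axis_id), function(ax) {
    has_zero <- any(dataset$entries$axis_id == ax &
                      abs(dataset$entries$level) < 1e-12)
    if (has_zero) return(tibble::tibble())
    one(ax, 0, dataset$base)
  })
  dplyr::arrange(dplyr::bind_rows(rows, base_rows), .data$axis_id,
                 .data$level, .data$year)
}

#' Write spider-plot series as CSV
#'
#' @param dataset A [one_way_analysis()] result.
#' @param path Output CSV path (columns `axis_id`, `level`, `year`,
#'   `value_qar`).
#' @param outcome Passed to [spider_series()]; default both outcomes.
#' @return `path`, invisibly.
#' @export
write_spider_csv <- function(dataset, path,
                             outcome = c("cumulative", "by_year")) {
  tab <- spider_series(dataset, outcome)
  tab$value_qar <- round_half_away(tab$value_qar)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
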