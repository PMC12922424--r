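#' Define a treatment arm
#'
#' An arm is an opaque cost-bearing basket of care. A budget impact model
#' needs at least one `intervention` arm (the treatment whose uptake is being
#' projected) and one or more `comparator_mix` arms, each of which may stand
#' for a blend of drugs and standard care priced at a single per-patient rate.
#'
#' @param arm_id Short unique identifier used in cost tables and trajectories.
#' @param label Display label, e.g. `"PLBO/RIBO/Other Tx"`.
#' @param role `"intervention"` or `"comparator_mix"`.
#' @return A `bia_arm` list.
#' @export
#' @examples
#' treatment_arm("abma", "ABMA", "intervention")
treatment_arm <- function(arm_id, label = arm_id,
                          role = c("intervention", "comparator_mix")) {
  role <- match.arg(role)
  stopifnot(is.character(arm_id), length(arm_id) == 1, nzchar(arm_id),
            is.character(label), length(label) == 1)
  structure(list(arm_id = arm_id, label = label, role = role),
            class = "bia_arm")
}

#' Per-patient annual unit costs by arm and calendar year
#'
#' Costs are stored per (arm, year) rather than as a base price plus an
#' inflation rule: real formulary prices drift non-uniformly, and the shipped
#' fixtures carry year-specific back-derived rates.
#'
#' @param entries A data frame with columns `arm_id`, `year`, `cost_qar`
#'   (QAR per patient per year, strictly positive).
#' @return A `bia_unit_costs` tibble.
#' @seealso [unit_cost()], [read_unit_costs()], [write_unit_costs()]
#' @export
unit_cost_table <- function(entries) {
  entries <- tibble::as_tibble(entries)
  need <- c("arm_id", "year", "cost_qar")
  if (!all(need %in% names(entries))) {
    abort_bia(paste0("unit cost table needs columns ",
                     paste(need, collapse = ", ")))
  }
  entries$arm_id <- as.character(entries$arm_id)
  entries$year <- as.integer(entries$year)
  entries$cost_qar <- as.numeric(entries$cost_qar)
  structure(entries[need], class = c("bia_unit_costs", class(entries)))
}

#' Bottom-up per-patient annual cost components
#'
#' Itemised components of one patient-year of treatment: drug acquisition per
#' cycle times cycles per year, plus annual laboratory, imaging, cardiac
#' monitoring, outpatient visit and hospitalisation costs. All in QAR.
#'
#' @param drug_cost_per_cycle QAR per treatment cycle.
#' @param cycles_per_year Cycles delivered per year (13 for a 28-day cycle).
#' @param lab_cost_per_year,imaging_cost_per_year,cardiac_monitoring_per_year,
#'   outpatient_visit_cost_per_year,hospitalisation_cost_per_year Annual QAR.
#' @return A `bia_cost_breakdown` list.
#' @seealso [annual_cost_from_components()]
#' @export
cost_breakdown <- function(drug_cost_per_cycle = 0, cycles_per_year = 0,
                           lab_cost_per_year = 0, imaging_cost_per_year = 0,
                           cardiac_monitoring_per_year = 0,
                           outpatient_visit_cost_per_year = 0,
                           hospitalisation_cost_per_year = 0) {
  x <- list(drug_cost_per_cycle = drug_cost_per_cycle,
            cycles_per_year = cycles_per_year,
            lab_cost_per_year = lab_cost_per_year,
            imaging_cost_per_year = imaging_cost_per_year,
            cardiac_monitoring_per_year = cardiac_monitoring_per_year,
            outpatient_visit_cost_per_year = outpatient_visit_cost_per_year,
            hospitalisation_cost_per_year = hospitalisation_cost_per_year)
  bad <- names(x)[!vapply(x, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v >= 0, logical(1))]
  if (length(bad)) {
    abort_bia(paste0("cost components must be single non-negative numbers: ",
                     paste(bad, collapse = ", ")))
  }
  if (all(unlist(x) == 0)) abort_bia("at least one cost component must be > 0")
  structure(x, class = "bia_cost_breakdown")
}

#' Eligible-population model
#'
#' The treated cohort starts at `base_count` in `base_year` and grows each
#' year by the net prevalence rate (incidence minus dropout), with each year's
#' count rounded before the next year's growth is applied.
#'
#' @param base_year First calendar year of the horizon.
#' @param base_count Patients on treatment in the base year (positive integer).
#' @param incidence_rate,dropout_rate Annual fractions in \[0, 1\].
#' @param horizon_years Number of years modelled (1--50).
#' @param rounding_policy `"nearest_half_away_from_zero"` (default) or
#'   `"none"` (keep fractional counts).
#' @return A `bia_population` list.
#' @seealso [project_population()], [net_growth_rate()]
#' @export
#' @examples
#' population_model(2024, 173, incidence_rate = 0.10, dropout_rate = 0.05,
#'                  horizon_years = 5)
population_model <- function(base_year, base_count, incidence_rate,
                             dropout_rate, horizon_years,
                             rounding_policy = c("nearest_half_away_from_zero",
                                                 "none")) {
  rounding_policy <- match.arg(rounding_policy)
  structure(list(base_year = as.integer(base_year),
                 base_count = as.numeric(base_count),
                 incidence_rate = as.numeric(incidence_rate),
                 dropout_rate = as.numeric(dropout_rate),
                 horizon_years = as.integer(horizon_years),
                 rounding_policy = rounding_policy),
            class = "bia_population")
}

#' Market-share trajectory for a named scenario
#'
#' @param scenario_name Scenario label, e.g. `"projected"`.
#' @param shares Data frame with columns `year`, `arm_id`, `share`; each
#'   year's shares must lie in \[0, 1\] and sum to 1.
#' @return A `bia_trajectory` object.
#' @export
market_share_trajectory <- function(scenario_name, shares) {
  shares <- tibble::as_tibble(shares)
  need <- c("year", "arm_id", "share")
  if (!all(need %in% names(shares))) {
    abort_bia(paste0("trajectory needs columns ", paste(need, collapse = ", ")))
  }
  shares$year <- as.integer(shares$year)
  shares$arm_id <- as.character(shares$arm_id)
  shares$share <- as.numeric(shares$share)
  structure(list(scenario_name = scenario_name, shares = shares[need]),
            class = "bia_trajectory")
}

#' Affordability threshold as a GDP-per-capita multiple
#'
#' The effective threshold is `override_value` when supplied, otherwise
#' `multiplier * gdp_per_capita`. A per-patient incremental impact above the
#' threshold but within `tolerance_fraction` of it is classified borderline
#' rather than unacceptable.
#'
#' @param gdp_per_capita GDP per capita in QAR.
#' @param multiplier Threshold multiple of GDP per capita (default 1.5).
#' @param override_value Optional verbatim threshold in QAR; wins over the
#'   formula when present.
#' @param tolerance_fraction Tolerance band above the threshold (default 0.10).
#' @return A `bia_threshold` list.
#' @seealso [effective_threshold()], [assess_affordability()]
#' @export
affordability_threshold <- function(gdp_per_capita, multiplier = 1.5,
                                    override_value = NULL,
                                    tolerance_fraction = 0.10) {
  structure(list(gdp_per_capita = as.numeric(gdp_per_capita),
                 multiplier = as.numeric(multiplier),
                 override_value = if (!is.null(override_value))
                   as.numeric(override_value),
                 tolerance_fraction = as.numeric(tolerance_fraction)),
            class = "bia_threshold")
}

#' Effective threshold value in QAR
#'
#' @param threshold A [affordability_threshold()] object.
#' @return The effective per-patient threshold T in QAR.
#' @export
effective_threshold <- function(threshold) {
  threshold$override_value %||%
    (threshold$multiplier * threshold$gdp_per_capita)
}

#' Currency settings
#'
#' @param reporting_currency Currency code amounts are reported in.
#' @param usd_per_unit_rate Units of the reporting currency per 1 USD
#'   (QAR 3.65 per USD).
#' @param conversion_rounding `"truncate_toward_zero"` (default) or
#'   `"nearest"` for converted whole-currency amounts.
#' @return A `bia_currency` list.
#' @seealso [convert_currency()]
#' @export
currency_settings <- function(reporting_currency = "QAR",
                              usd_per_unit_rate = 3.65,
                              conversion_rounding = c("truncate_toward_zero",
                                                      "nearest")) {
  conversion_rounding <- match.arg(conversion_rounding)
  structure(list(reporting_currency = reporting_currency,
                 usd_per_unit_rate = as.numeric(usd_per_unit_rate),
                 conversion_rounding = conversion_rounding),
            class = "bia_currency")
}

#' Assemble a complete budget-impact model specification
#'
#' Binds the population model, arms, unit costs, the baseline and projected
#' market-share trajectories, the affordability threshold and currency
#' settings into one validated object.
#'
#' @param population A [population_model()].
#' @param arms List of [treatment_arm()] objects.
#' @param unit_costs A [unit_cost_table()].
#' @param baseline,projected [market_share_trajectory()] objects covering
#'   exactly the population's horizon years.
#' @param threshold An [affordability_threshold()].
#' @param currency A [currency_settings()] (default QAR at 3.65 per USD).
#' @param name Optional model name carried into reports.
#' @param validate Abort on any invariant violation (default `TRUE`).
#' @return A `bia_model_spec` object.
#' @seealso [validate_model_spec()], [load_model_spec()], [run_budget_impact()]
#' @export
model_spec <- function(population, arms, unit_costs, baseline, projected,
                       threshold, currency = currency_settings(),
                       name = "unnamed model", validate = TRUE) {
  spec <- structure(list(name = name, population = population, arms = arms,
                         unit_costs = unit_costs, baseline = baseline,
                         projected = projected, threshold = threshold,
                         currency = currency),
                    class = "bia_model_spec")
  if (validate) {
    v <- validate_model_spec(spec)
    if (nrow(v) > 0) {
      abort_bia(paste0("invalid model spec:\n",
                       paste0("- [", v$type, "] ", v$field, " (", v$location,
                              "): ", v$message, collapse = "\n")))
    }
  }
  spec
}

#' Calendar years covered by a model spec
#' @param spec A `bia_model_spec`.
#' @return Integer vector of horizon years.
#' @export
model_years <- function(spec) {
  p <- spec$population
  seq.int(p$base_year, length.out = p$horizon_years)
}

arm_ids <- function(spec) vapply(spec$arms, `[[`, character(1), "arm_id")

#' Validate a model specification
#'
#' Checks every structural invariant and returns a report instead of
#' throwing: arm uniqueness, rate and cost positivity, per-year share sums,
#' year coverage of both trajectories, and unit-cost coverage of every
#' positive-share (arm, year).
#'
#' @param spec A `bia_model_spec` (typically built with `validate = FALSE`).
#' @return A tibble with columns `type`, `field`, `location`, `message`;
#'   zero rows iff the spec is valid.
#' @export
validate_model_spec <- function(spec) {
  v <- list()
  add <- function(type, field, location, message) {
    v[[length(v) + 1]] <<- tibble::tibble(type = type, field = field,
                                          location = as.character(location),
                                          message = message)
  }

  ids <- arm_ids(spec)
  if (length(ids) == 0) {
    add("TreatmentArm", "arms", "-", "at least one arm is required")
  }
  if (anyDuplicated(ids)) {
    add("TreatmentArm", "arm_id", paste(ids[duplicated(ids)], collapse = ","),
        "arm_id values must be unique")
  }

  p <- spec$population
  if (!is.finite(p$base_count) || p$base_count <= 0) {
    add("PopulationModel", "base_count", p$base_year, "must be > 0")
  }
  for (f in c("incidence_rate", "dropout_rate")) {
    if (!is.finite(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      add("PopulationModel", f, p$base_year, "must lie in [0, 1]")
    }
  }
  if (is.finite(p$incidence_rate) && is.finite(p$dropout_rate) &&
      p$incidence_rate - p$dropout_rate < -1) {
    add("PopulationModel", "net_growth", p$base_year, "net growth below -1")
  }
  if (is.na(p$horizon_years) || p$horizon_years < 1 || p$horizon_years > 50) {
    add("PopulationModel", "horizon_years", p$base_year,
        "must be an integer in 1..50")
  }

  uc <- spec$unit_costs
  bad_cost <- which(!is.finite(uc$cost_qar) | uc$cost_qar <= 0)
  for (i in bad_cost) {
    add("UnitCostTable", "cost_qar",
        paste0(uc$arm_id[i], "/", uc$year[i]),
        paste0("cost must be strictly positive, got ", uc$cost_qar[i]))
  }
  dup <- duplicated(uc[c("arm_id", "year")])
  for (i in which(dup)) {
    add("UnitCostTable", "entries", paste0(uc$arm_id[i], "/", uc$year[i]),
        "duplicate (arm, year) entry")
  }
  unknown <- setdiff(unique(uc$arm_id), ids)
  if (length(unknown)) {
    add("UnitCostTable", "arm_id", paste(unknown, collapse = ","),
        "cost entry for undefined arm")
  }

  years <- if (is.na(p$horizon_years) || p$horizon_years < 1) integer(0)
           else model_years(spec)
  for (side in c("baseline", "projected")) {
    tr <- spec[[side]]$shares
    missing_years <- setdiff(years, unique(tr$year))
    if (length(missing_years)) {
      add("MarketShareTrajectory", side,
          paste(missing_years, collapse = ","),
          "trajectory does not cover these horizon years")
    }
    extra <- setdiff(unique(tr$year), years)
    if (length(extra)) {
      add("MarketShareTrajectory", side, paste(extra, collapse = ","),
          "trajectory year outside the population horizon")
    }
    unknown <- setdiff(unique(tr$arm_id), ids)
    if (length(unknown)) {
      add("MarketShareTrajectory", side, paste(unknown, collapse = ","),
          "share for undefined arm")
    }
    out_of_range <- which(tr$share < 0 | tr$share > 1)
    for (i in out_of_range) {
      add("MarketShareTrajectory", side, paste0(tr$arm_id[i], "/", tr$year[i]),
          paste0("share ", tr$share[i], " outside [0, 1]"))
    }
    sums <- tapply(tr$share, tr$year, sum)
    for (yr in names(sums)) {
      if (abs(sums[[yr]] - 1) > 1e-9) {
        add("MarketShareTrajectory", side, yr,
            paste0("shares sum to ", format(sums[[yr]], digits = 12),
                   ", expected 1"))
      }
    }
    # every positive-share (arm, year) must have a unit cost
    pos <- tr[tr$share > 0, , drop = FALSE]
    if (nrow(pos)) {
      key_have <- paste(uc$arm_id, uc$year)
      miss <- !(paste(pos$arm_id, pos$year) %in% key_have) &
        pos$arm_id %in% ids
      for (i in which(miss)) {
        add("UnitCostTable", "coverage",
            paste0(pos$arm_id[i], "/", pos$year[i]),
            paste0("no unit cost for arm '", pos$arm_id[i], "' in year ",
                   pos$year[i], " (", side, " share ", pos$share[i], ")"))
      }
    }
  }

  th <- spec$threshold
  t_eff <- effective_threshold(th)
  if (!is.finite(t_eff) || t_eff <= 0) {
    add("AffordabilityThreshold", "effective_threshold", "-", "must be > 0")
  }
  if (!is.finite(th$tolerance_fraction) || th$tolerance_fraction < 0) {
    add("AffordabilityThreshold", "tolerance_fraction", "-", "must be >= 0")
  }

  if (!is.finite(spec$currency$usd_per_unit_rate) ||
      spec$currency$usd_per_unit_rate <= 0) {
    add("CurrencySettings", "usd_per_unit_rate", "-", "must be > 0")
  }

  if (length(v)) dplyr::bind_rows(v)
  else tibble::tibble(type = character(), field = character(),
                      location = character(), message = character())
}

#' @export
print.bia_model_spec <- function(x, ...) {
  yrs <- model_years(x)
  cat("<bia_model_spec> ", x$name, "\n",
      "  years: ", min(yrs), "-", max(yrs),
      ", base N = ", x$population$base_count, "\n",
      "  arms:  ", paste(vapply(x$arms, `[[`, character(1), "label"),
                         collapse = " | "), "\n",
      "  threshold: QAR ",
      format(effective_threshold(x$threshold), big.mark = ","),
      " per patient-year\n", sep = "")
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

spec_to_list <- function(spec) {
  traj_to_list <- function(tr) {
    by_year <- split(tr$shares, tr$shares$year)
    shares <- lapply(by_year, function(d) as.list(stats::setNames(d$share,
                                                                  d$arm_id)))
    list(scenario_name = tr$scenario_name, shares = shares)
  }
  list(
    schema_version = 1L,
    name = spec$name,
    population = unclass(spec$population),
    arms = lapply(spec$arms, unclass),
    unit_costs = lapply(seq_len(nrow(spec$unit_costs)), function(i)
      list(arm_id = spec$unit_costs$arm_id[i],
           year = spec$unit_costs$year[i],
           cost_qar = spec$unit_costs$cost_qar[i])),
    scenarios = list(baseline = traj_to_list(spec$baseline),
                     projected = traj_to_list(spec$projected)),
    threshold = Filter(Negate(is.null), unclass(spec$threshold)),
    currency = unclass(spec$currency)
  )
}

list_to_spec <- function(x, validate = TRUE) {
  req <- function(node, field, where) {
    if (is.null(node[[field]])) {
      abort_bia(paste0("model spec is missing '", field, "' under ", where))
    }
    node[[field]]
  }
  pop <- req(x, "population", "top level")
  population <- population_model(
    base_year = req(pop, "base_year", "population"),
    base_count = req(pop, "base_count", "population"),
    incidence_rate = req(pop, "incidence_rate", "population"),
    dropout_rate = req(pop, "dropout_rate", "population"),
    horizon_years = req(pop, "horizon_years", "population"),
    rounding_policy = pop$rounding_policy %||% "nearest_half_away_from_zero")
  arms <- lapply(req(x, "arms", "top level"), function(a)
    treatment_arm(req(a, "arm_id", "arms"), a$label %||% a$arm_id,
                  req(a, "role", "arms")))
  uc_rows <- req(x, "unit_costs", "top level")
  unit_costs <- unit_cost_table(dplyr::bind_rows(lapply(uc_rows, function(e)
    tibble::tibble(arm_id = req(e, "arm_id", "unit_costs"),
                   year = req(e, "year", "unit_costs"),
                   cost_qar = req(e, "cost_qar", "unit_costs")))))
  scen <- req(x, "scenarios", "top level")
  traj_from_list <- function(node, default_name) {
    shares <- req(node, "shares", default_name)
    rows <- dplyr::bind_rows(lapply(names(shares), function(yr) {
      tibble::tibble(year = as.integer(yr),
                     arm_id = names(shares[[yr]]),
                     share = as.numeric(unlist(shares[[yr]])))
    }))
    market_share_trajectory(node$scenario_name %||% default_name, rows)
  }
  th <- req(x, "threshold", "top level")
  cu <- x$currency %||% list()
  model_spec(
    population = population, arms = arms, unit_costs = unit_costs,
    baseline = traj_from_list(req(scen, "baseline", "scenarios"), "baseline"),
    projected = traj_from_list(req(scen, "projected", "scenarios"),
                               "projected"),
    threshold = affordability_threshold(
      gdp_per_capita = th$gdp_per_capita %||% NA_real_,
      multiplier = th$multiplier %||% 1.5,
      override_value = th$override_value,
      tolerance_fraction = th$tolerance_fraction %||% 0.10),
    currency = currency_settings(
      reporting_currency = cu$reporting_currency %||% "QAR",
      usd_per_unit_rate = cu$usd_per_unit_rate %||% 3.65,
      conversion_rounding = cu$conversion_rounding %||%
        "truncate_toward_zero"),
    name = x$name %||% "unnamed model",
    validate = validate)
}

#' Load a model specification from a YAML file
#'
#' Parses and validates a declarative model document (schema version 1, see
#' the files under `system.file("extdata", package = "bimpact")` for the
#' layout). Any invariant violation aborts with a message naming the
#' offending field and year.
#'
#' @param source Path to a YAML file, or a literal YAML string.
#' @param validate Abort on violations (default `TRUE`).
#' @return A `bia_model_spec`.
#' @seealso [write_model_spec()], [validate_model_spec()]
#' @export
load_model_spec <- function(source, validate = TRUE) {
  x <- if (length(source) == 1 && !grepl("\n", source) &&
           file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (!is.list(x)) abort_bia("model spec source did not parse to a mapping")
  list_to_spec(x, validate = validate)
}

#' Write a model specification to YAML
#'
#' @param spec A `bia_model_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(spec_to_list(spec), path, precision = 15)
  invisible(path)
}

#' Export a model specification as JSON
#'
#' @param spec A `bia_model_spec`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
model_spec_json <- function(spec, path = NULL) {
  js <- jsonlite::toJSON(spec_to_list(spec), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Stable digest of a model specification
#'
#' @param spec A `bia_model_spec`.
#' @return 8-hex-character digest identifying the spec content.
#' @export
spec_digest <- function(spec) {
  fnv1a_hex(as.character(jsonlite::toJSON(spec_to_list(spec),
                                          auto_unbox = TRUE, digits = NA)))
}

#' Convert a QAR amount to USD
#'
#' @param amount Amount in the reporting currency (QAR).
#' @param settings A [currency_settings()].
#' @return The USD amount, rounded per `settings$conversion_rounding`
#'   (truncation toward zero by default).
#' @export
#' @examples
#' convert_currency(14001749, currency_settings())  # 3836095
convert_currency <- function(amount, settings = currency_settings()) {
  if (!all(is.finite(amount))) abort_bia("amount must be finite")
  usd <- amount / settings$usd_per_unit_rate
  switch(settings$conversion_rounding,
         truncate_toward_zero = trunc(usd),
         nearest = round_half_away(usd))
}
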