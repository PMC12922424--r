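#' Net prevalence growth rate
#'
#' Additive convention: the treated cohort grows by annual incidence and
#' shrinks by annual dropout, so the net rate is their difference.
#'
#' @param incidence_rate,dropout_rate Annual fractions in \[0, 1\].
#' @return The net annual growth fraction.
#' @export
#' @examples
#' net_growth_rate(0.10, 0.05)  # 0.05
net_growth_rate <- function(incidence_rate, dropout_rate) {
  for (r in list(incidence_rate, dropout_rate)) {
    if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0 || r > 1) {
      abort_bia("incidence and dropout rates must be single numbers in [0, 1]")
    }
  }
  incidence_rate - dropout_rate
}

#' Project annual eligible patient counts
#'
#' Starting from the base-year cohort, each subsequent year's count is the
#' previous year's count grown by the net rate. Under the default rounding
#' policy the count is rounded to the nearest integer (ties away from zero)
#' each year, and the *rounded* value is carried into the next year's growth
#' -- the sequential convention used in formulary planning, where each year's
#' count is a whole number of patients.
#'
#' @param model A [population_model()].
#' @return A `bia_population_projection`: a list with `counts` (tibble with
#'   columns `year`, `n`), `growth_rate_used`, and `rounding_policy`.
#' @export
#' @examples
#' p <- population_model(2024, 173, 0.10, 0.05, horizon_years = 5)
#' project_population(p)$counts$n  # 173 182 191 201 211
project_population <- function(model) {
  if (is.na(model$horizon_years) || model$horizon_years < 1) {
    abort_bia("horizon_years must be at least 1")
  }
  g <- net_growth_rate(model$incidence_rate, model$dropout_rate)
  years <- seq.int(model$base_year, length.out = model$horizon_years)
  n <- numeric(model$horizon_years)
  n[1] <- model$base_count
  if (model$horizon_years > 1) {
    for (i in 2:model$horizon_years) {
      nxt <- n[i - 1] * (1 + g)
      n[i] <- if (model$rounding_policy == "none") nxt else round_half_away(nxt)
    }
  }
  structure(list(counts = tibble::tibble(year = years, n = n),
                 growth_rate_used = g,
                 rounding_policy = model$rounding_policy),
            class = "bia_population_projection")
}

#' @export
print.bia_population_projection <- function(x, ...) {
  cat("<bia_population_projection> net growth ",
      format(100 * x$growth_rate_used), "%/yr, rounding ",
      x$rounding_policy, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Write a population projection as a two-column CSV
#'
#' @param projection A [project_population()] result.
#' @param path Output CSV path (columns `year`, `n`).
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(projection, path) {
  utils::write.csv(projection$counts, path, row.names = FALSE)
  invisible(path)
}
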