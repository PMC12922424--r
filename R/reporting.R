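# Report writers behind the command-line tool (inst/cli/bia.R). Each
# subcommand function returns a run manifest listing what it wrote.

write_manifest <- function(output_dir, subcommand, spec_digest, outputs) {
  manifest <- list(
    subcommand = subcommand,
    spec_digest = spec_digest,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tool_version = as.character(utils::packageVersion("bimpact")),
    outputs = outputs)
  path <- file.path(output_dir, paste0(subcommand, "_manifest.json"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             path)
  missing <- outputs[!file.exists(unlist(outputs))]
  if (length(missing)) {
    abort_bia(paste0("manifest lists missing output(s): ",
                     paste(unlist(missing), collapse = ", ")))
  }
  manifest
}

ensure_outdir <- function(output_dir) {
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (!dir.exists(output_dir) || file.access(output_dir, 2) != 0) {
    abort_bia(paste0("output directory not writable: ", output_dir))
  }
  invisible(output_dir)
}

#' Run a budget impact analysis from a spec file
#'
#' Loads and validates a model-spec YAML, runs the engine, and writes the
#' result table CSV, a JSON result document, and a run manifest into
#' `output_dir`.
#'
#' @param spec_path Path to a model-spec YAML file.
#' @param output_dir Output directory (created if needed).
#' @param currency_display `"QAR"` (default) or `"USD"`; USD additionally
#'   logs converted headline figures.
#' @return The run manifest, invisibly.
#' @export
bia_run <- function(spec_path, output_dir, currency_display = "QAR") {
  ensure_outdir(output_dir)
  spec <- load_model_spec(spec_path)
  res <- run_budget_impact(spec)
  csv <- file.path(output_dir, "budget_impact.csv")
  js <- file.path(output_dir, "budget_impact.json")
  write_result_csv(res, csv)
  result_json(res, js)
  cum <- round_half_away(res$cumulative)
  message("cumulative budget impact: QAR ", format(cum, big.mark = ","),
          if (currency_display == "USD")
            paste0(" (USD ", format(res$cumulative_usd, big.mark = ","), ")")
          else "")
  invisible(write_manifest(output_dir, "run", res$spec_digest,
                           list(csv = csv, json = js)))
}

#' Load sensitivity axes from a YAML file
#'
#' The document is a list of axis mappings with keys `axis_id`, `target`,
#' `levels`, and optional `arm_selector`, `scenario_scope`,
#' `perturbation_kind`.
#'
#' @param path Path to the axes YAML file.
#' @return List of [sensitivity_axis()] objects.
#' @export
load_axes <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.list(x) || length(x) == 0) {
    abort_bia(paste0("no sensitivity axes found in ", path))
  }
  lapply(x, function(a) {
    if (is.null(a$axis_id) || is.null(a$target) || is.null(a$levels)) {
      abort_bia("each axis needs axis_id, target and levels")
    }
    sensitivity_axis(axis_id = a$axis_id, target = a$target,
                     levels = as.numeric(unlist(a$levels)),
                     arm_selector = if (!is.null(a$arm_selector))
                       as.character(unlist(a$arm_selector)),
                     scenario_scope = a$scenario_scope %||% "both",
                     perturbation_kind = a$perturbation_kind)
  })
}

#' Run a one-way sensitivity analysis from files
#'
#' @param spec_path Path to a model-spec YAML file.
#' @param axes_path Path to an axes YAML file ([load_axes()]).
#' @param output_dir Output directory.
#' @return The run manifest, invisibly.
#' @export
bia_sensitivity <- function(spec_path, axes_path, output_dir) {
  ensure_outdir(output_dir)
  spec <- load_model_spec(spec_path)
  axes <- load_axes(axes_path)
  for (ax in axes) {
    message("axis '", ax$axis_id, "': ", ax$target, " levels ",
            paste(ax$levels, collapse = ", "))
  }
  sp <- one_way_analysis(spec, axes)
  csv <- file.path(output_dir, "spider.csv")
  write_spider_csv(sp, csv)
  invisible(write_manifest(output_dir, "sensitivity", sp$base$spec_digest,
                           list(spider = csv)))
}

#' Materialise the shipped scenario fixtures
#'
#' Writes both CDK4/6 scenario fixtures as model-spec YAML files together
#' with their consistency reports against the printed table cells.
#'
#' @param output_dir Output directory.
#' @return The run manifest, invisibly.
#' @export
bia_fixtures <- function(output_dir) {
  ensure_outdir(output_dir)
  outputs <- list()
  digests <- character()
  for (k in 1:2) {
    spec <- if (k == 1) scenario1_fixture() else scenario2_fixture()
    rep <- fixture_consistency(spec, printed_table_cells(k))
    spec_file <- file.path(output_dir, paste0("scenario", k, ".yaml"))
    rep_file <- file.path(output_dir,
                          paste0("scenario", k, "_consistency.csv"))
    write_model_spec(spec, spec_file)
    utils::write.csv(rep$cells, rep_file, row.names = FALSE)
    message("scenario ", k, ": max relative deviation ",
            format(rep$max_rel_dev, digits = 3),
            if (rep$pass) " (pass)" else " (FAIL)")
    outputs[[paste0("scenario", k)]] <- spec_file
    outputs[[paste0("scenario", k, "_report")]] <- rep_file
    digests[k] <- spec_digest(spec)
  }
  invisible(write_manifest(output_dir, "fixtures",
                           paste(digests, collapse = "+"), outputs))
}

#' Validate a spec file and report violations
#'
#' @param spec_path Path to a model-spec YAML file.
#' @return A tibble of violations (zero rows if valid), invisibly; also
#'   printed.
#' @export
bia_validate <- function(spec_path) {
  spec <- load_model_spec(spec_path, validate = FALSE)
  v <- validate_model_spec(spec)
  if (nrow(v) == 0) message("spec is valid: ", spec_path)
  else print(v, n = Inf)
  invisible(v)
}
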