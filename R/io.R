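param_field_map <- function() {
  p <- list(
    epi = c("p_severe_annual", "p_no_eai", "p_biphasic", "p_ed_ww",
            "p_hosp_given_ed", "p_fatal_hosp", "p_fatal_overall_annual",
            "ww_fatality_multiplier", "p_remission_annual",
            "remission_min_age", "remission_max_age", "p_fa_ww_daily",
            "p_fa_ww_annual"),
    cost = c("eai_unit_cost", "ed_injection_cost", "p_eai_before_ed",
             "epi_cost_immediate_ed", "ambulance_cost",
             "ed_visit_medical_cost", "hosp_daily_cost",
             "annual_fa_medical_cost", "annual_remission_medical_cost",
             "ed_oop_cost", "annual_fa_oop_cost", "annual_fa_indirect_cost",
             "hourly_wage", "ed_wait_hours", "hosp_workday_hours",
             "ed_indirect_cost", "hosp_indirect_cost"),
    util = c("u_food_allergy", "disutility_reaction", "u_remission"),
    settings = c("discount_rate_annual", "wtp", "horizon_years", "cycle_days",
                 "days_per_year", "start_age_years", "perspective")
  )
  stats::setNames(rep(names(p), lengths(p)), unlist(p))
}

#' Flatten a parameter set to a named list
#'
#' One flat key per field (field names are unique across the four groups),
#' suitable for YAML/JSON serialization.
#'
#' @param params A `ww_parameters` object.
#' @return A named list of scalars.
#' @export
flatten_parameters <- function(params) {
  fm <- param_field_map()
  out <- lapply(names(fm), function(nm) params[[fm[[nm]]]][[nm]])
  stats::setNames(out, names(fm))
}

#' Apply flat-key overrides to a parameter set
#'
#' Assigns each override by its flat field name, rejects unknown keys with
#' an error naming the key, re-derives dependent fields (derived fields that
#' were themselves overridden are kept as given), and validates the result.
#'
#' @param params A `ww_parameters` object.
#' @param overrides Named list of field values.
#' @return The updated, validated `ww_parameters` object.
#' @export
apply_overrides <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  fm <- param_field_map()
  unknown <- setdiff(names(overrides), names(fm))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(overrides))
    params[[fm[[nm]]]][[nm]] <- overrides[[nm]]
  # validate raw ranges first so errors name the offending field, then
  # re-derive dependants and validate the final object
  validate_parameters(params)
  params <- rederive_parameters(
    params, keep = intersect(names(overrides), .derived_fields))
  validate_parameters(params)
  params
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path)
}

#' Write a parameter set to YAML or JSON
#' @param params A `ww_parameters` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  flat <- flatten_parameters(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(flat, path, precision = 15)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else stop("path must end in .yaml/.yml or .json")
  invisible(path)
}

#' Read a parameter set from YAML or JSON
#'
#' Keys must be known flat field names; unknown keys error. Missing fields
#' keep their base-case values; derived fields present in the file are kept
#' as written, otherwise re-derived.
#'
#' @param path Input path.
#' @param base Parameter set supplying defaults.
#' @return A validated `ww_parameters` object.
#' @export
read_parameters <- function(path, base = default_parameters()) {
  apply_overrides(base, read_structured(path))
}

#' Load a run configuration
#'
#' A configuration file (YAML or JSON) may set the analysis kind (`base`,
#' `dsa`, `psa`, `ceac`, `scenarios`), `seed`, `n_iterations`, `output_dir`,
#' the economic settings (`wtp`, `perspective`, `discount_rate_annual`,
#' `start_age_years`, `horizon_years`), and an `overrides` map of flat
#' parameter keys. An empty file yields the full base-case defaults.
#' Unknown keys raise an error naming the key.
#'
#' @param path Path to the config file.
#' @return A `run_config` list: `analysis`, `seed`, `n_iterations`,
#'   `output_dir`, and the validated `params`.
#' @export
load_config <- function(path) {
  raw <- read_structured(path)
  if (is.null(raw)) raw <- list()
  known <- c("analysis", "seed", "n_iterations", "output_dir", "wtp",
             "perspective", "discount_rate_annual", "start_age_years",
             "horizon_years", "overrides")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  analysis <- if (is.null(raw$analysis)) "base" else
    match.arg(raw$analysis, c("base", "dsa", "psa", "ceac", "scenarios"))
  settings_keys <- intersect(names(raw), c("wtp", "perspective",
                                           "discount_rate_annual",
                                           "start_age_years", "horizon_years"))
  overrides <- c(raw[settings_keys],
                 if (is.null(raw$overrides)) list() else raw$overrides)
  params <- apply_overrides(default_parameters(), overrides)
  structure(list(
    analysis = analysis,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    n_iterations = if (is.null(raw$n_iterations)) 1000L
                   else as.integer(raw$n_iterations),
    output_dir = if (is.null(raw$output_dir)) "results" else raw$output_dir,
    params = params
  ), class = "run_config")
}

#' Serialize a comparison or strategy result to JSON
#'
#' Currency fields carry a `CAD2022` unit tag. Values are written at full
#' precision (no display rounding), so reading the file back with
#' [jsonlite::read_json()] reproduces the stored values to double read-back
#' precision (15 significant digits).
#'
#' @param x A `ce_comparison` or `strategy_result`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(as_result_list(x), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

as_result_list <- function(x) {
  if (inherits(x, "ce_comparison")) {
    list(unit = "CAD2022",
         delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
         icer = x$icer, inmb = x$inmb, wtp = x$wtp,
         delta_fa_death_risk = x$delta_fa_death_risk,
         cost_per_death_prevented = x$cost_per_death_prevented)
  } else if (inherits(x, "strategy_result")) {
    list(unit = "CAD2022", strategy = x$strategy,
         total_cost_discounted = x$total_cost_discounted,
         total_qaly_discounted = x$total_qaly_discounted,
         total_cost_undiscounted = x$total_cost_undiscounted,
         total_qaly_undiscounted = x$total_qaly_undiscounted,
         fa_death_risk = x$fa_death_risk)
  } else stop("cannot serialize object of class ", class(x)[1])
}

#' One-row data.frame view of a comparison
#' @param x A `ce_comparison`.
#' @return A data.frame with one row (currency columns in 2022 CAD).
#' @export
comparison_to_row <- function(x) {
  data.frame(delta_cost_cad2022 = x$delta_cost, delta_qaly = x$delta_qaly,
             icer_cad2022_per_qaly = x$icer, inmb_cad2022 = x$inmb,
             delta_fa_death_risk = x$delta_fa_death_risk,
             cost_per_death_prevented_cad2022 = x$cost_per_death_prevented)
}
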