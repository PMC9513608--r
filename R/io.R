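#' Read a stratified mortality table
#'
#' Long-format CSV with columns `age_low`, `age_high` (empty for the open
#' terminal band), `sex`, `population`, `cause`, `deaths`.
#'
#' @param path CSV file path.
#' @return A validated strata tibble.
#' @export
read_strata <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      age_low = readr::col_double(),
      age_high = readr::col_double(),
      sex = readr::col_character(),
      population = readr::col_double(),
      cause = readr::col_character(),
      deaths = readr::col_double()
    )
  )
  validate_strata(out)
  out
}

#' Write a stratified mortality table
#'
#' @param strata Strata tibble (see [read_strata()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_strata <- function(strata, path) {
  validate_strata(strata)
  readr::write_csv(strata[, c(
    "age_low", "age_high", "sex", "population", "cause", "deaths"
  )], path, na = "")
  invisible(path)
}

#' Read a dose-response table
#'
#' CSV with columns `cause`, `pathway`, `beta`, `sbp_slope`, `beta_sbp`,
#' `se`, `reference_exposure`, `age_low`, `age_high`, `sex`. Empty
#' `age_high` is read as unbounded; empty `sex` matches both sexes.
#'
#' @param path CSV file path.
#' @return A dose-response tibble.
#' @export
read_dose_response <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      cause = readr::col_character(),
      pathway = readr::col_character(),
      beta = readr::col_double(),
      sbp_slope = readr::col_double(),
      beta_sbp = readr::col_double(),
      se = readr::col_double(),
      reference_exposure = readr::col_double(),
      age_low = readr::col_double(),
      age_high = readr::col_double(),
      sex = readr::col_character()
    )
  )
  out$age_low[is.na(out$age_low)] <- 0
  out$age_high[is.na(out$age_high)] <- Inf
  bad <- !out$pathway %in% c("direct", "sbp_mediated")
  if (any(bad)) {
    stop("unknown pathway: ", paste(unique(out$pathway[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(out$se < 0, na.rm = TRUE)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  miss <- is.na(effective_beta(out))
  if (any(miss)) {
    stop("rows without a resolvable slope: ",
      paste(unique(out$cause[miss]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Write a dose-response table
#'
#' @param dose_responses Dose-response tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(dose_responses, path) {
  out <- dose_responses
  out$age_high[is.infinite(out$age_high)] <- NA_real_
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a scenario battery from a YAML config
#'
#' The file holds a top-level `scenarios:` list; each entry carries the
#' [scenario_spec()] fields (missing fields take the constructor defaults).
#'
#' @param path YAML file path.
#' @return A list of [scenario_spec()] objects.
#' @export
read_battery_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios)) {
    stop("config must contain a top-level `scenarios:` list", call. = FALSE)
  }
  lapply(cfg$scenarios, function(s) do.call(scenario_spec, s))
}

#' Write a scenario battery config as YAML
#'
#' @param specs List of [scenario_spec()] objects.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_battery_config <- function(specs, path) {
  yaml::write_yaml(list(scenarios = lapply(specs, unclass)), path)
  invisible(path)
}

#' Write battery results as a report-style CSV
#'
#' Columns mirror the standard report table: description, baseline intake,
#' absolute reduction, counterfactual intake, deaths averted and the
#' confidence-interval endpoints.
#'
#' @param battery A [run_battery()] result.
#' @param path Output CSV path.
#' @param rounded Round to report precision via [format_battery()]
#'   (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_battery_results <- function(battery, path, rounded = TRUE) {
  tab <- if (rounded) format_battery(battery) else tibble::as_tibble(battery)
  out <- tibble::tibble(
    description = tab$label,
    baseline_salt_g_day = tab$baseline,
    absolute_reduction_g_day = tab$reduction,
    counterfactual_salt_g_day = tab$counterfactual,
    deaths_averted = tab$deaths_averted_central,
    ci_low = tab$ci_low,
    ci_high = tab$ci_high
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a market decomposition with segment salt levels as CSV
#'
#' @param reduction A [scenario_reduction()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reduction_table <- function(reduction, path) {
  stopifnot(inherits(reduction, "reduction_result"))
  seg <- reduction$per_segment
  out <- tibble::tibble(
    segment = seg$segment,
    tonnes_per_year = seg$tonnes_per_year,
    share = seg$weight,
    salt_g_per_100g_baseline = seg$salt_g_per_100g,
    salt_g_per_100g_counterfactual = seg$salt_g_per_100g_counterfactual,
    reduction_t_day = seg$reduction_t_day
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
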