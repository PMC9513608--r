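#' Define one scenario of the sensitivity battery
#'
#' A scenario row bundles everything needed to turn the market model into a
#' (baseline, reduction) pair: the legal salt threshold and its scope, the
#' assumed bakery compliance with the voluntary 1.0 g level, the baseline
#' salt intake, an optional multiplicative rescaling of that baseline, and
#' an optional additive adjustment of the final per-capita reduction
#' (used to move the bread share of salt by percentage points of intake).
#'
#' @param label Unique scenario label.
#' @param threshold_g_per_100g Salt cap applied, g/100 g bread.
#' @param scope `"all_bread"` (exemptions removed) or `"non_exempt_only"`.
#' @param baseline_salt_g_day Baseline per-capita salt intake, g/day.
#' @param bread_share_of_salt Fraction of salt intake from bread.
#' @param compliance_fraction Bakery compliance with the voluntary 1.0 g
#'   level, used when calibrating segment salt densities.
#' @param bread_share_adjustment_g_day Signed g/day added to the computed
#'   reduction after the market step (e.g. `+0.01 * baseline` to emulate a
#'   one-percentage-point higher bread share of salt).
#' @param baseline_scale Multiplier applied to the baseline intake before
#'   the market calibration (e.g. 0.99 for a 1% lower baseline).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label,
                          threshold_g_per_100g,
                          scope = "all_bread",
                          baseline_salt_g_day = 7.4,
                          bread_share_of_salt = 0.182,
                          compliance_fraction = 0.76,
                          bread_share_adjustment_g_day = 0,
                          baseline_scale = 1) {
  scope <- match.arg(scope, c("all_bread", "non_exempt_only"))
  stopifnot(
    is.character(label), length(label) == 1L, nzchar(label),
    threshold_g_per_100g > 0,
    baseline_salt_g_day >= 0,
    bread_share_of_salt >= 0, bread_share_of_salt <= 1,
    compliance_fraction >= 0, compliance_fraction <= 1,
    baseline_scale > 0
  )
  structure(
    list(
      label = label,
      threshold_g_per_100g = threshold_g_per_100g,
      scope = scope,
      baseline_salt_g_day = baseline_salt_g_day,
      bread_share_of_salt = bread_share_of_salt,
      compliance_fraction = compliance_fraction,
      bread_share_adjustment_g_day = bread_share_adjustment_g_day,
      baseline_scale = baseline_scale
    ),
    class = "scenario_spec"
  )
}

#' Resolve a scenario to a baseline and per-capita reduction
#'
#' Runs the full market pathway for one scenario: scale the baseline
#' intake, derive the implied mean bread-salt density, calibrate segment
#' densities under the scenario's compliance assumption, apply the salt cap
#' to the in-scope segments, and finally apply the additive reduction
#' adjustment. A negative adjusted reduction is clipped to zero with a
#' warning; the counterfactual intake is never negative.
#'
#' @param spec A [scenario_spec()].
#' @param inputs A [market_inputs()] object.
#' @param total_t_yr Optional published total tonnage passed through to
#'   [decompose_market()].
#' @return A list with `label`, `baseline` (g/day), `reduction` (g/day),
#'   `counterfactual` (g/day) and the underlying `reduction_result`.
#' @export
#' @examples
#' fx <- portugal_market_fixture()
#' cf2 <- scenario_spec("all bread at 1.0 g", 1.0)
#' resolve_scenario(cf2, fx$inputs, fx$total_t_yr_published)
resolve_scenario <- function(spec, inputs, total_t_yr = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(inputs, "market_inputs"))
  baseline <- spec$baseline_salt_g_day * spec$baseline_scale
  bl <- salt_baseline(
    baseline, spec$bread_share_of_salt, inputs$per_capita_bread_g_day
  )
  dec <- decompose_market(inputs, total_t_yr)
  seg <- calibrate_segment_salt(
    dec, bl$mean_salt_density_g_per_100g, spec$compliance_fraction
  )
  red <- scenario_reduction(
    seg,
    salt_scenario(spec$threshold_g_per_100g, spec$scope, spec$label),
    bl, inputs$population
  )
  reduction <- red$salt_reduction_g_capita_day + spec$bread_share_adjustment_g_day
  if (reduction < 0) {
    warning("adjusted reduction below zero; clipped to 0", call. = FALSE)
    reduction <- 0
  }
  if (reduction > baseline) reduction <- baseline
  list(
    label = spec$label,
    baseline = baseline,
    reduction = reduction,
    counterfactual = baseline - reduction,
    market = red
  )
}

#' The default twelve-row scenario battery
#'
#' Two counterfactual scenarios and ten sensitivity variants:
#' * `CF1` — the 1.4 g/100 g legal limit extended to all bread (exemptions
#'   removed); `CF2` — a 1.0 g/100 g limit on all bread.
#' * `SA1a`/`SA1b` — bakery compliance with the voluntary 1.0 g level moved
#'   from 76% to 100% / 50% (1.4 g cap).
#' * `SA2a`/`SA2b` — higher baseline intake of 10.7 g/day (urinary-sodium
#'   estimate) under each cap.
#' * `SA3a`/`SA3b` per cap — bread's share of salt intake one percentage
#'   point higher/lower, operationalised as `reduction +/- 0.01 * baseline`.
#' * `SA4a`/`SA4b` — baseline intake 1% lower under each cap.
#'
#' @param baseline_salt_g_day Main baseline intake, g/day.
#' @param alt_baseline_salt_g_day Higher urinary-sodium baseline, g/day.
#' @param bread_share_of_salt Bread's share of salt intake.
#' @param compliance_fraction Main-model bakery compliance.
#' @return A list of [scenario_spec()] objects, in report order.
#' @export
default_battery <- function(baseline_salt_g_day = 7.4,
                            alt_baseline_salt_g_day = 10.7,
                            bread_share_of_salt = 0.182,
                            compliance_fraction = 0.76) {
  b <- baseline_salt_g_day
  pp <- 0.01 * b # one percentage point of intake, in g/day
  base <- function(label, threshold, ...) {
    args <- utils::modifyList(
      list(
        label = label, threshold_g_per_100g = threshold,
        scope = "all_bread", baseline_salt_g_day = b,
        bread_share_of_salt = bread_share_of_salt,
        compliance_fraction = compliance_fraction
      ),
      list(...)
    )
    do.call(scenario_spec, args)
  }
  list(
    base("CF1: all bread <1.4 g/100 g", 1.4),
    base("SA1a: compliance 100%, cap 1.4", 1.4, compliance_fraction = 1.0),
    base("SA1b: compliance 50%, cap 1.4", 1.4, compliance_fraction = 0.5),
    scenario_spec("SA2a: baseline 10.7 g, cap 1.4", 1.4,
      baseline_salt_g_day = alt_baseline_salt_g_day,
      bread_share_of_salt = bread_share_of_salt,
      compliance_fraction = compliance_fraction
    ),
    base("SA3a: +1pp bread share, cap 1.4", 1.4,
      bread_share_adjustment_g_day = pp
    ),
    base("SA3b: -1pp bread share, cap 1.4", 1.4,
      bread_share_adjustment_g_day = -pp
    ),
    base("SA4a: baseline 1% lower, cap 1.4", 1.4, baseline_scale = 0.99),
    base("CF2: all bread <1.0 g/100 g", 1.0),
    scenario_spec("SA2b: baseline 10.7 g, cap 1.0", 1.0,
      baseline_salt_g_day = alt_baseline_salt_g_day,
      bread_share_of_salt = bread_share_of_salt,
      compliance_fraction = compliance_fraction
    ),
    base("SA3a: +1pp bread share, cap 1.0", 1.0,
      bread_share_adjustment_g_day = pp
    ),
    base("SA3b: -1pp bread share, cap 1.0", 1.0,
      bread_share_adjustment_g_day = -pp
    ),
    base("SA4b: baseline 1% lower, cap 1.0", 1.0, baseline_scale = 0.99)
  )
}

#' Run a scenario battery
#'
#' Resolves every scenario through the market model, runs the Monte Carlo
#' mortality estimate for each, and returns one row per scenario with the
#' columns of the standard report table. Each scenario uses a seed derived
#' deterministically from `mc$seed` and its position, so the whole table is
#' reproducible bit-for-bit under a fixed configuration.
#'
#' @param specs List of [scenario_spec()] objects; labels must be unique.
#' @param strata Long-format mortality table (see [deaths_averted()]).
#' @param dose_responses Dose-response table.
#' @param mc An [mc_config()].
#' @param inputs A [market_inputs()] object.
#' @param total_t_yr Optional published total tonnage.
#' @param sd Exposure-distribution standard deviation (default 0: point).
#' @return A tibble of class `scenario_battery` with columns `label`,
#'   `baseline`, `reduction`, `counterfactual`, `deaths_averted_central`,
#'   `ci_low`, `ci_high`.
#' @export
run_battery <- function(specs, strata, dose_responses, mc, inputs,
                        total_t_yr = NULL, sd = 0) {
  stopifnot(inherits(mc, "mc_config"))
  if (length(specs) == 0L) {
    out <- tibble::tibble(
      label = character(), baseline = numeric(), reduction = numeric(),
      counterfactual = numeric(), deaths_averted_central = numeric(),
      ci_low = numeric(), ci_high = numeric()
    )
    class(out) <- c("scenario_battery", class(out))
    return(out)
  }
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate scenario labels: ",
      paste(unique(labels[duplicated(labels)]), collapse = ", "),
      call. = FALSE
    )
  }
  rows <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    res <- tryCatch(
      resolve_scenario(spec, inputs, total_t_yr),
      error = function(e) {
        stop(sprintf("scenario '%s' failed: %s", spec$label, conditionMessage(e)),
          call. = FALSE
        )
      }
    )
    mc_i <- mc_config(mc$n_draws, seed = mc$seed + i - 1L, ci_level = mc$ci_level)
    sr <- run_monte_carlo(
      strata, dose_responses,
      baseline_mean = res$baseline, shift = -res$reduction,
      mc = mc_i, sd = sd, label = spec$label
    )
    tibble::tibble(
      label = spec$label,
      baseline = res$baseline,
      reduction = res$reduction,
      counterfactual = res$counterfactual,
      deaths_averted_central = sr$deaths_averted_central,
      ci_low = sr$ci_low,
      ci_high = sr$ci_high
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scenario_battery", class(out))
  out
}

#' Round a battery table to report precision
#'
#' Intakes and reductions to two decimals, deaths and interval endpoints to
#' the nearest integer — the precision used in published report tables.
#' Computation elsewhere stays at full floating precision.
#'
#' @param battery A [run_battery()] result.
#' @return A tibble with the same columns, rounded.
#' @export
format_battery <- function(battery) {
  dplyr::mutate(
    tibble::as_tibble(battery),
    dplyr::across(c("baseline", "reduction", "counterfactual"), ~ round(.x, 2)),
    dplyr::across(
      c("deaths_averted_central", "ci_low", "ci_high"), ~ round(.x, 0)
    )
  )
}
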