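#' Bread market inputs
#'
#' Bundle and validate the national market constants the pipeline starts
#' from: per-capita bread consumption, population, pre-packaged sales,
#' imports, the fraction of national production classified as traditional
#' (and therefore exempt from the salt limit), and the fraction of bakeries
#' already meeting the voluntary 1.0 g/100 g target.
#'
#' @param per_capita_bread_g_day Mean bread consumption, g/person/day.
#' @param population Resident population (persons).
#' @param days_per_year Length of the reference year in days. Defaults to
#'   the mean Gregorian year, 365.25.
#' @param prepackaged_sold_t_yr Annual pre-packaged bread sales, tonnes/year.
#' @param imported_t_yr Annual imported (always pre-packaged) bread,
#'   tonnes/year. Must not exceed `prepackaged_sold_t_yr`.
#' @param traditional_fraction_of_national Fraction of nationally produced
#'   bread classified as traditional, in `[0, 1]`.
#' @param bakery_compliance_fraction Fraction of regulated bread already at
#'   the voluntary 1.0 g/100 g salt level, in `[0, 1]`.
#'
#' @return An object of class `market_inputs` (a named list).
#' @export
#' @examples
#' market_inputs(100.3, 10.3e6,
#'   prepackaged_sold_t_yr = 40040, imported_t_yr = 21764,
#'   traditional_fraction_of_national = 0.45,
#'   bakery_compliance_fraction = 0.76
#' )
market_inputs <- function(per_capita_bread_g_day,
                          population,
                          days_per_year = 365.25,
                          prepackaged_sold_t_yr,
                          imported_t_yr,
                          traditional_fraction_of_national,
                          bakery_compliance_fraction) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      stop("`", nm, "` must be a single non-missing number", call. = FALSE)
    }
    as.double(x)
  }
  out <- list(
    per_capita_bread_g_day = num1(per_capita_bread_g_day, "per_capita_bread_g_day"),
    population = num1(population, "population"),
    days_per_year = num1(days_per_year, "days_per_year"),
    prepackaged_sold_t_yr = num1(prepackaged_sold_t_yr, "prepackaged_sold_t_yr"),
    imported_t_yr = num1(imported_t_yr, "imported_t_yr"),
    traditional_fraction_of_national =
      num1(traditional_fraction_of_national, "traditional_fraction_of_national"),
    bakery_compliance_fraction =
      num1(bakery_compliance_fraction, "bakery_compliance_fraction")
  )
  mass_fields <- c(
    "per_capita_bread_g_day", "population", "days_per_year",
    "prepackaged_sold_t_yr", "imported_t_yr"
  )
  for (nm in mass_fields) {
    if (out[[nm]] < 0) stop("`", nm, "` must be non-negative", call. = FALSE)
  }
  for (nm in c("traditional_fraction_of_national", "bakery_compliance_fraction")) {
    if (out[[nm]] < 0 || out[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (out$imported_t_yr > out$prepackaged_sold_t_yr) {
    stop("imported bread cannot exceed total pre-packaged sales", call. = FALSE)
  }
  structure(out, class = "market_inputs")
}

#' Total annual bread consumption
#'
#' Per-capita daily intake times population times the year length, converted
#' from grams to tonnes (1 t = 1e6 g).
#'
#' @inheritParams market_inputs
#' @return Tonnes of bread per year.
#' @export
#' @examples
#' total_annual_bread(100.3, 10.3e6) # about 377,336 t/yr
total_annual_bread <- function(per_capita_bread_g_day, population,
                               days_per_year = 365.25) {
  if (any(c(per_capita_bread_g_day, population, days_per_year) < 0)) {
    stop("all inputs must be non-negative", call. = FALSE)
  }
  per_capita_bread_g_day * population * days_per_year / 1e6
}

#' Decompose the bread market into regulated and exempt segments
#'
#' Splits total annual tonnage into imported pre-packaged, nationally
#' produced pre-packaged, and loose bakery bread, then into the
#' legislatively exempt pool (traditional plus imported) and the regulated
#' remainder. Traditional bread is a fixed fraction of national production,
#' i.e. of `total - imported`.
#'
#' @param inputs A [market_inputs()] object.
#' @param total_t_yr Total bread sold, tonnes/year. Defaults to
#'   [total_annual_bread()] on `inputs`; pass the nationally published total
#'   directly when reproducing published tables, since a rounded population
#'   figure can shift the product by a few thousand tonnes.
#'
#' @return An object of class `market_decomposition`: a named list with
#'   tonnages (`total_t_yr`, `imported_prepackaged_t_yr`,
#'   `national_prepackaged_t_yr`, `loose_bakery_t_yr`, `traditional_t_yr`,
#'   `exempt_t_yr`, `regulated_t_yr`) and the corresponding shares of total.
#' @export
#' @examples
#' mi <- market_inputs(100.3, 10.3e6,
#'   prepackaged_sold_t_yr = 40040, imported_t_yr = 21764,
#'   traditional_fraction_of_national = 0.45,
#'   bakery_compliance_fraction = 0.76
#' )
#' decompose_market(mi, total_t_yr = 376218)
decompose_market <- function(inputs, total_t_yr = NULL) {
  stopifnot(inherits(inputs, "market_inputs"))
  if (is.null(total_t_yr)) {
    total_t_yr <- total_annual_bread(
      inputs$per_capita_bread_g_day, inputs$population, inputs$days_per_year
    )
  }
  if (inputs$prepackaged_sold_t_yr > total_t_yr) {
    stop("pre-packaged sales exceed total bread sold: inconsistent inputs",
      call. = FALSE
    )
  }
  imported <- inputs$imported_t_yr
  national_prepackaged <- inputs$prepackaged_sold_t_yr - imported
  loose <- total_t_yr - inputs$prepackaged_sold_t_yr
  traditional <- inputs$traditional_fraction_of_national * (total_t_yr - imported)
  exempt <- traditional + imported
  regulated <- total_t_yr - exempt

  out <- list(
    total_t_yr = total_t_yr,
    imported_prepackaged_t_yr = imported,
    national_prepackaged_t_yr = national_prepackaged,
    loose_bakery_t_yr = loose,
    traditional_t_yr = traditional,
    exempt_t_yr = exempt,
    regulated_t_yr = regulated,
    shares = c(
      imported_prepackaged = imported / total_t_yr,
      national_prepackaged = national_prepackaged / total_t_yr,
      loose_bakery = loose / total_t_yr,
      exempt = exempt / total_t_yr,
      regulated = regulated / total_t_yr,
      traditional_of_exempt = if (exempt > 0) traditional / exempt else 0,
      imported_of_exempt = if (exempt > 0) imported / exempt else 0
    )
  )
  structure(out, class = "market_decomposition")
}

#' @export
print.market_decomposition <- function(x, ...) {
  cat("Bread market decomposition (tonnes/year)\n")
  fmt <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  pct <- function(v) sprintf("%.2f%%", 100 * v)
  cat("  total:               ", fmt(x$total_t_yr), "\n")
  cat(
    "  imported prepackaged:", fmt(x$imported_prepackaged_t_yr),
    sprintf("(%s)", pct(x$shares[["imported_prepackaged"]])), "\n"
  )
  cat(
    "  national prepackaged:", fmt(x$national_prepackaged_t_yr),
    sprintf("(%s)", pct(x$shares[["national_prepackaged"]])), "\n"
  )
  cat(
    "  loose bakery:        ", fmt(x$loose_bakery_t_yr),
    sprintf("(%s)", pct(x$shares[["loose_bakery"]])), "\n"
  )
  cat(
    "  exempt (trad + imp): ", fmt(x$exempt_t_yr),
    sprintf("(%s)", pct(x$shares[["exempt"]])), "\n"
  )
  cat(
    "  regulated:           ", fmt(x$regulated_t_yr),
    sprintf("(%s)", pct(x$shares[["regulated"]])), "\n"
  )
  invisible(x)
}

#' Baseline salt intake attributable to bread
#'
#' From total per-capita salt intake and the survey-based share of salt
#' coming from bread, derives per-capita bread salt and the implied mean
#' salt density of bread on the market.
#'
#' @param per_capita_salt_g_day Total salt intake, g/person/day.
#' @param bread_share_of_salt Fraction of salt intake coming from bread,
#'   in `[0, 1]`.
#' @param per_capita_bread_g_day Bread consumption, g/person/day.
#' @return An object of class `salt_baseline`: a list with the inputs plus
#'   `per_capita_bread_salt_g_day` and `mean_salt_density_g_per_100g`.
#' @export
#' @examples
#' salt_baseline(7.4, 0.182, 100.3) # implied density about 1.343 g/100 g
salt_baseline <- function(per_capita_salt_g_day = 7.4,
                          bread_share_of_salt = 0.182,
                          per_capita_bread_g_day = 100.3) {
  stopifnot(
    per_capita_salt_g_day >= 0,
    bread_share_of_salt >= 0, bread_share_of_salt <= 1,
    per_capita_bread_g_day >= 0
  )
  bread_salt <- bread_share_of_salt * per_capita_salt_g_day
  structure(
    list(
      per_capita_salt_g_day = per_capita_salt_g_day,
      bread_share_of_salt = bread_share_of_salt,
      per_capita_bread_g_day = per_capita_bread_g_day,
      per_capita_bread_salt_g_day = bread_salt,
      mean_salt_density_g_per_100g = implied_salt_density(
        bread_share_of_salt, per_capita_salt_g_day, per_capita_bread_g_day
      )
    ),
    class = "salt_baseline"
  )
}

#' Implied mean salt density of bread
#'
#' The market-wide mean salt content (g per 100 g bread) consistent with a
#' given share of total salt intake coming from bread.
#'
#' @inheritParams salt_baseline
#' @return Salt density in g per 100 g bread.
#' @export
#' @examples
#' implied_salt_density(0.182, 7.4, 100.3)
implied_salt_density <- function(bread_share_of_salt, per_capita_salt_g_day,
                                 per_capita_bread_g_day) {
  if (bread_share_of_salt == 0) {
    return(0)
  }
  if (per_capita_bread_g_day <= 0) {
    stop("bread intake must be positive when bread contributes salt",
      call. = FALSE
    )
  }
  bread_share_of_salt * per_capita_salt_g_day / per_capita_bread_g_day * 100
}

#' Solve a salt-density closure with one free segment
#'
#' Given segment weights and densities with exactly one unknown (`NA`),
#' solves for the unknown density so that the weighted mean equals
#' `target_mean`.
#'
#' @param weights Non-negative segment weights (need not sum to one; they
#'   are normalised internally).
#' @param densities Segment salt densities (g/100 g) with exactly one `NA`.
#' @param target_mean The weight-averaged density the closure must hit.
#' @return The `densities` vector with the `NA` replaced by the solution.
#' @export
#' @examples
#' solve_segment_closure(c(0.5, 0.5), c(1.0, NA), 1.2) # free segment 1.4
solve_segment_closure <- function(weights, densities, target_mean) {
  stopifnot(length(weights) == length(densities), all(weights >= 0))
  free <- which(is.na(densities))
  if (length(free) != 1L) {
    stop("exactly one density must be NA (the free segment)", call. = FALSE)
  }
  w <- weights / sum(weights)
  if (w[free] == 0) {
    stop("free segment has zero weight; closure is underdetermined",
      call. = FALSE
    )
  }
  fixed_mass <- sum(w[-free] * densities[-free])
  densities[free] <- (target_mean - fixed_mass) / w[free]
  densities
}

#' Calibrate per-segment salt densities
#'
#' Splits the regulated market into a compliant part (at the voluntary
#' salt level, default 1.0 g/100 g) and a non-compliant part (at the legal
#' maximum, default 1.4 g/100 g), then solves for the exempt-segment
#' density so that the tonnage-weighted mean over all segments equals the
#' survey-implied market mean. The exempt density is the free parameter of
#' the closure because no direct measurements of traditional or imported
#' bread salt content exist.
#'
#' @param decomp A [decompose_market()] result.
#' @param mean_density_g_per_100g Market-wide mean salt density (g/100 g),
#'   typically `salt_baseline(...)$mean_salt_density_g_per_100g`.
#' @param compliance_fraction Fraction of the regulated segment at
#'   `compliant_level`; the remainder sits at `noncompliant_level`.
#' @param compliant_level Salt density of compliant regulated bread,
#'   g/100 g.
#' @param noncompliant_level Salt density of non-compliant regulated bread,
#'   g/100 g (default: the 1.4 g legal maximum).
#' @param max_plausible_density Calibration guard: an exempt density above
#'   this (or below zero) aborts with an error.
#'
#' @return An object of class `segment_salt`: a tibble with columns
#'   `segment`, `tonnes_per_year`, `weight`, `salt_g_per_100g`, `exempt`.
#' @export
#' @examples
#' mi <- market_inputs(100.3, 10.3e6,
#'   prepackaged_sold_t_yr = 40040, imported_t_yr = 21764,
#'   traditional_fraction_of_national = 0.45,
#'   bakery_compliance_fraction = 0.76
#' )
#' dec <- decompose_market(mi, total_t_yr = 376218)
#' calibrate_segment_salt(dec, 1.3428, compliance_fraction = 0.76)
calibrate_segment_salt <- function(decomp,
                                   mean_density_g_per_100g,
                                   compliance_fraction,
                                   compliant_level = 1.0,
                                   noncompliant_level = 1.4,
                                   max_plausible_density = 10) {
  stopifnot(
    inherits(decomp, "market_decomposition"),
    mean_density_g_per_100g > 0,
    compliance_fraction >= 0, compliance_fraction <= 1
  )
  reg <- decomp$regulated_t_yr
  tonnes <- c(
    regulated_compliant = reg * compliance_fraction,
    regulated_noncompliant = reg * (1 - compliance_fraction),
    exempt = decomp$exempt_t_yr
  )
  dens <- c(compliant_level, noncompliant_level, NA_real_)
  dens <- solve_segment_closure(tonnes, dens, mean_density_g_per_100g)
  exempt_density <- dens[3L]
  if (exempt_density < 0 || exempt_density > max_plausible_density) {
    stop(
      sprintf(
        "calibrated exempt-segment density %.3f g/100 g is implausible",
        exempt_density
      ),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    segment = names(tonnes),
    tonnes_per_year = unname(tonnes),
    weight = unname(tonnes) / sum(tonnes),
    salt_g_per_100g = dens,
    exempt = c(FALSE, FALSE, TRUE)
  )
  class(out) <- c("segment_salt", class(out))
  out
}

#' Define a salt-limit policy scenario
#'
#' @param threshold_g_per_100g Legal maximum salt density, g per 100 g bread.
#' @param scope Which bread the limit applies to: `"all_bread"` (exemptions
#'   removed) or `"non_exempt_only"` (current legal scope).
#' @param label Scenario label used in reports.
#' @return An object of class `salt_scenario`.
#' @export
#' @examples
#' salt_scenario(1.0, "all_bread", label = "proposed limit, no exemptions")
salt_scenario <- function(threshold_g_per_100g,
                          scope = c("all_bread", "non_exempt_only"),
                          label = NULL) {
  scope <- match.arg(scope)
  stopifnot(is.numeric(threshold_g_per_100g), threshold_g_per_100g > 0)
  if (is.null(label)) {
    label <- sprintf("cap %.1f g/100 g (%s)", threshold_g_per_100g, scope)
  }
  structure(
    list(
      threshold_g_per_100g = threshold_g_per_100g,
      scope = scope, label = label
    ),
    class = "salt_scenario"
  )
}

#' Counterfactual salt-intake reduction under a scenario
#'
#' Caps every in-scope segment at the scenario threshold (segments already
#' below it are untouched), aggregates the tonnage-weighted density excess,
#' and converts it into g/person/day and tonnes of salt per day.
#'
#' The per-capita reduction is computed on the consumption side
#' (density excess times per-capita bread intake), and the tonnes/day figure
#' follows by the exact identity `t/day = g/capita/day * population / 1e6`,
#' so the two reported numbers are always mutually consistent.
#'
#' @param segment_salt A [calibrate_segment_salt()] table (or any
#'   `segment_salt` tibble with `weight`, `salt_g_per_100g`, `exempt`).
#' @param scenario A [salt_scenario()].
#' @param baseline A [salt_baseline()] object.
#' @param population Persons, for the per-capita/tonnage conversion.
#' @return An object of class `reduction_result`: a list with
#'   `salt_reduction_g_capita_day`, `salt_reduction_t_day`,
#'   `baseline_intake_g_capita_day`, `counterfactual_intake_g_capita_day`,
#'   and a `per_segment` tibble with baseline and counterfactual densities.
#' @export
#' @examples
#' mi <- market_inputs(100.3, 10.3e6,
#'   prepackaged_sold_t_yr = 40040, imported_t_yr = 21764,
#'   traditional_fraction_of_national = 0.45,
#'   bakery_compliance_fraction = 0.76
#' )
#' dec <- decompose_market(mi, total_t_yr = 376218)
#' bl <- salt_baseline(7.4, 0.182, 100.3)
#' seg <- calibrate_segment_salt(dec, bl$mean_salt_density_g_per_100g, 0.76)
#' scenario_reduction(seg, salt_scenario(1.0, "all_bread"), bl, 10.3e6)
scenario_reduction <- function(segment_salt, scenario, baseline, population) {
  stopifnot(
    inherits(segment_salt, "segment_salt"),
    inherits(scenario, "salt_scenario"),
    inherits(baseline, "salt_baseline"),
    population > 0
  )
  in_scope <- if (scenario$scope == "all_bread") {
    rep(TRUE, nrow(segment_salt))
  } else {
    !segment_salt$exempt
  }
  excess <- pmax(0, segment_salt$salt_g_per_100g - scenario$threshold_g_per_100g)
  excess[!in_scope] <- 0
  cf_density <- segment_salt$salt_g_per_100g - excess

  # g salt / 100 g bread, averaged over the whole market
  mean_excess <- sum(segment_salt$weight * excess)
  red_g_capita <- mean_excess * baseline$per_capita_bread_g_day / 100
  red_t_day <- per_capita_to_tons_per_day(red_g_capita, population)

  per_segment <- dplyr::mutate(
    tibble::as_tibble(segment_salt),
    in_scope = in_scope,
    salt_g_per_100g_counterfactual = cf_density,
    reduction_t_day = .data$weight * excess *
      baseline$per_capita_bread_g_day / 100 * population / 1e6
  )
  structure(
    list(
      scenario = scenario,
      salt_reduction_g_capita_day = red_g_capita,
      salt_reduction_t_day = red_t_day,
      baseline_intake_g_capita_day = baseline$per_capita_salt_g_day,
      counterfactual_intake_g_capita_day =
        baseline$per_capita_salt_g_day - red_g_capita,
      per_segment = per_segment
    ),
    class = "reduction_result"
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("Scenario: %s\n", x$scenario$label))
  cat(sprintf(
    "  salt reduction: %.3f g/capita/day (%.2f t/day)\n",
    x$salt_reduction_g_capita_day, x$salt_reduction_t_day
  ))
  cat(sprintf(
    "  intake: %.2f -> %.2f g/capita/day\n",
    x$baseline_intake_g_capita_day, x$counterfactual_intake_g_capita_day
  ))
  invisible(x)
}

#' Convert tonnes of salt per day to g per capita per day
#'
#' @param tonnes_day Tonnes/day.
#' @param population Persons; must be positive.
#' @return g/person/day.
#' @export
#' @examples
#' tons_per_day_to_per_capita(3.6, 10.3e6) # about 0.35 g/day
tons_per_day_to_per_capita <- function(tonnes_day, population) {
  if (population <= 0) stop("population must be positive", call. = FALSE)
  tonnes_day * 1e6 / population
}

#' Convert g per capita per day to tonnes per day
#'
#' Inverse of [tons_per_day_to_per_capita()].
#' @param g_capita_day g/person/day.
#' @inheritParams tons_per_day_to_per_capita
#' @return Tonnes/day.
#' @export
per_capita_to_tons_per_day <- function(g_capita_day, population) {
  if (population <= 0) stop("population must be positive", call. = FALSE)
  g_capita_day * population / 1e6
}
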