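#' Configuration for the synthetic-data generator
#'
#' Controls the seeded generator that emulates the stratified
#' demographic/mortality table the mortality model consumes (5-year age
#' bands by sex, population, and deaths for the salt-related causes) and a
#' matching dose-response parameter set with known truth.
#'
#' @param seed Integer seed; all generated output is deterministic under it.
#' @param n_age_bands Number of 5-year age bands, terminal band open-ended
#'   (default 18: 0-4 through 85+).
#' @param causes Cause labels (default [salt_related_causes()]).
#' @param total_population Total population across all strata.
#' @param cause_totals Named vector of expected national deaths per cause
#'   before scaling. Defaults are synthetic magnitudes plausible for a
#'   southern-European country of ten million people.
#' @param total_deaths_scale Multiplier on all expected death counts
#'   (0 gives an all-zero mortality table).
#' @param dispersion Negative-binomial size parameter for death-count noise
#'   (larger = closer to the expected counts).
#' @param exposure_mean Baseline salt intake, g/day.
#' @param exposure_sd Exposure standard deviation, g/day (0 = point mass).
#' @param beta_truth Named vector of true log-RR slopes per g/day salt, one
#'   per cause; recycled to all causes if length 1.
#' @param se_scale Standard errors are `se_scale * |beta_truth|`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_age_bands = 18,
                             causes = salt_related_causes(),
                             total_population = 10.3e6,
                             cause_totals = NULL,
                             total_deaths_scale = 1,
                             dispersion = 100,
                             exposure_mean = 7.4,
                             exposure_sd = 0,
                             beta_truth = NULL,
                             se_scale = 0.25) {
  stopifnot(
    n_age_bands >= 2, total_population >= 0,
    total_deaths_scale >= 0, dispersion > 0,
    exposure_mean >= 0, exposure_sd >= 0, se_scale >= 0
  )
  if (is.null(cause_totals)) {
    defaults <- c(
      cerebrovascular_disease = 10900,
      ischaemic_heart_disease = 6800,
      heart_failure = 4300,
      aortic_aneurysm = 500,
      pulmonary_embolism = 600,
      rheumatic_heart_disease = 200,
      hypertensive_disease = 5100
    )
    cause_totals <- defaults[causes]
    cause_totals[is.na(cause_totals)] <- 1000
    names(cause_totals) <- causes
  }
  if (is.null(beta_truth)) {
    beta_truth <- stats::setNames(rep(log(1.03), length(causes)), causes)
  }
  if (length(beta_truth) == 1L && is.null(names(beta_truth))) {
    beta_truth <- stats::setNames(rep(beta_truth, length(causes)), causes)
  }
  if (!all(causes %in% names(beta_truth))) {
    stop("`beta_truth` must name every cause", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_age_bands = as.integer(n_age_bands),
      causes = causes, total_population = total_population,
      cause_totals = cause_totals, total_deaths_scale = total_deaths_scale,
      dispersion = dispersion, exposure_mean = exposure_mean,
      exposure_sd = exposure_sd, beta_truth = beta_truth[causes],
      se_scale = se_scale
    ),
    class = "synthetic_config"
  )
}

#' Generate a stratified population/mortality table
#'
#' Emulates a national age/sex mortality table: population plateaus through
#' mid-life and declines logistically at old age, with the female decline
#' set later than the male one so the oldest bands carry a female excess.
#' Cardiovascular death rates rise exponentially with age (Gompertz-like)
#' with a male rate excess; expected counts are normalised to the
#' configured per-cause national totals, scaled by `total_deaths_scale`,
#' and observed counts are drawn from a seeded negative binomial around
#' them.
#'
#' @param cfg A [synthetic_config()].
#' @return A long-format tibble with columns `age_low`, `age_high` (`NA`
#'   for the open terminal band), `sex`, `population`, `cause`, `deaths` —
#'   the schema consumed by [deaths_averted()].
#' @export
#' @examples
#' strata <- generate_strata(synthetic_config(seed = 7))
#' nrow(strata) # 18 bands x 2 sexes x 7 causes
generate_strata <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_age_bands
  age_low <- (seq_len(n) - 1L) * 5
  age_high <- c(age_low[-1L], NA_real_)
  mid <- ifelse(is.na(age_high), age_low + 5, (age_low + age_high) / 2)

  # population shape: plateau then logistic decline; females decline later
  pop_weight <- function(center) 1 / (1 + exp((mid - center) / 7))
  w_m <- pop_weight(71)
  w_f <- pop_weight(78)
  pop_m <- round(cfg$total_population * 0.49 * w_m / sum(w_m))
  pop_f <- round(cfg$total_population * 0.51 * w_f / sum(w_f))

  base <- tibble::tibble(
    age_low = rep(age_low, 2L),
    age_high = rep(age_high, 2L),
    sex = rep(c("male", "female"), each = n),
    population = c(pop_m, pop_f)
  )

  # Gompertz-like CVD mortality rate, male excess
  rate <- exp(0.095 * (rep(mid, 2L) - 85))
  rate <- rate * ifelse(base$sex == "male", 1.5, 1.0)
  expected_shape <- base$population * rate

  set.seed(cfg$seed)
  rows <- lapply(cfg$causes, function(cz) {
    mu <- expected_shape / sum(expected_shape) *
      cfg$cause_totals[[cz]] * cfg$total_deaths_scale
    deaths <- stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu)
    dplyr::mutate(base, cause = cz, deaths = as.double(deaths))
  })
  dplyr::bind_rows(rows)
}

#' Generate a dose-response table with known truth
#'
#' One direct-pathway entry per cause with `beta = beta_truth[cause]`,
#' `se = se_scale * |beta|` and reference exposure at the configured
#' baseline mean, so downstream estimates can be checked against the
#' closed-form potential impact fraction.
#'
#' @param cfg A [synthetic_config()].
#' @return A dose-response tibble (see [dose_response()]).
#' @export
generate_dose_response <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dplyr::bind_rows(lapply(cfg$causes, function(cz) {
    b <- cfg$beta_truth[[cz]]
    dose_response(cz,
      pathway = "direct", beta = b, se = cfg$se_scale * abs(b),
      reference_exposure = cfg$exposure_mean
    )
  }))
}

#' Portuguese 2016 market fixture
#'
#' The published national constants the main analysis runs from: mean bread
#' intake 100.3 g/person/day, salt intake 7.4 g/person/day with 18.2% from
#' bread, 40,040 t/yr of pre-packaged bread sold of which 21,764 t/yr
#' imported, 45% of national production classified as traditional, 76%
#' bakery compliance with the voluntary 1.0 g/100 g level, a population of
#' 10,300,000, and the published annual total of 376,218 t of bread. The
#' published total is carried separately because multiplying the printed
#' per-capita intake by the rounded population gives about 377,336 t; the
#' published figure implies an unrounded population near 10.27 million.
#'
#' @return A list with `inputs` ([market_inputs()]), `baseline`
#'   ([salt_baseline()]), `total_t_yr_published`, and `battery`
#'   (the [default_battery()] scenario list).
#' @export
#' @examples
#' fx <- portugal_market_fixture()
#' decompose_market(fx$inputs, fx$total_t_yr_published)
portugal_market_fixture <- function() {
  inputs <- market_inputs(
    per_capita_bread_g_day = 100.3,
    population = 10300000,
    days_per_year = 365.25,
    prepackaged_sold_t_yr = 40040,
    imported_t_yr = 21764,
    traditional_fraction_of_national = 0.45,
    bakery_compliance_fraction = 0.76
  )
  list(
    inputs = inputs,
    baseline = salt_baseline(7.4, 0.182, 100.3),
    total_t_yr_published = 376218,
    battery = default_battery()
  )
}

#' Default dose-response parameter set
#'
#' A salt-to-blood-pressure-to-mortality parameterisation assembled from
#' published meta-analyses of sodium trials and prospective blood-pressure
#' cohorts: age-specific systolic blood pressure response per g/day of salt
#' (stronger at older ages) composed with age-specific log relative risks
#' per mmHg for each cardiovascular cause. Shipped as a plain-text table in
#' `extdata`; treat it as a reasonable default, not a calibrated national
#' parameter file — package tests never rely on these values.
#'
#' @return A dose-response tibble.
#' @export
default_dose_response <- function() {
  path <- system.file("extdata", "dose_response_default.csv",
    package = "saltimpact"
  )
  if (!nzchar(path)) stop("default dose-response file not found", call. = FALSE)
  read_dose_response(path)
}
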