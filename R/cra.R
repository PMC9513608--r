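#' The seven salt-related causes of death
#'
#' Cardiovascular causes with an established link to sodium intake, used as
#' the default cause list throughout the package.
#'
#' @return Character vector of cause labels.
#' @export
salt_related_causes <- function() {
  c(
    "cerebrovascular_disease",
    "ischaemic_heart_disease",
    "heart_failure",
    "aortic_aneurysm",
    "pulmonary_embolism",
    "rheumatic_heart_disease",
    "hypertensive_disease"
  )
}

#' Build a dose-response entry
#'
#' One row of a dose-response table: a log-linear relative-risk slope per
#' g/day of salt for one cause, either acting directly on mortality
#' (`pathway = "direct"`) or mediated through systolic blood pressure
#' (`pathway = "sbp_mediated"`, where the effective slope is
#' `sbp_slope * beta_sbp`: mmHg per g salt times log-RR per mmHg).
#' Optional age/sex qualifiers restrict the row to matching strata.
#'
#' @param cause Cause label.
#' @param pathway `"direct"` or `"sbp_mediated"`.
#' @param beta Log relative risk per g/day salt (direct pathway).
#' @param sbp_slope mmHg systolic blood pressure per g/day salt
#'   (sbp_mediated pathway).
#' @param beta_sbp Log relative risk per mmHg (sbp_mediated pathway).
#' @param se Standard error of the effective log-RR slope (per g/day salt);
#'   0 means the slope is treated as known.
#' @param reference_exposure Exposure at which RR = 1, g/day.
#' @param age_low,age_high Optional age qualifiers: the row applies to
#'   strata whose lower age bound falls in `[age_low, age_high)`. Defaults
#'   cover all ages.
#' @param sex Optional sex qualifier (`"male"`/`"female"`); `NA` matches both.
#' @return A one-row tibble; bind rows to build a dose-response table.
#' @export
#' @examples
#' dose_response("ischaemic_heart_disease", beta = log(1.05), se = 0.01,
#'   reference_exposure = 7.4)
dose_response <- function(cause,
                          pathway = c("direct", "sbp_mediated"),
                          beta = NA_real_,
                          sbp_slope = NA_real_,
                          beta_sbp = NA_real_,
                          se = 0,
                          reference_exposure,
                          age_low = 0,
                          age_high = Inf,
                          sex = NA_character_) {
  pathway <- match.arg(pathway)
  if (pathway == "direct" && is.na(beta)) {
    stop("direct pathway requires `beta`", call. = FALSE)
  }
  if (pathway == "sbp_mediated" && (is.na(sbp_slope) || is.na(beta_sbp))) {
    stop("sbp_mediated pathway requires `sbp_slope` and `beta_sbp`",
      call. = FALSE
    )
  }
  if (se < 0) stop("`se` must be non-negative", call. = FALSE)
  tibble::tibble(
    cause = cause, pathway = pathway,
    beta = beta, sbp_slope = sbp_slope, beta_sbp = beta_sbp,
    se = se, reference_exposure = reference_exposure,
    age_low = age_low, age_high = age_high, sex = sex
  )
}

#' Effective log-RR slope per g/day salt
#'
#' Direct pathway: `beta`. SBP-mediated pathway: `sbp_slope * beta_sbp`.
#'
#' @param dr A dose-response table (any number of rows).
#' @return Numeric vector of effective slopes, one per row.
#' @export
effective_beta <- function(dr) {
  ifelse(dr$pathway == "sbp_mediated", dr$sbp_slope * dr$beta_sbp, dr$beta)
}

#' Relative risk at a given exposure
#'
#' Log-linear model: `RR = exp(beta_eff * (exposure - reference))`, so that
#' RR at the reference exposure is exactly 1.
#'
#' @param exposure Salt intake, g/day (vectorised).
#' @param dr A one-row dose-response table.
#' @return Relative risk (dimensionless).
#' @export
#' @examples
#' dr <- dose_response("x", beta = log(1.05), reference_exposure = 7.4)
#' relative_risk(9.4, dr) # 1.05^2
relative_risk <- function(exposure, dr) {
  stopifnot(nrow(dr) == 1L)
  exp(effective_beta(dr) * (exposure - dr$reference_exposure))
}

#' Exposure distribution of salt intake
#'
#' Either a point mass at the mean (the deterministic shift used for the
#' headline scenarios) or a normal distribution truncated at 0 g/day.
#'
#' @param mean Mean salt intake, g/day.
#' @param sd Standard deviation, g/day; 0 forces the point family.
#' @param family `"point"` or `"normal"`.
#' @return An object of class `exposure_distribution`.
#' @export
exposure_distribution <- function(mean, sd = 0,
                                  family = if (sd > 0) "normal" else "point") {
  family <- match.arg(family, c("point", "normal"))
  stopifnot(sd >= 0, mean >= 0)
  if (sd == 0) family <- "point"
  structure(list(family = family, mean = mean, sd = sd),
    class = "exposure_distribution"
  )
}

#' Population-mean relative risk under an exposure distribution
#'
#' `E[RR(X)]` for the log-linear model. Point family: `RR(mean)`. Normal
#' family: Gauss-Hermite quadrature of fixed order; with `truncate = TRUE`
#' (default) the density is truncated at 0 g/day and renormalised by
#' discarding quadrature nodes below zero. For the untruncated normal the
#' quadrature reproduces the log-normal-mean closed form
#' `exp(beta * (mu - ref) + beta^2 * sigma^2 / 2)`.
#'
#' @param dist An [exposure_distribution()].
#' @param dr A one-row dose-response table.
#' @param order Gauss-Hermite quadrature order (default 64).
#' @param truncate Truncate the normal at 0 g/day (default `TRUE`).
#' @return Mean relative risk (dimensionless, > 0).
#' @export
#' @examples
#' dr <- dose_response("x", beta = 0.1, reference_exposure = 0)
#' mean_rr(exposure_distribution(5, 1), dr, truncate = FALSE) # exp(0.505)
mean_rr <- function(dist, dr, order = 64, truncate = TRUE) {
  stopifnot(inherits(dist, "exposure_distribution"), nrow(dr) == 1L)
  if (dist$family == "point" || dist$sd == 0) {
    return(relative_risk(dist$mean, dr))
  }
  gh <- gauss_hermite_rule(order)
  x <- dist$mean + sqrt(2) * dist$sd * gh$x
  w <- gh$w / sqrt(pi)
  if (truncate) {
    keep <- x >= 0
    if (!any(keep)) stop("exposure distribution has no mass above 0", call. = FALSE)
    x <- x[keep]
    w <- w[keep] / sum(w[keep])
  }
  val <- sum(w * relative_risk(x, dr))
  if (!is.finite(val)) stop("quadrature did not converge", call. = FALSE)
  val
}

# cached Gauss-Hermite nodes/weights per order
gh_cache <- new.env(parent = emptyenv())
gauss_hermite_rule <- function(order) {
  key <- as.character(order)
  if (is.null(gh_cache[[key]])) {
    gh_cache[[key]] <- pracma::gaussHermite(order)
  }
  gh_cache[[key]]
}

#' Potential impact fraction
#'
#' Proportional change in deaths when the exposure distribution shifts from
#' `baseline` to `counterfactual`:
#' `PIF = 1 - E_cf[RR] / E_base[RR]`.
#' For a pure mean shift `delta` with equal variances and a log-linear RR
#' (untruncated), this reduces exactly to `1 - exp(beta * delta)`.
#'
#' @param baseline,counterfactual [exposure_distribution()] objects.
#' @param dr A one-row dose-response table.
#' @param ... Passed on to [mean_rr()] (`order`, `truncate`).
#' @return A dimensionless fraction in `(-Inf, 1]`; negative values mean
#'   the counterfactual is harmful.
#' @export
#' @examples
#' dr <- dose_response("x", beta = log(1.05), reference_exposure = 7.4)
#' impact_fraction(
#'   exposure_distribution(7.4), exposure_distribution(7.05), dr
#' ) # 1 - 1.05^(-0.35)
impact_fraction <- function(baseline, counterfactual, dr, ...) {
  1 - mean_rr(counterfactual, dr, ...) / mean_rr(baseline, dr, ...)
}

#' Match dose-response rows to strata
#'
#' For every (cause, age, sex) combination present in `strata`, finds the
#' unique dose-response row whose cause matches and whose age/sex
#' qualifiers cover the stratum. Errors if a combination has no match or
#' several.
#'
#' @param strata Long-format mortality table (see [deaths_averted()]).
#' @param dose_responses Dose-response table.
#' @return Integer vector: row index into `dose_responses` per strata row.
#' @keywords internal
match_dose_response <- function(strata, dose_responses) {
  dr <- dose_responses
  idx <- vapply(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    hit <- which(
      dr$cause == s$cause &
        (is.na(dr$sex) | dr$sex == s$sex) &
        dr$age_low <= s$age_low &
        s$age_low < dr$age_high
    )
    if (length(hit) == 0L) {
      stop(
        sprintf(
          "no dose-response entry for cause '%s' (age %s, sex %s)",
          s$cause, s$age_low, s$sex
        ),
        call. = FALSE
      )
    }
    if (length(hit) > 1L) {
      stop(
        sprintf(
          "ambiguous dose-response entries for cause '%s' (age %s, sex %s)",
          s$cause, s$age_low, s$sex
        ),
        call. = FALSE
      )
    }
    hit
  }, integer(1))
  idx
}

#' Deaths averted under a counterfactual salt-intake shift
#'
#' Applies the potential impact fraction per stratum and cause:
#' `averted = deaths * PIF`, then aggregates to totals, by sex, by cause,
#' and for the under-75 population (age bands whose upper bound is at most
#' 75).
#'
#' @param strata Long-format tibble with columns `age_low`, `age_high`
#'   (`NA` = open-ended terminal band), `sex` (`"male"`/`"female"`),
#'   `population`, `cause`, `deaths`.
#' @param dose_responses Dose-response table covering every cause present.
#' @param baseline_mean Baseline mean salt intake, g/day.
#' @param shift Signed change in mean intake, g/day (negative = reduction).
#' @param sd Common standard deviation of the exposure distribution
#'   (default 0: point mass, the deterministic-shift model).
#' @param ... Passed on to [mean_rr()].
#' @return An object of class `impact_estimate`: a list with
#'   `deaths_averted_total`, `by_sex`, `by_cause`, `under_75` (by sex), and
#'   the `per_stratum` tibble carrying `pif` and `averted` per row.
#' @export
#' @examples
#' strata <- tibble::tibble(
#'   age_low = 65, age_high = 70, sex = "female", population = 1e5,
#'   cause = "ischaemic_heart_disease", deaths = 1000
#' )
#' dr <- dose_response("ischaemic_heart_disease", beta = log(1.05),
#'   reference_exposure = 7.4)
#' deaths_averted(strata, dr, baseline_mean = 7.4, shift = -0.35)
deaths_averted <- function(strata, dose_responses, baseline_mean, shift,
                           sd = 0, ...) {
  validate_strata(strata)
  idx <- match_dose_response(strata, dose_responses)
  base <- exposure_distribution(baseline_mean, sd)
  cf <- exposure_distribution(max(0, baseline_mean + shift), sd)

  pif_by_dr <- vapply(
    unique(idx),
    function(j) impact_fraction(base, cf, dose_responses[j, ], ...),
    numeric(1)
  )
  names(pif_by_dr) <- as.character(unique(idx))
  pif <- unname(pif_by_dr[as.character(idx)])

  per_stratum <- dplyr::mutate(strata, pif = pif, averted = .data$deaths * pif)
  total <- sum(per_stratum$averted)
  by_sex <- vapply(
    split(per_stratum$averted, per_stratum$sex), sum,
    numeric(1)
  )
  by_cause <- vapply(
    split(per_stratum$averted, per_stratum$cause), sum,
    numeric(1)
  )
  u75 <- dplyr::filter(per_stratum, !is.na(.data$age_high), .data$age_high <= 75)
  under_75 <- vapply(
    split(u75$averted, factor(u75$sex, levels = sort(unique(per_stratum$sex)))),
    sum, numeric(1)
  )
  structure(
    list(
      deaths_averted_total = total,
      by_sex = by_sex,
      by_cause = by_cause,
      under_75 = under_75,
      per_stratum = per_stratum
    ),
    class = "impact_estimate"
  )
}

#' @export
print.impact_estimate <- function(x, ...) {
  cat(sprintf("Deaths averted: %.1f\n", x$deaths_averted_total))
  cat("  by sex:  ", paste(sprintf("%s %.1f", names(x$by_sex), x$by_sex),
    collapse = ", "
  ), "\n")
  cat("  under 75:", paste(
    sprintf("%s %.1f", names(x$under_75), x$under_75),
    collapse = ", "
  ), "\n")
  cat("  by cause:\n")
  for (nm in names(x$by_cause)) {
    cat(sprintf("    %-26s %8.1f\n", nm, x$by_cause[[nm]]))
  }
  invisible(x)
}

validate_strata <- function(strata) {
  needed <- c("age_low", "age_high", "sex", "population", "cause", "deaths")
  missing <- setdiff(needed, names(strata))
  if (length(missing)) {
    stop("strata table lacks columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(strata$population < 0, na.rm = TRUE) ||
    any(strata$deaths < 0, na.rm = TRUE)) {
    stop("population and deaths must be non-negative", call. = FALSE)
  }
  if (!all(strata$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  invisible(strata)
}
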