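# Shared miniature fixtures, built in code.

pt_inputs <- function() {
  market_inputs(
    per_capita_bread_g_day = 100.3,
    population = 10.3e6,
    prepackaged_sold_t_yr = 40040,
    imported_t_yr = 21764,
    traditional_fraction_of_national = 0.45,
    bakery_compliance_fraction = 0.76
  )
}

PT_TOTAL_T <- 376218

one_stratum <- function(deaths = 1000, cause = "ischaemic_heart_disease",
                        age_low = 65, age_high = 70, sex = "female") {
  tibble::tibble(
    age_low = age_low, age_high = age_high, sex = sex,
    population = 1e5, cause = cause, deaths = deaths
  )
}

simple_dr <- function(beta = log(1.05), se = 0, cause = "ischaemic_heart_disease",
                      ref = 7.4) {
  dose_response(cause, beta = beta, se = se, reference_exposure = ref)
}
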