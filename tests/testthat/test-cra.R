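test_that("relative risk is 1 at the reference and compounds log-linearly", {
  dr <- simple_dr(beta = log(1.05))
  expect_equal(relative_risk(7.4, dr), 1.0)
  expect_equal(relative_risk(7.4 + 2, dr), 1.05^2)
  dr0 <- simple_dr(beta = 0)
  expect_equal(relative_risk(c(0, 5, 20), dr0), c(1, 1, 1))
})

test_that("sbp-mediated slopes compose the two stages", {
  dr <- dose_response("hypertensive_disease",
    pathway = "sbp_mediated",
    sbp_slope = 0.8, beta_sbp = 0.04, reference_exposure = 7.4
  )
  expect_equal(effective_beta(dr), 0.8 * 0.04)
  expect_equal(relative_risk(8.4, dr), exp(0.032))
  expect_error(
    dose_response("x", pathway = "sbp_mediated", reference_exposure = 7.4),
    "sbp_slope"
  )
})

test_that("mean RR under a normal exposure matches the log-normal closed form", {
  # E[exp(bX)] = exp(b*mu + b^2 sigma^2 / 2) for untruncated normal
  dr <- dose_response("x", beta = 0.1, reference_exposure = 0)
  m <- mean_rr(exposure_distribution(5, 1), dr, truncate = FALSE)
  expect_equal(m, exp(0.1 * 5 + 0.01 / 2), tolerance = 1e-9)
  expect_equal(round(m, 4), round(exp(0.505), 4))

  for (beta in c(-0.5, -0.1, 0.05, 0.3)) {
    for (sigma in c(0.2, 1, 2)) {
      if (abs(beta) * sigma > 1) next
      drb <- dose_response("x", beta = beta, reference_exposure = 7.4)
      got <- mean_rr(exposure_distribution(9, sigma), drb, truncate = FALSE)
      want <- exp(beta * (9 - 7.4) + beta^2 * sigma^2 / 2)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("degenerate and point exposures coincide", {
  dr <- simple_dr(beta = 0.2)
  expect_equal(
    mean_rr(exposure_distribution(6.5, 0), dr),
    relative_risk(6.5, dr)
  )
  expect_equal(
    mean_rr(exposure_distribution(6.5, 0, family = "normal"), dr),
    relative_risk(6.5, dr)
  )
})

test_that("truncation at zero is negligible in the dietary-intake regime", {
  dr <- simple_dr(beta = 0.1)
  d <- exposure_distribution(7.4, 1)
  expect_equal(
    mean_rr(d, dr, truncate = TRUE),
    mean_rr(d, dr, truncate = FALSE),
    tolerance = 1e-8
  )
})

test_that("impact fraction has the closed form for a pure mean shift", {
  dr <- simple_dr(beta = log(1.05))
  base <- exposure_distribution(7.4)
  expect_equal(impact_fraction(base, base, dr), 0)
  pif <- impact_fraction(base, exposure_distribution(7.05), dr)
  expect_equal(pif, 1 - 1.05^(-0.35))
  expect_equal(round(pif, 5), 0.01693)
  # upward shift with harmful exposure: negative PIF
  expect_lt(impact_fraction(base, exposure_distribution(8.4), dr), 0)
})

test_that("deaths averted equals deaths times the closed-form PIF", {
  ie <- deaths_averted(one_stratum(1000), simple_dr(), 7.4, -0.35)
  expect_equal(ie$deaths_averted_total, 1000 * (1 - 1.05^(-0.35)))
  expect_equal(round(ie$deaths_averted_total, 2), 16.93)

  # zero shift, zero effect
  expect_equal(
    deaths_averted(one_stratum(1000), simple_dr(), 7.4, 0)$deaths_averted_total,
    0
  )
  expect_equal(
    deaths_averted(
      one_stratum(1000), simple_dr(beta = 0), 7.4, -0.35
    )$deaths_averted_total,
    0
  )
})

test_that("impact estimates are additive and scale-equivariant", {
  st1 <- one_stratum(1000)
  st2 <- dplyr::bind_rows(st1, st1)
  dr <- simple_dr()
  a1 <- deaths_averted(st1, dr, 7.4, -0.35)$deaths_averted_total
  a2 <- deaths_averted(st2, dr, 7.4, -0.35)$deaths_averted_total
  expect_equal(a2, 2 * a1)

  st_k <- dplyr::mutate(st1, deaths = deaths * 7)
  expect_equal(
    deaths_averted(st_k, dr, 7.4, -0.35)$deaths_averted_total,
    7 * a1
  )
})

test_that("aggregates decompose the total consistently", {
  cfg <- synthetic_config(seed = 11, total_population = 2e6)
  strata <- generate_strata(cfg)
  drs <- generate_dose_response(cfg)
  ie <- deaths_averted(strata, drs, 7.4, -0.35)
  expect_equal(sum(ie$by_sex), ie$deaths_averted_total, tolerance = 1e-9)
  expect_equal(sum(ie$by_cause), ie$deaths_averted_total, tolerance = 1e-9)
  expect_true(all(ie$under_75 <= ie$by_sex[names(ie$under_75)]))
  # under-75 uses bands with an upper bound at or below 75
  u75 <- ie$per_stratum[!is.na(ie$per_stratum$age_high) &
    ie$per_stratum$age_high <= 75, ]
  expect_equal(sum(u75$averted), sum(ie$under_75))
})

test_that("monotonicity: larger downward shifts avert at least as many deaths", {
  cfg <- synthetic_config(seed = 3)
  strata <- generate_strata(cfg)
  drs <- generate_dose_response(cfg)
  shifts <- -c(0, 0.1, 0.35, 0.7, 1.5)
  averted <- vapply(shifts, function(s) {
    deaths_averted(strata, drs, 7.4, s)$deaths_averted_total
  }, numeric(1))
  expect_true(all(diff(averted) >= 0))
})

test_that("dose-response matching is strict", {
  st <- one_stratum(100, cause = "heart_failure")
  expect_error(
    deaths_averted(st, simple_dr(cause = "aortic_aneurysm"), 7.4, -0.35),
    "no dose-response entry"
  )
  dup <- dplyr::bind_rows(
    simple_dr(cause = "heart_failure"),
    simple_dr(cause = "heart_failure")
  )
  expect_error(deaths_averted(st, dup, 7.4, -0.35), "ambiguous")
})

test_that("age- and sex-qualified entries route strata correctly", {
  strata <- dplyr::bind_rows(
    one_stratum(100, age_low = 50, age_high = 55),
    one_stratum(100, age_low = 80, age_high = 85)
  )
  drs <- dplyr::bind_rows(
    dose_response("ischaemic_heart_disease",
      beta = log(1.10), reference_exposure = 7.4, age_low = 0, age_high = 65
    ),
    dose_response("ischaemic_heart_disease",
      beta = log(1.02), reference_exposure = 7.4, age_low = 65, age_high = Inf
    )
  )
  ie <- deaths_averted(strata, drs, 7.4, -1)
  expect_equal(
    ie$per_stratum$averted,
    100 * (1 - c(1.10, 1.02)^(-1))
  )
})
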