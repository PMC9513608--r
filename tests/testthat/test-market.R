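test_that("total annual bread follows the per-capita identity", {
  # direct arithmetic oracle: g/day * persons * days / 1e6
  expect_equal(
    total_annual_bread(100.3, 10.3e6, 365.25),
    100.3 * 10.3e6 * 365.25 / 1e6
  )
  expect_equal(round(total_annual_bread(100.3, 10.3e6, 365.25)), 377336)
  expect_equal(total_annual_bread(100.3, 0), 0)
  expect_equal(total_annual_bread(0, 10.3e6), 0)
  expect_error(total_annual_bread(-1, 10), "non-negative")
})

test_that("market decomposition reproduces the national 2016 segmentation", {
  dec <- decompose_market(pt_inputs(), total_t_yr = PT_TOTAL_T)
  expect_equal(dec$national_prepackaged_t_yr, 18276)
  expect_equal(round(dec$exempt_t_yr), 181268)
  expect_equal(round(100 * dec$shares[["exempt"]], 2), 48.18)
  expect_equal(round(100 * dec$shares[["national_prepackaged"]], 2), 4.86)
  expect_equal(round(100 * dec$shares[["loose_bakery"]], 2), 89.36)
  expect_equal(round(100 * dec$shares[["traditional_of_exempt"]]), 88)
  expect_equal(round(100 * dec$shares[["imported_of_exempt"]]), 12)
})

test_that("decomposition conserves tonnage and partitions exempt/regulated", {
  for (trad in c(0, 0.3, 0.45, 1)) {
    mi <- market_inputs(100.3, 10.3e6,
      prepackaged_sold_t_yr = 40040, imported_t_yr = 21764,
      traditional_fraction_of_national = trad,
      bakery_compliance_fraction = 0.76
    )
    dec <- decompose_market(mi, total_t_yr = PT_TOTAL_T)
    expect_equal(
      dec$imported_prepackaged_t_yr + dec$national_prepackaged_t_yr +
        dec$loose_bakery_t_yr,
      dec$total_t_yr,
      tolerance = 0.5 / PT_TOTAL_T
    )
    expect_equal(dec$exempt_t_yr + dec$regulated_t_yr, dec$total_t_yr)
    expect_equal(
      dec$traditional_t_yr,
      trad * (dec$total_t_yr - dec$imported_prepackaged_t_yr)
    )
  }
})

test_that("degenerate market with no pre-packaged bread is all loose", {
  mi <- market_inputs(100, 1e6,
    prepackaged_sold_t_yr = 0, imported_t_yr = 0,
    traditional_fraction_of_national = 0, bakery_compliance_fraction = 0.5
  )
  dec <- decompose_market(mi, total_t_yr = 50000)
  expect_equal(dec$loose_bakery_t_yr, 50000)
  expect_equal(dec$exempt_t_yr, 0)
})

test_that("inconsistent tonnages are rejected", {
  expect_error(
    market_inputs(100, 1e6,
      prepackaged_sold_t_yr = 10, imported_t_yr = 20,
      traditional_fraction_of_national = 0, bakery_compliance_fraction = 0.5
    ),
    "imported"
  )
  expect_error(
    decompose_market(pt_inputs(), total_t_yr = 30000),
    "exceed"
  )
  expect_error(
    market_inputs(100, 1e6,
      prepackaged_sold_t_yr = 10, imported_t_yr = 5,
      traditional_fraction_of_national = 1.2, bakery_compliance_fraction = 0.5
    ),
    "\\[0, 1\\]"
  )
})

test_that("implied salt density matches the intake-share arithmetic", {
  expect_equal(round(implied_salt_density(0.182, 7.4, 100.3), 4), 1.3428)
  expect_equal(implied_salt_density(0, 7.4, 100.3), 0)
  expect_equal(implied_salt_density(1.0, 7.4, 100.0), 7.4)
  expect_error(implied_salt_density(0.2, 7.4, 0), "positive")
})

test_that("segment closure solves the free density", {
  expect_equal(solve_segment_closure(c(0.5, 0.5), c(1.0, NA), 1.2), c(1.0, 1.4))
  # all-equal identity: free segment recovers the common density
  expect_equal(
    solve_segment_closure(c(0.2, 0.3, 0.5), c(1.1, 1.1, NA), 1.1),
    rep(1.1, 3)
  )
  expect_error(solve_segment_closure(c(1, 1), c(NA, NA), 1), "exactly one")
  expect_error(solve_segment_closure(c(1, 0), c(1, NA), 1), "zero weight")
})

test_that("calibration closes on the implied market mean", {
  dec <- decompose_market(pt_inputs(), total_t_yr = PT_TOTAL_T)
  dens <- implied_salt_density(0.182, 7.4, 100.3)
  seg <- calibrate_segment_salt(dec, dens, compliance_fraction = 0.76)
  # independently derived closure solution
  w_reg <- dec$regulated_t_yr / dec$total_t_yr
  w_ex <- dec$exempt_t_yr / dec$total_t_yr
  expected_exempt <- (dens - w_reg * (0.76 * 1.0 + 0.24 * 1.4)) / w_ex
  expect_equal(seg$salt_g_per_100g[seg$segment == "exempt"], expected_exempt)
  expect_equal(round(seg$salt_g_per_100g[seg$segment == "exempt"], 3), 1.608)
  # tonnage-weighted mean equals the implied density to 1e-9
  expect_equal(sum(seg$weight * seg$salt_g_per_100g), dens, tolerance = 1e-9)
})

test_that("implausible calibration is rejected", {
  dec <- decompose_market(pt_inputs(), total_t_yr = PT_TOTAL_T)
  expect_error(
    calibrate_segment_salt(dec, 0.5, compliance_fraction = 0.76),
    "implausible"
  )
  expect_error(
    calibrate_segment_salt(dec, 8, compliance_fraction = 0.76),
    "implausible"
  )
})

test_that("scenario reduction caps in-scope segments only", {
  dec <- decompose_market(pt_inputs(), total_t_yr = PT_TOTAL_T)
  bl <- salt_baseline(7.4, 0.182, 100.3)
  seg <- calibrate_segment_salt(dec, bl$mean_salt_density_g_per_100g, 0.76)

  # every segment already at/below the cap: nothing changes
  red0 <- scenario_reduction(seg, salt_scenario(2.0, "all_bread"), bl, 10.3e6)
  expect_equal(red0$salt_reduction_g_capita_day, 0)
  expect_equal(red0$counterfactual_intake_g_capita_day, 7.4)

  # cap on all bread at 1.0: weighted density excess times intake
  red <- scenario_reduction(seg, salt_scenario(1.0, "all_bread"), bl, 10.3e6)
  excess <- pmax(0, seg$salt_g_per_100g - 1.0)
  expect_equal(
    red$salt_reduction_g_capita_day,
    sum(seg$weight * excess) * 100.3 / 100
  )
  expect_equal(round(red$salt_reduction_g_capita_day, 3), 0.344)
  expect_equal(round(red$salt_reduction_t_day, 1), 3.5)

  # legal scope only: exempt segment untouched
  red_ne <- scenario_reduction(
    seg, salt_scenario(1.0, "non_exempt_only"), bl, 10.3e6
  )
  ex_row <- red_ne$per_segment[red_ne$per_segment$exempt, ]
  expect_equal(ex_row$salt_g_per_100g_counterfactual, ex_row$salt_g_per_100g)
  expect_lt(red_ne$salt_reduction_g_capita_day, red$salt_reduction_g_capita_day)
})

test_that("reduction is monotone in threshold and scope", {
  dec <- decompose_market(pt_inputs(), total_t_yr = PT_TOTAL_T)
  bl <- salt_baseline(7.4, 0.182, 100.3)
  seg <- calibrate_segment_salt(dec, bl$mean_salt_density_g_per_100g, 0.76)
  thresholds <- c(1.6, 1.4, 1.2, 1.0, 0.8)
  for (scope in c("all_bread", "non_exempt_only")) {
    reds <- vapply(thresholds, function(th) {
      scenario_reduction(seg, salt_scenario(th, scope), bl, 10.3e6)$salt_reduction_g_capita_day
    }, numeric(1))
    expect_true(all(diff(reds) >= 0)) # lower cap never reduces the reduction
  }
  for (th in thresholds) {
    r_all <- scenario_reduction(seg, salt_scenario(th, "all_bread"), bl, 10.3e6)
    r_ne <- scenario_reduction(seg, salt_scenario(th, "non_exempt_only"), bl, 10.3e6)
    expect_gte(
      r_all$salt_reduction_g_capita_day, r_ne$salt_reduction_g_capita_day
    )
  }
})

test_that("applying a scenario to its own counterfactual is idempotent", {
  dec <- decompose_market(pt_inputs(), total_t_yr = PT_TOTAL_T)
  bl <- salt_baseline(7.4, 0.182, 100.3)
  seg <- calibrate_segment_salt(dec, bl$mean_salt_density_g_per_100g, 0.76)
  sc <- salt_scenario(1.0, "all_bread")
  red <- scenario_reduction(seg, sc, bl, 10.3e6)
  seg2 <- seg
  seg2$salt_g_per_100g <- red$per_segment$salt_g_per_100g_counterfactual
  red2 <- scenario_reduction(seg2, sc, bl, 10.3e6)
  expect_equal(red2$salt_reduction_g_capita_day, 0)
})

test_that("per-capita unit conversions round-trip", {
  expect_equal(round(tons_per_day_to_per_capita(3.6, 10.3e6), 2), 0.35)
  expect_equal(tons_per_day_to_per_capita(0, 5e6), 0)
  expect_equal(tons_per_day_to_per_capita(10.3, 10.3e6), 1.0)
  for (t in c(0.01, 1.4, 3.6, 120)) {
    expect_equal(
      per_capita_to_tons_per_day(tons_per_day_to_per_capita(t, 10.3e6), 10.3e6),
      t
    )
  }
  expect_error(tons_per_day_to_per_capita(1, 0), "positive")
})
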