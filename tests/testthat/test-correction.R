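test_that("clock times parse as HH:MM or decimal hours", {
  expect_equal(parse_clock_time("9:30"), 9.5)
  expect_equal(parse_clock_time(c("14:45", "08:00")), c(14.75, 8))
  expect_equal(parse_clock_time(10.25), 10.25)
  expect_error(parse_clock_time("noon"), "cannot parse")
})

test_that("the single-case correction reproduces the canonical example", {
  # 3000 ml at 9:30, 3020 ml at 14:45, lower-leg coefficient 0.288 %/h
  res <- apply_time_correction(3000, "9:30", 3020, "14:45",
                               published_coefficients()$coeff_legBD)
  expect_equal(res$delta_t, 5.25)
  expect_equal(round(res$delta_pct_meas, 2), 0.67)
  expect_equal(round(res$delta_pct_corr, 2), -0.85)
  # the unrounded measured change must be carried into the formula: with the
  # displayed 0.67 the corrected change would wrongly be -0.84
  expect_equal(res$delta_pct_meas, 100 * 20 / 3000, tolerance = 1e-12)
  expect_equal(res$delta_pct_corr, 100 * 20 / 3000 - 0.288 * 5.25,
               tolerance = 1e-12)
  expect_equal(round(0.67 - 0.288 * 5.25, 2), -0.84)

  # identities: zero time difference or zero coefficient change nothing
  expect_equal(apply_time_correction(3000, 9.5, 3020, 9.5, 0.288)$delta_pct_corr,
               100 * 20 / 3000)
  expect_equal(apply_time_correction(3000, 9.5, 3020, 14.75, 0)$delta_pct_corr,
               100 * 20 / 3000)
  expect_error(apply_time_correction(-1, 9, 10, 10, 0.288), "positive")
  expect_error(apply_time_correction(3000, 25, 3020, 10, 0.288), "24")
})

test_that("swapping the visit order negates the correction to first order", {
  fwd <- apply_time_correction(3000, 9.5, 3020, 14.75, 0.288)
  rev <- apply_time_correction(3020, 14.75, 3000, 9.5, 0.288)
  expect_equal(rev$delta_t, -fwd$delta_t)
  # percent changes are asymmetric by (delta%)^2/100, so match at that order
  expect_lt(abs(rev$delta_pct_corr + fwd$delta_pct_corr),
            fwd$delta_pct_meas^2 / 100 + 1e-9)
})

test_that("the pooled regression recovers an exactly linear drift", {
  # visit 1 pinned at the 08:00 drift anchor makes the generative model
  # exactly linear in the time difference: slope == injected rate
  n <- 40
  vt <- cbind(rep(8, n), seq(8.5, 18, length.out = n))
  eff <- effects_off(drift_legBD = 0.288, drift_limbBF = 0.259,
                     between_subject_cv = 12)
  rec <- simulate_cohort(cohort_config(n_subjects = n, seed = 55,
                                       effects = eff, visit_times = vt))
  fit <- fit_time_volume_regression(rec, "legBD", "relative_pct")
  expect_equal(fit$slope, 0.288, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  fit2 <- fit_time_volume_regression(rec, "limbBF", "relative_pct")
  expect_equal(fit2$slope, 0.259, tolerance = 1e-6)

  # absolute-scale slope is the relative slope times the mean volume / 100
  fa <- fit_time_volume_regression(rec, "legBD", "absolute_ml")
  expect_equal(fa$slope / mean(rec$vol_legBD_ml) * 100, 0.288,
               tolerance = 0.05)
})

test_that("degenerate regression designs are rejected", {
  eff <- effects_off(between_subject_cv = 10)
  rec <- simulate_cohort(cohort_config(n_subjects = 6, seed = 2,
                                       effects = eff,
                                       visit_times = c(9, 12)))
  expect_error(fit_time_volume_regression(rec, "legBD"), "singular")
  rec$vol_limbBF_ml <- NULL
  expect_error(fit_time_volume_regression(rec, "limbBF"), "missing column")
})

test_that("derived coefficients match the injected drift at scale", {
  rec <- simulate_cohort(cohort_config(n_subjects = 1000, seed = 77))
  co <- derive_correction(rec)
  expect_lt(abs(co$coeff_legBD - 0.288), 0.02)
  expect_lt(abs(co$coeff_limbBF - 0.259), 0.02)
  expect_equal(co$source, "derived")
  expect_equal(co$coeff_legBD, round(co$provenance$legBD$slope, 3))

  # driftless cohort: derived coefficients near zero, not significant
  eff <- effect_params(drift_legBD = 0, drift_limbBF = 0)
  rec0 <- simulate_cohort(cohort_config(n_subjects = 60, seed = 78,
                                        effects = eff))
  co0 <- derive_correction(rec0)
  expect_lt(abs(co0$coeff_legBD), 0.05)
  expect_gte(co0$provenance$legBD$p_value, 0.05)
  expect_output(print(co0), "no significant time dependence")
})

test_that("cohort correction inverts a pure drift and is identity at zero", {
  eff <- effects_off(drift_legBD = 0.288, drift_limbBF = 0.259,
                     between_subject_cv = 17.5)
  rec <- simulate_cohort(cohort_config(n_subjects = 63, seed = 404,
                                       effects = eff))
  cc <- correct_cohort(rec, published_coefficients())
  crude_cvw <- cc$crude$components$cv_w_pct
  corr_cvw <- cc$corrected$components$cv_w_pct
  # the percent-scale correction inverts the anchored drift up to its
  # second-order term (~c^2 dt^2 / 1e4): CV_W collapses by more than 10x
  expect_gt(min(crude_cvw), 0.3)
  expect_lt(max(corr_cvw), 0.05)
  # visit-1 records are untouched
  expect_identical(cc$records$vol_legBD_ml[cc$records$visit == 1],
                   rec$vol_legBD_ml[rec$visit == 1])

  zero <- new_coeffs_zero()
  cc0 <- correct_cohort(rec, zero)
  expect_equal(cc0$records$vol_legBD_ml, rec$vol_legBD_ml, tolerance = 1e-15)
})

test_that("self-consistency: correcting with the derived coefficients removes
           the time signal", {
  rec <- simulate_cohort(cohort_config(n_subjects = 300, seed = 11))
  co <- derive_correction(rec)
  cc <- correct_cohort(rec, co)
  refit <- fit_time_volume_regression(cc$records, "legBD", "relative_pct")
  expect_true(refit$ci95_low <= 0 && refit$ci95_high >= 0)
})
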