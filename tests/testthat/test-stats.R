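test_that("analytical component matches the hand-computed duplicate formula", {
  # identical duplicates: no measurement error
  z <- analytical_component(rbind(c(100, 100), c(250, 250)))
  expect_equal(z$s2_analytical, 0)
  expect_equal(z$cv_analytical, 0)

  # pairs (100,102) and (200,198): s2 = (4+4)/4 = 2, CV = 100*sqrt(2)/150
  a <- analytical_component(rbind(c(100, 102), c(200, 198)))
  expect_equal(a$s2_analytical, 2)
  expect_equal(a$cv_analytical, 100 * sqrt(2) / 150)
  expect_equal(round(a$cv_analytical, 3), 0.943)

  expect_error(analytical_component(rbind(c(1, 2))), "at least 2")
  expect_error(analytical_component(matrix(1:9, 3)), "two-column")
})

test_that("analytical component is scale-free and equals the ANOVA
           mean square within", {
  set.seed(42)
  pairs <- cbind(rnorm(40, 2300, 300), rnorm(40, 2300, 300))
  a <- analytical_component(pairs)
  a10 <- analytical_component(10 * pairs)
  expect_equal(a10$cv_analytical, a$cv_analytical, tolerance = 1e-12)

  # oracle: replicate-level one-way ANOVA grouped by measurement occasion
  ms <- aov_mean_squares(as.numeric(t(pairs)), rep(seq_len(40), each = 2))
  expect_equal(a$s2_analytical, ms$msw, tolerance = 1e-10)
})

test_that("within-individual component matches its hand oracle", {
  w0 <- within_individual_component(rbind(c(2000, 2000), c(3100, 3100)))
  expect_equal(w0$cv_within, 0)

  # (2000,2020), (3000,2985): s2 = (400+225)/4 = 156.25, CV = 1250/2501.25
  w <- within_individual_component(rbind(c(2000, 2020), c(3000, 2985)))
  expect_equal(w$s2_within, 156.25)
  expect_equal(w$cv_within, 100 * 12.5 / 2501.25)
  expect_equal(round(w$cv_within, 4), 0.4998)

  # incomplete subject-legs are excluded with a warning
  expect_warning(
    w2 <- within_individual_component(rbind(c(2000, 2020), c(3000, 2985),
                                            c(2500, NA))),
    "excluded")
  expect_equal(w2$n_subjects, 2)

  # Fraser-Harris mode subtracts the analytical share of the visit means
  wf <- within_individual_component(rbind(c(2000, 2020), c(3000, 2985)),
                                    fraser_harris = TRUE,
                                    s2_analytical = 100, n_replicates = 2)
  expect_equal(wf$s2_within_corrected, 156.25 - 50)
})

test_that("one-way ICC matches an independent ANOVA computation", {
  # visits identical within subject: perfect reliability
  expect_equal(icc_oneway(rbind(c(10, 10), c(20, 20), c(30, 30))), 1)

  m <- rbind(c(10, 12), c(20, 19), c(30, 31))
  ms <- aov_mean_squares(as.numeric(t(m)), rep(1:3, each = 2))
  oracle <- (ms$msb - ms$msw) / (ms$msb + (2 - 1) * ms$msw)
  expect_equal(icc_oneway(m), oracle, tolerance = 1e-12)

  expect_error(icc_oneway(matrix(5, 3, 2)), "zero total variance")
  expect_error(icc_oneway(rbind(c(1, 2))), ">= 2 subjects")
  expect_error(icc_oneway(rbind(c(1, NA), c(2, 3))), "complete")
})

test_that("ICC respects its algebraic bounds on random matrices", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    m <- matrix(rnorm(6 * k), nrow = 6)
    icc <- icc_oneway(m)
    expect_gte(icc, -1 / (k - 1) - 1e-12)
    expect_lte(icc, 1 + 1e-12)
  }
})

test_that("paired t handles regular and degenerate inputs", {
  # (1,2,3) vs (2,2,4): diffs (1,0,1), mean 2/3, t = 2, df 2
  p <- paired_t(c(1, 2, 3), c(2, 2, 4))
  expect_equal(p$mean_diff, 2 / 3)
  expect_equal(p$sd_diff, sd(c(1, 0, 1)))
  expect_equal(p$t_statistic, 2, tolerance = 1e-12)
  expect_equal(p$df, 2)
  ref <- t.test(c(2, 2, 4), c(1, 2, 3), paired = TRUE)
  expect_equal(p$p_value, ref$p.value)

  same <- paired_t(c(5, 6), c(5, 6))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  const <- paired_t(c(5, 6, 7), c(6, 7, 8))
  expect_identical(const$t_statistic, Inf)
  expect_equal(const$p_value, 0)

  expect_error(paired_t(1:3, 1:4), "equal lengths")
})

test_that("injected analytical noise is recovered at Monte-Carlo scale", {
  eff <- effects_off(cv_analytical_legBD = 0.5, cv_analytical_limbBF = 0.7,
                     cv_within = 0.7 / sqrt(2), between_subject_cv = 17.5)
  rec <- simulate_cohort(cohort_config(n_subjects = 1000, seed = 2024,
                                       effects = eff))
  s <- summarize_cohort(rec)
  cva <- s$components$cv_a_pct[s$components$volume_type == "legBD"]
  expect_true(all(cva > 0.45 & cva < 0.55))
  cvb <- s$components$cv_a_pct[s$components$volume_type == "limbBF"]
  expect_true(all(cvb > 0.63 & cvb < 0.77))
})

test_that("injected between-visit variability is recovered at Monte-Carlo
           scale", {
  eff <- effect_params(drift_legBD = 0, drift_limbBF = 0,
                       orthostatic_legBD = 0, orthostatic_limbBF = 0)
  rec <- simulate_cohort(cohort_config(n_subjects = 1000, seed = 2025,
                                       effects = eff))
  s <- summarize_cohort(rec)
  expect_true(all(s$components$cv_w_pct > 1.15 & s$components$cv_w_pct < 1.45))
  expect_true(all(s$components$icc > 0.98))
})

test_that("cohort summaries follow the two-table layout", {
  rec <- simulate_cohort(cohort_config(n_subjects = 20, seed = 4))
  s <- summarize_cohort(rec, fraser_harris = TRUE)
  expect_setequal(s$components$volume_type, c("legBD", "limbBF"))
  expect_setequal(s$components$side, c("left", "right"))
  expect_true(all(c("cv_a_pct", "cv_w_pct", "icc", "cv_w_corrected_pct")
                  %in% names(s$components)))
  # corrected CV_W never exceeds the total CV_W
  expect_true(all(s$components$cv_w_corrected_pct <= s$components$cv_w_pct))
  # replicate-shift table: per-side rows plus a pooled both-legs row
  expect_true(all(c("left", "right", "both") %in% s$replicate_shift$side))
  both <- s$replicate_shift[s$replicate_shift$side == "both" &
                              s$replicate_shift$volume_type == "legBD", ]
  expect_equal(both$n_pairs, 20 * 2 * 2)

  one <- rec[rec$subject_id == "S001", ]
  expect_error(summarize_cohort(one), "2 subjects")
})

test_that("noise-free cohorts give zero CVs and unit ICC", {
  eff <- effects_off(between_subject_cv = 15)
  rec <- simulate_cohort(cohort_config(n_subjects = 10, seed = 6,
                                       effects = eff))
  s <- summarize_cohort(rec)
  expect_true(all(s$components$cv_a_pct == 0))
  expect_true(all(s$components$cv_w_pct == 0))
  expect_true(all(s$components$icc == 1))
})
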