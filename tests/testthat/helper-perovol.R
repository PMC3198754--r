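# shared fixtures, built in code

default_profile <- function(slice_thickness = 4.7) {
  generate_leg_profile(leg_shape_params(), slice_thickness)
}

# effect configuration with every effect switched off except the overrides
effects_off <- function(...) {
  base <- list(drift_legBD = 0, drift_limbBF = 0,
               orthostatic_legBD = 0, orthostatic_limbBF = 0,
               cv_analytical_legBD = 0, cv_analytical_limbBF = 0,
               cv_within = 0, between_subject_cv = 0)
  over <- list(...)
  base[names(over)] <- over
  do.call(effect_params, base)
}

# exact ellipse perimeter via numerical quadrature of the complete elliptic
# integral; independent oracle for the Ramanujan approximation
ellipse_perimeter_exact <- function(a, b) {
  hi <- max(a, b)
  lo <- min(a, b)
  e2 <- 1 - (lo / hi)^2
  4 * hi * stats::integrate(function(t) sqrt(1 - e2 * sin(t)^2), 0, pi / 2,
                            rel.tol = 1e-12)$value
}

new_coeffs_zero <- function() {
  perovol:::new_correction_coefficients(0, 0, source = "published")
}

# one-way ANOVA mean squares through stats::aov; independent oracle for the
# hand-rolled ICC / analytical-variance sums of squares
aov_mean_squares <- function(values, groups) {
  fit <- stats::aov(values ~ factor(groups))
  sm <- summary(fit)[[1]]
  list(msb = sm$`Mean Sq`[1], msw = sm$`Mean Sq`[2])
}
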