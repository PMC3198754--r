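#' Parse a clock time into decimal hours
#'
#' Accepts `"HH:MM"` strings (9:30 becomes 9.50) or numeric decimal hours,
#' which pass through unchanged.
#'
#' @param x Character or numeric vector.
#' @return Numeric decimal hours.
#' @examples
#' parse_clock_time(c("9:30", "14:45"))
#' @export
parse_clock_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^\\s*([0-9]{1,2}):([0-9]{2})\\s*$", x))
  out <- vapply(seq_along(x), function(i) {
    if (length(m[[i]]) != 3L) return(NA_real_)
    as.numeric(m[[i]][2]) + as.numeric(m[[i]][3]) / 60
  }, numeric(1))
  if (any(is.na(out))) {
    stop("parse_clock_time(): cannot parse '",
         paste(x[is.na(out)], collapse = "', '"),
         "' as HH:MM or decimal hours", call. = FALSE)
  }
  out
}

#' Published daytime-correction coefficients
#'
#' The linear daytime drift of standing leg volume, in percent per hour of
#' between-visit clock-time difference: 0.288 %/h for the lower leg (B-D
#' segment) and 0.259 %/h for the whole limb (B-F segment). Corrections
#' subtract `coefficient * delta_t` percentage points from the measured
#' between-visit percentage change.
#'
#' @return An object of class `correction_coefficients`.
#' @export
published_coefficients <- function() {
  new_correction_coefficients(0.288, 0.259, source = "published")
}

new_correction_coefficients <- function(coeff_legBD, coeff_limbBF, source,
                                        provenance = NULL) {
  if (!is.finite(coeff_legBD) || !is.finite(coeff_limbBF)) {
    stop("correction coefficients must be finite", call. = FALSE)
  }
  structure(
    list(coeff_legBD = coeff_legBD, coeff_limbBF = coeff_limbBF,
         source = source, provenance = provenance),
    class = "correction_coefficients"
  )
}

#' @export
print.correction_coefficients <- function(x, ...) {
  cat(sprintf("daytime correction coefficients (%s):\n", x$source))
  cat(sprintf("  leg_BD : %.3f %%/h\n  limb_BF: %.3f %%/h\n",
              x$coeff_legBD, x$coeff_limbBF))
  if (!is.null(x$provenance)) {
    pv <- x$provenance
    for (ep in names(pv)) {
      cat(sprintf(
        "  [%s] n = %d legs, r^2 = %.3f, 95%% CI %.3f to %.3f, p = %.2g%s\n",
        ep, pv[[ep]]$n_points, pv[[ep]]$r_squared, pv[[ep]]$ci95_low,
        pv[[ep]]$ci95_high, pv[[ep]]$p_value,
        if (pv[[ep]]$p_value >= 0.05) " (no significant time dependence)"
        else ""))
    }
  }
  invisible(x)
}

#' Fit the pooled regression of between-visit volume change on time difference
#'
#' For every subject-leg with both visits, the response is the visit-2 minus
#' visit-1 change of the per-visit replicate means — in ml
#' (`scale = "absolute_ml"`) or in percent of the visit-1 mean
#' (`scale = "relative_pct"`) — and the predictor is the signed clock-time
#' difference in decimal hours. Left and right legs are pooled and treated as
#' independent observations; note that within-subject correlation between a
#' subject's two legs makes the nominal confidence interval somewhat
#' optimistic (reported as-is, not corrected).
#'
#' @param records A `measurement_records` data frame with two visits.
#' @param volume_type `"legBD"` or `"limbBF"`.
#' @param scale `"relative_pct"` (percent change per hour) or
#'   `"absolute_ml"` (ml per hour).
#' @param abs_dt Use the absolute instead of the signed time difference.
#' @return An object of class `time_regression`: slope, intercept, 95% CI of
#'   the slope, r^2, p value, n, plus the underlying `lm` fit and the
#'   per-leg regression table.
#' @export
fit_time_volume_regression <- function(records,
                                       volume_type = c("legBD", "limbBF"),
                                       scale = c("relative_pct",
                                                 "absolute_ml"),
                                       abs_dt = FALSE) {
  volume_type <- match.arg(volume_type)
  scale <- match.arg(scale)
  tab <- between_visit_table(records, volume_type)
  if (nrow(tab) < 3L) {
    stop("fit_time_volume_regression(): need >= 3 subject-legs with both ",
         "visits", call. = FALSE)
  }
  dt <- tab$t2 - tab$t1
  if (abs_dt) dt <- abs(dt)
  if (max(dt) - min(dt) < 1e-9) {
    stop("fit_time_volume_regression(): all time differences identical; ",
         "design is singular", call. = FALSE)
  }
  dv <- if (scale == "relative_pct") 100 * (tab$v2 - tab$v1) / tab$v1
        else tab$v2 - tab$v1
  fit <- stats::lm(dv ~ dt)
  sm <- summary(fit)
  ci <- stats::confint(fit, "dt", level = 0.95)
  structure(
    list(slope = unname(stats::coef(fit)["dt"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         ci95_low = ci[1], ci95_high = ci[2],
         r_squared = sm$r.squared,
         p_value = sm$coefficients["dt", "Pr(>|t|)"],
         n_points = nrow(tab),
         volume_type = volume_type, scale = scale, abs_dt = abs_dt,
         fit = fit, data = data.frame(dt = dt, dv = dv)),
    class = "time_regression"
  )
}

#' @export
print.time_regression <- function(x, ...) {
  unit <- if (x$scale == "relative_pct") "%/h" else "ml/h"
  cat(sprintf(
    "time-volume regression (%s, %s): slope %.3f %s (95%% CI %.3f to %.3f)\n",
    x$volume_type, x$scale, x$slope, unit, x$ci95_low, x$ci95_high))
  cat(sprintf("  r^2 = %.3f, p = %.3g, n = %d legs\n",
              x$r_squared, x$p_value, x$n_points))
  invisible(x)
}

#' @export
coef.time_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.time_regression <- function(x, ...) {
  unit <- if (x$scale == "relative_pct") "[%]" else "[ml]"
  graphics::plot(x$data$dt, x$data$dv,
                 xlab = "clock-time difference V2 - V1 [h]",
                 ylab = paste("volume change V2 - V1", unit), ...)
  graphics::abline(x$fit, lwd = 2)
  invisible(x)
}

# per subject-leg between-visit table: visit means and clock times
between_visit_table <- function(records, volume_type) {
  records <- validate_records(records)
  col <- if (volume_type == "legBD") "vol_legBD_ml" else "vol_limbBF_ml"
  if (!col %in% names(records)) {
    stop("records are missing column ", col, call. = FALSE)
  }
  visits <- sort(unique(records$visit))
  if (length(visits) < 2L) {
    stop("between-visit analysis needs records from two visits",
         call. = FALSE)
  }
  v1 <- visits[1L]; v2 <- visits[2L]
  key <- interaction(records$subject_id, records$side, drop = TRUE)
  sel1 <- records$visit == v1
  sel2 <- records$visit == v2
  m1 <- tapply(records[[col]][sel1], key[sel1], mean)[levels(key)]
  m2 <- tapply(records[[col]][sel2], key[sel2], mean)[levels(key)]
  t1 <- tapply(records$clock_time_decimal[sel1], key[sel1],
               mean)[levels(key)]
  t2 <- tapply(records$clock_time_decimal[sel2], key[sel2],
               mean)[levels(key)]
  tab <- data.frame(leg = levels(key), v1 = as.numeric(m1),
                    v2 = as.numeric(m2), t1 = as.numeric(t1),
                    t2 = as.numeric(t2), stringsAsFactors = FALSE)
  tab[stats::complete.cases(tab), , drop = FALSE]
}

#' Derive daytime-correction coefficients from cohort data
#'
#' Fits the pooled relative-scale time-volume regression for both volume
#' endpoints and packages the slopes, rounded to three decimals, as
#' correction coefficients with full provenance (n, r^2, CI, p). A slope
#' whose p value is >= 0.05 is flagged as showing no significant time
#' dependence when printed.
#'
#' @param records A `measurement_records` data frame with two visits.
#' @param abs_dt Passed to [fit_time_volume_regression()].
#' @return A `correction_coefficients` object with `source = "derived"`.
#' @export
derive_correction <- function(records, abs_dt = FALSE) {
  fits <- lapply(c("legBD", "limbBF"), function(ep) {
    fit_time_volume_regression(records, ep, "relative_pct", abs_dt = abs_dt)
  })
  names(fits) <- c("legBD", "limbBF")
  prov <- lapply(fits, function(f) {
    f[c("slope", "ci95_low", "ci95_high", "r_squared", "p_value",
        "n_points")]
  })
  new_correction_coefficients(
    round(fits$legBD$slope, 3), round(fits$limbBF$slope, 3),
    source = "derived", provenance = prov
  )
}

#' Apply the daytime correction to a single between-visit comparison
#'
#' Implements the percent-scale correction
#' `delta_pct_corr = delta_pct_meas - coefficient * delta_t` with
#' `delta_pct_meas = 100 * (v2 - v1) / v1` carried unrounded and
#' `delta_t = t2 - t1` signed, in decimal hours. Rounding to display
#' precision must happen only at output: with v1 = 3000 ml at 9:30 and
#' v2 = 3020 ml at 14:45 the measured change prints as +0.67 % but the
#' corrected change is 0.6667 - 0.288 * 5.25 = -0.845, i.e. -0.85 % — using
#' the rounded 0.67 inside the formula would give -0.84.
#'
#' @param v1,v2 Volumes (ml) at the first and second visit; positive.
#' @param t1,t2 Clock times of the two measurements, `"HH:MM"` or decimal
#'   hours in `[0, 24)`.
#' @param coefficient Correction coefficient in %/h (see
#'   [published_coefficients()]).
#' @return An object of class `correction_result` with `delta_pct_meas`,
#'   `delta_t`, `coefficient` and `delta_pct_corr` (all unrounded).
#' @examples
#' apply_time_correction(3000, "9:30", 3020, "14:45",
#'                       published_coefficients()$coeff_legBD)
#' @export
apply_time_correction <- function(v1, t1, v2, t2, coefficient) {
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0) {
    stop("apply_time_correction(): volumes must be positive", call. = FALSE)
  }
  t1 <- parse_clock_time(t1)
  t2 <- parse_clock_time(t2)
  if (t1 < 0 || t1 >= 24 || t2 < 0 || t2 >= 24) {
    stop("apply_time_correction(): clock times must lie in [0, 24) hours",
         call. = FALSE)
  }
  delta_pct_meas <- 100 * (v2 - v1) / v1
  delta_t <- t2 - t1
  structure(
    list(delta_pct_meas = delta_pct_meas, delta_t = delta_t,
         coefficient = coefficient,
         delta_pct_corr = delta_pct_meas - coefficient * delta_t),
    class = "correction_result"
  )
}

#' @export
print.correction_result <- function(x, digits = 2, ...) {
  cat(sprintf("  measured change : %+.*f %%\n", digits, x$delta_pct_meas))
  cat(sprintf("  time difference : %+.2f h\n", x$delta_t))
  cat(sprintf("  coefficient     : %.3f %%/h\n", x$coefficient))
  cat(sprintf("  corrected change: %+.*f %%\n", digits, x$delta_pct_corr))
  invisible(x)
}

#' Apply the daytime correction to a whole cohort and re-assess reproducibility
#'
#' Replaces every visit-2 volume by `V2 / (1 + coefficient * delta_t / 100)`,
#' the volume-level equivalent of subtracting `coefficient * delta_t`
#' percentage points from the measured relative change (`delta_t` is the
#' subject-leg's signed visit-2 minus visit-1 clock-time difference). The
#' variance components are then recomputed, so crude and corrected
#' within-individual CVs and ICCs can be compared side by side.
#'
#' @param records A `measurement_records` data frame with two visits.
#' @param coefficients A `correction_coefficients` object
#'   ([published_coefficients()] or [derive_correction()]).
#' @param fraser_harris Passed to [summarize_cohort()].
#' @return An object of class `corrected_cohort`: `records` (corrected),
#'   `crude` and `corrected` ([summarize_cohort()] outputs) and the
#'   `coefficients` used.
#' @export
correct_cohort <- function(records, coefficients = published_coefficients(),
                           fraser_harris = FALSE) {
  records <- validate_records(records)
  if (!inherits(coefficients, "correction_coefficients")) {
    stop("correct_cohort(): coefficients must be a correction_coefficients ",
         "object", call. = FALSE)
  }
  visits <- sort(unique(records$visit))
  if (length(visits) < 2L) {
    stop("correct_cohort(): need two-visit records", call. = FALSE)
  }
  v1 <- visits[1L]
  key <- interaction(records$subject_id, records$side, drop = TRUE)
  sel1 <- records$visit == v1
  t1 <- tapply(records$clock_time_decimal[sel1], key[sel1], mean)
  dt <- records$clock_time_decimal - as.numeric(t1[as.character(key)])

  corrected <- records
  later <- records$visit != v1
  corrected$vol_legBD_ml[later] <- records$vol_legBD_ml[later] /
    (1 + coefficients$coeff_legBD * dt[later] / 100)
  corrected$vol_limbBF_ml[later] <- records$vol_limbBF_ml[later] /
    (1 + coefficients$coeff_limbBF * dt[later] / 100)

  structure(
    list(records = corrected,
         crude = summarize_cohort(records, fraser_harris = fraser_harris),
         corrected = summarize_cohort(corrected,
                                      fraser_harris = fraser_harris),
         coefficients = coefficients),
    class = "corrected_cohort"
  )
}

#' @export
print.corrected_cohort <- function(x, digits = 4, ...) {
  cat("Daytime-corrected cohort (coefficients: ", x$coefficients$source,
      ")\n\nCrude components:\n", sep = "")
  print(format_num_df(x$crude$components, digits), row.names = FALSE)
  cat("\nCorrected components:\n")
  print(format_num_df(x$corrected$components, digits), row.names = FALSE)
  invisible(x)
}
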