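#' Reproducibility and daytime-bias analysis of a volumetry cohort
#'
#' The package's central fitting function. Given a two-visit,
#' duplicate-measurement record table it (1) decomposes the measurement
#' variability into the analytical CV (immediate duplicates), the
#' within-individual between-visit CV and the one-way ICC, per side and
#' volume endpoint; (2) quantifies the orthostatic replicate-1 to
#' replicate-2 shift with paired t tests; (3) fits the pooled linear
#' regression of between-visit volume change on the signed clock-time
#' difference, in percent and in ml per hour; (4) turns the relative slopes
#' into daytime-correction coefficients (or adopts the published 0.288 /
#' 0.259 %/h pair); and (5) applies the correction and re-computes the
#' variance components on the corrected volumes.
#'
#' @param records A `measurement_records` data frame from
#'   [simulate_cohort()] or [read_measurements()].
#' @param coefficients `"derived"` (default: use this cohort's own fitted
#'   slopes), `"published"`, or a ready-made `correction_coefficients`
#'   object.
#' @param fraser_harris Also report analytically corrected within-individual
#'   CVs (`s_W^2 - s_A^2 / k`).
#' @param abs_dt Regress on the absolute instead of the signed time
#'   difference.
#' @return An object of class `volrep` with components `records`, `crude`
#'   (a [summarize_cohort()] result), `fits` (relative and absolute
#'   [fit_time_volume_regression()] fits per endpoint), `coefficients`, and
#'   `corrected` (a [correct_cohort()] result).
#' @seealso [print.volrep()], [summary.volrep()], [coef.volrep()],
#'   [plot.volrep()]
#' @examples
#' rec <- simulate_cohort(cohort_config(n_subjects = 25, seed = 7))
#' fit <- volrep(rec)
#' fit
#' coef(fit)
#' @export
volrep <- function(records, coefficients = c("derived", "published"),
                   fraser_harris = FALSE, abs_dt = FALSE) {
  records <- validate_records(records)
  fits <- list(
    relative = list(
      legBD = fit_time_volume_regression(records, "legBD", "relative_pct",
                                         abs_dt = abs_dt),
      limbBF = fit_time_volume_regression(records, "limbBF", "relative_pct",
                                          abs_dt = abs_dt)
    ),
    absolute = list(
      legBD = fit_time_volume_regression(records, "legBD", "absolute_ml",
                                         abs_dt = abs_dt),
      limbBF = fit_time_volume_regression(records, "limbBF", "absolute_ml",
                                          abs_dt = abs_dt)
    )
  )
  coefs <- if (inherits(coefficients, "correction_coefficients")) {
    coefficients
  } else {
    switch(match.arg(coefficients),
           published = published_coefficients(),
           derived = derive_correction(records, abs_dt = abs_dt))
  }
  corrected <- correct_cohort(records, coefs, fraser_harris = fraser_harris)
  structure(
    list(records = records, crude = corrected$crude, fits = fits,
         coefficients = coefs, corrected = corrected,
         call = match.call()),
    class = "volrep"
  )
}

#' @export
print.volrep <- function(x, ...) {
  cat("Leg volumetry reproducibility analysis\n")
  cat("  ", x$crude$n_records, " measurements, ",
      length(unique(x$records$subject_id)), " subjects\n\n", sep = "")
  print(x$coefficients)
  cat("\nCrude vs corrected within-individual CV [%] and ICC:\n")
  comp <- merge(
    x$crude$components[c("side", "volume_type", "cv_a_pct", "cv_w_pct",
                         "icc")],
    x$corrected$corrected$components[c("side", "volume_type", "cv_w_pct",
                                       "icc")],
    by = c("side", "volume_type"), suffixes = c("_crude", "_corrected"))
  print(format_num_df(comp, 4), row.names = FALSE)
  invisible(x)
}

#' Detailed summary of a volrep analysis
#'
#' @param object A [volrep] object.
#' @param ... Unused.
#' @return `object`, invisibly, after printing the component tables, the
#'   replicate-shift table and both regression fits.
#' @export
summary.volrep <- function(object, ...) {
  print(object$crude)
  cat("\nTime-volume regressions (pooled legs):\n")
  print(object$fits$relative$legBD)
  print(object$fits$relative$limbBF)
  print(object$fits$absolute$legBD)
  print(object$fits$absolute$limbBF)
  cat("\n")
  print(object$coefficients)
  cat("\nComponents after daytime correction:\n")
  print(format_num_df(object$corrected$corrected$components, 4),
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.volrep <- function(object, ...) {
  c(coeff_legBD = object$coefficients$coeff_legBD,
    coeff_limbBF = object$coefficients$coeff_limbBF)
}

#' Regression scatter of between-visit change against time difference
#'
#' @param x A [volrep] object.
#' @param volume_type Endpoint to plot.
#' @param scale Response scale.
#' @param ... Passed to [plot.time_regression()].
#' @return `x`, invisibly.
#' @export
plot.volrep <- function(x, volume_type = c("legBD", "limbBF"),
                        scale = c("relative_pct", "absolute_ml"), ...) {
  volume_type <- match.arg(volume_type)
  scale <- if (match.arg(scale) == "relative_pct") "relative" else "absolute"
  plot(x$fits[[scale]][[volume_type]], ...)
  invisible(x)
}
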