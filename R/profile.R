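#' Width-profile container for one scanned leg
#'
#' A leg enters the volumetry engine as two silhouette width series — front
#' view and side view — sampled every `slice_thickness` mm from the sole
#' upward. Heights must form an arithmetic progression with step equal to the
#' slice thickness.
#'
#' @param heights Numeric vector, mm from the sole, strictly increasing with
#'   constant step.
#' @param front_width,side_width Numeric vectors of silhouette widths in mm,
#'   same length as `heights`, positive.
#' @param slice_thickness Slice thickness in mm; inferred from the height step
#'   when `NULL`, validated against it otherwise.
#' @return An object of class `leg_profile`.
#' @export
leg_profile <- function(heights, front_width, side_width,
                        slice_thickness = NULL) {
  n <- length(heights)
  if (n < 2L) stop("leg_profile(): need at least 2 slices", call. = FALSE)
  if (length(front_width) != n || length(side_width) != n) {
    stop("leg_profile(): heights, front_width and side_width must have equal ",
         "lengths", call. = FALSE)
  }
  steps <- diff(heights)
  if (any(steps <= 0) || max(steps) - min(steps) > 1e-6 * mean(steps)) {
    stop("leg_profile(): heights must be strictly increasing with a constant ",
         "step", call. = FALSE)
  }
  step <- mean(steps)
  if (is.null(slice_thickness)) {
    slice_thickness <- step
  } else if (abs(slice_thickness - step) > 1e-6 * slice_thickness) {
    stop("leg_profile(): slice_thickness (", slice_thickness, ") does not ",
         "match the height step (", signif(step, 8), ")", call. = FALSE)
  }
  if (any(!is.finite(front_width)) || any(!is.finite(side_width)) ||
      any(front_width <= 0) || any(side_width <= 0)) {
    stop("leg_profile(): widths must be positive and finite", call. = FALSE)
  }
  structure(
    list(heights = as.numeric(heights),
         front_width = as.numeric(front_width),
         side_width = as.numeric(side_width),
         slice_thickness = slice_thickness),
    class = "leg_profile"
  )
}

as_leg_profile <- function(x) {
  if (inherits(x, "leg_profile")) return(x)
  if (is.data.frame(x) &&
      all(c("height_mm", "front_width_mm", "side_width_mm") %in% names(x))) {
    return(leg_profile(x$height_mm, x$front_width_mm, x$side_width_mm))
  }
  stop("expected a leg_profile object", call. = FALSE)
}

#' @export
print.leg_profile <- function(x, ...) {
  cat(sprintf(
    "leg_profile: %d slices of %.2f mm (%.1f-%.1f mm from sole)\n",
    length(x$heights), x$slice_thickness, min(x$heights), max(x$heights)))
  invisible(x)
}

#' @export
plot.leg_profile <- function(x, ...) {
  geom <- circumference_profile(x)
  graphics::plot(geom$height, geom$circumference, type = "l",
                 xlab = "height above sole [mm]", ylab = "circumference [mm]",
                 ...)
  invisible(x)
}

#' Parametric leg-shape description
#'
#' Anatomic control points of a standing leg, sole upward: a foot bulge, the
#' ankle circumference minimum (future B-measure), the calf maximum (C), a
#' local minimum at the knee bend, and a monotone widening into the thigh.
#' [generate_leg_profile()] interpolates these smoothly.
#'
#' @param total_height Sole to mid-thigh top, mm.
#' @param foot_top_height Height where the foot bulge ends, mm.
#' @param ankle_height Height of the ankle circumference minimum, mm.
#' @param ankle_circ Circumference at the ankle minimum, mm.
#' @param calf_peak_height Height of the lower-leg circumference maximum, mm.
#' @param calf_circ Circumference at the calf maximum, mm.
#' @param knee_height Height of the knee-bend local minimum, mm.
#' @param knee_circ Circumference at the knee minimum, mm.
#' @param thigh_top_circ Circumference at `total_height`, mm.
#' @param ellipticity Side-width / front-width ratio, constant over the leg.
#' @return A validated list of class `leg_shape_params`.
#' @examples
#' p <- leg_shape_params()
#' prof <- generate_leg_profile(p, slice_thickness = 4.7)
#' @export
leg_shape_params <- function(total_height = 800, foot_top_height = 70,
                             ankle_height = 120, ankle_circ = 220,
                             calf_peak_height = 330, calf_circ = 370,
                             knee_height = 500, knee_circ = 350,
                             thigh_top_circ = 560, ellipticity = 0.9) {
  p <- list(total_height = total_height, foot_top_height = foot_top_height,
            ankle_height = ankle_height, ankle_circ = ankle_circ,
            calf_peak_height = calf_peak_height, calf_circ = calf_circ,
            knee_height = knee_height, knee_circ = knee_circ,
            thigh_top_circ = thigh_top_circ, ellipticity = ellipticity)
  check <- function(ok, msg) if (!ok) stop("leg_shape_params(): ", msg,
                                           call. = FALSE)
  circs <- c(p$ankle_circ, p$calf_circ, p$knee_circ, p$thigh_top_circ)
  check(all(circs > 0), "all circumferences must be > 0")
  check(p$ellipticity > 0, "ellipticity must be > 0")
  check(p$ankle_circ < p$calf_circ, "ankle_circ must be < calf_circ")
  check(p$knee_circ < p$calf_circ, "knee_circ must be < calf_circ")
  check(p$knee_circ < p$thigh_top_circ,
        "knee_circ must be < thigh_top_circ")
  check(p$foot_top_height < p$ankle_height,
        "foot_top_height must be < ankle_height")
  check(p$ankle_height < p$calf_peak_height,
        "ankle_height must be < calf_peak_height")
  check(p$calf_peak_height < p$knee_height,
        "calf_peak_height must be < knee_height")
  check(p$knee_height < p$total_height,
        "knee_height must be < total_height")
  structure(p, class = "leg_shape_params")
}

#' Generate a synthetic silhouette width profile from shape parameters
#'
#' Builds a smooth circumference-against-height curve through the anatomic
#' control points of [leg_shape_params()] (cubic smoothstep between
#' consecutive control points, zero slope at each, so the curve is C1 and its
#' extrema sit exactly on the control points), then converts circumference to
#' front/side widths by inverting the Ramanujan ellipse perimeter at the
#' requested constant ellipticity. The number of slices is
#' `floor(total_height / slice_thickness)`; a residual sliver above the last
#' full slice is discarded. Slice heights are slice midpoints.
#'
#' @param params A [leg_shape_params] object.
#' @param slice_thickness Slice thickness in mm (scanner default 4.7).
#' @return A [leg_profile].
#' @export
generate_leg_profile <- function(params, slice_thickness = 4.7) {
  if (!inherits(params, "leg_shape_params")) {
    params <- do.call(leg_shape_params, as.list(params))
  }
  if (!is.finite(slice_thickness) || slice_thickness <= 0) {
    stop("generate_leg_profile(): slice_thickness must be > 0", call. = FALSE)
  }
  n <- floor(params$total_height / slice_thickness + 1e-9)
  if (n < 2L) {
    stop("generate_leg_profile(): fewer than 2 slices fit total_height",
         call. = FALSE)
  }
  heights <- (seq_len(n) - 0.5) * slice_thickness

  # foot bulge: rises from the sole to the foot top, then falls to the ankle
  ctrl_h <- c(0, params$foot_top_height, params$ankle_height,
              params$calf_peak_height, params$knee_height,
              params$total_height)
  ctrl_c <- c(1.10 * params$ankle_circ, 1.30 * params$ankle_circ,
              params$ankle_circ, params$calf_circ, params$knee_circ,
              params$thigh_top_circ)
  circ <- smoothstep_interp(ctrl_h, ctrl_c, heights)

  front <- circ / width_to_perimeter_factor(params$ellipticity)
  side <- params$ellipticity * front
  leg_profile(heights, front, side, slice_thickness)
}

# piecewise cubic smoothstep through (xk, yk); zero derivative at every knot
smoothstep_interp <- function(xk, yk, x) {
  seg <- findInterval(x, xk, all.inside = TRUE)
  u <- (x - xk[seg]) / (xk[seg + 1L] - xk[seg])
  u <- pmin(pmax(u, 0), 1)
  s <- u * u * (3 - 2 * u)
  yk[seg] + (yk[seg + 1L] - yk[seg]) * s
}

# Ramanujan perimeter of an ellipse with front width w and side width e*w,
# expressed as factor k(e) such that perimeter = k(e) * w
width_to_perimeter_factor <- function(e) {
  (pi / 2) * (3 * (1 + e) - sqrt((3 + e) * (1 + 3 * e)))
}

#' Scale a width profile to a target lower-leg volume
#'
#' Multiplies both width series by `sqrt(target / current)` so the measured
#' lower-leg volume (B to D) equals `target_legBD`. Because the scaling is
#' uniform across slices, the circumference profile scales uniformly too and
#' the landmark heights are unchanged.
#'
#' @param profile A [leg_profile].
#' @param target_legBD Target lower-leg volume in ml; positive.
#' @return The rescaled [leg_profile].
#' @export
scale_profile_to_volume <- function(profile, target_legBD) {
  profile <- as_leg_profile(profile)
  if (!is.finite(target_legBD) || target_legBD <= 0) {
    stop("scale_profile_to_volume(): target volume must be > 0",
         call. = FALSE)
  }
  current <- measure_leg(profile)$leg_BD
  k <- sqrt(target_legBD / current)
  leg_profile(profile$heights, k * profile$front_width,
              k * profile$side_width, profile$slice_thickness)
}
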