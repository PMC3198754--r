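#' Elliptical slice geometry
#'
#' An optoelectronic leg scanner records, every `slice_thickness` mm along the
#' leg, the silhouette width seen from the front and from the side. Each slice
#' is modelled as an ellipse whose axes are those two widths: semi-axes
#' `a = front_width / 2` and `b = side_width / 2`. The cross-sectional area is
#' the exact ellipse area `pi * a * b`; the circumference uses Ramanujan's
#' first approximation
#' `pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))`,
#' whose relative error is below 1e-6 for the axis ratios seen in human legs.
#'
#' @param front_width Front-view silhouette width(s) in mm; positive.
#' @param side_width Side-view silhouette width(s) in mm; positive, recycled
#'   against `front_width`.
#' @return A data frame with one row per slice and columns `area` (mm^2) and
#'   `circumference` (mm).
#' @examples
#' slice_geometry(100, 100) # circle: area 2500*pi, circumference 100*pi
#' slice_geometry(120, 80)
#' @export
slice_geometry <- function(front_width, side_width) {
  if (length(front_width) == 0L || length(side_width) == 0L) {
    stop("slice_geometry(): empty width input", call. = FALSE)
  }
  bad <- !is.finite(front_width) | !is.finite(side_width) |
    front_width <= 0 | side_width <= 0
  if (any(bad)) {
    stop("slice_geometry(): non-positive or non-finite width at slice ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  a <- front_width / 2
  b <- side_width / 2
  data.frame(
    area = pi * a * b,
    circumference = ellipse_perimeter(a, b)
  )
}

#' Ramanujan's first ellipse-perimeter approximation
#'
#' Exact for circles (`a == b`); relative error < 1e-6 for axis ratios up to
#' about 3, far beyond leg-like ellipticities.
#'
#' @param a,b Semi-axes in mm.
#' @return Perimeter in mm.
#' @keywords internal
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Per-slice circumference and area profile
#'
#' Applies [slice_geometry()] to every slice of a width profile, preserving
#' slice order. The circumference-against-height curve is the basis of
#' landmark detection.
#'
#' @param profile A [leg_profile] object.
#' @return A data frame of class `slice_profile` with columns `height`
#'   (mm from sole), `area` (mm^2) and `circumference` (mm).
#' @export
circumference_profile <- function(profile) {
  profile <- as_leg_profile(profile)
  if (length(profile$heights) == 0L) {
    stop("circumference_profile(): profile has no slices", call. = FALSE)
  }
  geom <- slice_geometry(profile$front_width, profile$side_width)
  out <- data.frame(
    height = profile$heights,
    area = geom$area,
    circumference = geom$circumference
  )
  class(out) <- c("slice_profile", "data.frame")
  out
}

#' Detect the B/C/D/F anatomic landmarks on a circumference profile
#'
#' Landmarks follow the scanner's verbal convention:
#' \describe{
#'   \item{B}{smallest circumference at ankle level: the minimum within the
#'     ankle search window, the lower 35\% of the profile above the foot top.}
#'   \item{C}{largest lower-leg circumference: maximum between B and the knee
#'     minimum.}
#'   \item{knee}{deepest local minimum above C (not returned, anchors D).}
#'   \item{D}{calf slice right below the knee bend: knee index − 1.}
#'   \item{F}{mid-thigh: slice nearest to the midpoint height between the knee
#'     and the profile top; ties resolved to the lower index.}
#' }
#' Extrema are located on a 3-slice moving-average smoothing of the raw
#' circumference profile to suppress single-slice noise, and the calf/knee
#' extrema must additionally be prominent by at least 5 mm of circumference
#' so that residual noise in monotone stretches of the profile cannot
#' masquerade as anatomy; all ties break to the lowest index. The foot top — needed to exclude the foot from the ankle
#' search — is the first slice where the smoothed circumference starts
#' decreasing with height, unless supplied explicitly.
#'
#' @param geometry A `slice_profile` from [circumference_profile()], or a
#'   numeric vector of circumferences.
#' @param heights Slice heights in mm from the sole; taken from `geometry` if
#'   it is a `slice_profile`.
#' @param foot_top_index Optional explicit index of the top of the foot.
#' @return An object of class `leg_landmarks`: a list with integer slice
#'   indices `index_B`, `index_C`, `index_D`, `index_F`, the knee index, and
#'   the corresponding heights in mm.
#' @export
detect_landmarks <- function(geometry, heights = NULL, foot_top_index = NULL) {
  if (inherits(geometry, "slice_profile")) {
    circ <- geometry$circumference
    if (is.null(heights)) heights <- geometry$height
  } else {
    circ <- as.numeric(geometry)
  }
  n <- length(circ)
  if (is.null(heights) || length(heights) != n) {
    stop("detect_landmarks(): heights must match the circumference profile",
         call. = FALSE)
  }
  if (n < 20L) {
    stop("detect_landmarks(): need at least 20 slices, got ", n, call. = FALSE)
  }

  sm <- smooth_ma3(circ)

  if (is.null(foot_top_index)) {
    dec <- which(diff(sm) < 0)
    if (length(dec) == 0L) {
      stop("landmark detection failed: no ankle minimum ",
           "(circumference never decreases with height)", call. = FALSE)
    }
    foot_top_index <- dec[1L]
  }
  foot_top_index <- as.integer(foot_top_index)

  # ankle window: lower 35% of the profile above the foot top
  win_hi <- foot_top_index + max(2L, floor(0.35 * (n - foot_top_index)))
  win <- seq.int(foot_top_index, min(win_hi, n))
  idx_B <- win[which.min(sm[win])]
  if (idx_B <= 1L || idx_B >= n ||
      !(sm[idx_B] <= sm[idx_B - 1L] && sm[idx_B] <= sm[idx_B + 1L]) ||
      idx_B == win[length(win)]) {
    stop("landmark detection failed: no ankle minimum (B-measure) ",
         "inside the ankle search window", call. = FALSE)
  }

  # provisional lower-leg maximum above the ankle, then the knee minimum;
  # only extrema prominent by >= 5 mm of circumference count, so slice-level
  # noise in monotone stretches cannot masquerade as anatomy
  pe <- prominent_extrema(sm, from = idx_B, to = n, delta = 5)
  if (length(pe$maxima) == 0L) {
    stop("landmark detection failed: no calf maximum (C-measure) ",
         "above the ankle", call. = FALSE)
  }
  knee_candidates <- pe$minima[pe$minima > pe$maxima[1L]]
  if (length(knee_candidates) == 0L) {
    stop("landmark detection failed: no knee minimum above the calf maximum",
         call. = FALSE)
  }
  idx_knee <- knee_candidates[which.min(sm[knee_candidates])]
  # C is the maximum strictly between B and the knee minimum
  seg <- seq.int(idx_B + 1L, idx_knee - 1L)
  idx_C <- seg[which.max(sm[seg])]
  idx_D <- idx_knee - 1L

  target_F <- (heights[idx_knee] + heights[n]) / 2
  idx_F <- which.min(abs(heights - target_F)) # which.min ties -> lowest index

  ord <- c(idx_B, idx_C, idx_D, idx_F)
  if (any(diff(ord) <= 0)) {
    stop("landmark detection failed: landmarks out of order (B=", idx_B,
         ", C=", idx_C, ", D=", idx_D, ", F=", idx_F, ")", call. = FALSE)
  }

  structure(
    list(
      index_B = idx_B, index_C = idx_C, index_D = idx_D, index_F = idx_F,
      index_knee = idx_knee,
      height_B = heights[idx_B], height_C = heights[idx_C],
      height_D = heights[idx_D], height_F = heights[idx_F],
      height_knee = heights[idx_knee]
    ),
    class = "leg_landmarks"
  )
}

#' @export
print.leg_landmarks <- function(x, ...) {
  cat("Leg landmarks (slice index @ height mm from sole):\n")
  cat(sprintf("  B (ankle min)      %4d @ %7.1f\n", x$index_B, x$height_B))
  cat(sprintf("  C (calf max)       %4d @ %7.1f\n", x$index_C, x$height_C))
  cat(sprintf("  D (below knee)     %4d @ %7.1f\n", x$index_D, x$height_D))
  cat(sprintf("  F (mid-thigh)      %4d @ %7.1f\n", x$index_F, x$height_F))
  invisible(x)
}

# 3-slice centred moving average; end slices keep their raw value
smooth_ma3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  out
}

# alternating prominent extrema of x over [from, to]: a maximum (minimum) is
# emitted once the profile has dropped (risen) by at least delta since it;
# strict comparisons keep ties at the lowest index
prominent_extrema <- function(x, from, to, delta) {
  ext_max <- integer(0)
  ext_min <- integer(0)
  cur_max <- from
  cur_min <- from
  mode <- "none"
  for (i in seq.int(from, to)) {
    if (x[i] > x[cur_max]) cur_max <- i
    if (x[i] < x[cur_min]) cur_min <- i
    if (mode != "falling" && x[cur_max] - x[i] >= delta) {
      ext_max <- c(ext_max, cur_max)
      mode <- "falling"
      cur_min <- i
    } else if (mode != "rising" && x[i] - x[cur_min] >= delta) {
      ext_min <- c(ext_min, cur_min)
      mode <- "rising"
      cur_max <- i
    }
  }
  list(maxima = ext_max, minima = ext_min)
}

#' Integrate the volume of a slice range
#'
#' Sums `area * slice_thickness` over the half-open slice range
#' `[from_index, to_index)` and converts mm^3 to ml. The half-open convention
#' makes segment volumes exactly additive:
#' `segment_volume(p, i, j) + segment_volume(p, j, k) == segment_volume(p, i, k)`.
#'
#' @param profile A [leg_profile] object.
#' @param from_index,to_index Slice indices, `from_index < to_index`, both
#'   within `1 .. n_slices + 1` (the upper bound may be one past the last
#'   slice so the final slice can be included).
#' @return Volume in ml.
#' @export
segment_volume <- function(profile, from_index, to_index) {
  profile <- as_leg_profile(profile)
  n <- length(profile$heights)
  from_index <- as.integer(from_index)
  to_index <- as.integer(to_index)
  if (is.na(from_index) || is.na(to_index) ||
      from_index < 1L || to_index > n + 1L || from_index >= to_index) {
    stop("segment_volume(): need 1 <= from_index < to_index <= n_slices + 1 ",
         "(got from=", from_index, ", to=", to_index, ", n=", n, ")",
         call. = FALSE)
  }
  idx <- seq.int(from_index, to_index - 1L)
  a <- pi * (profile$front_width[idx] / 2) * (profile$side_width[idx] / 2)
  sum(a) * profile$slice_thickness / 1000
}

#' Measure lower-leg and whole-limb volumes of a width profile
#'
#' Detects the B/C/D/F landmarks and integrates the lower leg without the
#' foot, from B up to D (`leg_BD`), and the limb without the foot up to
#' mid-thigh, from B up to F (`limb_BF`).
#'
#' @param profile A [leg_profile] object.
#' @param foot_top_index Optional explicit foot-top slice index passed on to
#'   [detect_landmarks()].
#' @return A list of class `leg_measurement` with elements `leg_BD` (ml),
#'   `limb_BF` (ml) and `landmarks`.
#' @export
measure_leg <- function(profile, foot_top_index = NULL) {
  profile <- as_leg_profile(profile)
  geom <- circumference_profile(profile)
  lm_ <- detect_landmarks(geom, foot_top_index = foot_top_index)
  leg_BD <- segment_volume(profile, lm_$index_B, lm_$index_D)
  limb_BF <- segment_volume(profile, lm_$index_B, lm_$index_F)
  structure(
    list(leg_BD = leg_BD, limb_BF = limb_BF, landmarks = lm_),
    class = "leg_measurement"
  )
}

#' @export
print.leg_measurement <- function(x, ...) {
  cat(sprintf("Leg volumes: leg_BD %.1f ml, limb_BF %.1f ml\n",
              x$leg_BD, x$limb_BF))
  print(x$landmarks)
  invisible(x)
}
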