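#' Effect sizes injected into a simulated volumetry cohort
#'
#' Defaults reproduce the magnitudes reported for standing optoelectronic leg
#' volumetry in healthy adults: a diurnal volume drift of ~0.29 %/h for the
#' lower leg and ~0.26 %/h for the whole limb, an orthostatic increase of
#' 0.33 % (lower leg) / 0.52 % (limb) between two immediate replicates,
#' analytical noise of CV 0.5 % / 0.7 %, a total between-visit within-subject
#' CV of 1.3 %, and a between-subject spread of 17.5 % around the cohort
#' means.
#'
#' @param drift_legBD,drift_limbBF Diurnal drift in % of baseline per hour.
#' @param orthostatic_legBD,orthostatic_limbBF Volume increase in % per
#'   replicate step (replicate r is inflated by `ortho * (r - 1)` %).
#' @param cv_analytical_legBD,cv_analytical_limbBF Analytical (replicate)
#'   noise CV in %.
#' @param cv_within Target total between-visit within-subject CV of replicate
#'   means, in %. The injected day-to-day SD is
#'   `sqrt(cv_within^2 - cv_analytical^2 / n_replicates)` so the observed
#'   between-visit CV of replicate means matches `cv_within` when the drift
#'   contributes nothing.
#' @param between_subject_cv Between-subject CV of baseline volumes, in %.
#' @return A list of class `effect_params`.
#' @export
effect_params <- function(drift_legBD = 0.288, drift_limbBF = 0.259,
                          orthostatic_legBD = 0.33, orthostatic_limbBF = 0.52,
                          cv_analytical_legBD = 0.5,
                          cv_analytical_limbBF = 0.7,
                          cv_within = 1.3, between_subject_cv = 17.5) {
  p <- list(drift_legBD = drift_legBD, drift_limbBF = drift_limbBF,
            orthostatic_legBD = orthostatic_legBD,
            orthostatic_limbBF = orthostatic_limbBF,
            cv_analytical_legBD = cv_analytical_legBD,
            cv_analytical_limbBF = cv_analytical_limbBF,
            cv_within = cv_within, between_subject_cv = between_subject_cv)
  cvs <- c(p$cv_analytical_legBD, p$cv_analytical_limbBF, p$cv_within,
           p$between_subject_cv)
  if (any(!is.finite(unlist(p))) || any(cvs < 0)) {
    stop("effect_params(): CVs must be >= 0 and all parameters finite",
         call. = FALSE)
  }
  structure(p, class = "effect_params")
}

#' Configuration of a simulated two-visit volumetry cohort
#'
#' Mirrors the measurement protocol being emulated: each subject attends
#' `n_visits` visits (default two, three weeks apart), chooses a clock time
#' freely inside `visit_time_window`, and at each visit both legs are
#' measured `n_replicates` times in immediate succession.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; mandatory — the simulation is fully
#'   reproducible from the configuration.
#' @param sides Character vector of sides measured per subject.
#' @param n_visits,n_replicates Visits per subject and replicate measurements
#'   per visit (`n_replicates >= 2` so the analytical variance is estimable).
#' @param visit_time_window Decimal-hour window `c(lo, hi)` from which visit
#'   clock times are drawn uniformly.
#' @param visit_times Optional fixed clock times: a vector of length
#'   `n_visits` (shared by all subjects) or an `n_subjects x n_visits`
#'   matrix; overrides random time sampling.
#' @param weeks_between_visits Spacing between visits, weeks (metadata only).
#' @param effects An [effect_params] object.
#' @param mean_legBD,mean_limbBF Cohort mean baseline volumes in ml.
#' @param endpoint_correlation Correlation of the subject-level log-factors
#'   of the two volume endpoints.
#' @param drop_fraction Fraction of records dropped uniformly at random to
#'   emulate attrition (default 0: full 2 x 2 x 2 design for everyone).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 63, seed,
                          sides = c("left", "right"),
                          n_visits = 2, n_replicates = 2,
                          visit_time_window = c(8, 18),
                          visit_times = NULL,
                          weeks_between_visits = 3,
                          effects = effect_params(),
                          mean_legBD = 2297, mean_limbBF = 5875,
                          endpoint_correlation = 0.9,
                          drop_fraction = 0) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("cohort_config(): an integer seed is required", call. = FALSE)
  }
  if (n_subjects < 2) stop("cohort_config(): n_subjects must be >= 2",
                           call. = FALSE)
  if (n_replicates < 2) {
    stop("cohort_config(): n_replicates must be >= 2 for analytical-",
         "variance estimation", call. = FALSE)
  }
  if (n_visits < 1) stop("cohort_config(): n_visits must be >= 1",
                         call. = FALSE)
  if (visit_time_window[1] >= visit_time_window[2]) {
    stop("cohort_config(): visit_time_window lower bound must be below the ",
         "upper bound", call. = FALSE)
  }
  if (!inherits(effects, "effect_params")) {
    effects <- do.call(effect_params, as.list(effects))
  }
  if (!is.null(visit_times)) {
    if (is.matrix(visit_times)) {
      stopifnot(nrow(visit_times) == n_subjects,
                ncol(visit_times) == n_visits)
    } else {
      stopifnot(length(visit_times) == n_visits)
    }
  }
  if (drop_fraction < 0 || drop_fraction >= 1) {
    stop("cohort_config(): drop_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), sides = sides,
         n_visits = as.integer(n_visits),
         n_replicates = as.integer(n_replicates),
         visit_time_window = visit_time_window, visit_times = visit_times,
         weeks_between_visits = weeks_between_visits,
         seed = as.integer(seed), effects = effects,
         mean_legBD = mean_legBD, mean_limbBF = mean_limbBF,
         endpoint_correlation = endpoint_correlation,
         drop_fraction = drop_fraction),
    class = "cohort_config"
  )
}

#' Simulate a two-visit, duplicate-measurement volumetry cohort
#'
#' Generative model, multiplicative with all effects in percent. For subject
#' i, side s, visit v, replicate r measured at clock time t:
#' \deqn{V = V_{base}(i,s) (1 + drift (t - 8)/100) (1 + ortho (r-1)/100)
#'           (1 + \delta_{visit}(i,s,v)/100) (1 + \epsilon/100)}
#' with \eqn{V_{base}} log-normal around the cohort mean at the configured
#' between-subject CV (the two volume endpoints share a subject-side factor
#' at the configured correlation), \eqn{\delta_{visit}} a per-visit normal
#' day-to-day deviation with SD
#' `sqrt(cv_within^2 - cv_analytical^2 / n_replicates)`, and \eqn{\epsilon} a
#' per-measurement analytical deviation with SD `cv_analytical`. The drift is
#' anchored at the 08:00 start of the measurement window, so only the
#' between-visit clock-time difference creates a between-visit signal. All
#' normal deviates are truncated at ±5 SD so volumes stay positive. The same
#' configuration (including seed) always produces the identical table.
#'
#' @param config A [cohort_config] object.
#' @return A data frame of class `measurement_records`, one row per
#'   measurement: `subject_id`, `side`, `visit`, `replicate`,
#'   `clock_time_decimal`, `vol_legBD_ml`, `vol_limbBF_ml`.
#' @examples
#' cfg <- cohort_config(n_subjects = 5, seed = 42)
#' head(simulate_cohort(cfg))
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  ef <- config$effects
  k <- config$n_replicates
  sigma_day2 <- list(
    legBD = ef$cv_within^2 - ef$cv_analytical_legBD^2 / k,
    limbBF = ef$cv_within^2 - ef$cv_analytical_limbBF^2 / k
  )
  if (any(unlist(sigma_day2) < -1e-12)) {
    stop("simulate_cohort(): cv_within^2 < cv_analytical^2 / n_replicates; ",
         "the injected day-to-day variance would be negative", call. = FALSE)
  }
  sigma_day <- lapply(sigma_day2, function(x) sqrt(max(x, 0)))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  ns <- config$n_subjects
  sides <- config$sides
  nsd <- length(sides)
  nv <- config$n_visits

  # baseline volumes: one shared and one endpoint-specific standard normal
  # per subject-side, combined at the configured correlation
  rho <- config$endpoint_correlation
  z_shared <- rtnorm5(ns * nsd)
  z_indep <- rtnorm5(ns * nsd)
  z_leg <- z_shared
  z_limb <- rho * z_shared + sqrt(1 - rho^2) * z_indep
  cvb <- ef$between_subject_cv / 100
  sig_ln <- sqrt(log(1 + cvb^2))
  vbase_leg <- config$mean_legBD * exp(sig_ln * z_leg - sig_ln^2 / 2)
  vbase_limb <- config$mean_limbBF * exp(sig_ln * z_limb - sig_ln^2 / 2)

  # visit clock times: one per subject-visit (both legs and replicates share)
  if (is.null(config$visit_times)) {
    tt <- matrix(stats::runif(ns * nv, config$visit_time_window[1],
                              config$visit_time_window[2]),
                 nrow = ns, ncol = nv)
  } else if (is.matrix(config$visit_times)) {
    tt <- config$visit_times
  } else {
    tt <- matrix(config$visit_times, nrow = ns, ncol = nv, byrow = TRUE)
  }

  # day-to-day deviations: one per subject-side-visit and endpoint
  d_leg <- array(rtnorm5(ns * nsd * nv) * sigma_day$legBD,
                 dim = c(ns, nsd, nv))
  d_limb <- array(rtnorm5(ns * nsd * nv) * sigma_day$limbBF,
                  dim = c(ns, nsd, nv))

  grid <- expand.grid(replicate = seq_len(k), visit = seq_len(nv),
                      side = seq_len(nsd), subject = seq_len(ns),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$subject, grid$side, grid$visit, grid$replicate), ,
               drop = FALSE]
  m <- nrow(grid)

  eps_leg <- rtnorm5(m) * ef$cv_analytical_legBD
  eps_limb <- rtnorm5(m) * ef$cv_analytical_limbBF

  iss <- (grid$subject - 1L) * nsd + grid$side
  t_rec <- tt[cbind(grid$subject, grid$visit)]
  dd_leg <- d_leg[cbind(grid$subject, grid$side, grid$visit)]
  dd_limb <- d_limb[cbind(grid$subject, grid$side, grid$visit)]

  v_leg <- vbase_leg[iss] *
    (1 + ef$drift_legBD * (t_rec - 8) / 100) *
    (1 + ef$orthostatic_legBD * (grid$replicate - 1) / 100) *
    (1 + dd_leg / 100) * (1 + eps_leg / 100)
  v_limb <- vbase_limb[iss] *
    (1 + ef$drift_limbBF * (t_rec - 8) / 100) *
    (1 + ef$orthostatic_limbBF * (grid$replicate - 1) / 100) *
    (1 + dd_limb / 100) * (1 + eps_limb / 100)

  out <- data.frame(
    subject_id = sprintf("S%03d", grid$subject),
    side = sides[grid$side],
    visit = grid$visit,
    replicate = grid$replicate,
    clock_time_decimal = t_rec,
    vol_legBD_ml = v_leg,
    vol_limbBF_ml = v_limb,
    stringsAsFactors = FALSE
  )
  if (config$drop_fraction > 0) {
    keep <- stats::runif(m) >= config$drop_fraction
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("measurement_records", "data.frame")
  out
}

# standard normal truncated (clamped) at +/- 5 SD; keeps multiplicative
# percent noise from producing non-positive volumes
rtnorm5 <- function(n) {
  pmin(pmax(stats::rnorm(n), -5), 5)
}
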