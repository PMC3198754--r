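#' Analytical variance component from immediate duplicates
#'
#' Estimates the measurement error (analytical variance) from duplicate
#' measurements taken seconds apart, using the duplicate-difference form of
#' the within-subject variance: \eqn{s_A^2 = \sum d_i^2 / (2n)} over the
#' within-pair differences \eqn{d_i}. This equals the mean square within of a
#' replicate-level one-way ANOVA grouped by measurement occasion. The CV is
#' `100 * sqrt(s2) / grand mean` of all replicate values, so it is invariant
#' under rescaling all volumes.
#'
#' Note the differences enter uncentred: a systematic difference between the
#' first and second replicate (such as an orthostatic volume shift) is part
#' of the estimate, as in the classical duplicate-based definition.
#'
#' @param replicate_pairs Two-column matrix or data frame; each row the two
#'   replicate values (ml) of one measurement occasion.
#' @return List with `s2_analytical` (ml^2), `cv_analytical` (%),
#'   `grand_mean` (ml) and `n_pairs`.
#' @examples
#' analytical_component(rbind(c(100, 102), c(200, 198)))
#' @export
analytical_component <- function(replicate_pairs) {
  m <- as.matrix(replicate_pairs)
  if (ncol(m) != 2L) {
    stop("analytical_component(): expected a two-column matrix of duplicate ",
         "pairs", call. = FALSE)
  }
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) {
    stop("analytical_component(): need at least 2 duplicate pairs",
         call. = FALSE)
  }
  d <- m[, 1L] - m[, 2L]
  s2 <- sum(d^2) / (2 * n)
  gm <- mean(m)
  list(s2_analytical = s2, cv_analytical = 100 * sqrt(s2) / gm,
       grand_mean = gm, n_pairs = n)
}

#' Within-individual variance component across visits
#'
#' Estimates the between-visit within-subject variance from the per-visit
#' replicate means of each subject-leg: \eqn{s_W^2 = \sum (m_{1i} -
#' m_{2i})^2 / (2n)}. The analytical component is deliberately not
#' subtracted, so the CV reported here is the *total* between-visit
#' within-subject CV of replicate means; set `fraser_harris = TRUE` to also
#' obtain the analytically corrected component
#' \eqn{s_W^2 - s_A^2 / k}.
#'
#' @param visit_means Two-column matrix or data frame; each row one
#'   subject-leg, columns the visit-1 and visit-2 replicate means (ml). Rows
#'   with a missing visit are excluded with a warning.
#' @param fraser_harris Logical; also report the analytically corrected
#'   within-individual variance.
#' @param s2_analytical,n_replicates Analytical variance (ml^2) and
#'   replicates per visit mean, required when `fraser_harris = TRUE`.
#' @return List with `s2_within` (ml^2), `cv_within` (%), `grand_mean`,
#'   `n_subjects`, and when requested `s2_within_corrected` /
#'   `cv_within_corrected`.
#' @examples
#' within_individual_component(rbind(c(2000, 2020), c(3000, 2985)))
#' @export
within_individual_component <- function(visit_means, fraser_harris = FALSE,
                                        s2_analytical = NULL,
                                        n_replicates = 2) {
  m <- as.matrix(visit_means)
  if (ncol(m) != 2L) {
    stop("within_individual_component(): expected a two-column matrix of ",
         "per-visit means", call. = FALSE)
  }
  cc <- stats::complete.cases(m)
  if (any(!cc)) {
    warning(sum(!cc), " subject-leg(s) excluded: missing visit mean")
    m <- m[cc, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2L) {
    stop("within_individual_component(): need at least 2 subjects",
         call. = FALSE)
  }
  d <- m[, 1L] - m[, 2L]
  s2 <- sum(d^2) / (2 * n)
  gm <- mean(m)
  out <- list(s2_within = s2, cv_within = 100 * sqrt(s2) / gm,
              grand_mean = gm, n_subjects = n)
  if (fraser_harris) {
    if (is.null(s2_analytical)) {
      stop("within_individual_component(): fraser_harris = TRUE requires ",
           "s2_analytical", call. = FALSE)
    }
    s2c <- max(s2 - s2_analytical / n_replicates, 0)
    out$s2_within_corrected <- s2c
    out$cv_within_corrected <- 100 * sqrt(s2c) / gm
  }
  out
}

#' One-way intraclass correlation coefficient ICC(1,1)
#'
#' One-way random-effects ICC from the one-way ANOVA with subjects as
#' groups: `ICC = (MSB - MSW) / (MSB + (k - 1) * MSW)` with k measurements
#' (visits) per subject. Values near 1 mean the within-subject variation is
#' negligible relative to the between-subject spread; the algebraic lower
#' bound is `-1 / (k - 1)`.
#'
#' @param values Numeric matrix, subjects in rows, repeated measurements
#'   (visits) in columns; complete.
#' @return The ICC as a single number.
#' @examples
#' icc_oneway(rbind(c(10, 12), c(20, 19), c(30, 31)))
#' @export
icc_oneway <- function(values) {
  m <- as.matrix(values)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("icc_oneway(): need >= 2 subjects and >= 2 measurements each",
         call. = FALSE)
  }
  if (any(!stats::complete.cases(m))) {
    stop("icc_oneway(): matrix must be complete", call. = FALSE)
  }
  n <- nrow(m)
  k <- ncol(m)
  row_means <- rowMeans(m)
  grand <- mean(m)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  if (ssb + ssw <= 0) {
    stop("icc_oneway(): zero total variance, ICC undefined", call. = FALSE)
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Paired t comparison
#'
#' Classical two-sided paired t test on `after - before`, with the two
#' degenerate zero-spread cases handled explicitly: identical vectors give
#' `t = 0, p = 1`; a constant non-zero difference gives an infinite t
#' (flagged) with `p = 0`.
#'
#' @param before,after Numeric vectors of equal length >= 2.
#' @return List of class `paired_comparison`: `mean_diff`, `sd_diff`,
#'   `t_statistic`, `df`, `p_value`, `n_pairs`, `degenerate`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop("paired_t(): before and after must have equal lengths",
         call. = FALSE)
  }
  d <- after - before
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("paired_t(): need at least 2 pairs", call. = FALSE)
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (md == 0) {
      res <- list(mean_diff = 0, sd_diff = 0, t_statistic = 0, df = n - 1,
                  p_value = 1, n_pairs = n, degenerate = TRUE)
    } else {
      res <- list(mean_diff = md, sd_diff = 0,
                  t_statistic = sign(md) * Inf, df = n - 1, p_value = 0,
                  n_pairs = n, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(after, before, paired = TRUE)
    res <- list(mean_diff = md, sd_diff = sd_d,
                t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, n_pairs = n, degenerate = FALSE)
  }
  class(res) <- "paired_comparison"
  res
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "paired t: mean diff %.4g +/- %.4g (n = %d), t = %.3g, p = %.3g%s\n",
    x$mean_diff, x$sd_diff, x$n_pairs, x$t_statistic, x$p_value,
    if (x$degenerate) " [degenerate: zero spread]" else ""))
  invisible(x)
}

#' Variance-component and duplicate-shift summary of a measurement cohort
#'
#' For each side and each volume endpoint (lower leg B-D and whole limb
#' B-F) computes: the analytical CV from within-visit duplicate pairs pooled
#' over all visits; the within-individual CV and one-way ICC from the
#' between-visit replicate means (replicates are averaged per visit before
#' any between-visit analysis); and the replicate-1 to replicate-2 increase
#' in ml and in percent with its paired t test, pooled over visits. A pooled
#' both-legs row accompanies the per-side duplicate-shift summaries.
#'
#' @param records A `measurement_records` data frame (from
#'   [simulate_cohort()] or [read_measurements()]).
#' @param fraser_harris Logical; additionally report the analytically
#'   corrected within-individual CV (`s_W^2 - s_A^2 / k`).
#' @return An object of class `cohort_summary`: a list with `components`
#'   (data frame: side, volume_type, grand_mean_ml, cv_a_pct, cv_w_pct, icc,
#'   n_subject_legs, and corrected columns when requested) and
#'   `replicate_shift` (data frame of mean duplicate increases with t/p, per
#'   side and pooled).
#' @export
summarize_cohort <- function(records, fraser_harris = FALSE) {
  records <- validate_records(records)
  if (length(unique(records$subject_id)) < 2L) {
    stop("summarize_cohort(): need records from at least 2 subjects",
         call. = FALSE)
  }
  endpoints <- c(legBD = "vol_legBD_ml", limbBF = "vol_limbBF_ml")
  sides <- sort(unique(records$side))
  n_rep <- max(records$replicate)

  comp_rows <- list()
  shift_rows <- list()
  for (ep in names(endpoints)) {
    col <- endpoints[[ep]]
    for (sd_ in sides) {
      sub <- records[records$side == sd_, ]
      pairs <- replicate_pair_matrix(sub, col)
      an <- analytical_component(pairs)
      vm <- visit_mean_matrix(sub, col)
      icc <- tryCatch(icc_oneway(vm), error = function(e) NA_real_)
      wi <- within_individual_component(
        vm, fraser_harris = fraser_harris,
        s2_analytical = an$s2_analytical, n_replicates = n_rep)
      row <- data.frame(
        side = sd_, volume_type = ep,
        grand_mean_ml = an$grand_mean,
        cv_a_pct = an$cv_analytical,
        cv_w_pct = wi$cv_within,
        icc = icc,
        n_subject_legs = wi$n_subjects,
        stringsAsFactors = FALSE
      )
      if (fraser_harris) row$cv_w_corrected_pct <- wi$cv_within_corrected
      comp_rows[[paste(ep, sd_)]] <- row
      shift_rows[[paste(ep, sd_)]] <- replicate_shift_row(sub, col, ep, sd_)
    }
    shift_rows[[paste(ep, "both")]] <-
      replicate_shift_row(records, col, ep, "both")
  }
  structure(
    list(components = do.call(rbind, c(comp_rows, make.row.names = FALSE)),
         replicate_shift = do.call(rbind,
                                   c(shift_rows, make.row.names = FALSE)),
         n_records = nrow(records),
         fraser_harris = fraser_harris),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, digits = 4, ...) {
  cat("Cohort reproducibility summary (", x$n_records, " measurements)\n\n",
      sep = "")
  cat("Variance components (CVs in %, volumes in ml):\n")
  print(format_num_df(x$components, digits), row.names = FALSE)
  cat("\nReplicate 1 -> 2 volume shift (pooled over visits):\n")
  print(format_num_df(x$replicate_shift, digits), row.names = FALSE)
  invisible(x)
}

format_num_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  df
}

# wide matrix of replicate pairs (r1, r2) per subject-side-visit
replicate_pair_matrix <- function(records, col) {
  key <- interaction(records$subject_id, records$side, records$visit,
                     drop = TRUE)
  r1 <- records$replicate == 1L
  r2 <- records$replicate == 2L
  v1 <- tapply(records[[col]][r1], key[r1], mean)
  v2 <- tapply(records[[col]][r2], key[r2], mean)
  common <- intersect(names(v1), names(v2))
  cbind(v1 = as.numeric(v1[common]), v2 = as.numeric(v2[common]))
}

# subjects-x-visits matrix of replicate means per subject-side
visit_mean_matrix <- function(records, col) {
  key <- interaction(records$subject_id, records$side, drop = TRUE)
  visits <- sort(unique(records$visit))
  out <- sapply(visits, function(v) {
    sel <- records$visit == v
    as.numeric(tapply(records[[col]][sel], key[sel], mean)[levels(key)])
  })
  rownames(out) <- levels(key)
  out
}

replicate_shift_row <- function(records, col, ep, side_label) {
  key <- interaction(records$subject_id, records$side, records$visit,
                     drop = TRUE)
  r1 <- records$replicate == 1L
  r2 <- records$replicate == 2L
  v1 <- tapply(records[[col]][r1], key[r1], mean)
  v2 <- tapply(records[[col]][r2], key[r2], mean)
  common <- intersect(names(v1), names(v2))
  v1 <- as.numeric(v1[common]); v2 <- as.numeric(v2[common])
  tt_abs <- paired_t(v1, v2)
  rel <- 100 * (v2 - v1) / v1
  data.frame(
    side = side_label, volume_type = ep,
    mean_increase_ml = tt_abs$mean_diff, sd_increase_ml = tt_abs$sd_diff,
    mean_increase_pct = mean(rel), sd_increase_pct = stats::sd(rel),
    t_statistic = tt_abs$t_statistic, p_value = tt_abs$p_value,
    n_pairs = tt_abs$n_pairs, stringsAsFactors = FALSE
  )
}
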