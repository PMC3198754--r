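#' Read a measurement-record CSV
#'
#' Expects the documented schema: header `subject_id, side, visit, replicate,
#' clock_time_decimal, vol_legBD_ml, vol_limbBF_ml`, UTF-8, `.` decimal
#' separator. All malformed rows are collected and reported together with
#' their line numbers (line 1 is the header).
#'
#' @param path Path to the CSV file.
#' @return A `measurement_records` data frame (possibly empty, with a
#'   warning, if the file holds only a header).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop("read_measurements(): no such file: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(records_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("read_measurements(): missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("read_measurements(): ", path, " contains a header only")
    out <- empty_records()
    return(out)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  visit <- num(raw$visit); replicate <- num(raw$replicate)
  ct <- num(raw$clock_time_decimal)
  v_leg <- num(raw$vol_legBD_ml); v_limb <- num(raw$vol_limbBF_ml)

  problems <- character(0)
  line <- seq_len(nrow(raw)) + 1L
  flag <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, paste0(
        what, " on line ", paste(line[bad], collapse = ", ")))
    }
  }
  flag(is.na(visit) | visit != round(visit) | visit < 1, "invalid visit")
  flag(is.na(replicate) | replicate != round(replicate) | replicate < 1,
       "invalid replicate")
  flag(is.na(ct) | ct < 0 | ct >= 24,
       "clock time outside [0, 24) or non-numeric")
  flag(is.na(v_leg) | v_leg <= 0, "non-positive or non-numeric vol_legBD_ml")
  flag(is.na(v_limb) | v_limb <= 0,
       "non-positive or non-numeric vol_limbBF_ml")
  if (length(problems) > 0L) {
    stop("read_measurements(): validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  out <- data.frame(
    subject_id = raw$subject_id, side = raw$side,
    visit = as.integer(visit), replicate = as.integer(replicate),
    clock_time_decimal = ct, vol_legBD_ml = v_leg, vol_limbBF_ml = v_limb,
    stringsAsFactors = FALSE
  )
  class(out) <- c("measurement_records", "data.frame")
  out
}

records_columns <- function() {
  c("subject_id", "side", "visit", "replicate", "clock_time_decimal",
    "vol_legBD_ml", "vol_limbBF_ml")
}

empty_records <- function() {
  out <- data.frame(
    subject_id = character(0), side = character(0), visit = integer(0),
    replicate = integer(0), clock_time_decimal = numeric(0),
    vol_legBD_ml = numeric(0), vol_limbBF_ml = numeric(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("measurement_records", "data.frame")
  out
}

validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop("expected a measurement_records data frame", call. = FALSE)
  }
  missing_cols <- setdiff(records_columns(), names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) > 0L &&
      (any(records$vol_legBD_ml <= 0) || any(records$vol_limbBF_ml <= 0))) {
    stop("records contain non-positive volumes", call. = FALSE)
  }
  records
}

#' Write measurement records to CSV
#'
#' Inverse of [read_measurements()]: same column order, UTF-8, `.` decimal
#' separator, no row names. `write_measurements()` then
#' `read_measurements()` reproduces the input (up to numeric printing at 15
#' significant digits).
#'
#' @param records A `measurement_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  records <- validate_records(records)
  out <- as.data.frame(records)[records_columns()]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a silhouette width-profile CSV
#'
#' One file per leg scan with columns `height_mm, front_width_mm,
#' side_width_mm`; the slice thickness is inferred from the height step.
#'
#' @param path CSV path.
#' @param slice_thickness Optional expected slice thickness (mm); validated
#'   against the height step when given.
#' @return `read_profile_csv()`: a [leg_profile]. `write_profile_csv()`:
#'   `path`, invisibly.
#' @export
read_profile_csv <- function(path, slice_thickness = NULL) {
  if (!file.exists(path)) {
    stop("read_profile_csv(): no such file: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("height_mm", "front_width_mm", "side_width_mm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("read_profile_csv(): missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  leg_profile(raw$height_mm, raw$front_width_mm, raw$side_width_mm,
              slice_thickness = slice_thickness)
}

#' @rdname read_profile_csv
#' @param profile A [leg_profile] to write.
#' @export
write_profile_csv <- function(profile, path) {
  profile <- as_leg_profile(profile)
  out <- data.frame(height_mm = sprintf("%.15g", profile$heights),
                    front_width_mm = sprintf("%.15g", profile$front_width),
                    side_width_mm = sprintf("%.15g", profile$side_width))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML file with an optional `cohort:` block (arguments of
#' [cohort_config()], including an `effects:` sub-block with
#' [effect_params()] arguments), and top-level keys `correction_source`
#' (`"published"` or `"derived"`), `fraser_harris`, `decimals`, and
#' optionally `measurements_csv` to ingest an existing record table instead
#' of simulating. A seed is mandatory (in the file or via the `seed`
#' argument).
#'
#' @param path YAML config path.
#' @param seed Optional seed overriding the file.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    stop("read_pipeline_config(): no such file: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  build_pipeline_config(cfg, seed = seed)
}

#' Assemble a pipeline configuration from a list
#'
#' @param cfg Named list mirroring the YAML schema of
#'   [read_pipeline_config()]; may be empty for all-defaults.
#' @param seed Seed overriding `cfg$cohort$seed`.
#' @return A list of class `pipeline_config`.
#' @export
build_pipeline_config <- function(cfg = list(), seed = NULL) {
  cohort_args <- if (is.null(cfg$cohort)) list() else cfg$cohort
  if (!is.null(seed)) cohort_args$seed <- seed
  if (is.null(cohort_args$seed) && is.null(cfg$measurements_csv)) {
    stop("pipeline config: a seed is required (config cohort.seed or the ",
         "seed argument/flag)", call. = FALSE)
  }
  if (!is.null(cohort_args$effects) &&
      !inherits(cohort_args$effects, "effect_params")) {
    cohort_args$effects <- do.call(effect_params,
                                   as.list(cohort_args$effects))
  }
  cohort <- if (is.null(cfg$measurements_csv)) {
    do.call(cohort_config, cohort_args)
  } else NULL
  source <- cfg$correction_source
  if (is.null(source)) source <- "derived"
  if (!source %in% c("published", "derived")) {
    stop("pipeline config: correction_source must be 'published' or ",
         "'derived'", call. = FALSE)
  }
  structure(
    list(cohort = cohort,
         measurements_csv = cfg$measurements_csv,
         correction_source = source,
         fraser_harris = isTRUE(cfg$fraser_harris),
         decimals = if (is.null(cfg$decimals)) 2L else
           as.integer(cfg$decimals)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline and write an output bundle
#'
#' Executes simulate (or ingest) -> variance-component summary -> pooled
#' time-volume regression -> correction coefficients (published or derived)
#' -> cohort correction -> corrected summary, and writes the bundle to
#' `out_dir`: `measurements.csv`, `components.csv`, `replicate_shift.csv`,
#' `coefficients.yaml`, `measurements_corrected.csv`,
#' `components_corrected.csv` and `run_log.txt` (seed, package version and
#' full parameter echo — enough to reproduce the bundle exactly). A failing
#' stage aborts with the stage name and removes any partial outputs.
#'
#' @param config A `pipeline_config` (from [read_pipeline_config()] or
#'   [build_pipeline_config()]) or a path to a YAML config file.
#' @param out_dir Output directory, created if needed.
#' @param seed Optional seed overriding the config (only when `config` is a
#'   path).
#' @return Invisibly, a list with the in-memory `records`, `summary`,
#'   `fits`, `coefficients`, `corrected` objects and the written `files`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- read_pipeline_config(config, seed = seed)
  }
  if (!inherits(config, "pipeline_config")) {
    stop("run_pipeline(): config must be a pipeline_config or a YAML path",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(fname, writer) {
    p <- file.path(out_dir, fname)
    writer(p)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  tryCatch({
    stage <- "simulate/ingest"
    records <- if (is.null(config$measurements_csv)) {
      simulate_cohort(config$cohort)
    } else {
      read_measurements(config$measurements_csv)
    }
    emit("measurements.csv", function(p) write_measurements(records, p))

    stage <- "analyze"
    summary_ <- summarize_cohort(records,
                                 fraser_harris = config$fraser_harris)
    emit("components.csv", function(p) {
      utils::write.csv(summary_$components, p, row.names = FALSE,
                       quote = FALSE)
    })
    emit("replicate_shift.csv", function(p) {
      utils::write.csv(summary_$replicate_shift, p, row.names = FALSE,
                       quote = FALSE)
    })

    stage <- "regression"
    fits <- list(
      legBD = fit_time_volume_regression(records, "legBD", "relative_pct"),
      limbBF = fit_time_volume_regression(records, "limbBF", "relative_pct")
    )

    stage <- "coefficients"
    coefficients <- if (config$correction_source == "published") {
      published_coefficients()
    } else {
      derive_correction(records)
    }
    emit("coefficients.yaml", function(p) {
      yaml::write_yaml(coefficients_to_list(coefficients), p)
    })

    stage <- "correct"
    corrected <- correct_cohort(records, coefficients,
                                fraser_harris = config$fraser_harris)
    emit("measurements_corrected.csv", function(p) {
      write_measurements(corrected$records, p)
    })
    emit("components_corrected.csv", function(p) {
      utils::write.csv(corrected$corrected$components, p, row.names = FALSE,
                       quote = FALSE)
    })

    stage <- "log"
    emit("run_log.txt", function(p) {
      writeLines(pipeline_log_lines(config, coefficients,
                                    nrow(records)), p)
    })

    invisible(list(records = records, summary = summary_, fits = fits,
                   coefficients = coefficients, corrected = corrected,
                   files = written))
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

coefficients_to_list <- function(x) {
  out <- list(coeff_legBD = x$coeff_legBD, coeff_limbBF = x$coeff_limbBF,
              source = x$source)
  if (!is.null(x$provenance)) out$provenance <- x$provenance
  out
}

pipeline_log_lines <- function(config, coefficients, n_records) {
  cohort_echo <- if (is.null(config$cohort)) {
    paste0("ingested: ", config$measurements_csv)
  } else {
    cc <- config$cohort
    paste0(
      "seed=", cc$seed, " n_subjects=", cc$n_subjects,
      " sides=", paste(cc$sides, collapse = "+"),
      " n_visits=", cc$n_visits, " n_replicates=", cc$n_replicates,
      " window=[", cc$visit_time_window[1], ",", cc$visit_time_window[2],
      "] drop_fraction=", cc$drop_fraction, " effects={",
      paste(names(unclass(cc$effects)), unlist(cc$effects), sep = "=",
            collapse = ", "), "}"
    )
  }
  c(paste0("perovol pipeline, package version ",
           as.character(utils::packageVersion("perovol"))),
    paste0("records: ", n_records),
    paste0("cohort: ", cohort_echo),
    paste0("correction: source=", coefficients$source,
           " coeff_legBD=", coefficients$coeff_legBD,
           " coeff_limbBF=", coefficients$coeff_limbBF))
}
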