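SAMPLE_COLUMNS <- c("time_min", "counts", "duration_s", "volume_mL",
                    "detector", "compartment", "pre_injection")

#' Construct a blood examination object
#'
#' An examination bundles every blood sample drawn while a participant is in
#' the PET system: the continuous automatic blood sampling system (ABSS)
#' stream, the manual whole-blood and plasma samples, the parent-fraction
#' measurements, and the instrument constants needed to assemble model
#' offsets.
#'
#' @param samples data.frame with columns `time_min` (minutes post
#'   injection), `counts` (recorded gamma counts, non-negative integer),
#'   `duration_s` (counting duration, seconds), `volume_mL` (sample volume),
#'   `detector` (`"abss"` or `"manual"`), `compartment` (`"whole_blood"` or
#'   `"plasma"`) and logical `pre_injection`.
#' @param pf_measurements data.frame with columns `time_min` and
#'   `parent_fraction` (in `[0, 1]`).
#' @param half_life_min isotope half-life in minutes (carbon-11: 20.36).
#' @param kappa_s ABSS external dispersion constant \eqn{\kappa} in seconds.
#' @param rho_per_mL gamma-counter volume-calibration factor \eqn{\rho}
#'   entering the offset as \eqn{e^{\rho \cdot vol}}.
#' @param abss_cutoff_min time after which manual samples bypass the ABSS
#'   tubing and receive no dispersion correction (default 10 min).
#' @param exam_id label for the examination.
#'
#' @return An object of class `blood_exam`.
#' @export
blood_exam <- function(samples, pf_measurements = NULL,
                       half_life_min = 20.36, kappa_s = 2.5,
                       rho_per_mL = 0, abss_cutoff_min = 10,
                       exam_id = "exam") {
  if (is.null(pf_measurements)) {
    pf_measurements <- data.frame(time_min = numeric(0),
                                  parent_fraction = numeric(0))
  }
  exam <- structure(list(
    exam_id = as.character(exam_id),
    samples = as.data.frame(samples, stringsAsFactors = FALSE),
    pf_measurements = as.data.frame(pf_measurements),
    half_life_min = half_life_min,
    kappa_s = kappa_s,
    rho_per_mL = rho_per_mL,
    abss_cutoff_min = abss_cutoff_min
  ), class = "blood_exam")
  validate_exam(exam)
  exam
}

#' Validate a blood examination
#'
#' Checks the per-sample invariants (integer non-negative counts, positive
#' durations and volumes, ABSS samples measured in whole blood), the
#' parent-fraction range, and time ordering within each detector stream.
#'
#' @param exam a `blood_exam`.
#' @return `exam`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_exam <- function(exam) {
  s <- exam$samples
  missing_cols <- setdiff(SAMPLE_COLUMNS, names(s))
  if (length(missing_cols) > 0L) {
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("invalid sample row %d: %s", which(!ok)[1L], what),
           call. = FALSE)
    }
  }
  bad_row(is.finite(s$time_min) & s$time_min >= 0, "time_min must be >= 0")
  bad_row(is.finite(s$counts) & s$counts >= 0 &
            abs(s$counts - round(s$counts)) < 1e-8,
          "counts must be a non-negative integer")
  bad_row(is.finite(s$duration_s) & s$duration_s > 0, "duration_s must be > 0")
  bad_row(is.finite(s$volume_mL) & s$volume_mL > 0, "volume_mL must be > 0")
  bad_row(s$detector %in% c("abss", "manual"), "unknown detector")
  bad_row(s$compartment %in% c("whole_blood", "plasma"), "unknown compartment")
  bad_row(!(s$detector == "abss" & s$compartment != "whole_blood"),
          "abss samples must be whole_blood")
  if (nrow(exam$pf_measurements) > 0) {
    pf <- exam$pf_measurements$parent_fraction
    if (any(!is.finite(pf) | pf < 0 | pf > 1)) {
      stop(sprintf("invalid parent fraction in row %d: must be in [0, 1]",
                   which(!is.finite(pf) | pf < 0 | pf > 1)[1L]), call. = FALSE)
    }
  }
  for (det in c("abss", "manual")) {
    tt <- s$time_min[s$detector == det & !s$pre_injection]
    if (length(tt) > 1 && any(diff(tt) < -1e-9)) {
      # manual streams interleave whole blood and plasma at shared times
      tt_wb <- s$time_min[s$detector == det & !s$pre_injection &
                            s$compartment == "whole_blood"]
      tt_pl <- s$time_min[s$detector == det & !s$pre_injection &
                            s$compartment == "plasma"]
      if ((length(tt_wb) > 1 && any(diff(tt_wb) < -1e-9)) ||
          (length(tt_pl) > 1 && any(diff(tt_pl) < -1e-9))) {
        stop("sample times must be non-decreasing within each detector stream",
             call. = FALSE)
      }
    }
  }
  if (!any(!s$pre_injection)) {
    stop("examination has no post-injection samples", call. = FALSE)
  }
  invisible(exam)
}

#' Read a per-sample blood table into an examination
#'
#' @param table_path path to a CSV (`.csv`) or TSV (any other extension)
#'   table with the sample schema of [blood_exam()].
#' @param constants either a list with elements `half_life_min`, `kappa_s`,
#'   `rho_per_mL` (optionally `abss_cutoff_min`, `exam_id`) or a path to a
#'   JSON file holding them.
#' @param pf_path optional path to a two-column table (`time_min`,
#'   `parent_fraction`); if `NULL` and the constants block contains a
#'   `pf_measurements` element, that is used.
#'
#' @return A validated `blood_exam`. Row order is preserved within each
#'   detector stream and counts are coerced to integer only when exactly
#'   integral.
#' @export
parse_blood_table <- function(table_path, constants, pf_path = NULL) {
  sep <- if (grepl("\\.csv$", table_path, ignore.case = TRUE)) "," else "\t"
  s <- utils::read.table(table_path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(SAMPLE_COLUMNS, names(s))
  if (length(missing_cols) > 0L) {
    stop("schema error: table lacks column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  s$pre_injection <- as.logical(s$pre_injection)
  if (is.character(constants)) constants <- jsonlite::read_json(constants,
                                                                simplifyVector = TRUE)
  pf <- NULL
  if (!is.null(pf_path)) {
    psep <- if (grepl("\\.csv$", pf_path, ignore.case = TRUE)) "," else "\t"
    pf <- utils::read.table(pf_path, header = TRUE, sep = psep)
  } else if (!is.null(constants$pf_measurements)) {
    pf <- as.data.frame(constants$pf_measurements)
  }
  blood_exam(samples = s[, SAMPLE_COLUMNS],
             pf_measurements = pf,
             half_life_min = constants$half_life_min,
             kappa_s = constants$kappa_s,
             rho_per_mL = constants$rho_per_mL,
             abss_cutoff_min = constants$abss_cutoff_min %||% 10,
             exam_id = constants$exam_id %||% "exam")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an examination back to disk
#'
#' Writes the sample table as TSV and, optionally, the constants (plus
#' parent-fraction measurements) as JSON so that
#' `parse_blood_table(write_examination(...))` is the identity.
#'
#' @param exam a `blood_exam`.
#' @param table_path output path for the TSV sample table.
#' @param constants_path optional output path for the JSON constants block.
#' @return `table_path`, invisibly.
#' @export
write_examination <- function(exam, table_path, constants_path = NULL) {
  utils::write.table(exam$samples, table_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(constants_path)) {
    jsonlite::write_json(list(
      exam_id = exam$exam_id,
      half_life_min = exam$half_life_min,
      kappa_s = exam$kappa_s,
      rho_per_mL = exam$rho_per_mL,
      abss_cutoff_min = exam$abss_cutoff_min,
      pf_measurements = exam$pf_measurements
    ), constants_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(table_path)
}

#' Subtract detector background from ABSS counts
#'
#' The background rate is estimated as the mean counts-per-second over the
#' pre-injection ABSS samples and subtracted from every post-injection ABSS
#' sample; results are rounded to the nearest integer and clamped at zero so
#' counts remain valid Poisson support. Manual samples are untouched and the
#' pre-injection samples are dropped from the returned examination.
#'
#' @param exam a `blood_exam` containing at least one pre-injection ABSS
#'   sample.
#' @return A `blood_exam` with background-corrected ABSS counts.
#' @export
subtract_background <- function(exam) {
  s <- exam$samples
  pre <- s$pre_injection & s$detector == "abss"
  if (!any(pre)) {
    stop("no pre-injection ABSS samples: skip background subtraction ",
         "explicitly if your data are already background-corrected",
         call. = FALSE)
  }
  b <- mean(s$counts[pre] / s$duration_s[pre])
  post_abss <- !s$pre_injection & s$detector == "abss"
  s$counts[post_abss] <- pmax(0, round(s$counts[post_abss] -
                                         b * s$duration_s[post_abss]))
  exam$samples <- s[!s$pre_injection, , drop = FALSE]
  rownames(exam$samples) <- NULL
  exam$background_rate_cps <- b
  validate_exam(exam)
  exam
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i] <- mean(x[j])
  }
  out
}

#' Restrict an examination to the descent of the curve
#'
#' Locates the peak as the time of the maximum of a moving average of the
#' ABSS counts-per-second series (falling back to manual whole-blood rates
#' when no ABSS stream is present) and retains all samples drawn at or after
#' that time. Models are fitted to the descent only; the short ascent is not
#' modelled.
#'
#' @param exam a `blood_exam` with post-injection samples.
#' @param window moving-average window in samples (default 5); ties are
#'   broken to the earliest maximum.
#' @return A `blood_exam` restricted to `time_min >= t_peak`, with the peak
#'   time attached as `$peak_time_min`.
#' @export
select_descent <- function(exam, window = 5L) {
  s <- exam$samples[!exam$samples$pre_injection, , drop = FALSE]
  abss <- s[s$detector == "abss", , drop = FALSE]
  if (nrow(abss) > 0) {
    cps <- moving_average(abss$counts / abss$duration_s, window)
    t_peak <- abss$time_min[which.max(cps)]
  } else {
    wb <- s[s$compartment == "whole_blood", , drop = FALSE]
    if (nrow(wb) == 0) {
      stop("cannot locate peak: no ABSS stream and no manual whole-blood ",
           "samples", call. = FALSE)
    }
    t_peak <- wb$time_min[which.max(wb$counts / wb$duration_s)]
  }
  exam$samples <- s[s$time_min >= t_peak - 1e-12, , drop = FALSE]
  rownames(exam$samples) <- NULL
  exam$peak_time_min <- t_peak
  validate_exam(exam)
  exam
}

#' Export an interpolated AIF as a two-column TSV
#'
#' Writes `time_min` and the model's decay-corrected parent-plasma estimate
#' (manual reference by default) for downstream kinetic-modelling tools.
#'
#' @param fit an [aif_fit] object.
#' @param times time grid in minutes.
#' @param path output TSV path.
#' @param reference `"manual"` (default, ABSS bias removed) or `"abss"`.
#' @param ... further arguments passed to [predict_aif()].
#' @return `path`, invisibly.
#' @export
export_aif_tsv <- function(fit, times, path, reference = "manual", ...) {
  pr <- predict_aif(fit, times, reference = reference, ...)
  utils::write.table(data.frame(time_min = times, aif = pr$estimate),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.blood_exam <- function(x, ...) {
  s <- x$samples
  cat(sprintf("Blood examination '%s'\n", x$exam_id))
  cat(sprintf("  %d samples (%d ABSS, %d manual wb, %d plasma; %d pre-injection)\n",
              nrow(s), sum(s$detector == "abss" & !s$pre_injection),
              sum(s$detector == "manual" & s$compartment == "whole_blood"),
              sum(s$compartment == "plasma"), sum(s$pre_injection)))
  cat(sprintf("  %d parent-fraction measurements\n", nrow(x$pf_measurements)))
  cat(sprintf("  half-life %.2f min, kappa %.2f s, rho %.4g /mL\n",
              x$half_life_min, x$kappa_s, x$rho_per_mL))
  invisible(x)
}
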