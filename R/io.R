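# CSV / JSON interchange. CSV is the interchange format (there is no
# community standard for syllectograms); column names are fixed:
#   syllectograms: time_s, intensity
#   cohort tables: subject_id, group, repeat_idx, minutes_after_draw,
#                  eak5s_true, eak5s_fitted [, hematocrit_pct]

#' Read a syllectogram from CSV
#'
#' Expects columns `time_s` and `intensity`; any additional constant columns
#' are kept as metadata. Times are re-based so the first sample is at t = 0
#' (a message reports a non-zero offset). Malformed files — fewer than 8
#' rows, non-increasing times, non-positive intensities — produce errors
#' naming the offending row.
#'
#' @param path Path to a CSV file.
#' @return A [syllectogram()]; `meta$source` records the file, and
#'   `meta$time_offset_s` any re-basing applied.
#' @export
read_syllectogram_csv <- function(path) {
  if (!file.exists(path)) {
    stop_eak(sprintf("file not found: %s", path), "eak_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_eak(sprintf("%s: missing required column(s): %s", path,
                     paste(missing_cols, collapse = ", ")), "eak_io_error")
  }
  if (nrow(df) < 8L) {
    stop_eak(sprintf("%s: a syllectogram needs at least 8 rows, got %d",
                     path, nrow(df)), "eak_io_error")
  }
  t <- as.numeric(df$time_s)
  if (any(!is.finite(t))) {
    stop_eak(sprintf("%s: non-numeric time_s at row %d", path,
                     which(!is.finite(t))[1L]), "eak_io_error")
  }
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1L] + 1L
    stop_eak(sprintf("%s: time_s not strictly increasing at row %d", path, bad),
             "eak_io_error")
  }
  I <- as.numeric(df$intensity)
  if (any(!is.finite(I) | I <= 0)) {
    bad <- which(!is.finite(I) | I <= 0)[1L]
    stop_eak(sprintf("%s: non-positive or missing intensity at row %d", path, bad),
             "eak_io_error")
  }
  offset <- t[1L]
  if (offset != 0) {
    message(sprintf("re-based times by -%.6g s so the recording starts at t = 0", offset))
    t <- t - offset
  }
  meta <- list(source = path, time_offset_s = offset)
  extra <- setdiff(names(df), need)
  for (col in extra) {
    vals <- unique(df[[col]])
    if (length(vals) == 1L) meta[[col]] <- vals
  }
  syllectogram(t, I, meta = meta)
}

#' Write a syllectogram to CSV
#'
#' @param s A [syllectogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_syllectogram_csv <- function(s, path) {
  stopifnot(inherits(s, "syllectogram"))
  utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  invisible(path)
}

#' Serialise a fit result as a report list
#'
#' Turns fit objects into plain lists suitable for JSON serialisation.
#'
#' @param x A `"mono_exp_fit"`, `"model1_fit"`, `"bi_exp_fit"` or
#'   `"segment_selection"`.
#' @return A named list of plain values.
#' @export
as_report <- function(x) UseMethod("as_report")

#' @export
as_report.mono_exp_fit <- function(x) {
  list(model = "mono-exponential",
       A0 = x$params$A0, k_per_s = x$params$k,
       half_life_s = x$half_life, r2 = x$r2,
       segment_duration_s = x$segment_duration,
       n_points = x$n_points, converged = x$converged, offset = x$offset)
}

#' @export
as_report.model1_fit <- function(x) {
  list(model = "inverse-linear",
       k = x$slope, inv_A0 = x$intercept, r2 = x$r2,
       n_points = x$n_points, under_determined = x$under_determined)
}

#' @export
as_report.bi_exp_fit <- function(x) {
  p <- x$params
  list(model = "bi-exponential",
       I_f = p$I_f, k_f_s = p$k_f, I_s = p$I_s, k_s_s = p$k_s, I_0 = p$I_0,
       r2 = x$r2, converged = x$converged, clamped = x$clamped,
       init = list(I_f = x$init_params$I_f, k_f_s = x$init_params$k_f,
                   I_s = x$init_params$I_s, k_s_s = x$init_params$k_s,
                   I_0 = x$init_params$I_0))
}

#' @export
as_report.segment_selection <- function(x) {
  list(model = "segment-selection",
       best_duration_s = x$best_duration, rule = x$rule,
       segments = lapply(x$fits, function(f) {
         if (is.null(f)) list(converged = FALSE) else as_report(f)
       }))
}

#' Write a report list as JSON
#'
#' @param report A list (e.g. from [as_report()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
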