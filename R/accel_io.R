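# Reading and writing logger traces, deployment tables and metrics tables.

#' Accelerometer CSV dialect
#'
#' The shipped default mimics a pendant-logger export reduced to plain CSV:
#' no skipped header lines, one timestamp column in seconds from event
#' start, and one column per axis in g. Field exports with leading metadata
#' lines are handled via `skip`.
#'
#' @param time_col,x_col,y_col,z_col column names.
#' @param skip number of lines to skip before the header.
#' @return a list of class `accel_dialect`.
#' @export
accel_dialect <- function(time_col = "t_s", x_col = "x_g", y_col = "y_g",
                          z_col = "z_g", skip = 0L) {
  structure(list(time_col = time_col, x_col = x_col, y_col = y_col,
                 z_col = z_col, skip = as.integer(skip)),
            class = "accel_dialect")
}

#' Read a tri-axial accelerometer trace
#'
#' Validates the schema and timestamps, clips out-of-range samples to the
#' logger range with a warning giving the count, and flags (but keeps)
#' timestamp gaps via the `gap_count` attribute. Timestamps are seconds
#' since event start and must be strictly increasing.
#'
#' @param path CSV file.
#' @param dialect an [accel_dialect()].
#' @param clip_g logger range in g (default 3.0).
#' @param event_id event identifier; defaults to the file name stripped of
#'   `_accel.csv`/`.csv`.
#' @return an `accel_trace` data frame (`event_id`, `t_s`, `x_g`, `y_g`,
#'   `z_g`), with attributes `clipped_count` and `gap_count`.
#' @export
read_accel_csv <- function(path, dialect = accel_dialect(), clip_g = 3.0,
                           event_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, skip = dialect$skip)
  need <- c(dialect$time_col, dialect$x_col, dialect$y_col, dialect$z_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("schema error in %s: missing column(s): %s",
          basename(path), paste(miss, collapse = ", "))
  }
  t_s <- df[[dialect$time_col]]
  if (anyNA(t_s) || any(t_s < 0)) {
    stopf("timestamps must be non-negative and complete in %s", basename(path))
  }
  bad <- which(diff(t_s) <= 0)
  if (length(bad)) {
    stopf("timestamps not strictly increasing in %s: first offending row %d",
          basename(path), bad[1] + 1L)
  }
  out <- data.frame(
    event_id = event_id %||% sub("(_accel)?\\.csv$", "", basename(path)),
    t_s = t_s,
    x_g = df[[dialect$x_col]], y_g = df[[dialect$y_col]], z_g = df[[dialect$z_col]]
  )
  vals <- as.matrix(out[, c("x_g", "y_g", "z_g")])
  n_clip <- sum(abs(vals) > clip_g, na.rm = TRUE)
  if (n_clip > 0) {
    warnf("%d sample value(s) outside +-%.1f g clipped in %s",
          n_clip, clip_g, basename(path))
    out$x_g <- pmin(pmax(out$x_g, -clip_g), clip_g)
    out$y_g <- pmin(pmax(out$y_g, -clip_g), clip_g)
    out$z_g <- pmin(pmax(out$z_g, -clip_g), clip_g)
  }
  class(out) <- c("accel_trace", "data.frame")
  attr(out, "sample_rate_hz") <- 1
  attr(out, "clipped_count") <- n_clip
  attr(out, "gap_count") <- sum(diff(t_s) > 1.5)
  out
}

#' Write an accelerometer trace as CSV
#' @param trace an `accel_trace`.
#' @param path output file.
#' @param dialect an [accel_dialect()] giving the column names to write.
#' @export
write_accel_csv <- function(trace, path, dialect = accel_dialect()) {
  df <- data.frame(trace$t_s, trace$x_g, trace$y_g, trace$z_g)
  names(df) <- c(dialect$time_col, dialect$x_col, dialect$y_col, dialect$z_col)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validation limits for deployment records
#' @param max_duration_min upper limit on capture duration; sets were capped
#'   at 4.5 h in the emulated protocol, so the default is 270 min.
#' @param sst_range plausible SST range, deg C.
#' @export
deployment_limits <- function(max_duration_min = 270, sst_range = c(15, 35)) {
  list(max_duration_min = max_duration_min, sst_range = sst_range)
}

.deployment_required <- c("event_id", "species", "tl_cm", "sst_c",
                          "capture_duration_min")
.panel_cols <- c("ph37", "lactate", "glucose", "haematocrit",
                 "sodium", "potassium", "chloride", "calcium")

#' Read a deployment/physiology table
#'
#' One row per shark: species, total length (cm), SST (deg C), capture
#' duration from the hook timer (min) and the blood panel. Empty cells
#' become `NA` --- missingness is preserved, never imputed. Out-of-range
#' covariates and physically impossible panel values are errors.
#'
#' @param path CSV file.
#' @param limits a [deployment_limits()].
#' @return a `deployment_table` data frame.
#' @export
read_deployment_table <- function(path, limits = deployment_limits()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.deployment_required, names(df))
  if (length(miss)) {
    stopf("schema error in %s: missing column(s): %s",
          basename(path), paste(miss, collapse = ", "))
  }
  for (col in .panel_cols) if (is.null(df[[col]])) df[[col]] <- NA_real_
  dur <- df$capture_duration_min
  if (anyNA(dur) || any(dur <= 0)) {
    stopf("capture_duration_min must be present and > 0")
  }
  if (any(dur > limits$max_duration_min)) {
    stopf("capture_duration_min %.2f exceeds limit %.0f min (row %d)",
          max(dur), limits$max_duration_min, which.max(dur))
  }
  sst_bad <- which(!is.na(df$sst_c) &
                     (df$sst_c < limits$sst_range[1] | df$sst_c > limits$sst_range[2]))
  if (length(sst_bad)) {
    stopf("sst_c outside plausible range [%g, %g] at row %d",
          limits$sst_range[1], limits$sst_range[2], sst_bad[1])
  }
  if (any(!is.na(df$tl_cm) & df$tl_cm <= 0)) stopf("tl_cm must be > 0")
  for (i in seq_len(nrow(df))) {
    validate_panel(df[i, .panel_cols], quiet = TRUE)
  }
  class(df) <- c("deployment_table", "data.frame")
  df
}

#' Write a deployment/physiology table as CSV
#' @param df a deployment table (data frame).
#' @param path output file.
#' @export
write_deployment_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
  invisible(path)
}

.metrics_cols <- c("event_id", "p_low", "p_med", "p_high",
                   "capture_duration_min", "mean_fight_intensity",
                   "n_seconds", "k_used")

#' Write an exercise-metrics table as CSV
#'
#' Fixed column set: `event_id`, `p_low`, `p_med`, `p_high` (proportions of
#' the capture event at each intensity), `capture_duration_min`,
#' `mean_fight_intensity` (g min^-1), `n_seconds`, `k_used`. An empty input
#' writes a header-only file.
#'
#' @param metrics data frame of per-event metrics (rows may be empty).
#' @param path output file.
#' @export
write_metrics_table <- function(metrics, path) {
  if (is.null(metrics) || nrow(metrics) == 0) {
    metrics <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(.metrics_cols)), .metrics_cols))
    metrics$event_id <- character(0)
  }
  miss <- setdiff(.metrics_cols, names(metrics))
  if (length(miss)) stopf("metrics table missing column(s): %s",
                          paste(miss, collapse = ", "))
  utils::write.csv(metrics[, .metrics_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read an exercise-metrics table
#' @param path CSV file written by [write_metrics_table()].
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.metrics_cols, names(df))
  if (length(miss)) stopf("schema error in %s: missing column(s): %s",
                          basename(path), paste(miss, collapse = ", "))
  df
}
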