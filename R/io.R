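# Readers and writers: per-recording CSV time series, cohort manifests
# (YAML), and long-format results tables. CSV dialect: comma separator, dot
# decimal, mandatory header; times in seconds, 0-based from recording start.

#' Read an evenly sampled signal from CSV
#'
#' Expects a header row, a time column in seconds and one value column. The
#' sampling interval is inferred from the median time difference; timing must
#' be uniform within `1e-6 * dt`.
#'
#' @param path Path to a CSV file.
#' @param time_col,value_col Column names (defaults `"time_s"` and the first
#'   non-time column).
#' @param units Unit label to attach.
#' @return A [uniform_signal].
#' @export
read_signal_csv <- function(path, time_col = "time_s", value_col = NULL,
                            units = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!time_col %in% names(df))
    stop(sprintf("format error: missing time column '%s' in %s", time_col, path),
         call. = FALSE)
  if (is.null(value_col)) value_col <- setdiff(names(df), time_col)[1]
  if (is.na(value_col) || !value_col %in% names(df))
    stop(sprintf("format error: missing value column in %s", path), call. = FALSE)
  t <- as.numeric(df[[time_col]])
  v <- as.numeric(df[[value_col]])
  bad <- which(!is.finite(v))
  if (length(bad) > 0)
    stop(sprintf("non-finite sample(s) in %s at row %s", path,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  dtv <- diff(t)
  if (any(dtv <= 0))
    stop(sprintf("format error: time not strictly increasing in %s", path),
         call. = FALSE)
  dt <- stats::median(dtv)
  if (any(abs(dtv - dt) > 1e-6 * dt))
    stop(sprintf("format error: non-uniform sampling in %s (max deviation %.3g s)",
                 path, max(abs(dtv - dt))), call. = FALSE)
  uniform_signal(v, dt = dt, units = units, t0 = t[1])
}

#' Write a recording (BP + BFV) to CSV
#'
#' Columns: `time_s`, `bp_mmHg`, `bfv_cm_s`. Values are printed with enough
#' digits to round-trip through [read_signal_csv()].
#'
#' @param bp,bfv [uniform_signal]s on the same time grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(bp, bfv, path) {
  stopifnot(inherits(bp, "uniform_signal"), inherits(bfv, "uniform_signal"))
  if (length(bp$values) != length(bfv$values) || abs(bp$dt - bfv$dt) > 1e-12)
    stop("BP and BFV channels must share a time grid", call. = FALSE)
  df <- data.frame(time_s = signal_time(bp),
                   bp_mmHg = signal_values(bp),
                   bfv_cm_s = signal_values(bfv))
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Materialize a synthetic cohort on disk
#'
#' Generates every (subject, posture) recording of a [synthetic_cohort_spec],
#' writes one CSV per recording and a YAML manifest listing files, posture
#' labels, heart rates and true ARI grades.
#'
#' @param spec A [synthetic_cohort_spec].
#' @param dir Output directory (created if needed).
#' @return The manifest as a list (also written to `dir/manifest.yaml`).
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (p in spec$postures) {
      rec <- generate_recording(spec, s, p)
      file <- sprintf("subject%02d_%s.csv", s, p)
      write_recording_csv(rec$bp, rec$bfv, file.path(dir, file))
      recs[[length(recs) + 1L]] <- list(
        subject_id = sprintf("S%02d", s), posture = p, file = file,
        hemisphere = "merged",
        true_ari_grade = rec$truth$ari_grade,
        heart_rate_hz = rec$truth$heart_rate_hz)
    }
  }
  manifest <- list(fs_raw = spec$fs_raw, duration_s = spec$duration_s,
                   seed = spec$seed, recordings = recs)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path Path to a `manifest.yaml` written by [generate_cohort()].
#' @return The manifest list; each recording must name exactly one file per
#'   (subject, posture, hemisphere).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  key <- vapply(m$recordings, function(r)
    paste(r$subject_id, r$posture, r$hemisphere %||% "merged", sep = "|"), "")
  if (anyDuplicated(key))
    stop("manifest error: duplicate (subject, posture, hemisphere) entry",
         call. = FALSE)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a long-format results table
#'
#' Rows carry `(subject, posture, metric, value)`; written as CSV with a
#' header, ordered by (subject, posture, metric). Duplicate keys are a
#' validation error.
#'
#' @param rows A data.frame with columns `subject`, `posture`, `metric`,
#'   `value` (zero rows allowed).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  needed <- c("subject", "posture", "metric", "value")
  if (!is.data.frame(rows) || !all(needed %in% names(rows)))
    stop("rows must be a data.frame with columns subject, posture, metric, value",
         call. = FALSE)
  rows <- rows[needed]
  if (nrow(rows) > 0) {
    key <- paste(rows$subject, rows$posture, rows$metric, sep = "|")
    if (anyDuplicated(key))
      stop("validation error: duplicate (subject, posture, metric) row",
           call. = FALSE)
    rows <- rows[order(rows$subject, rows$posture, rows$metric), ]
    rows$value <- signif(rows$value, 6)
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
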