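#' Evenly sampled scalar time series
#'
#' `uniform_signal()` is the basic container used throughout the package for
#' arterial blood pressure (BP, mmHg) and cerebral blood flow velocity
#' (BFV, cm/s) channels: a numeric vector together with its sampling interval,
#' start time and units.
#'
#' @param values Numeric vector of samples (length >= 2, all finite unless
#'   `allow_na = TRUE`, used internally before gap repair).
#' @param dt Sampling interval in seconds (> 0).
#' @param units Unit label, e.g. `"mmHg"` or `"cm/s"`.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param allow_na Allow `NA` samples (pre-repair signals only).
#'
#' @return An object of class `uniform_signal`: a list with elements
#'   `values`, `dt`, `units`, `t0`.
#' @examples
#' s <- uniform_signal(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.01)
#' signal_time(s)[1:3]
#' @export
uniform_signal <- function(values, dt, units = "", t0 = 0, allow_na = FALSE) {
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  if (length(values) < 2L)
    stop("a uniform_signal needs at least 2 samples", call. = FALSE)
  bad <- !is.finite(values)
  if (any(bad) && !allow_na) {
    idx <- which(bad)
    stop(sprintf("non-finite sample(s) at index %s%s",
                 paste(utils::head(idx, 5L), collapse = ", "),
                 if (length(idx) > 5L) ", ..." else ""),
         call. = FALSE)
  }
  structure(list(values = values, dt = dt, units = units, t0 = t0),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %.6g Hz (dt = %.6g s)%s\n",
              length(x$values), 1 / x$dt, x$dt,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  cat(sprintf("  t: %.3f .. %.3f s   range: [%.4g, %.4g]\n",
              x$t0, x$t0 + (length(x$values) - 1L) * x$dt,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$values)

#' Sample times of a uniform signal
#'
#' @param x A [uniform_signal].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

#' Sample values of a uniform signal
#'
#' @param x A [uniform_signal].
#' @return Numeric vector of samples.
#' @export
signal_values <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$values
}

# internal: replace values, keep metadata
set_values <- function(x, values) {
  x$values <- as.numeric(values)
  x
}
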