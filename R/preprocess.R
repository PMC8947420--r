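# Preprocessing chain for raw hemodynamic recordings, in fixed order:
# spline gap repair -> Hampel outlier removal -> zero-phase low-pass ->
# beat detection (on BP) -> per-beat averaging -> uniform resampling ->
# min-max normalization to [-1, 1].

#' Repair long gaps by cubic-spline interpolation
#'
#' Runs of masked samples longer than 4 are replaced by natural cubic-spline
#' interpolation through the surrounding valid samples; runs of 4 or fewer
#' are left for the Hampel stage. Gaps touching the signal boundary are not
#' repairable.
#'
#' @param x A [uniform_signal] (may contain `NA` inside the mask).
#' @param gap_mask Logical vector marking missing/bad samples; default: the
#'   non-finite samples of `x`.
#' @return A [uniform_signal] with long gaps filled.
#' @export
spline_repair <- function(x, gap_mask = NULL) {
  stopifnot(inherits(x, "uniform_signal"))
  v <- x$values
  if (is.null(gap_mask)) gap_mask <- !is.finite(v)
  if (length(gap_mask) != length(v))
    stop("gap_mask length mismatch", call. = FALSE)
  if (!any(gap_mask)) return(x)
  r <- rle(gap_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long_runs <- which(r$values & r$lengths > 4L)
  if (length(long_runs) > 0) {
    repair <- rep(FALSE, length(v))
    for (i in long_runs) repair[starts[i]:ends[i]] <- TRUE
    if (repair[1] || repair[length(v)])
      stop("unrepairable: gap at signal boundary", call. = FALSE)
    valid <- which(!gap_mask & is.finite(v))
    for (i in long_runs) {
      left <- sum(valid < starts[i]); right <- sum(valid > ends[i])
      if (left < 4L || right < 4L)
        stop("unrepairable: fewer than 4 valid samples bordering a gap",
             call. = FALSE)
    }
    sf <- stats::splinefun(valid, v[valid], method = "natural")
    v[repair] <- sf(which(repair))
  }
  set_values(x, v)
}

#' Hampel filter for isolated outliers
#'
#' Sliding-window median filter: a sample is replaced by its window median
#' when it deviates from it by more than `n_mad` robust standard deviations
#' (1.4826 x window MAD). Samples within `window_halfwidth` of the
#' boundaries are left unchanged.
#'
#' @param x A [uniform_signal].
#' @param window_halfwidth Half-width k of the window (2k+1 samples,
#'   default 10).
#' @param n_mad Rejection threshold in robust SDs (default 3).
#' @return A [uniform_signal]; the indices of replaced samples are attached
#'   as attribute `"replaced"`.
#' @export
hampel_filter <- function(x, window_halfwidth = 10L, n_mad = 3) {
  stopifnot(inherits(x, "uniform_signal"))
  k <- as.integer(window_halfwidth)
  if (k < 1L) stop("window_halfwidth must be >= 1", call. = FALSE)
  v <- x$values
  n <- length(v)
  if (2L * k + 1L > n)
    stop("parameter error: window larger than signal", call. = FALSE)
  wins <- stats::embed(v, 2L * k + 1L)            # rows: windows, newest first
  meds <- apply(wins, 1L, stats::median)
  mads <- apply(abs(wins - meds), 1L, stats::median)
  centre <- (k + 1L):(n - k)
  dev <- abs(v[centre] - meds)
  out <- dev > n_mad * 1.4826 * mads
  replaced <- centre[out]
  v[replaced] <- meds[out]
  res <- set_values(x, v)
  attr(res, "replaced") <- replaced
  res
}

#' Zero-phase low-pass filter
#'
#' Fourth-order Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), giving an eighth-order magnitude response with zero
#' phase. Default cutoff 20 Hz.
#'
#' @param x A [uniform_signal].
#' @param cutoff_hz Cutoff frequency in Hz, below Nyquist.
#' @param order Per-pass filter order (default 4).
#' @return A filtered [uniform_signal].
#' @export
lowpass_zero_phase <- function(x, cutoff_hz = 20, order = 4L) {
  stopifnot(inherits(x, "uniform_signal"))
  nyq <- 1 / (2 * x$dt)
  if (cutoff_hz >= nyq)
    stop(sprintf("parameter error: cutoff %.3g Hz >= Nyquist %.3g Hz",
                 cutoff_hz, nyq), call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # odd-reflection padding suppresses the forward/backward edge transients
  v <- x$values
  n <- length(v)
  pad <- min(n - 1L, max(3L * (order * 2L + 1L), ceiling(3 / (cutoff_hz * x$dt))))
  vp <- c(2 * v[1] - v[(pad + 1L):2], v, 2 * v[n] - v[(n - 1L):(n - pad)])
  fp <- signal::filtfilt(bf, vp)
  set_values(x, fp[(pad + 1L):(pad + n)])
}

#' Per-heartbeat times, landmarks and averages
#'
#' Container produced by [detect_beats()] and [beat_average()]: upstroke
#' times, per-beat landmark indices (upstroke, max, min) and, once averaged,
#' per-beat mean values of a channel.
#'
#' @param beat_times Strictly increasing upstroke times (s).
#' @param landmarks Data frame with integer columns `upstroke`, `max`, `min`.
#' @param mean_values Optional per-beat means.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(beat_times, landmarks, mean_values = NULL) {
  if (any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing", call. = FALSE)
  structure(list(beat_times = beat_times, landmarks = landmarks,
                 mean_values = mean_values),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %.3f .. %.3f s (mean rate %.3g Hz)%s\n",
              length(x$beat_times), min(x$beat_times), max(x$beat_times),
              1 / mean(diff(x$beat_times)),
              if (is.null(x$mean_values)) "" else ", with per-beat means"))
  invisible(x)
}

#' Detect heartbeats in an arterial pressure signal
#'
#' Locates one beat per cardiac cycle on a filtered BP signal: upstrokes are
#' the maxima of the positive derivative, subject to a refractory period of
#' `1/max_hr_hz`; the systolic maximum and diastolic minimum are located
#' between successive upstrokes.
#'
#' @param bp A filtered [uniform_signal] of arterial pressure.
#' @param min_hr_hz,max_hr_hz Plausible heart-rate bounds in Hz
#'   (defaults 0.67 and 3).
#' @param margin_s Boundary margin in seconds; upstrokes closer than this to
#'   either end are discarded (zero-phase filtering leaves edge transients
#'   that mimic upstrokes).
#' @return A [beat_series] with landmark indices.
#' @export
detect_beats <- function(bp, min_hr_hz = 0.67, max_hr_hz = 3, margin_s = 0.5) {
  stopifnot(inherits(bp, "uniform_signal"))
  v <- bp$values
  dt <- bp$dt
  d <- c(0, diff(v)) / dt
  thr <- 0.25 * stats::quantile(d[d > 0], 0.98, names = FALSE)
  refractory <- max(1L, floor(1 / max_hr_hz / dt))
  cand <- which(d > thr)
  if (length(cand) == 0)
    stop("detection error: no upstrokes found", call. = FALSE)
  # group threshold crossings into events, take the derivative peak of each
  grp <- cumsum(c(1L, diff(cand) > refractory %/% 2L))
  peaks <- vapply(split(cand, grp),
                  function(ix) ix[which.max(d[ix])], integer(1))
  peaks <- sort(unname(peaks))
  margin <- ceiling(margin_s / dt)
  peaks <- peaks[peaks > margin & peaks <= length(v) - margin]
  if (length(peaks) < 3L)
    stop("detection error: fewer than 3 beats found", call. = FALSE)
  keep <- peaks[1]
  for (p in peaks[-1]) if (p - keep[length(keep)] >= refractory) keep <- c(keep, p)
  if (length(keep) < 3L)
    stop("detection error: fewer than 3 beats found", call. = FALSE)
  nb <- length(keep)
  lmax <- integer(nb); lmin <- integer(nb)
  bounds <- c(keep, length(v) + 1L)
  for (i in seq_len(nb)) {
    seg <- keep[i]:(bounds[i + 1L] - 1L)
    lmax[i] <- seg[which.max(v[seg])]
    lmin[i] <- seg[which.min(v[seg])]
  }
  beat_series(bp$t0 + (keep - 1L) * dt,
              data.frame(upstroke = keep, max = lmax, min = lmin))
}

#' Average a channel over each beat
#'
#' Means of `channel` over the half-open intervals between consecutive
#' upstrokes `[u_i, u_{i+1})`. The result keeps one entry per complete beat.
#'
#' @param channel A [uniform_signal] covering the beat times.
#' @param beats A [beat_series] from [detect_beats()].
#' @return A [beat_series] whose `mean_values` hold the per-beat means and
#'   whose `beat_times` are the upstroke times of the complete beats.
#' @export
beat_average <- function(channel, beats) {
  stopifnot(inherits(channel, "uniform_signal"), inherits(beats, "beat_series"))
  up <- beats$landmarks$upstroke
  nb <- length(up) - 1L
  if (nb < 1L) stop("detection error: need at least 2 upstrokes", call. = FALSE)
  v <- channel$values
  means <- numeric(nb)
  for (i in seq_len(nb)) {
    seg <- up[i]:(up[i + 1L] - 1L)
    if (length(seg) == 0L)
      stop("detection error: empty beat interval", call. = FALSE)
    means[i] <- mean(v[seg])
  }
  beat_series(beats$beat_times[seq_len(nb)],
              beats$landmarks[seq_len(nb), , drop = FALSE],
              mean_values = means)
}

#' Resample per-beat means onto a uniform grid
#'
#' Cubic interpolation of the beat-averaged values evaluated at a constant
#' interval `dt_out` (default 0.4 s, i.e. 2.5 Hz), spanning the first to the
#' last beat time.
#'
#' @param beats A [beat_series] with `mean_values`.
#' @param dt_out Output sampling interval in seconds (default 0.4).
#' @return A [uniform_signal].
#' @export
resample_uniform <- function(beats, dt_out = 0.4) {
  stopifnot(inherits(beats, "beat_series"))
  if (is.null(beats$mean_values))
    stop("beats carry no mean values; run beat_average() first", call. = FALSE)
  if (dt_out <= 0) stop("parameter error: dt_out must be positive", call. = FALSE)
  if (length(beats$beat_times) < 4L)
    stop("need at least 4 beats to resample", call. = FALSE)
  t_out <- seq(beats$beat_times[1], max(beats$beat_times), by = dt_out)
  v <- stats::spline(beats$beat_times, beats$mean_values, xout = t_out,
                     method = "fmm")$y
  uniform_signal(v, dt = dt_out, t0 = t_out[1])
}

#' Min-max normalization to \[-1, 1\]
#'
#' `x_norm(n) = 2 (x(n) - xmin) / (xmax - xmin) - 1`; the output attains -1
#' and +1 exactly. The original range is attached as attribute `"norm"`
#' (`c(xmin, xmax)`) so model outputs can be mapped back to physical units.
#'
#' @param x A [uniform_signal] (non-constant).
#' @return A normalized [uniform_signal].
#' @export
minmax_normalize <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  xmin <- min(x$values); xmax <- max(x$values)
  if (xmax <= xmin)
    stop("degenerate range: constant signal cannot be normalized", call. = FALSE)
  res <- set_values(x, 2 * (x$values - xmin) / (xmax - xmin) - 1)
  res$units <- "normalized"
  attr(res, "norm") <- c(xmin = xmin, xmax = xmax)
  res
}

# invert minmax_normalize given the stored range
minmax_denormalize <- function(values, norm) {
  (values + 1) / 2 * (norm[["xmax"]] - norm[["xmin"]]) + norm[["xmin"]]
}

#' Run the full preprocessing chain on a two-channel recording
#'
#' Applies, in fixed order: spline gap repair, Hampel outlier removal,
#' zero-phase low-pass, beat detection on BP, per-beat averaging of both
#' channels, uniform resampling and min-max normalization.
#'
#' @param bp,bfv Raw [uniform_signal]s (100 Hz typical).
#' @param cutoff_hz Low-pass cutoff (default 20 Hz).
#' @param hampel_k,hampel_nmad Hampel window half-width and threshold.
#' @param dt_out Resampling interval (default 0.4 s).
#' @param min_hr_hz,max_hr_hz Heart-rate bounds for beat detection.
#' @return An object of class `preprocessed_recording`: normalized channels
#'   `p` and `v` on a common 1/`dt_out` Hz grid, the unnormalized
#'   beat-resampled channels `p_beat`/`v_beat`, the detected `beats`, and the
#'   normalization ranges `p_norm`/`v_norm`.
#' @export
preprocess_recording <- function(bp, bfv, cutoff_hz = 20,
                                 hampel_k = 10L, hampel_nmad = 3,
                                 dt_out = 0.4,
                                 min_hr_hz = 0.67, max_hr_hz = 3) {
  stage <- function(x) {
    x <- spline_repair(x)
    x <- hampel_filter(x, hampel_k, hampel_nmad)
    lowpass_zero_phase(x, cutoff_hz)
  }
  bp_f <- stage(bp)
  bfv_f <- stage(bfv)
  beats <- detect_beats(bp_f, min_hr_hz, max_hr_hz)
  bp_b <- beat_average(bp_f, beats)
  bfv_b <- beat_average(bfv_f, beats)
  p_u <- resample_uniform(bp_b, dt_out)
  v_u <- resample_uniform(bfv_b, dt_out)
  p_n <- minmax_normalize(p_u)
  v_n <- minmax_normalize(v_u)
  structure(list(p = p_n, v = v_n, p_beat = p_u, v_beat = v_u,
                 beats = bp_b,
                 p_norm = attr(p_n, "norm"), v_norm = attr(v_n, "norm")),
            class = "preprocessed_recording")
}

#' @export
print.preprocessed_recording <- function(x, ...) {
  cat(sprintf("<preprocessed_recording> %d samples @ %.3g Hz, %d beats\n",
              length(x$p$values), 1 / x$p$dt, length(x$beats$beat_times)))
  cat(sprintf("  BP range %.4g..%.4g mmHg | BFV range %.4g..%.4g cm/s\n",
              x$p_norm[["xmin"]], x$p_norm[["xmax"]],
              x$v_norm[["xmin"]], x$v_norm[["xmax"]]))
  invisible(x)
}
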