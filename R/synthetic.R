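# Synthetic cohort generator: pulsatile arterial pressure with cardiac,
# respiratory and Mayer-wave components, and flow velocity produced from it
# through the Tiecks model at a known ARI grade. Gives every downstream stage
# a ground-truth input without any recorded data.

posture_baselines <- c(lay = 74.96, stand = 84.81, sit = 81.45)   # mmHg
posture_baseline_v <- c(lay = 59.27, stand = 53.50, sit = 52.88)  # cm/s

#' Specification of a synthetic hemodynamics cohort
#'
#' Collects every parameter of the generator: cohort size, postures, recording
#' duration and raw sampling rate, per-subject heart rates, the true ARI grade
#' per posture, noise level, outlier rate and the master seed. Defaults follow
#' a five-minute protocol sampled at 100 Hz with posture-specific baseline
#' pressures.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param postures Character vector of posture labels from
#'   `c("lay", "sit", "stand")`.
#' @param duration_s Recording duration per posture in seconds (default 300).
#' @param fs_raw Raw sampling rate in Hz (default 100). Must exceed twice the
#'   fastest heart rate.
#' @param heart_rate_hz Heart rate(s) in Hz; either a single value, one per
#'   subject, or `NULL` to draw subject rates uniformly in 0.9-1.3 Hz.
#' @param ari_grade_per_posture Named integer vector (names = postures) or a
#'   single grade applied to all postures; each in 0..9.
#' @param noise_sd Additive noise SD as a fraction of the clean signal SD.
#' @param outlier_rate Fraction of samples hit by spike artifacts.
#' @param hrv_frac Beat-to-beat period jitter as a fraction of the cycle.
#' @param pulse_pressure Systolic-diastolic excursion in mmHg (default 40).
#' @param seed Master integer seed; fixed seed implies identical output.
#' @return An object of class `synthetic_cohort_spec`.
#' @examples
#' spec <- synthetic_cohort_spec(n_subjects = 2, duration_s = 60, seed = 7)
#' @export
synthetic_cohort_spec <- function(n_subjects,
                                  postures = c("lay", "sit", "stand"),
                                  duration_s = 300,
                                  fs_raw = 100,
                                  heart_rate_hz = NULL,
                                  ari_grade_per_posture = 5L,
                                  noise_sd = 0.02,
                                  outlier_rate = 0.001,
                                  hrv_frac = 0.02,
                                  pulse_pressure = 40,
                                  seed = 1L) {
  if (duration_s <= 0 || fs_raw <= 0)
    stop("invalid spec: duration_s and fs_raw must be positive", call. = FALSE)
  postures <- match.arg(postures, c("lay", "sit", "stand"), several.ok = TRUE)
  if (is.null(heart_rate_hz)) {
    rng <- local_rng(seed)
    heart_rate_hz <- stats::runif(n_subjects, 0.9, 1.3)
    restore_rng(rng)
  } else if (length(heart_rate_hz) == 1L) {
    heart_rate_hz <- rep(heart_rate_hz, n_subjects)
  }
  if (length(heart_rate_hz) != n_subjects)
    stop("invalid spec: need one heart rate per subject", call. = FALSE)
  if (fs_raw <= 2 * max(heart_rate_hz))
    stop("invalid spec: fs_raw must exceed twice the cardiac frequency",
         call. = FALSE)
  if (length(ari_grade_per_posture) == 1L && is.null(names(ari_grade_per_posture)))
    ari_grade_per_posture <- stats::setNames(
      rep(as.integer(ari_grade_per_posture), length(postures)), postures)
  if (!all(postures %in% names(ari_grade_per_posture)))
    stop("invalid spec: ari_grade_per_posture must cover every posture",
         call. = FALSE)
  g <- ari_grade_per_posture[postures]
  if (any(g != round(g)) || any(g < 0) || any(g > 9))
    stop("invalid spec: ARI grades must be integers in 0..9", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), postures = postures,
                 duration_s = duration_s, fs_raw = fs_raw,
                 heart_rate_hz = heart_rate_hz,
                 ari_grade_per_posture = g,
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 hrv_frac = hrv_frac, pulse_pressure = pulse_pressure,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' @export
print.synthetic_cohort_spec <- function(x, ...) {
  cat(sprintf("<synthetic_cohort_spec> %d subjects x {%s}, %g s @ %g Hz, seed %d\n",
              x$n_subjects, paste(x$postures, collapse = ", "),
              x$duration_s, x$fs_raw, x$seed))
  cat(sprintf("  ARI grades: %s | noise_sd %.3g | outlier_rate %.3g\n",
              paste(sprintf("%s=%d", names(x$ari_grade_per_posture),
                            x$ari_grade_per_posture), collapse = " "),
              x$noise_sd, x$outlier_rate))
  invisible(x)
}

# deterministic per-recording sub-seed below 2^31
recording_seed <- function(spec, subject, posture_idx) {
  as.integer((as.numeric(spec$seed) * 7919 + subject * 1299709 +
                posture_idx * 104729) %% 2147483629)
}

# clipped raised-cosine systolic pulse: phase in [0,1), bump over [0, width]
pulse_shape <- function(phase, width = 0.45) {
  s <- numeric(length(phase))
  in_bump <- phase >= 0 & phase < width
  s[in_bump] <- 0.5 * (1 - cos(2 * pi * phase[in_bump] / width))
  s
}

# 1/f (pink-ish) noise with unit SD via FFT amplitude shaping
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a pulsatile arterial blood pressure signal
#'
#' Builds one raw BP recording for a subject/posture: posture-specific
#' baseline plus a cardiac raised-cosine pulse train, respiratory (~0.25 Hz)
#' and Mayer-wave (~0.10 Hz) oscillations, 1/f noise scaled by
#' `spec$noise_sd`, and isolated spike artifacts at `spec$outlier_rate`.
#' Deterministic for a fixed spec seed.
#'
#' @param spec A [synthetic_cohort_spec].
#' @param subject Subject index (1-based).
#' @param posture Posture label present in `spec$postures`.
#' @return A [uniform_signal] in mmHg. Ground truth is attached as attributes:
#'   `beat_onsets` (s), `systolic`, `diastolic`, `baseline`, `cycle_mean`.
#' @examples
#' spec <- synthetic_cohort_spec(1, duration_s = 30, seed = 2)
#' bp <- generate_bp(spec, 1, "lay")
#' @export
generate_bp <- function(spec, subject = 1L, posture = spec$postures[1]) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (spec$duration_s <= 0 || spec$fs_raw <= 0)
    stop("invalid spec: non-positive duration or rate", call. = FALSE)
  if (!posture %in% spec$postures)
    stop(sprintf("posture '%s' not in the cohort spec", posture), call. = FALSE)
  pidx <- match(posture, c("lay", "sit", "stand"))
  rng <- local_rng(recording_seed(spec, subject, pidx))
  on.exit(restore_rng(rng))

  fs <- spec$fs_raw
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  hr <- spec$heart_rate_hz[subject]
  baseline <- posture_baselines[[posture]]
  pp <- spec$pulse_pressure
  width <- 0.45
  # cycle mean of the clipped raised cosine is width/2, so anchoring the
  # diastolic level pp*width/2 below baseline keeps the cycle mean at baseline
  diastolic <- baseline - pp * width / 2

  # beat onset schedule with mild beat-to-beat jitter
  mean_period <- 1 / hr
  n_beats <- ceiling(spec$duration_s / mean_period) + 2L
  periods <- mean_period * (1 + spec$hrv_frac * stats::rnorm(n_beats))
  periods <- pmax(periods, 0.4 * mean_period)
  onsets <- c(0, cumsum(periods))
  beat <- findInterval(t, onsets)
  phase <- (t - onsets[beat]) / periods[pmin(beat, n_beats)]
  x <- diastolic + pp * pulse_shape(phase, width)

  # slow physiological oscillations (amplitudes in mmHg)
  x <- x + 1.5 * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi)) +
           2.0 * sin(2 * pi * 0.10 * t + stats::runif(1, 0, 2 * pi))

  clean_sd <- stats::sd(x)
  if (spec$noise_sd > 0) x <- x + spec$noise_sd * clean_sd * pink_noise(n)

  if (spec$outlier_rate > 0) {
    n_spk <- round(spec$outlier_rate * n)
    if (n_spk > 0) {
      pos <- sort(sample(seq(10L, n - 10L), n_spk))
      len <- sample(1:2, n_spk, replace = TRUE)
      sgn <- sample(c(-1, 1), n_spk, replace = TRUE)
      for (i in seq_len(n_spk)) {
        idx <- pos[i]:min(pos[i] + len[i] - 1L, n)
        x[idx] <- x[idx] + sgn[i] * 5 * clean_sd
      }
    }
  }

  out <- uniform_signal(x, dt = 1 / fs, units = "mmHg")
  attr(out, "beat_onsets") <- onsets[onsets <= spec$duration_s]
  # steepest point of the raised-cosine upstroke sits at phase width/4
  up <- onsets + width / 4 * periods[pmin(seq_along(onsets), length(periods))]
  attr(out, "upstroke_times") <- up[onsets <= spec$duration_s]
  attr(out, "systolic") <- diastolic + pp
  attr(out, "diastolic") <- diastolic
  attr(out, "baseline") <- baseline
  attr(out, "cycle_mean") <- baseline
  out
}

#' Generate one synthetic BP/BFV recording with ground truth
#'
#' Convenience wrapper: generates the pressure channel with [generate_bp()]
#' and drives the Tiecks model at the posture's configured ARI grade to
#' produce the flow-velocity channel.
#'
#' @inheritParams generate_bp
#' @return List with `bp`, `bfv` ([uniform_signal]s) and `truth` (list with
#'   `ari_grade`, `heart_rate_hz`, `baseline_bp`, `baseline_v`, `beat_onsets`).
#' @export
generate_recording <- function(spec, subject = 1L, posture = spec$postures[1]) {
  bp <- generate_bp(spec, subject, posture)
  grade <- spec$ari_grade_per_posture[[posture]]
  baseline_v <- posture_baseline_v[[posture]]
  pidx <- match(posture, c("lay", "sit", "stand"))
  bfv <- tiecks_bfv(bp, tiecks_params(grade), baseline_v = baseline_v,
                    noise_sd = spec$noise_sd,
                    seed = recording_seed(spec, subject, pidx) + 1L,
                    p_ref = attr(bp, "baseline"))
  list(bp = bp, bfv = bfv,
       truth = list(ari_grade = grade,
                    heart_rate_hz = spec$heart_rate_hz[subject],
                    baseline_bp = attr(bp, "baseline"),
                    baseline_v = baseline_v,
                    beat_onsets = attr(bp, "beat_onsets")))
}

#' Piecewise-constant negative pressure step
#'
#' @param duration_s Total duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param step_time_s Step onset, strictly inside `(0, duration_s)`. The
#'   sample at the boundary takes the post-step level.
#' @param pre_level,post_level Levels before/after the step;
#'   `post_level < pre_level` is required.
#' @return A [uniform_signal].
#' @examples
#' s <- negative_step(10, 2.5, 5, 1, 0)
#' @export
negative_step <- function(duration_s, fs, step_time_s, pre_level, post_level) {
  if (post_level >= pre_level)
    stop("invalid step: post_level must be below pre_level", call. = FALSE)
  if (step_time_s <= 0 || step_time_s >= duration_s)
    stop("invalid step: step_time_s must lie strictly inside the recording",
         call. = FALSE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- ifelse(t < step_time_s, pre_level, post_level)
  uniform_signal(x, dt = 1 / fs)
}

#' Signal whose wavelet energy sits at a single scale
#'
#' Reconstructs a signal from one detail coefficient at level `level_j` of a
#' periodized orthogonal decomposition. Its relative wavelet energy is a
#' point mass at that level, which pins the entropy at 0 and the
#' disequilibrium at 1.
#'
#' @param level_j Detail level (1 = finest).
#' @param length Signal length; must satisfy `2^level_j < length` and be
#'   divisible by `2^level_j`.
#' @param wavelet One of [available_wavelets()].
#' @param dt Sampling interval attached to the output (default 1 s).
#' @return A [uniform_signal].
#' @export
scale_concentrated_signal <- function(level_j, length, wavelet = "db4", dt = 1) {
  if (2^level_j >= length)
    stop("decomposition error: level too deep for this length", call. = FALSE)
  d <- dwt_decompose(numeric(length), wavelet, m = level_j)
  k <- length(d$details[[level_j]])
  d$details[[level_j]][max(1L, k %/% 2L)] <- 1
  uniform_signal(dwt_reconstruct(d), dt = dt)
}

#' Noise signal with a prescribed wavelet-band energy profile
#'
#' Generates Gaussian white noise, decomposes it, rescales each detail level
#' so that the level energies match `weights` (the approximation is zeroed),
#' and reconstructs. Used to build groups of signals whose entropy and
#' statistical complexity differ by construction.
#'
#' @param weights Non-negative energy weights, one per level (finest first);
#'   normalized internally.
#' @param length Signal length, divisible by `2^length(weights)`.
#' @param wavelet One of [available_wavelets()].
#' @param seed Integer seed.
#' @param dt Sampling interval of the output.
#' @return A [uniform_signal] with total energy 1.
#' @export
band_weighted_signal <- function(weights, length, wavelet = "db4", seed = 1L,
                                 dt = 1) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  w <- weights / sum(weights)
  rng <- local_rng(seed)
  x <- stats::rnorm(length)
  restore_rng(rng)
  d <- dwt_decompose(x, wavelet, m = base::length(w))
  for (j in seq_along(w)) {
    e <- sum(d$details[[j]]^2)
    d$details[[j]] <- if (e > 0) d$details[[j]] * sqrt(w[j] / e) else d$details[[j]]
  }
  d$approximation[] <- 0
  uniform_signal(dwt_reconstruct(d), dt = dt)
}

#' Inject long gaps (runs of missing samples) into a signal
#'
#' Marks `n_gaps` runs of `gap_len` consecutive samples as missing (`NA`),
#' away from the signal boundaries, and returns the damaged signal together
#' with the gap mask. Complements the spike artifacts of [generate_bp()]:
#' runs longer than 4 samples are the province of spline repair rather than
#' the Hampel filter.
#'
#' @param x A [uniform_signal].
#' @param n_gaps Number of gaps.
#' @param gap_len Gap length in samples (> 4 to target spline repair).
#' @param seed Integer seed for gap placement.
#' @return List with `signal` (values `NA` inside gaps) and `mask` (logical).
#' @export
inject_gaps <- function(x, n_gaps = 1L, gap_len = 10L, seed = 1L) {
  stopifnot(inherits(x, "uniform_signal"))
  n <- length(x$values)
  margin <- gap_len + 8L
  rng <- local_rng(seed)
  starts <- sort(sample(seq(margin, n - margin), n_gaps))
  restore_rng(rng)
  mask <- rep(FALSE, n)
  for (s in starts) mask[s:(s + gap_len - 1L)] <- TRUE
  damaged <- x
  damaged$values[mask] <- NA_real_
  list(signal = uniform_signal(damaged$values, x$dt, x$units, x$t0,
                               allow_na = TRUE),
       mask = mask)
}
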