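# Autoregulation index estimation: drive a trained model with a negative
# pressure step, gate the response by the three physiological-plausibility
# criteria, and match it against the ten Tiecks templates.
#
# Matching works on a drop-normalized scale. The Tiecks recursion is linear
# in the normalized pressure deviation dP, so the unit-step template shape is
# independent of the step size; a model probed with a modest step (default
# 10% of baseline pressure, which stays near its training range) is rescaled
# by the applied dP before comparison, putting model responses and templates
# on a common scale where the pre-step level is 1 and an unregulated response
# settles at 0.

#' Configuration of the negative pressure step probe
#'
#' @param pre_hold_s Pre-step hold used to let the model settle (s).
#' @param post_s Post-step window (s); must cover at least the 10 s
#'   comparison window plus the plausibility checks.
#' @param pre_keep_s Pre-step context retained in the returned response (s).
#' @param drop_fraction Step size: fraction of the observed (min-max)
#'   pressure range when `drop_mode = "range"` (default 0.5, which keeps the
#'   probe inside the pressure values the model was trained on), or fraction
#'   of the baseline pressure when `drop_mode = "baseline"`.
#' @param drop_mode `"range"` or `"baseline"` (see `drop_fraction`).
#' @param crcp Critical closing pressure (mmHg) for the dP normalization.
#' @return A list of class `step_config`.
#' @export
step_config <- function(pre_hold_s = 20, post_s = 12, pre_keep_s = 4,
                        drop_fraction = 0.5, drop_mode = c("range", "baseline"),
                        crcp = 12) {
  drop_mode <- match.arg(drop_mode)
  stopifnot(pre_hold_s > 0, post_s >= 6, drop_fraction > 0, drop_fraction < 1)
  structure(list(pre_hold_s = pre_hold_s, post_s = post_s,
                 pre_keep_s = pre_keep_s, drop_fraction = drop_fraction,
                 drop_mode = drop_mode, crcp = crcp),
            class = "step_config")
}

new_step_response <- function(time, response, dt, source = "model") {
  structure(list(time = time, response = response, dt = dt, source = source,
                 plausibility = NULL),
            class = "step_response")
}

#' @export
print.step_response <- function(x, ...) {
  cat(sprintf("<step_response> (%s) %d samples @ dt = %.3g s, t = %.1f..%.1f s\n",
              x$source, length(x$time), x$dt, min(x$time), max(x$time)))
  if (!is.null(x$plausibility))
    cat(sprintf("  plausible: %s (i %s, ii %s, iii %s)\n",
                x$plausibility$verdict, x$plausibility$criterion_i,
                x$plausibility$criterion_ii, x$plausibility$criterion_iii))
  invisible(x)
}

#' Response of a trained model to a negative pressure step
#'
#' Holds the pressure at the model's training baseline, drops it by
#' `drop_fraction`, simulates the model in free-run mode, converts the
#' predicted flow back to physical units, and expresses it relative to the
#' pre-step mean, rescaled to a unit pressure-deviation step.
#'
#' @param model A [trained_flow_model] carrying normalization ranges.
#' @param cfg A [step_config].
#' @return A [step_response]; time 0 is the step onset, pre-step level 1.
#' @export
model_step_response <- function(model, cfg = step_config()) {
  stopifnot(inherits(model, "trained_flow_model"))
  if (is.null(model$p_norm) || is.null(model$v_norm))
    stop("model carries no normalization ranges; train with p_norm/v_norm",
         call. = FALSE)
  dt <- model$dt
  if (is.null(dt)) stop("model carries no sampling interval", call. = FALSE)
  if (cfg$pre_hold_s < 10 * dt)
    stop("pre-step hold too short to settle (need >= 10 dt)", call. = FALSE)
  p0 <- minmax_denormalize(model$p_train_mean, model$p_norm)
  p1 <- if (cfg$drop_mode == "range")
    p0 - cfg$drop_fraction * (model$p_norm[["xmax"]] - model$p_norm[["xmin"]])
  else p0 * (1 - cfg$drop_fraction)
  if (p0 <= cfg$crcp || p1 <= cfg$crcp)
    stop("pressure at or below critical closing pressure", call. = FALSE)
  dP_applied <- (p1 - p0) / (p0 - cfg$crcp)    # negative

  n_pre <- round(cfg$pre_hold_s / dt)
  n_post <- round(cfg$post_s / dt)
  p_phys <- c(rep(p0, n_pre), rep(p1, n_post))
  p_n <- 2 * (p_phys - model$p_norm[["xmin"]]) /
    (model$p_norm[["xmax"]] - model$p_norm[["xmin"]]) - 1

  seed <- rep(model$v_train_mean, max(model$spec$n_v, 1L))
  vhat <- free_run_predict(model, p_n, v_init = seed)
  if (isTRUE(attr(vhat, "diverged")) || any(!is.finite(vhat)))
    stop("divergence error: model step response is not finite", call. = FALSE)
  # predictions cover samples (n_p + 1) .. length(p_n)
  t_all <- (model$spec$n_p + seq_along(vhat) - 1L) * dt - n_pre * dt
  v_phys <- minmax_denormalize(as.numeric(vhat), model$v_norm)
  pre_idx <- t_all >= -5 & t_all < 0
  if (!any(pre_idx)) stop("no settled pre-step segment", call. = FALSE)
  v_pre <- mean(v_phys[pre_idx])
  if (abs(v_pre) < 1e-12)
    stop("degenerate pre-step level", call. = FALSE)
  resp_unit <- 1 + (v_phys / v_pre - 1) / abs(dP_applied)
  keep <- t_all >= -cfg$pre_keep_s
  new_step_response(t_all[keep], resp_unit[keep], dt, source = "model")
}

#' Tiecks template step responses for grades 0-9
#'
#' Runs the Tiecks recursion at every grade, driven by a unit negative
#' pressure-deviation step on the same time grid convention as
#' [model_step_response()] (pre-step level 1, step onset at t = 0).
#'
#' @param dt Sampling interval matching the model response grid (s).
#' @param cfg A [step_config] (only the window lengths are used).
#' @return List of 10 [step_response]s, names `"0" .. "9"`.
#' @export
tiecks_templates <- function(dt, cfg = step_config()) {
  n_pre <- round(cfg$pre_hold_s / dt)
  n_post <- round(cfg$post_s / dt)
  dP <- c(rep(0, n_pre), rep(-1, n_post))
  t_all <- (seq_along(dP) - 1L) * dt - n_pre * dt
  keep <- t_all >= -cfg$pre_keep_s
  out <- lapply(0:9, function(g) {
    v <- tiecks_recursion(dP, dt, tiecks_params(g))
    new_step_response(t_all[keep], v[keep], dt, source = sprintf("template%d", g))
  })
  names(out) <- as.character(0:9)
  out
}

#' Physiological plausibility of a step response
#'
#' Three criteria gate a response before ARI matching (levels are relative to
#' the pre-step mean, which is 1 on the drop-normalized scale):
#' (i) the response must drop by at least 40% of the pre-step level;
#' (ii) the post-recovery plateau must lie between the response minimum and
#' the pre-step level plus 10%;
#' (iii) the response must have recovered at least half of its drop
#' throughout the 3-6 s post-step window (an absent recovery, as at grade 0,
#' fails; a fast recovery that completes before 3 s and holds passes).
#'
#' @param resp A [step_response] covering at least 6 s post-step.
#' @param drop_mode `"drop"` (default: drop amplitude >= 40% of pre-step
#'   level) or `"residual"` (residual level <= 40% of pre-step level), the
#'   two readings of criterion (i).
#' @param recovery_threshold Fraction of the drop that must be recovered in
#'   the 3-6 s window (default 0.5).
#' @return The response with its `plausibility` field set: a list with
#'   `verdict` and per-criterion logical flags.
#' @export
plausibility_check <- function(resp, drop_mode = c("drop", "residual"),
                               recovery_threshold = 0.5) {
  stopifnot(inherits(resp, "step_response"))
  drop_mode <- match.arg(drop_mode)
  t <- resp$time; y <- resp$response
  if (max(t) < 6)
    stop("insufficient-window error: response must cover >= 6 s post-step",
         call. = FALSE)
  pre <- mean(y[t < 0])
  post6 <- t >= 0 & t <= 6
  m <- min(y[post6])
  drop <- pre - m
  c1 <- if (drop_mode == "drop") drop >= 0.40 * pre else m <= 0.40 * pre
  plateau_win <- t >= 6 & t <= min(10, max(t))
  plateau <- mean(y[plateau_win])
  c2 <- plateau >= m - 1e-9 && plateau <= pre * 1.10 + 1e-9
  win36 <- t >= 3 & t <= 6
  c3 <- if (drop < 1e-9) FALSE else
    all((y[win36] - m) / drop >= recovery_threshold)
  resp$plausibility <- list(verdict = c1 && c2 && c3,
                            criterion_i = c1, criterion_ii = c2,
                            criterion_iii = c3,
                            pre_level = pre, minimum = m, plateau = plateau)
  resp
}

#' Match a step response to the Tiecks templates
#'
#' Mean-squared difference over the comparison window (step onset to +10 s,
#' or the available post-step extent if shorter); the estimated grade is the
#' argmin, ties broken toward the lower grade. A quadratic interpolation
#' around the argmin yields an optional fractional grade.
#'
#' @param resp A [step_response] (run [plausibility_check()] first; by
#'   default implausible responses get `grade = NA`).
#' @param templates Output of [tiecks_templates()] on the same dt grid.
#' @param window_s Comparison window length after the step (default 10 s).
#' @param fractional Also report a quadratically interpolated grade.
#' @param require_plausible Set `grade` to `NA` when the plausibility verdict
#'   is missing or `FALSE`.
#' @return An object of class `ari_estimate`: `grade`, `grade_fractional`,
#'   `mse` (named length-10 vector), `plausible`.
#' @export
match_ari <- function(resp, templates, window_s = 10, fractional = FALSE,
                      require_plausible = TRUE) {
  stopifnot(inherits(resp, "step_response"))
  if (abs(resp$dt - templates[[1]]$dt) > 1e-9)
    stop("alignment error: response and template grids differ", call. = FALSE)
  w_end <- min(window_s, max(resp$time))
  sel_r <- resp$time >= 0 & resp$time <= w_end + 1e-9
  tr <- resp$time[sel_r]
  mse <- vapply(templates, function(tp) {
    sel_t <- tp$time >= 0 & tp$time <= w_end + 1e-9
    tt <- tp$time[sel_t]
    n <- min(length(tt), length(tr))
    if (max(abs(tt[seq_len(n)] - tr[seq_len(n)])) > resp$dt / 2)
      stop("alignment error: time grids do not coincide", call. = FALSE)
    mean((resp$response[sel_r][seq_len(n)] - tp$response[sel_t][seq_len(n)])^2)
  }, 0)
  names(mse) <- names(templates)
  g <- as.integer(names(mse)[which.min(mse)])   # which.min ties -> first = lower
  gf <- NA_real_
  if (fractional) {
    i <- which.min(mse)
    if (i > 1L && i < length(mse)) {
      y0 <- mse[i - 1L]; y1 <- mse[i]; y2 <- mse[i + 1L]
      den <- y0 - 2 * y1 + y2
      gf <- if (den > 0) (i - 1) + 0.5 * (y0 - y2) / den else as.numeric(i - 1)
    } else gf <- as.numeric(g)
  }
  plausible <- if (is.null(resp$plausibility)) NA else resp$plausibility$verdict
  grade <- if (require_plausible && !isTRUE(plausible)) NA_integer_ else g
  structure(list(grade = grade, grade_unchecked = g, grade_fractional = gf,
                 mse = mse, plausible = plausible),
            class = "ari_estimate")
}

#' @export
print.ari_estimate <- function(x, ...) {
  cat(sprintf("<ari_estimate> grade = %s (plausible: %s); best MSE %.3g at template %d\n",
              ifelse(is.na(x$grade), "NA", x$grade), x$plausible,
              min(x$mse), x$grade_unchecked))
  invisible(x)
}

#' Estimate the autoregulation index of a trained model
#'
#' Composes [model_step_response()], [plausibility_check()] and
#' [match_ari()].
#'
#' @param model A [trained_flow_model].
#' @param cfg A [step_config].
#' @param ... Passed to [match_ari()].
#' @return An `ari_estimate`.
#' @export
estimate_ari <- function(model, cfg = step_config(), ...) {
  resp <- model_step_response(model, cfg)
  resp <- plausibility_check(resp)
  match_ari(resp, tiecks_templates(model$dt, cfg), ...)
}
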