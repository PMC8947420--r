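# Tiecks second-order model of dynamic cerebral autoregulation.
#
# The classic grade table (autoregulation index 0..9) maps each grade to a
# time constant T [s], damping factor D and autoregulatory gain K. Values
# transcribed from the classic Tiecks formulation of the ARI; grade 0 is
# absent autoregulation (K = 0), grade 9 the fastest/strongest response.

tiecks_table <- data.frame(
  grade = 0:9,
  T = c(2.00, 2.00, 2.00, 2.00, 2.00, 1.90, 1.60, 1.20, 0.87, 0.65),
  D = c(0.00, 1.60, 1.50, 1.15, 0.90, 0.75, 0.65, 0.55, 0.52, 0.50),
  K = c(0.00, 0.20, 0.40, 0.60, 0.80, 0.90, 0.94, 0.96, 0.97, 0.98)
)

#' Tiecks model parameters for an autoregulation grade
#'
#' Returns the time constant `T` (s), damping factor `D` and gain `K` of the
#' second-order Tiecks model for an integer autoregulation index (ARI) grade.
#' `K` is 0 at grade 0 (no autoregulation) and increases with grade.
#'
#' @param grade Integer ARI grade in 0..9.
#' @return A list of class `tiecks_params` with fields `T`, `D`, `K`, `grade`.
#' @examples
#' tiecks_params(9)
#' @export
tiecks_params <- function(grade) {
  if (length(grade) != 1L || is.na(grade) || grade != round(grade) ||
      grade < 0 || grade > 9)
    stop("`grade` must be a single integer in 0..9", call. = FALSE)
  row <- tiecks_table[tiecks_table$grade == grade, ]
  structure(list(T = row$T, D = row$D, K = row$K, grade = as.integer(grade)),
            class = "tiecks_params")
}

#' @export
print.tiecks_params <- function(x, ...) {
  cat(sprintf("<tiecks_params> grade %d: T = %.2f s, D = %.2f, K = %.2f\n",
              x$grade, x$T, x$D, x$K))
  invisible(x)
}

# Core recursion. dP is the normalized pressure deviation
# (P - P_ref) / (P_ref - CrCP); returns relative velocity V/V_base.
# State update per sample at rate f = 1/dt:
#   x2[n] = x2[n-1] + (x1[n-1] - 2 D x2[n-1]) / (f T)
#   x1[n] = x1[n-1] + (dP[n]   - x2[n-1])     / (f T)
#   v[n]  = 1 + dP[n] - K x2[n]
tiecks_recursion <- function(dP, dt, params) {
  if (params$T <= 0) stop("time constant T must be positive", call. = FALSE)
  if (dt >= params$T)
    stop(sprintf("sampling interval %.3g s too coarse for T = %.3g s (unstable discretization)",
                 dt, params$T), call. = FALSE)
  fT <- params$T / dt           # f * T with f = 1/dt
  n <- length(dP)
  v <- numeric(n)
  x1 <- 0; x2 <- 0
  D2 <- 2 * params$D
  K <- params$K
  for (i in seq_len(n)) {
    x2new <- x2 + (x1 - D2 * x2) / fT
    x1 <- x1 + (dP[i] - x2) / fT
    x2 <- x2new
    v[i] <- 1 + dP[i] - K * x2
  }
  v
}

#' Simulate blood flow velocity from pressure via the Tiecks model
#'
#' Drives the second-order Tiecks autoregulation model with an arterial
#' pressure signal and returns the cerebral blood flow velocity it predicts
#' at a given ARI grade. The pressure deviation is normalized by
#' `(p_ref - crcp)` where `crcp` is the critical closing pressure.
#'
#' @param bp A [uniform_signal] of arterial pressure (mmHg).
#' @param params A [tiecks_params] object (or integer grade 0..9).
#' @param baseline_v Baseline flow velocity in cm/s used to scale the output.
#' @param noise_sd Gaussian noise standard deviation as a fraction of
#'   `baseline_v` (0 = deterministic).
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @param p_ref Reference (baseline) pressure; default the mean of `bp`.
#' @param crcp Critical closing pressure in mmHg (default 12).
#' @return A [uniform_signal] of flow velocity in cm/s.
#' @examples
#' bp <- negative_step(60, 10, 30, 80, 70)
#' v <- tiecks_bfv(bp, tiecks_params(9), baseline_v = 55)
#' @export
tiecks_bfv <- function(bp, params, baseline_v = 55, noise_sd = 0, seed = 1L,
                       p_ref = NULL, crcp = 12) {
  stopifnot(inherits(bp, "uniform_signal"))
  if (is.numeric(params)) params <- tiecks_params(params)
  stopifnot(inherits(params, "tiecks_params"))
  p <- signal_values(bp)
  if (is.null(p_ref)) p_ref <- mean(p)
  if (p_ref <= crcp)
    stop("reference pressure must exceed the critical closing pressure",
         call. = FALSE)
  dP <- (p - p_ref) / (p_ref - crcp)
  v <- tiecks_recursion(dP, bp$dt, params) * baseline_v
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd * baseline_v)
    restore_rng(rng)
  }
  uniform_signal(v, dt = bp$dt, units = "cm/s", t0 = bp$t0)
}

# seed handling that does not disturb the caller's RNG stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
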