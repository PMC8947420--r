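# Wavelet relative-energy distribution, Shannon entropy, disequilibrium and
# Lopez-Ruiz statistical complexity of a flow-velocity signal, plus the
# complexity-entropy plane coordinates.

#' Wavelet energy distribution of a signal
#'
#' Mean-removes the signal, applies an `m`-level periodized orthogonal
#' wavelet decomposition and returns the energy per detail level
#' `E_j = sum_k |C_j(k)|^2` together with the relative energies
#' `p_j = E_j / sum(E)`. The approximation (slowest trend) energy is excluded
#' from `p` by default since it otherwise dominates the distribution.
#'
#' @param x A [uniform_signal] or numeric vector, length >= `2^m`. The signal
#'   is truncated to the largest multiple of `2^m` samples.
#' @param wavelet One of [available_wavelets()] (default `"db4"`).
#' @param m Number of levels; default `floor(log2(length)) - 2`, keeping at
#'   least 4 coefficients at the deepest level.
#' @param include_approx Include the approximation energy in `p`.
#' @return An object of class `wavelet_energy_distribution` with fields
#'   `E` (per-level energies, finest first), `p`, `m`, `wavelet`,
#'   `approx_energy`, `total_energy`.
#' @export
wavelet_energy <- function(x, wavelet = "db4", m = NULL,
                           include_approx = FALSE) {
  v <- if (inherits(x, "uniform_signal")) x$values else as.numeric(x)
  n <- length(v)
  if (is.null(m)) m <- max(2L, floor(log2(n)) - 2L)
  m <- as.integer(m)
  if (m < 2L) stop("need at least 2 levels for a distribution", call. = FALSE)
  if (2^m > n)
    stop(sprintf("decomposition error: %d levels too deep for length %d", m, n),
         call. = FALSE)
  n_use <- (n %/% 2^m) * 2^m
  v <- v[seq_len(n_use)]
  v <- v - mean(v)
  d <- dwt_decompose(v, wavelet, m)
  E <- vapply(d$details, function(z) sum(z^2), 0)
  approx_energy <- sum(d$approximation^2)
  tot <- if (include_approx) sum(E) + approx_energy else sum(E)
  if (tot <= 0) stop("zero-energy signal", call. = FALSE)
  p <- if (include_approx) c(E, approx_energy) / tot else E / tot
  structure(list(E = E, p = p, m = m, wavelet = wavelet,
                 approx_energy = approx_energy,
                 total_energy = sum(E) + approx_energy,
                 include_approx = include_approx,
                 n_used = n_use),
            class = "wavelet_energy_distribution")
}

#' @export
print.wavelet_energy_distribution <- function(x, ...) {
  cat(sprintf("<wavelet_energy_distribution> %s, %d levels (%d samples)\n",
              x$wavelet, x$m, x$n_used))
  cat("  p_j:", paste(sprintf("%.4f", x$p), collapse = " "), "\n")
  invisible(x)
}

check_prob <- function(p, tol = 1e-9) {
  if (inherits(p, "wavelet_energy_distribution")) p <- p$p
  p <- as.numeric(p)
  if (any(p < -tol) || abs(sum(p) - 1) > tol)
    stop("distribution error: p must be a probability vector", call. = FALSE)
  pmax(p, 0)
}

#' Shannon entropy of a relative-energy distribution
#'
#' `H = -sum p_j ln p_j` in nats (with `0 ln 0 = 0`), and the normalized
#' entropy `H / ln(m)` in `[0, 1]`.
#'
#' @param p Probability vector (or a [wavelet_energy_distribution]).
#' @return List with `H` and `H_norm`.
#' @export
shannon_entropy <- function(p) {
  p <- check_prob(p)
  m <- length(p)
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz]))
  list(H = H, H_norm = H / log(m))
}

#' Disequilibrium of a distribution
#'
#' Normalized distance between `p` and the uniform distribution over the
#' same `m` levels. Euclidean form: `Q = Q0 sum (p_j - 1/m)^2` with
#' `Q0 = m / (m - 1)`; Wootters form: `Q = Q0 acos( sum sqrt(p_j / m) )`
#' with `Q0 = 1 / acos(sqrt(1/m))`. Both equal 0 at the uniform distribution
#' and 1 at a point mass.
#'
#' @param p Probability vector (or a [wavelet_energy_distribution]).
#' @param kind `"euclidean"` (default) or `"wootters"`.
#' @return Disequilibrium Q in `[0, 1]`.
#' @export
disequilibrium <- function(p, kind = c("euclidean", "wootters")) {
  kind <- match.arg(kind)
  p <- check_prob(p)
  m <- length(p)
  if (kind == "euclidean") {
    m / (m - 1) * sum((p - 1 / m)^2)
  } else {
    arg <- min(1, sum(sqrt(p / m)))
    acos(arg) / acos(sqrt(1 / m))
  }
}

#' Lopez-Ruiz statistical complexity
#'
#' The product of normalized entropy and disequilibrium: zero both at
#' perfect order (point mass) and full randomness (uniform distribution).
#'
#' @param H_norm Normalized entropy in `[0, 1]`.
#' @param Q Disequilibrium in `[0, 1]`.
#' @return Complexity `C = H_norm * Q`.
#' @export
statistical_complexity <- function(H_norm, Q) {
  if (H_norm < -1e-12 || H_norm > 1 + 1e-12 || Q < -1e-12 || Q > 1 + 1e-12)
    stop("domain error: H_norm and Q must lie in [0, 1]", call. = FALSE)
  H_norm * Q
}

#' Complexity-entropy plane coordinates of a signal
#'
#' Composes [wavelet_energy()], [shannon_entropy()], [disequilibrium()] and
#' [statistical_complexity()]. The plane plots `H_norm` (abscissa) against
#' `C` (ordinate).
#'
#' @param x A [uniform_signal] or numeric vector (a preprocessed
#'   flow-velocity signal, typically).
#' @param wavelet,m,include_approx Passed to [wavelet_energy()].
#' @param kind Disequilibrium distance, `"euclidean"` or `"wootters"`.
#' @param normalized_entropy Use `H_norm` in the complexity product (default);
#'   `FALSE` uses raw `H` in nats.
#' @return An object of class `complexity_point`: `H`, `H_norm`, `Q`, `C`,
#'   `m`, `wavelet`, `distance_kind`, and the distribution `p`.
#' @export
complexity_entropy_point <- function(x, wavelet = "db4", m = NULL,
                                     kind = c("euclidean", "wootters"),
                                     include_approx = FALSE,
                                     normalized_entropy = TRUE) {
  kind <- match.arg(kind)
  dist <- wavelet_energy(x, wavelet, m, include_approx)
  ent <- shannon_entropy(dist)
  Q <- disequilibrium(dist, kind)
  C <- if (normalized_entropy) statistical_complexity(ent$H_norm, Q)
       else ent$H * Q
  structure(list(H = ent$H, H_norm = ent$H_norm, Q = Q, C = C,
                 m = dist$m, wavelet = wavelet, distance_kind = kind,
                 p = dist$p),
            class = "complexity_point")
}

#' @export
print.complexity_point <- function(x, ...) {
  cat(sprintf("<complexity_point> H = %.4f nats, H_norm = %.4f, Q = %.4f, C = %.4f\n",
              x$H, x$H_norm, x$Q, x$C))
  cat(sprintf("  %s wavelet, %d levels, %s distance\n",
              x$wavelet, x$m, x$distance_kind))
  invisible(x)
}
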