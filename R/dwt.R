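# Periodized orthogonal discrete wavelet transform (Mallat pyramid).
#
# Only the handful of orthonormal filters the complexity analysis needs are
# embedded (standard published scaling coefficients; "db4" means four
# vanishing moments, an 8-tap filter). Periodization keeps the transform
# orthonormal on any even length, so Parseval holds exactly and energy
# bookkeeping per level is clean.

# orthonormal scaling filters in natural order (h[0] first)
dwt_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(0.48296291314453416, 0.8365163037378079,
           0.2241438680420134, -0.12940952255126037),
  db4  = c(0.2303778133088965, 0.7148465705529157,
           0.6308807679298589, -0.027983769416859854,
           -0.18703481171909309, 0.030841381835560764,
           0.0328830116668852, -0.010597401785069032),
  sym4 = c(0.0322231006040427, -0.012603967262037833,
           -0.09921954357684722, 0.29785779560527736,
           0.8037387518059161, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333)
)

#' Names of the available orthogonal wavelets
#'
#' @return Character vector of wavelet names usable wherever a
#'   `wavelet` argument is accepted (`"haar"`, `"db2"`, `"db4"`, `"sym4"`).
#' @export
available_wavelets <- function() names(dwt_filters)

get_dwt_filter <- function(wavelet) {
  if (!wavelet %in% names(dwt_filters))
    stop(sprintf("unknown wavelet '%s'; available: %s", wavelet,
                 paste(names(dwt_filters), collapse = ", ")), call. = FALSE)
  lo <- dwt_filters[[wavelet]]
  L <- length(lo)
  # quadrature mirror: hi[n] = (-1)^n lo[L-1-n]  (0-based n)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  # phase offset aligning the circular transform with the usual
  # periodized-convolution convention
  list(lo = lo, hi = hi, length = L, offset = -(L %/% 2L - 1L))
}

# one periodized analysis step: x (even length N) -> list(a, d) of length N/2
dwt_step <- function(x, f) {
  N <- length(x)
  half <- N %/% 2L
  L <- f$length
  # index matrix: row k (0-based) uses samples (2k + n + offset) mod N
  k <- 2L * (seq_len(half) - 1L)
  idx <- (outer(k, 0:(L - 1L) + f$offset, `+`) %% N + N) %% N + 1L
  xm <- matrix(x[idx], nrow = half, ncol = L)
  list(a = drop(xm %*% f$lo), d = drop(xm %*% f$hi))
}

# inverse of dwt_step
idwt_step <- function(a, d, f) {
  half <- length(a)
  N <- 2L * half
  L <- f$length
  x <- numeric(N)
  k <- 2L * (seq_len(half) - 1L)
  for (n in 0:(L - 1L)) {
    pos <- ((k + n + f$offset) %% N + N) %% N + 1L
    contrib <- f$lo[n + 1L] * a + f$hi[n + 1L] * d
    # positions can repeat across k only when L > N; accumulate safely
    for (i in seq_len(half)) x[pos[i]] <- x[pos[i]] + contrib[i]
  }
  x
}

#' Periodized discrete wavelet decomposition
#'
#' Multilevel orthonormal DWT with circular (periodized) boundary handling.
#' Level 1 is the finest detail (highest frequency band); level `m` the
#' coarsest, accompanied by the approximation at level `m`.
#'
#' @param x Numeric vector; `length(x)` must be divisible by `2^m`.
#' @param wavelet One of [available_wavelets()].
#' @param m Number of decomposition levels (>= 1).
#' @return List with `details` (list of coefficient vectors, levels 1..m),
#'   `approximation` (level-m scaling coefficients), `wavelet`, `m`.
#' @examples
#' d <- dwt_decompose(rnorm(256), "db4", m = 4)
#' sum(vapply(d$details, function(z) sum(z^2), 0)) + sum(d$approximation^2)
#' @export
dwt_decompose <- function(x, wavelet = "db4", m = 1L) {
  x <- as.numeric(x)
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (length(x) %% (2^m) != 0L)
    stop(sprintf("signal length %d is not divisible by 2^%d; cannot decompose",
                 length(x), m), call. = FALSE)
  if (length(x) / 2^m < 1L)
    stop("too many levels for this signal length", call. = FALSE)
  f <- get_dwt_filter(wavelet)
  details <- vector("list", m)
  a <- x
  for (j in seq_len(m)) {
    st <- dwt_step(a, f)
    details[[j]] <- st$d
    a <- st$a
  }
  structure(list(details = details, approximation = a,
                 wavelet = wavelet, m = m),
            class = "dwt_decomposition")
}

#' Reconstruct a signal from a periodized wavelet decomposition
#'
#' @param decomp A decomposition as returned by [dwt_decompose()]; coefficient
#'   vectors may be modified (e.g. zeroed) before reconstruction.
#' @return Numeric vector of the reconstructed signal.
#' @export
dwt_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "dwt_decomposition"))
  f <- get_dwt_filter(decomp$wavelet)
  a <- decomp$approximation
  for (j in rev(seq_len(decomp$m)))
    a <- idwt_step(a, decomp$details[[j]], f)
  a
}
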