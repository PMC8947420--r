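# Dynamic pressure-to-flow models fitted by nu-support-vector regression
# (libsvm via e1071, the engine the underlying optimization problem targets).
# Four families: FIR/ARX use a linear kernel, NFIR/NARX a Gaussian kernel;
# ARX/NARX add flow-velocity recurrences that are fed back during free-run
# (model-predictive-output) validation.

model_families <- c("fir", "nfir", "arx", "narx")

#' Specification of a dynamic flow model
#'
#' @param family One of `"fir"`, `"nfir"`, `"arx"`, `"narx"`.
#' @param n_p Pressure delay order (>= 0; features `p(n) .. p(n - n_p)`).
#' @param n_v Flow recurrence order; must be >= 1 for ARX/NARX and 0 for
#'   FIR/NFIR.
#' @param C Regularization constant of the nu-SVR problem.
#' @param nu The nu parameter in (0, 1) (bounds the support-vector fraction;
#'   the epsilon tube is set by the optimizer).
#' @param sigma Gaussian kernel width (ignored by the linear families).
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("narx", n_p = 3, n_v = 2, C = 16, nu = 0.5, sigma = 1)
#' @export
model_spec <- function(family, n_p, n_v = 0L, C = 1, nu = 0.5, sigma = 1) {
  family <- match.arg(tolower(family), model_families)
  recurrent <- family %in% c("arx", "narx")
  if (n_p < 0) stop("n_p must be >= 0", call. = FALSE)
  if (recurrent && n_v < 1L)
    stop("ARX/NARX require n_v >= 1", call. = FALSE)
  if (!recurrent && n_v != 0L)
    stop("FIR/NFIR require n_v = 0", call. = FALSE)
  if (nu <= 0 || nu >= 1) stop("nu must lie in (0, 1)", call. = FALSE)
  if (C <= 0 || sigma <= 0) stop("C and sigma must be positive", call. = FALSE)
  structure(list(family = family, n_p = as.integer(n_p), n_v = as.integer(n_v),
                 kernel = if (family %in% c("fir", "arx")) "linear" else "gaussian",
                 C = C, nu = nu, sigma = sigma),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s kernel): n_p = %d, n_v = %d, C = %.4g, nu = %.2f%s\n",
              toupper(x$family), x$kernel, x$n_p, x$n_v, x$C, x$nu,
              if (x$kernel == "gaussian") sprintf(", sigma = %.4g", x$sigma) else ""))
  invisible(x)
}

#' Build the delay-embedded regression problem
#'
#' Row `n` (for `n` from `max(n_p, n_v) + 1` to `L`) carries the features
#' `v(n-1), ..., v(n-n_v), p(n), p(n-1), ..., p(n-n_p)` and the target
#' `v(n)`.
#'
#' @param p,v Aligned numeric vectors or [uniform_signal]s of equal length.
#' @param n_p,n_v Delay orders.
#' @return List with matrix `X` (`L - max(n_p, n_v)` rows) and vector `y`.
#' @export
embed_signals <- function(p, v, n_p, n_v = 0L) {
  if (inherits(p, "uniform_signal")) p <- p$values
  if (inherits(v, "uniform_signal")) v <- v$values
  if (length(p) != length(v))
    stop("alignment error: signals of unequal length", call. = FALSE)
  L <- length(p)
  m <- max(n_p, n_v)
  if (L <= m) stop("signals too short for the requested orders", call. = FALSE)
  rows <- (m + 1L):L
  X <- matrix(0, nrow = length(rows),
              ncol = n_v + n_p + 1L)
  nm <- character(ncol(X))
  col <- 1L
  if (n_v > 0) for (k in seq_len(n_v)) {
    X[, col] <- v[rows - k]; nm[col] <- sprintf("v_lag%d", k); col <- col + 1L
  }
  for (k in 0:n_p) {
    X[, col] <- p[rows - k]; nm[col] <- sprintf("p_lag%d", k); col <- col + 1L
  }
  colnames(X) <- nm
  list(X = X, y = v[rows])
}

#' Train a dynamic flow model by one-step-ahead nu-SVR
#'
#' Fits the embedded regression with teacher forcing (measured flow values in
#' the recurrence features). Deterministic given the data and spec.
#'
#' @param p_train,v_train Normalized training channels ([uniform_signal]s or
#'   numeric vectors).
#' @param spec A [model_spec].
#' @param p_norm,v_norm Optional `c(xmin, xmax)` normalization ranges of the
#'   physical channels (stored for step-response scaling).
#' @param dt Sampling interval; taken from `p_train` when it is a
#'   [uniform_signal].
#' @return An object of class `trained_flow_model`.
#' @export
train_model <- function(p_train, v_train, spec, p_norm = NULL, v_norm = NULL,
                        dt = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(p_train, "uniform_signal")) {
    dt <- p_train$dt
    p_train <- p_train$values
  }
  if (inherits(v_train, "uniform_signal")) v_train <- v_train$values
  if (stats::sd(v_train) == 0)
    stop("training error: degenerate (constant) target", call. = FALSE)
  emb <- embed_signals(p_train, v_train, spec$n_p, spec$n_v)
  fit <- e1071::svm(emb$X, emb$y, type = "nu-regression", scale = FALSE,
                    kernel = if (spec$kernel == "linear") "linear" else "radial",
                    cost = spec$C, nu = spec$nu,
                    gamma = 1 / (2 * spec$sigma^2))
  structure(list(spec = spec, fit = fit, dt = dt,
                 n_train = length(p_train),
                 seed_values = utils::tail(v_train, max(spec$n_v, 1L)),
                 p_train_mean = mean(p_train),
                 v_train_mean = mean(v_train),
                 p_norm = p_norm, v_norm = v_norm),
            class = "trained_flow_model")
}

#' @export
print.trained_flow_model <- function(x, ...) {
  cat(sprintf("<trained_flow_model> %s: n_p = %d, n_v = %d, %d training samples, %d SVs\n",
              toupper(x$spec$family), x$spec$n_p, x$spec$n_v, x$n_train,
              x$fit$tot.nSV))
  invisible(x)
}

#' One-step-ahead prediction (teacher forcing)
#'
#' @param model A [trained_flow_model].
#' @param p,v Numeric vectors or [uniform_signal]s of the segment to predict.
#' @return List with `pred` and the matching `target` values.
#' @export
one_step_predict <- function(model, p, v) {
  emb <- embed_signals(p, v, model$spec$n_p, model$spec$n_v)
  list(pred = as.numeric(stats::predict(model$fit, emb$X)), target = emb$y)
}

#' Free-run (model-predictive-output) simulation
#'
#' Drives the model recursion over a pressure segment feeding predicted flow
#' values back into the recurrence features; no measured flow is used after
#' the seed. FIR/NFIR have no feedback path and ignore `v_init`. The output
#' covers samples `n_p + 1 .. length(p_val)` of the segment (a warm-up of
#' `n_p` samples is consumed by the pressure lags).
#'
#' @param model A [trained_flow_model].
#' @param p_val Pressure segment ([uniform_signal] or numeric vector).
#' @param v_init Seed values for the flow recurrences (last `n_v` training
#'   targets by default).
#' @return Numeric vector of predictions, with attribute `"diverged"` set to
#'   `TRUE` if the recursion left a plausible range (such models are
#'   discarded by [grid_search()]).
#' @export
free_run_predict <- function(model, p_val, v_init = model$seed_values) {
  stopifnot(inherits(model, "trained_flow_model"))
  if (inherits(p_val, "uniform_signal")) p_val <- p_val$values
  n_p <- model$spec$n_p; n_v <- model$spec$n_v
  L <- length(p_val)
  if (L < n_p + 1L) stop("length error: p_val shorter than n_p + 1", call. = FALSE)
  steps <- L - n_p
  bound <- 50  # normalized channels live in [-1, 1]; far outside = divergence
  if (n_v == 0L) {
    emb_rows <- (n_p + 1L):L
    X <- matrix(0, nrow = steps, ncol = n_p + 1L)
    for (k in 0:n_p) X[, k + 1L] <- p_val[emb_rows - k]
    colnames(X) <- sprintf("p_lag%d", 0:n_p)
    pred <- as.numeric(stats::predict(model$fit, X))
  } else {
    if (length(v_init) < n_v)
      stop(sprintf("v_init must supply %d seed values", n_v), call. = FALSE)
    hist <- utils::tail(v_init, n_v)   # hist[1] = v(n-n_v), ..., hist[n_v] = v(n-1)
    pred <- numeric(steps)
    X <- matrix(0, nrow = 1L, ncol = n_v + n_p + 1L)
    colnames(X) <- c(sprintf("v_lag%d", seq_len(n_v)), sprintf("p_lag%d", 0:n_p))
    for (i in seq_len(steps)) {
      n <- n_p + i
      X[1, seq_len(n_v)] <- rev(hist)
      X[1, n_v + 1L + 0:n_p] <- p_val[n - 0:n_p]
      vhat <- as.numeric(stats::predict(model$fit, X))
      if (!is.finite(vhat) || abs(vhat) > bound) {
        pred[i:steps] <- vhat
        pred <- pred[seq_len(i)]
        attr(pred, "diverged") <- TRUE
        return(pred)
      }
      pred[i] <- vhat
      hist <- c(hist[-1L][seq_len(max(n_v - 1L, 0L))], vhat)
    }
  }
  diverged <- any(!is.finite(pred)) || any(abs(pred) > bound)
  attr(pred, "diverged") <- diverged
  pred
}

#' Pearson correlation between measured and predicted flow
#'
#' @param v,v_hat Equal-length numeric vectors (n >= 3, non-constant).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(v, v_hat) {
  if (inherits(v, "uniform_signal")) v <- v$values
  if (length(v) != length(v_hat))
    stop("pearson_cc: unequal lengths", call. = FALSE)
  if (length(v) < 3L) stop("pearson_cc: need at least 3 samples", call. = FALSE)
  if (stats::sd(v) == 0 || stats::sd(v_hat) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  stats::cor(v, as.numeric(v_hat))
}

#' Hyperparameter grid for a model family
#'
#' Default ranges: delay orders 1-10 (FIR/NFIR) or 1-8 with recurrences 1-6
#' (ARX/NARX); `C` over powers of two from -2 to 14, `nu` from 0.1 to 0.9 and
#' `log2(sigma)` from -1 to 5, stepping the exponent by 2 to keep enumeration
#' tractable. A `reduced = TRUE` grid (used by the examples and the end-to-end
#' recovery analyses) keeps 2 values per dimension around the defaults.
#'
#' @param family Model family name.
#' @param reduced Use the small grid.
#' @param exp_step Exponent step for `C` and `sigma`.
#' @return List with vectors `n_p`, `n_v`, `C`, `nu`, `sigma`.
#' @export
default_grid <- function(family, reduced = FALSE, exp_step = 2) {
  family <- match.arg(tolower(family), model_families)
  recurrent <- family %in% c("arx", "narx")
  linear <- family %in% c("fir", "arx")
  if (reduced) {
    g <- list(n_p = c(2L, 4L),
              n_v = if (recurrent) c(1L, 2L, 3L) else 0L,
              C = 2^c(2, 6), nu = 0.5,
              sigma = if (linear) 1 else 2^c(1, 3, 5))
  } else {
    g <- list(n_p = if (recurrent) 1:8 else 1:10,
              n_v = if (recurrent) 1:6 else 0L,
              C = 2^seq(-2, 14, by = exp_step),
              nu = seq(0.1, 0.9, by = 0.2),
              sigma = if (linear) 1 else 2^seq(-1, 5, by = exp_step))
  }
  g
}

#' Exhaustive grid search with free-run validation
#'
#' Splits the recording 50/50 by duration, trains every grid candidate on the
#' first half by one-step-ahead nu-SVR, simulates the second half in free-run
#' mode, and returns the candidate with the highest validation Pearson
#' correlation. Ties are broken toward smaller `n_p + n_v`, then smaller `C`,
#' then enumeration order. Diverging free runs are discarded.
#'
#' @param p,v Normalized channels ([uniform_signal]s) of the full recording.
#' @param family Model family name.
#' @param grid Grid as from [default_grid()].
#' @param p_norm,v_norm Physical normalization ranges to store in the model.
#' @return List with `model` (the refitted best [trained_flow_model]),
#'   `cc_val`, `cc_train`, and `results` (one row per candidate).
#' @export
grid_search <- function(p, v, family = "narx",
                        grid = default_grid(family, reduced = TRUE),
                        p_norm = NULL, v_norm = NULL) {
  family <- match.arg(tolower(family), model_families)
  if (any(lengths(grid) == 0L)) stop("parameter error: empty grid", call. = FALSE)
  stopifnot(inherits(p, "uniform_signal"), inherits(v, "uniform_signal"))
  L <- length(p$values)
  half <- L %/% 2L
  split <- split_halves(p, v)
  cand <- expand.grid(n_p = grid$n_p, n_v = grid$n_v, C = grid$C,
                      nu = grid$nu, sigma = grid$sigma,
                      KEEP.OUT.ATTRS = FALSE)
  res <- cand
  res$cc_val <- NA_real_
  res$diverged <- FALSE
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    spec <- model_spec(family, cand$n_p[i], cand$n_v[i],
                       C = cand$C[i], nu = cand$nu[i], sigma = cand$sigma[i])
    m <- train_model(split$p_train, split$v_train, spec,
                     p_norm = p_norm, v_norm = v_norm)
    pred <- free_run_predict(m, split$p_val)
    if (isTRUE(attr(pred, "diverged"))) {
      res$diverged[i] <- TRUE
      next
    }
    target <- split$v_val$values[(spec$n_p + 1L):length(split$v_val$values)]
    cc <- tryCatch(pearson_cc(target, pred), error = function(e) NA_real_)
    res$cc_val[i] <- cc
    if (is.na(cc)) next
    if (is.null(best) || cc > best$cc + 1e-12 ||
        (abs(cc - best$cc) <= 1e-12 &&
         (cand$n_p[i] + cand$n_v[i] < best$order ||
          (cand$n_p[i] + cand$n_v[i] == best$order && cand$C[i] < best$C)))) {
      cc_tr <- {
        os <- one_step_predict(m, split$p_train, split$v_train)
        tryCatch(pearson_cc(os$target, os$pred), error = function(e) NA_real_)
      }
      best <- list(model = m, cc = cc, cc_train = cc_tr,
                   order = cand$n_p[i] + cand$n_v[i], C = cand$C[i])
    }
  }
  if (is.null(best))
    stop("grid search failed: every candidate diverged or was degenerate",
         call. = FALSE)
  list(model = best$model, cc_val = best$cc, cc_train = best$cc_train,
       results = res, n_evaluated = nrow(cand))
}

# 50/50 split by duration: first half train, second half validation
split_halves <- function(p, v) {
  L <- length(p$values)
  half <- L %/% 2L
  sub <- function(x, idx) uniform_signal(x$values[idx], x$dt, x$units,
                                         x$t0 + (idx[1] - 1L) * x$dt)
  list(p_train = sub(p, 1:half), v_train = sub(v, 1:half),
       p_val = sub(p, (half + 1L):L), v_val = sub(v, (half + 1L):L))
}
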