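# Cohort-level statistics: normality, paired hemisphere comparisons with the
# averaging rule, one-way repeated-measures ANOVA with Tukey HSD on the
# within-subject error term, and ROC/AUC posture discrimination.

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L)
    stop("sample-size error: Shapiro-Wilk needs 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(x) == 0) stop("undefined for a constant sample", call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Paired two-sample comparison
#'
#' Paired Student t-test under normality, Wilcoxon signed-rank test
#' otherwise.
#'
#' @param a,b Equal-length paired samples (n >= 3).
#' @param normal Logical: use the t-test (`TRUE`) or Wilcoxon (`FALSE`).
#' @return List with `statistic`, `p` and `method`.
#' @export
paired_compare <- function(a, b, normal = TRUE) {
  if (length(a) != length(b)) stop("paired samples of unequal length", call. = FALSE)
  if (length(a) < 3L) stop("need n >= 3 pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    # no information either way: the signed-rank convention reports p = 1,
    # while the t statistic is 0/0 and must be surfaced as degenerate
    if (normal)
      stop("degenerate error: all paired differences are zero", call. = FALSE)
    return(list(statistic = 0, p = 1, method = "wilcoxon signed-rank"))
  }
  if (normal) {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value, method = "paired t")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = "wilcoxon signed-rank")
  }
}

# validate and reshape a long cohort table into a subject x condition matrix
cohort_matrix <- function(table, metric = NULL) {
  if (!is.null(metric) && "metric" %in% names(table))
    table <- table[table$metric == metric, ]
  needed <- c("subject", "posture", "value")
  if (!all(needed %in% names(table)))
    stop("cohort table needs columns subject, posture, value", call. = FALSE)
  wide <- stats::xtabs(value ~ subject + posture, data = table)
  counts <- stats::xtabs(~ subject + posture, data = table)
  if (any(counts != 1L))
    stop("design error: unbalanced or incomplete design (no imputation)",
         call. = FALSE)
  mat <- matrix(as.numeric(wide), nrow = nrow(wide),
                dimnames = dimnames(wide))
  if (ncol(mat) < 2L || nrow(mat) < 3L)
    stop("need >= 2 conditions and >= 3 subjects", call. = FALSE)
  mat
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA on a long table of `(subject, posture, value)` rows:
#' `F = MS_condition / MS_(condition x subject)` with `df_effect = k - 1`
#' and `df_error = (k - 1)(n - 1)`. The Greenhouse-Geisser corrected p-value
#' is reported alongside the uncorrected one.
#'
#' @param table Data frame with columns `subject`, `posture`, `value` (and
#'   optionally `metric`).
#' @param metric If the table carries a `metric` column, which metric to use.
#' @return List with `F`, `df_effect`, `df_error`, `p`, `p_gg` and the
#'   Greenhouse-Geisser `epsilon`.
#' @export
rm_anova <- function(table, metric = NULL) {
  mat <- cohort_matrix(table, metric)
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_e <- k - 1L
  df_r <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df_e
  ms_err <- ss_err / df_r
  if (ms_err <= 0) {
    Fv <- if (ms_cond <= 1e-24) 0 else Inf
  } else Fv <- ms_cond / ms_err
  p <- if (Fv == 0) 1 else stats::pf(Fv, df_e, df_r, lower.tail = FALSE)
  # Greenhouse-Geisser epsilon from the double-centred covariance
  S <- stats::cov(mat)
  Sc <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(1, max(1 / (k - 1), eps))
  p_gg <- if (Fv == 0) 1 else
    stats::pf(Fv, eps * df_e, eps * df_r, lower.tail = FALSE)
  list(F = Fv, df_effect = df_e, df_error = df_r, p = p,
       p_gg = p_gg, epsilon = eps, ms_error = ms_err, n = n, k = k)
}

#' Tukey HSD post hoc on the within-subject error term
#'
#' Pairwise condition comparisons using the studentized range with the
#' repeated-measures error mean square; all `k(k-1)/2` pairs are reported.
#'
#' @inheritParams rm_anova
#' @return Data frame with columns `pair`, `difference`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(table, metric = NULL) {
  mat <- cohort_matrix(table, metric)
  an <- rm_anova(table, metric)
  n <- an$n; k <- an$k
  se <- sqrt(an$ms_error / n)
  cm <- colMeans(mat)
  pairs <- utils::combn(colnames(mat), 2)
  out <- data.frame(pair = apply(pairs, 2, paste, collapse = "-"),
                    difference = NA_real_, q = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    d <- cm[pairs[1, i]] - cm[pairs[2, i]]
    q <- abs(d) / se
    out$difference[i] <- d
    out$q[i] <- q
    out$p_adj[i] <- stats::ptukey(q, nmeans = k, df = an$df_error,
                                  lower.tail = FALSE)
  }
  out
}

#' ROC curve and AUC by the Mann-Whitney identity
#'
#' `AUC = P(value_1 > value_0) + P(value_1 = value_0) / 2`, computed from
#' ranks; the curve enumerates every threshold. Because class polarity is a
#' labelling choice, the oriented AUC `max(AUC, 1 - AUC)` is reported
#' alongside the raw directed value.
#'
#' @param values_group0,values_group1 Non-empty numeric vectors.
#' @return List with `auc` (oriented), `auc_directed`
#'   (`P(group1 > group0)` + half ties), `flipped`, and `curve`
#'   (data frame `threshold`, `fpr`, `tpr` treating group 1 as positive).
#' @export
roc_auc <- function(values_group0, values_group1) {
  g0 <- as.numeric(values_group0); g1 <- as.numeric(values_group1)
  if (length(g0) == 0L || length(g1) == 0L)
    stop("input error: both groups must be non-empty", call. = FALSE)
  n0 <- length(g0); n1 <- length(g1)
  r <- rank(c(g0, g1))
  auc_dir <- (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  thr <- c(-Inf, sort(unique(c(g0, g1))), Inf)
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(s) mean(g0 >= s), 0),
    tpr = vapply(thr, function(s) mean(g1 >= s), 0))
  list(auc = max(auc_dir, 1 - auc_dir), auc_directed = auc_dir,
       flipped = auc_dir < 0.5, curve = curve)
}

#' Merge hemisphere values when they do not differ
#'
#' Tests the paired left/right difference (t-test when both sides pass
#' Shapiro-Wilk at 0.05, Wilcoxon otherwise) and averages the two sides into
#' one value per subject only when the difference is non-significant at
#' `alpha`; otherwise both sides are retained and flagged.
#'
#' @param left,right Paired per-subject values.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `merged` (averaged values or `NULL`), `left`, `right`,
#'   `p`, `method`, `significant`.
#' @export
merge_hemispheres <- function(left, right, alpha = 0.05) {
  normal <- tryCatch(
    shapiro_wilk(left)$p > alpha && shapiro_wilk(right)$p > alpha,
    error = function(e) FALSE)
  cmp <- tryCatch(paired_compare(left, right, normal = normal),
                  error = function(e) list(statistic = 0, p = 1,
                                           method = "degenerate (identical sides)"))
  sig <- cmp$p < alpha
  list(merged = if (!sig) (left + right) / 2 else NULL,
       left = left, right = right,
       p = cmp$p, method = cmp$method, significant = sig)
}
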