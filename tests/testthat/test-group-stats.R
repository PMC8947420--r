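# Cohort statistics: normality, paired comparisons, repeated-measures ANOVA
# with Tukey post hoc, and ROC/AUC.

test_that("Shapiro-Wilk accepts normal and rejects bimodal samples", {
  accepted <- 0
  for (s in 1:100) {
    set.seed(s)
    if (shapiro_wilk(rnorm(50))$p > 0.05) accepted <- accepted + 1
  }
  expect_gte(accepted, 90)
  for (s in 1:20) {
    set.seed(s)
    bimodal <- c(rnorm(25, -10), rnorm(25, 10))
    expect_lt(shapiro_wilk(bimodal)$p, 0.05)
  }
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "sample-size")
})

test_that("paired comparison handles shifts, symmetry and degeneracy", {
  set.seed(71)
  a <- rnorm(10)
  b <- a + 1 + rnorm(10, sd = 1e-6)
  expect_lt(paired_compare(a, b, normal = TRUE)$p, 0.01)
  f <- paired_compare(a, b, normal = TRUE)
  r <- paired_compare(b, a, normal = TRUE)
  expect_equal(f$statistic, -r$statistic)
  expect_equal(f$p, r$p)
  # identical samples: signed-rank convention p = 1; t degenerate
  expect_equal(paired_compare(a, a, normal = FALSE)$p, 1)
  expect_error(paired_compare(a, a, normal = TRUE), "degenerate")
})

test_that("RM-ANOVA equals the paired-t squared identity on 2 conditions", {
  set.seed(72)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    a <- rnorm(n); b <- rnorm(n, mean = 0.5)
    tab <- data.frame(subject = rep(sprintf("s%d", 1:n), 2),
                      posture = rep(c("lay", "sit"), each = n),
                      value = c(a, b))
    an <- rm_anova(tab)
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(an$p, tt$p.value, tolerance = 1e-9)
    expect_equal(an$df_effect, 1)
  }
})

test_that("RM-ANOVA null and design checks behave", {
  tab <- data.frame(subject = rep(c("a", "b", "c"), each = 3),
                    posture = rep(c("lay", "sit", "stand"), 3),
                    value = rep(c(1, 5, 9), each = 3))
  an <- rm_anova(tab)   # no condition effect, only subject effect
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  expect_equal(an$df_effect, 2)
  expect_error(rm_anova(tab[-1, ]), "design error")
})

test_that("RM-ANOVA p agrees with a within-subject permutation test", {
  set.seed(73)
  n <- 8
  subj_eff <- rnorm(n, sd = 2)
  tab <- data.frame(
    subject = rep(sprintf("s%02d", 1:n), each = 3),
    posture = rep(c("lay", "sit", "stand"), n),
    value = rep(subj_eff, each = 3) + rep(c(0, 0.8, 0.2), n) + rnorm(3 * n))
  an <- rm_anova(tab)
  mat <- dcaflow:::cohort_matrix(tab)
  f_stat <- function(m) {
    grand <- mean(m)
    ssc <- nrow(m) * sum((colMeans(m) - grand)^2)
    sss <- ncol(m) * sum((rowMeans(m) - grand)^2)
    sse <- sum((m - grand)^2) - ssc - sss
    (ssc / (ncol(m) - 1)) / (sse / ((ncol(m) - 1) * (nrow(m) - 1)))
  }
  draws <- 10000
  exceed <- 0
  for (i in seq_len(draws)) {
    perm <- t(apply(mat, 1, sample))
    if (f_stat(perm) >= an$F - 1e-12) exceed <- exceed + 1
  }
  p_perm <- exceed / draws
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / draws)
  expect_lt(abs(p_perm - an$p), mc_err + 0.02)
})

test_that("Tukey HSD flags only the shifted condition", {
  set.seed(74)
  n <- 10
  base <- rnorm(n, sd = 0.3)
  tab <- data.frame(
    subject = rep(sprintf("s%02d", 1:n), each = 3),
    posture = rep(c("lay", "sit", "stand"), n),
    value = c(rbind(base + rnorm(n, sd = 0.2), base + rnorm(n, sd = 0.2),
                    base + 2 + rnorm(n, sd = 0.2))))
  tk <- tukey_hsd(tab)
  expect_equal(nrow(tk), 3)
  with_stand <- grepl("stand", tk$pair)
  expect_true(all(tk$p_adj[with_stand] < 0.01))
  expect_gt(tk$p_adj[!with_stand], 0.05)
  # adjusted p is never below the unadjusted paired p on the same data
  mat <- dcaflow:::cohort_matrix(tab)
  for (i in which(!with_stand)) {
    cols <- strsplit(tk$pair[i], "-")[[1]]
    p_raw <- t.test(mat[, cols[1]], mat[, cols[2]], paired = TRUE)$p.value
    expect_gte(tk$p_adj[i] + 0.01, p_raw)
  }
})

test_that("AUC equals brute-force concordant-pair counting", {
  g0 <- c(1, 2, 3); g1 <- c(2, 3, 4)
  brute <- function(a, b) {
    s <- 0
    for (x in a) for (y in b) s <- s + (y > x) + 0.5 * (y == x)
    s / (length(a) * length(b))
  }
  r <- roc_auc(g0, g1)
  expect_equal(r$auc_directed, brute(g0, g1))
  expect_equal(r$auc_directed, 7 / 9)
  set.seed(75)
  for (i in 1:10) {
    a <- sample(0:9, 12, TRUE); b <- sample(0:9, 15, TRUE) + rbinom(15, 3, 0.4)
    expect_equal(roc_auc(a, b)$auc_directed, brute(a, b), tolerance = 1e-12)
  }
})

test_that("AUC extremes, ties and invariance under monotone transforms", {
  expect_equal(roc_auc(c(1, 2, 3), c(10, 11, 12))$auc, 1)
  expect_equal(roc_auc(c(5, 5, 5), c(5, 5, 5))$auc_directed, 0.5)
  set.seed(76)
  a <- rnorm(20); b <- rnorm(20, 1)
  expect_equal(roc_auc(a, b)$auc_directed,
               roc_auc(exp(a), exp(b))$auc_directed, tolerance = 1e-12)
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(77)
  a <- rnorm(25); b <- rnorm(25, 0.8)
  r <- roc_auc(a, b)
  ref <- pROC::roc(response = rep(c(0, 1), each = 25), predictor = c(a, b),
                   quiet = TRUE, direction = "<")
  expect_equal(r$auc_directed, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("hemispheres merge only when the paired test is non-significant", {
  set.seed(78)
  l <- rnorm(12, 5)
  r_same <- l + rnorm(12, sd = 0.01)
  m1 <- merge_hemispheres(l, r_same)
  expect_false(m1$significant)
  expect_equal(m1$merged, (l + r_same) / 2)
  r_diff <- l + 2 + rnorm(12, sd = 0.05)
  m2 <- merge_hemispheres(l, r_diff)
  expect_true(m2$significant)
  expect_null(m2$merged)
})
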