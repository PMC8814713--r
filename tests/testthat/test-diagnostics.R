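test_that("AUC handles perfect separation and complete ties", {
  expect_equal(roc_curve(c(4, 4, 5), c(0, 1, 1))$auc, 1.0)
  expect_equal(roc_curve(1, 1)$auc, 0.5)
})

test_that("trapezoidal AUC equals all-pairs concordance on the worked example", {
  pos <- c(5, 6, 4, 7, 4, 5, 6, 1)
  neg <- c(0, 1, 2, 1, 0, 1, 2)
  roc <- roc_curve(pos, neg)
  expect_equal(roc$auc, concordance_auc(pos, neg))
})

test_that("AUC equals concordance and pROC on random instances", {
  withr::local_seed(2024)
  for (i in 1:40) {
    pos <- sample(0:12, sample(2:30, 1), replace = TRUE)
    neg <- sample(0:12, sample(2:30, 1), replace = TRUE)
    roc <- roc_curve(pos, neg)
    expect_equal(roc$auc, concordance_auc(pos, neg))
    # curve monotonicity along increasing thresholds
    expect_true(all(diff(roc$curve$sensitivity) <= 1e-12))
    expect_true(all(diff(roc$curve$specificity) >= -1e-12))
  }
  pos <- c(5, 6, 4, 7, 4, 5, 6, 1)
  neg <- c(0, 1, 2, 1, 0, 1, 2)
  ref <- suppressMessages(pROC::roc(
    response = rep(c(1, 0), c(length(pos), length(neg))),
    predictor = c(pos, neg), direction = "<"))
  expect_equal(roc_curve(pos, neg)$auc, as.numeric(pROC::auc(ref)))
})

test_that("ROC is invariant under strictly increasing score transforms", {
  withr::local_seed(5)
  pos <- rnorm(12, 2)
  neg <- rnorm(10)
  a <- roc_curve(pos, neg)
  b <- roc_curve(exp(pos), exp(neg))
  expect_equal(b$auc, a$auc)
  expect_equal(b$curve$sensitivity, a$curve$sensitivity)
  expect_equal(b$curve$specificity, a$curve$specificity)
})

test_that("cutoff selection maximises Youden's J over midpoint candidates", {
  expect_equal(roc_curve(c(4, 5, 6), c(0, 1, 2))$chosen_cutoff, 3.0)
  roc <- roc_curve(c(4, 5, 6), c(0, 1, 2))
  expect_equal(roc$sens_chosen, 1)
  expect_equal(roc$spec_chosen, 1)
  # brute-force sweep oracle on the overlapping example
  pos <- c(5, 6, 4, 7, 4, 5, 6, 1)
  neg <- c(0, 1, 2, 1, 0, 1, 2)
  roc <- roc_curve(pos, neg)
  cand <- roc$curve[is.finite(roc$curve$threshold), ]
  j <- vapply(cand$threshold,
              function(c) mean(pos > c) + mean(neg <= c) - 1, numeric(1))
  expect_equal(max(j), max(cand$youden_j))
  expect_equal(roc$curve$youden_j[roc$curve$threshold ==
                                    roc$chosen_cutoff], max(j))
  # here the optimum sits in the 2-4 gap, so the midpoint is 3.0
  expect_equal(roc$chosen_cutoff, 3.0)
})

test_that("confusion metrics are exact counts in percent", {
  m <- confusion_metrics(c(4, 4), c(0, 0), 3.5)
  expect_equal(m$sensitivity_pct, 100)
  expect_equal(m$specificity_pct, 100)
  m <- confusion_metrics(c(rep(4, 7), 1), rep(0, 7), 3.5)
  expect_equal(m$sensitivity_pct, 87.5)
  expect_equal(m$specificity_pct, 100)
  expect_equal(m$tp, 7)
  expect_equal(m$fn, 1)
  withr::local_seed(9)
  for (i in 1:25) {
    pos <- sample(0:10, 8, TRUE)
    neg <- sample(0:10, 7, TRUE)
    cut <- sample(0:10, 1) - 0.5
    m <- confusion_metrics(pos, neg, cut)
    expect_equal(m$tp, sum(pos > cut))
    expect_equal(m$tn, sum(neg <= cut))
    expect_equal(m$sensitivity_pct, 100 * sum(pos > cut) / length(pos))
    expect_equal(m$specificity_pct, 100 * sum(neg <= cut) / length(neg))
  }
})

test_that("empty score groups are rejected", {
  expect_error(roc_curve(numeric(0), 1:3),
               class = "amss_validation_error")
  expect_error(confusion_metrics(1:3, NA_real_, 1),
               class = "amss_validation_error")
})

test_that("Pearson r matches the product-moment formula and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  out <- correlate(x, y, "pearson")
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, manual)
  ref <- stats::cor.test(x, y)
  expect_equal(out$r, unname(ref$estimate))
  expect_equal(out$p, ref$p.value)
})

test_that("perfect linear relations give |r| = 1 and p = 0", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, 2 * x + 1)$p, 0)
  expect_equal(correlate(x, -x)$r, -1)
})

test_that("Spearman equals Pearson on midranks, with the t-transform p", {
  withr::local_seed(31)
  for (i in 1:25) {
    n <- sample(5:25, 1)
    x <- sample(0:8, n, TRUE)  # ties guaranteed
    y <- x + rnorm(n, sd = 2)
    a <- correlate(x, y, "spearman")
    b <- correlate(rank(x), rank(y), "pearson")
    expect_equal(a$r, b$r)
    expect_equal(a$p, b$p)
    ref <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(a$r, unname(ref$estimate))
  }
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(correlate(rep(1, 5), 1:5), regexp = "zero variance",
               class = "amss_validation_error")
  expect_error(correlate(1:2, 1:2), class = "amss_validation_error")
  expect_error(correlate(1:3, 1:4), class = "amss_validation_error")
})

test_that("identical cell means give a zero interaction F", {
  y <- rep(c(1, 2, 3, 4), times = 2) + rep(c(0, 0), each = 4)
  y <- c(y, y + 0.5)  # replicate with constant offset within cells
  a <- rep(rep(c("ctl", "sep"), each = 4), 2)
  b <- rep(c(0, 4, 12, 24), 4)
  fit <- two_way_anova(y, a, b)
  expect_equal(
    fit$effects$statistic[fit$effects$effect == "treatment:time"], 0)
  expect_equal(fit$effects$statistic[fit$effects$effect == "treatment"],
               0)
})

test_that("sums of squares partition the total on balanced designs", {
  withr::local_seed(77)
  y <- rnorm(16)
  a <- rep(c("x", "y"), each = 8)
  b <- rep(rep(c("t0", "t1"), each = 4), 2)
  fit <- two_way_anova(y, a, b)
  ss_total <- sum((y - mean(y))^2)
  expect_equal(sum(fit$effects$ss) + fit$residual$ss, ss_total)
})

test_that("balanced-design F values match the linear-model oracle", {
  withr::local_seed(123)
  for (i in 1:30) {
    n_per <- sample(2:5, 1)
    cellmeans <- matrix(rnorm(8, sd = 2), 2, 4)
    d <- expand.grid(rep_i = seq_len(n_per), a = 1:2, b = 1:4)
    d$y <- cellmeans[cbind(d$a, d$b)] + rnorm(nrow(d))
    fit <- two_way_anova(d$y, factor(d$a), factor(d$b))
    oracle <- summary(stats::aov(y ~ factor(a) * factor(b), data = d))[[1]]
    expect_equal(fit$effects$statistic,
                 oracle[["F value"]][1:3], tolerance = 1e-10)
    expect_equal(fit$effects$p, oracle[["Pr(>F)"]][1:3],
                 tolerance = 1e-10)
    expect_equal(fit$residual$ss, oracle[["Sum Sq"]][4])
  }
})

test_that("Bonferroni post-tests multiply raw p by the number of time levels", {
  withr::local_seed(55)
  d <- expand.grid(rep_i = 1:4, a = c("ctl", "sep"), b = c(0, 4, 12, 24))
  d$y <- rnorm(nrow(d)) + ifelse(d$a == "sep", d$b / 10, 0)
  fit <- two_way_anova(d$y, d$a, d$b)
  expect_equal(nrow(fit$posttests), 4)
  expect_equal(fit$posttests$p_adj,
               pmin(1, fit$posttests$p_raw * 4))
  # manual pooled-variance t for one timepoint
  ms_w <- fit$residual$ms
  sub <- d[d$b == 12, ]
  est <- mean(sub$y[sub$a == "sep"]) - mean(sub$y[sub$a == "ctl"])
  tval <- est / sqrt(ms_w * (1 / 4 + 1 / 4))
  expect_equal(fit$posttests$statistic[fit$posttests$time == "12"], tval)
})

test_that("degenerate and malformed factorial inputs are rejected", {
  expect_error(
    two_way_anova(rep(1, 8), rep(c("a", "b"), 4), rep(c(0, 4), each = 4)),
    class = "amss_degenerate_error")
  expect_error(
    two_way_anova(rnorm(4), rep("a", 4), rep(c(0, 4), 2)),
    class = "amss_validation_error")
  expect_error(
    two_way_anova(rnorm(6), rep(c("a", "b"), 3), rep(c(0, 4, 12), 2)),
    class = "amss_validation_error")  # one value per cell: no error df
})
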