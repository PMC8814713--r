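#' Pearson or Spearman correlation with a t-based test
#'
#' Pearson's r is the product-moment correlation; Spearman's rho is
#' Pearson's r applied to midranks. The two-sided p-value uses the
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` against Student's t with
#' n - 2 degrees of freedom; a perfect correlation gives p = 0. The method
#' is caller-chosen, not auto-selected by a normality screen.
#'
#' @param x,y Equal-length numeric vectors. Pairs with a missing value in
#'   either vector are dropped; at least 3 complete pairs are required.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble with `r`, `n`, `method`, `statistic` (the t
#'   value), and the two-sided `p`.
#' @examples
#' correlate(1:10, (1:10)^2, method = "spearman")
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop_validation("x and y must have equal length")
  }
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop_validation("need at least 3 complete pairs, got %d", n)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_validation("x and y must be finite")
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_validation("correlation undefined: zero variance in %s",
                    if (sd(x) == 0) "x" else "y")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (1 - r^2 <= .Machine$double.eps) {
    tval <- sign(r) * Inf
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(r = r, n = n, method = method, statistic = tval, p = p)
}

#' Two-way factorial ANOVA (time by treatment) with Bonferroni post-tests
#'
#' Fixed-effects factorial decomposition of a response measured over a
#' treatment factor and a time factor, the design used to compare the two
#' study arms across the monitoring grid. For unbalanced designs (the study
#' arms are n = 7 vs n = 8) the sums of squares use unweighted cell means
#' (the analysis-of-unweighted-means form of Type-III sums of squares),
#' which reduces to the classical partition when the design is balanced.
#' F ratios divide each effect mean square by the within-cell mean square.
#'
#' Post-tests compare the treatment groups within each time level with a
#' two-sided t statistic on the pooled within-cell variance, Bonferroni
#' adjusted for the number of time levels.
#'
#' @param values Numeric response vector.
#' @param treatment,time Factors (or vectors coerced to factors) of the
#'   same length as `values`; every treatment-by-time cell must contain at
#'   least one observation and each factor at least two levels.
#' @return An `amss_anova` object: a list with `effects` (tibble of
#'   `effect`, `df_num`, `df_den`, `ss`, `ms`, `statistic` (F), `p`),
#'   `residual` (within-cell df and SS), `cell_means`, and `posttests`
#'   (tibble of per-time treatment contrasts with raw and
#'   Bonferroni-adjusted p). `tidy()` returns the effects table;
#'   `glance()` a one-row summary.
#' @examples
#' scores <- score_cohort(generate_cohort(default_config(seed = 1)))
#' fit <- two_way_anova(scores$amss_total, scores$group, scores$time_h)
#' tidy(fit)
#' @export
two_way_anova <- function(values, treatment, time) {
  values <- as.numeric(values)
  treatment <- factor(treatment)
  time <- factor(time)
  if (length(values) != length(treatment) ||
      length(values) != length(time)) {
    stop_validation("values, treatment, and time must have equal length")
  }
  ok <- stats::complete.cases(values, treatment, time)
  values <- values[ok]
  treatment <- droplevels(treatment[ok])
  time <- droplevels(time[ok])
  if (nlevels(treatment) < 2 || nlevels(time) < 2) {
    stop_validation("both factors need at least 2 levels with data")
  }
  tab <- table(treatment, time)
  if (any(tab == 0)) {
    stop_validation("every treatment-by-time cell needs at least one value")
  }
  A <- nlevels(treatment)
  B <- nlevels(time)
  N <- length(values)
  cell <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(y = values, a = treatment, b = time),
      .data$a, .data$b),
    mean = mean(.data$y), n = dplyr::n(), ss = sum((.data$y - mean)^2),
    .groups = "drop")
  m <- matrix(NA_real_, A, B, dimnames = list(levels(treatment),
                                              levels(time)))
  nmat <- m
  m[cbind(as.integer(cell$a), as.integer(cell$b))] <- cell$mean
  nmat[cbind(as.integer(cell$a), as.integer(cell$b))] <- cell$n
  ss_within <- sum(cell$ss)
  df_within <- N - A * B
  if (df_within <= 0) {
    stop_validation("no within-cell replication: cannot estimate error")
  }
  if (ss_within <= 0) {
    abort("zero within-cell variance: F ratios are degenerate",
          class = "amss_degenerate_error")
  }
  # unweighted-means analysis: harmonic mean cell size scales cell-mean SS
  n_h <- A * B / sum(1 / nmat)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_a <- n_h * B * sum((row_m - grand)^2)
  ss_b <- n_h * A * sum((col_m - grand)^2)
  inter <- m - outer(row_m, rep(1, B)) - outer(rep(1, A), col_m) + grand
  ss_ab <- n_h * sum(inter^2)
  ms_within <- ss_within / df_within
  eff <- tibble::tibble(
    effect = c("treatment", "time", "treatment:time"),
    df_num = c(A - 1L, B - 1L, (A - 1L) * (B - 1L)),
    df_den = df_within,
    ss = c(ss_a, ss_b, ss_ab)
  )
  eff$ms <- eff$ss / eff$df_num
  eff$statistic <- eff$ms / ms_within
  eff$p <- pf(eff$statistic, eff$df_num, eff$df_den, lower.tail = FALSE)

  post <- purrr::map_dfr(levels(time), function(b) {
    purrr::map_dfr(utils::combn(levels(treatment), 2, simplify = FALSE),
                   function(pr) {
      n1 <- nmat[pr[1], b]
      n2 <- nmat[pr[2], b]
      est <- m[pr[2], b] - m[pr[1], b]
      se <- sqrt(ms_within * (1 / n1 + 1 / n2))
      tval <- est / se
      tibble::tibble(time = b,
                     contrast = sprintf("%s - %s", pr[2], pr[1]),
                     estimate = est, statistic = tval,
                     p_raw = 2 * pt(-abs(tval), df = df_within))
    })
  })
  post$p_adj <- pmin(1, post$p_raw * B)

  structure(
    list(effects = eff,
         residual = tibble::tibble(df = df_within, ss = ss_within,
                                   ms = ms_within),
         cell_means = m, cell_n = nmat, n = N, posttests = post),
    class = "amss_anova"
  )
}

#' @export
print.amss_anova <- function(x, ...) {
  cat(sprintf("Two-way factorial ANOVA (unweighted cell means), n = %d\n",
              x$n))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-15s F(%d, %d) = %8.3f, p = %.4g\n", e$effect[i],
                e$df_num[i], e$df_den[i], e$statistic[i], e$p[i]))
  }
  cat(sprintf("  residual SS %.4g on %d df\n", x$residual$ss,
              x$residual$df))
  sig <- x$posttests[x$posttests$p_adj < 0.05, ]
  cat(sprintf("  Bonferroni post-tests: %d of %d significant at 0.05\n",
              nrow(sig), nrow(x$posttests)))
  invisible(x)
}

#' @export
tidy.amss_anova <- function(x, ...) {
  x$effects
}

#' @export
glance.amss_anova <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    df_residual = x$residual$df,
    ms_residual = x$residual$ms,
    f_treatment = x$effects$statistic[x$effects$effect == "treatment"],
    p_treatment = x$effects$p[x$effects$effect == "treatment"],
    f_interaction =
      x$effects$statistic[x$effects$effect == "treatment:time"],
    p_interaction = x$effects$p[x$effects$effect == "treatment:time"]
  )
}
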