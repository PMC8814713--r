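#' ROC analysis of a diagnostic score
#'
#' Builds the ROC curve for a score where higher values indicate disease.
#' Candidate cutoffs are the midpoints between adjacent distinct observed
#' scores, bracketed by `-Inf`/`+Inf` sentinels; at a cutoff `c`,
#' sensitivity is the fraction of diseased (positive) scores strictly above
#' `c` and specificity the fraction of healthy (negative) scores at or
#' below `c`. The AUC is the trapezoidal area under the (1 - specificity,
#' sensitivity) polyline, which equals the Mann-Whitney concordance
#' probability with ties counted one half.
#'
#' The operating cutoff is chosen by maximising Youden's
#' J = sensitivity + specificity - 1, the standard operationalisation of
#' the "best balance" between the two error rates; ties are broken toward
#' higher specificity, then toward the lower threshold. Because candidates
#' are midpoints, integer scores yield half-integer cutoffs (such as the
#' 3.5 used for the A-MSS at 4 h).
#'
#' @param scores_positive Numeric scores of the diseased group (here,
#'   sepsis-arm animals).
#' @param scores_negative Numeric scores of the healthy group.
#' @param roc An `amss_roc` object.
#' @param cutoff A classification threshold; calls above it are positive.
#' @return `roc_curve()` returns an `amss_roc` object: a list with the
#'   threshold sweep (`curve`: threshold, sensitivity, specificity,
#'   youden_j), `auc`, the chosen cutoff and its sensitivity/specificity,
#'   and the group sizes. `select_cutoff()` returns the chosen threshold.
#'   `confusion_metrics()` returns a one-row tibble with `tp`, `fn`, `tn`,
#'   `fp`, and `sensitivity_pct`/`specificity_pct` in percent.
#' @examples
#' roc <- roc_curve(c(4, 5, 6, 7), c(0, 1, 1, 2))
#' roc$auc
#' select_cutoff(roc)
#' confusion_metrics(c(4, 5, 6, 7), c(0, 1, 1, 2), cutoff = 3.5)
#' @export
roc_curve <- function(scores_positive, scores_negative) {
  pos <- check_scores(scores_positive, "scores_positive")
  neg <- check_scores(scores_negative, "scores_negative")
  u <- sort(unique(c(pos, neg)))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  thresholds <- c(-Inf, mids, Inf)
  sens <- vapply(thresholds, function(c) mean(pos > c), numeric(1))
  spec <- vapply(thresholds, function(c) mean(neg <= c), numeric(1))
  fpr <- 1 - spec
  # thresholds increase, so fpr decreases from 1 to 0
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)
  out <- structure(
    list(
      curve = tibble::tibble(threshold = thresholds, sensitivity = sens,
                             specificity = spec,
                             youden_j = sens + spec - 1),
      auc = auc,
      n_positive = length(pos), n_negative = length(neg),
      chosen_cutoff = NA_real_, sens_chosen = NA_real_,
      spec_chosen = NA_real_
    ),
    class = "amss_roc"
  )
  cut <- select_cutoff(out)
  out$chosen_cutoff <- cut
  if (is.finite(cut)) {
    i <- which(thresholds == cut)
    out$sens_chosen <- sens[i]
    out$spec_chosen <- spec[i]
  }
  out
}

check_scores <- function(x, what) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    stop_validation("%s must contain at least one non-missing score", what)
  }
  if (any(!is.finite(x))) stop_validation("%s must be finite", what)
  x
}

#' @rdname roc_curve
#' @export
select_cutoff <- function(roc) {
  stopifnot(inherits(roc, "amss_roc"))
  cand <- roc$curve[is.finite(roc$curve$threshold), ]
  if (nrow(cand) == 0) return(NA_real_)
  cand <- cand[order(-cand$youden_j, -cand$specificity, cand$threshold), ]
  cand$threshold[1]
}

#' @rdname roc_curve
#' @export
confusion_metrics <- function(scores_positive, scores_negative, cutoff) {
  pos <- check_scores(scores_positive, "scores_positive")
  neg <- check_scores(scores_negative, "scores_negative")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff)) {
    stop_validation("cutoff must be a single number")
  }
  tp <- sum(pos > cutoff)
  fn <- length(pos) - tp
  tn <- sum(neg <= cutoff)
  fp <- length(neg) - tn
  tibble::tibble(
    cutoff = cutoff, tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity_pct = 100 * tp / (tp + fn),
    specificity_pct = 100 * tn / (tn + fp)
  )
}

#' @export
print.amss_roc <- function(x, ...) {
  cat(sprintf(
    "ROC analysis: %d positive vs %d negative scores\n", x$n_positive,
    x$n_negative))
  cat(sprintf("  AUC (trapezoid = concordance): %.4f\n", x$auc))
  if (is.finite(x$chosen_cutoff)) {
    cat(sprintf(
      "  cutoff %.4g (max Youden J): sensitivity %.1f%%, specificity %.1f%%\n",
      x$chosen_cutoff, 100 * x$sens_chosen, 100 * x$spec_chosen))
  } else {
    cat("  no finite cutoff (all scores tied)\n")
  }
  invisible(x)
}

#' @export
tidy.amss_roc <- function(x, ...) {
  x$curve
}

#' @export
glance.amss_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, cutoff = x$chosen_cutoff,
    sensitivity_pct = 100 * x$sens_chosen,
    specificity_pct = 100 * x$spec_chosen,
    n_positive = x$n_positive, n_negative = x$n_negative
  )
}

#' Plot an ROC curve
#'
#' @param object An `amss_roc` object.
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity with the chosen
#'   operating point marked.
#' @export
autoplot.amss_roc <- function(object, ...) {
  d <- object$curve
  d <- d[order(1 - d$specificity, d$sensitivity), ]
  chosen <- object$curve[
    is.finite(object$curve$threshold) &
      object$curve$threshold == object$chosen_cutoff, ]
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity,
                                  y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = chosen, colour = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc),
      subtitle = if (is.finite(object$chosen_cutoff)) {
        sprintf("cutoff %.4g: sens %.1f%%, spec %.1f%%",
                object$chosen_cutoff, 100 * object$sens_chosen,
                100 * object$spec_chosen)
      } else NULL
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
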