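#' End-to-end diagnostic validation of the A-MSS on a cohort
#'
#' Reproduces the score-validation workflow on any cohort with both study
#' arms: (i) ROC analysis of the A-MSS total at an early timepoint
#' (default 4 h) against group membership, with Youden-index cutoff
#' selection and sensitivity/specificity at the operating point; (ii) the
#' correlation panel — the early A-MSS against the late (default 24 h)
#' hematological severity markers (lymphocyte, white-cell, and platelet
#' counts, NLR, PLR, MPV/PC), and both score totals at the late timepoint
#' against glycemia, rectal temperature, and body weight measured then;
#' and (iii) a two-way factorial ANOVA (treatment by time) of the A-MSS
#' total with Bonferroni post-tests per timepoint.
#'
#' @param data A cohort tibble (see [cohort_cols()]).
#' @param score_time_h Timepoint (hours) at which the diagnostic score is
#'   evaluated. Default 4.
#' @param outcome_time_h Timepoint whose physiology and hematology serve
#'   as severity outcomes. Default 24.
#' @param cutoff Optional fixed diagnostic cutoff; by default the
#'   ROC-selected (max Youden J) cutoff is used.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @return An `amss_validation` object: a list with `roc` ([roc_curve()]
#'   result), `cutoff`, `metrics` (confusion tibble), `classification`
#'   (per-mouse calls at `score_time_h`), `correlations` (one row per
#'   score/variable pair), and `anova` ([two_way_anova()] of the A-MSS
#'   total). `tidy()` returns the correlation table, `glance()` the
#'   headline ROC numbers.
#' @examples
#' v <- validate_score(generate_cohort(default_config(seed = 1)))
#' glance(v)
#' @export
validate_score <- function(data, score_time_h = 4, outcome_time_h = 24,
                           cutoff = NULL,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  data <- validate_cohort(data)
  scores <- score_cohort(data)
  for (t in unique(c(score_time_h, outcome_time_h))) {
    if (!any(scores$time_h == t)) {
      stop_validation("cohort has no observations at %g h", t)
    }
  }
  at_score <- scores[scores$time_h == score_time_h &
                       !is.na(scores$amss_total), ]
  pos <- at_score$amss_total[at_score$group == "sepsis"]
  neg <- at_score$amss_total[at_score$group == "control"]
  if (length(pos) == 0 || length(neg) == 0) {
    stop_validation(
      "both groups need a complete A-MSS at %g h (control %d, sepsis %d)",
      score_time_h, length(neg), length(pos))
  }
  roc <- roc_curve(pos, neg)
  cutoff <- cutoff %||% roc$chosen_cutoff
  metrics <- confusion_metrics(pos, neg, cutoff)
  classification <- dplyr::transmute(
    at_score, .data$mouse_id, .data$group, .data$time_h, .data$amss_total,
    call = classify(.data$amss_total, cutoff))

  correlations <- dplyr::bind_rows(
    correlate_scores_vs_hematology(data, scores, score_time_h,
                                   outcome_time_h, method),
    correlate_scores_vs_physiology(scores, data, outcome_time_h, method)
  )

  anova <- tryCatch(
    two_way_anova(scores$amss_total, scores$group, scores$time_h),
    error = function(e) NULL
  )

  structure(
    list(score_time_h = score_time_h, outcome_time_h = outcome_time_h,
         roc = roc, cutoff = cutoff, metrics = metrics,
         classification = classification, correlations = correlations,
         anova = anova),
    class = "amss_validation"
  )
}

safe_correlate <- function(x, y, method) {
  tryCatch(correlate(x, y, method = method), error = function(e) NULL)
}

correlate_scores_vs_hematology <- function(data, scores, score_time_h,
                                           outcome_time_h, method) {
  idx <- index_timecourse(data)
  late <- idx[idx$time_h == outcome_time_h, ]
  if (nrow(late) == 0) return(empty_correlation_table())
  early <- scores[scores$time_h == score_time_h,
                  c("mouse_id", "amss_total")]
  joined <- dplyr::inner_join(early, late, by = "mouse_id")
  vars <- c(lymphocytes = "lymph_10e3_ul", wbc = "wbc_10e3_ul",
            platelets = "plt_10e3_ul", nlr = "nlr", plr = "plr",
            mpv_pc = "mpv_pc")
  purrr::map_dfr(names(vars), function(v) {
    res <- safe_correlate(joined$amss_total, joined[[vars[[v]]]], method)
    if (is.null(res)) return(empty_correlation_table())
    dplyr::bind_cols(
      tibble::tibble(score = "amss_total", score_time_h = score_time_h,
                     variable = v, variable_time_h = outcome_time_h),
      res)
  })
}

correlate_scores_vs_physiology <- function(scores, data, outcome_time_h,
                                           method) {
  late_raw <- relative_weight_loss(data)
  late_raw <- late_raw[late_raw$time_h == outcome_time_h, ]
  late_sc <- scores[scores$time_h == outcome_time_h, ]
  joined <- dplyr::inner_join(
    late_sc[c("mouse_id", "mss_subtotal", "amss_total")],
    late_raw[c("mouse_id", "glycemia_mgdl", "temp_c", "weight_g",
               "weight_loss_pct")],
    by = "mouse_id")
  vars <- c(glycemia = "glycemia_mgdl", temperature = "temp_c",
            weight = "weight_g", weight_loss = "weight_loss_pct")
  purrr::map_dfr(c("mss_subtotal", "amss_total"), function(sc) {
    purrr::map_dfr(names(vars), function(v) {
      res <- safe_correlate(joined[[sc]], joined[[vars[[v]]]], method)
      if (is.null(res)) return(empty_correlation_table())
      dplyr::bind_cols(
        tibble::tibble(score = sc, score_time_h = outcome_time_h,
                       variable = v, variable_time_h = outcome_time_h),
        res)
    })
  })
}

empty_correlation_table <- function() {
  tibble::tibble(score = character(0), score_time_h = numeric(0),
                 variable = character(0), variable_time_h = numeric(0),
                 r = numeric(0), n = integer(0), method = character(0),
                 statistic = numeric(0), p = numeric(0))
}

#' @export
print.amss_validation <- function(x, ...) {
  cat(sprintf("A-MSS validation: score at %g h, outcomes at %g h\n",
              x$score_time_h, x$outcome_time_h))
  print(x$roc)
  cat(sprintf("  operating cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, x$metrics$sensitivity_pct,
              x$metrics$specificity_pct))
  if (nrow(x$correlations) > 0) {
    cat(sprintf("  %d correlations computed; strongest |r| = %.2f (%s vs %s)\n",
                nrow(x$correlations),
                max(abs(x$correlations$r)),
                x$correlations$score[which.max(abs(x$correlations$r))],
                x$correlations$variable[which.max(abs(x$correlations$r))]))
  }
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}

#' @export
tidy.amss_validation <- function(x, ...) {
  x$correlations
}

#' @export
glance.amss_validation <- function(x, ...) {
  tibble::tibble(
    auc = x$roc$auc, cutoff = x$cutoff,
    sensitivity_pct = x$metrics$sensitivity_pct,
    specificity_pct = x$metrics$specificity_pct,
    n_positive = x$roc$n_positive, n_negative = x$roc$n_negative
  )
}

#' Serialise a validation report to JSON
#'
#' Writes the machine-readable form of an [validate_score()] report:
#' ROC sweep and AUC, cutoff and confusion metrics, per-mouse calls,
#' the correlation table, and the ANOVA tables. The output is stable
#' across reruns on identical input (no timestamps).
#'
#' @param x An `amss_validation` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(x, path) {
  stopifnot(inherits(x, "amss_validation"))
  payload <- list(
    score_time_h = x$score_time_h,
    outcome_time_h = x$outcome_time_h,
    roc = list(auc = x$roc$auc, curve = x$roc$curve,
               n_positive = x$roc$n_positive,
               n_negative = x$roc$n_negative),
    cutoff = x$cutoff,
    metrics = x$metrics,
    classification = x$classification,
    correlations = x$correlations,
    anova = if (is.null(x$anova)) NULL else list(
      effects = x$anova$effects, residual = x$anova$residual,
      posttests = x$anova$posttests)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
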