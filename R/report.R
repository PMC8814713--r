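#' Group summaries and full cohort report
#'
#' `summarise_cohort()` computes the per-group, per-timepoint mean, SD,
#' and n of every measured variable, the two score totals, and (when
#' hematology is present) the derived indices — the tabular form of the
#' usual time-course panels. `cohort_report()` bundles those summaries
#' with per-variable two-way ANOVA tables and, when both arms allow it,
#' the diagnostic validation of [validate_score()].
#'
#' @param data A cohort tibble.
#' @param score_time_h,outcome_time_h Passed to [validate_score()].
#' @param cutoff Optional fixed diagnostic cutoff.
#' @return `summarise_cohort()` returns a long tibble with columns
#'   `variable`, `group`, `time_h`, `mean`, `sd`, `n`. `cohort_report()`
#'   returns an `amss_report` list with elements `summaries`, `anova`
#'   (named list of effect tables), `validation` (an `amss_validation` or
#'   `NULL`), and `hematology_present`.
#' @examples
#' rep <- cohort_report(generate_cohort(default_config(seed = 1)))
#' rep$summaries
#' @export
summarise_cohort <- function(data) {
  data <- validate_cohort(data)
  scores <- score_cohort(data)
  idx <- index_timecourse(data)
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(
      data[c("group", "time_h", "weight_g", "temp_c", "glycemia_mgdl",
             hematology_cols())],
      cols = -c("group", "time_h"), names_to = "variable"),
    tidyr::pivot_longer(
      scores[c("group", "time_h", "mss_subtotal", "amss_total")],
      cols = -c("group", "time_h"), names_to = "variable",
      values_transform = as.numeric),
    if (nrow(idx) > 0) {
      tidyr::pivot_longer(
        idx[c("group", "time_h", "nlr", "plr", "mpv_pc",
              "plt_relative_pct")],
        cols = -c("group", "time_h"), names_to = "variable")
    }
  )
  long |>
    dplyr::group_by(.data$variable, .data$group, .data$time_h) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean = ifelse(is.nan(.data$mean), NA_real_, .data$mean))
}

#' @rdname summarise_cohort
#' @export
cohort_report <- function(data, score_time_h = 4, outcome_time_h = 24,
                          cutoff = NULL) {
  data <- validate_cohort(data)
  scores <- score_cohort(data)
  idx <- index_timecourse(data)
  heme_present <- nrow(idx) > 0

  anova_safe <- function(v, d) {
    tryCatch(
      two_way_anova(v, d$group, d$time_h)$effects,
      error = function(e) NULL
    )
  }
  anova_tables <- purrr::compact(c(
    list(
      amss_total = anova_safe(scores$amss_total, scores),
      mss_subtotal = anova_safe(scores$mss_subtotal, scores),
      glycemia_mgdl = anova_safe(data$glycemia_mgdl, data),
      temp_c = anova_safe(data$temp_c, data),
      weight_g = anova_safe(data$weight_g, data)
    ),
    if (heme_present) list(
      plt_10e3_ul = anova_safe(idx$plt_10e3_ul, idx),
      nlr = anova_safe(idx$nlr, idx),
      plr = anova_safe(idx$plr, idx),
      mpv_pc = anova_safe(idx$mpv_pc, idx)
    )
  ))
  validation <- tryCatch(
    validate_score(data, score_time_h = score_time_h,
                   outcome_time_h = outcome_time_h, cutoff = cutoff),
    error = function(e) NULL
  )
  structure(
    list(summaries = summarise_cohort(data), anova = anova_tables,
         validation = validation, hematology_present = heme_present),
    class = "amss_report"
  )
}

#' @export
print.amss_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d variables summarised, hematology %s\n",
              dplyr::n_distinct(x$summaries$variable),
              if (x$hematology_present) "present" else "absent"))
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

#' Write a cohort report as JSON
#'
#' The JSON carries the group summaries, ANOVA tables, and validation
#' results; absent sections (for example hematology in a cohort without
#' blood counts) are marked absent rather than dropped. Output is stable
#' across reruns on identical input.
#'
#' @param x An `amss_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  stopifnot(inherits(x, "amss_report"))
  v <- x$validation
  payload <- list(
    summaries = x$summaries,
    anova = x$anova,
    hematology = list(present = x$hematology_present),
    validation = if (is.null(v)) list(available = FALSE) else list(
      available = TRUE,
      auc = v$roc$auc, cutoff = v$cutoff, metrics = v$metrics,
      correlations = v$correlations,
      classification = v$classification
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Time-course plot of a cohort variable
#'
#' Group mean with an SD ribbon over the monitoring grid, the standard
#' presentation of these longitudinal panels.
#'
#' @param data A cohort tibble.
#' @param variable One of the variables summarised by
#'   [summarise_cohort()], e.g. `"glycemia_mgdl"` or `"amss_total"`.
#' @return A ggplot.
#' @examples
#' plot_timecourse(generate_cohort(default_config(seed = 1)), "temp_c")
#' @export
plot_timecourse <- function(data, variable = "amss_total") {
  s <- summarise_cohort(data)
  s <- s[s$variable == variable, ]
  if (nrow(s) == 0) {
    stop_validation("no data for variable '%s'", variable)
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_h, y = .data$mean,
                                  colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time after induction (h)", y = variable,
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}
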