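#' The ten-item A-MSS rubric
#'
#' Returns the full scoring rubric as a tibble: one row per item, one
#' column per score level 0-4, with the descriptor a rater uses to assign
#' that level. The first seven items are the observational Murine Sepsis
#' Score; the last three bin rectal temperature, glycemia, and relative
#' body-weight loss onto the same 0-4 scale, making the A-MSS total 0-40.
#'
#' `export_rubric()` writes the same table as a Markdown reference sheet
#' suitable for printing and use at the cage side.
#'
#' @param path File to write the Markdown rubric to.
#' @return `amss_rubric()` returns a 10-row tibble with columns `item`,
#'   `score_0` ... `score_4`; `export_rubric()` returns `path` invisibly.
#' @examples
#' amss_rubric()
#' @export
amss_rubric <- function() {
  tibble::tribble(
    ~item, ~score_0, ~score_1, ~score_2, ~score_3, ~score_4,
    "appearance",
    "Coat is smooth",
    "Patches of hair piloerected",
    "Majority of back is piloerected",
    "Piloerection may or may not be present; mouse appears “puffy”",
    "Piloerection may or may not be present; mouse appears emaciated",
    "consciousness",
    "Mouse is active",
    "Mouse is active but avoids standing upright",
    "Mouse activity is noticeably slowed. The mouse is still ambulant",
    paste("Activity is impaired. Mouse only moves when provoked;",
          "movements have a tremor"),
    paste("Activity severely impaired. Remains stationary when provoked,",
          "with possible tremor"),
    "activity",
    paste("Normal amount of activity. Mouse is any of eating, drinking,",
          "climbing, running, and fighting"),
    "Slightly suppressed activity. Mouse is moving around bottom of cage",
    paste("Suppressed activity. Mouse is stationary with occasional",
          "investigative movements"),
    "No activity",
    "No activity. Mouse experiencing tremors, particularly in the hind legs",
    "stimulus",
    "Mouse responds immediately to auditory stimulus or touch",
    paste("Slow or no response to auditory stimulus; strong response to",
          "touch (moves to escape)"),
    paste("No response to auditory stimulus; moderate response to touch",
          "(moves a few steps)"),
    paste("No response to auditory stimulus; mild response to touch",
          "(no locomotion)"),
    paste("No response to auditory stimulus. Little or no response to",
          "touch. Cannot right itself if pushed over"),
    "eyes",
    "Open",
    "Eyes not fully open, possibly with secretions",
    "Eyes at least half closed, possibly with secretions",
    "Eyes half closed or more, possibly with secretions",
    "Eyes closed or milky",
    "resp_rate",
    "Normal, rapid mouse respiration",
    "Slightly decreased respiration (rate not quantifiable by the eye)",
    paste("Moderately reduced respiration (rate at the upper range of",
          "quantifying by the eye)"),
    paste("Severely reduced respiration (rate easily countable by the eye,",
          "0.5 s between breaths)"),
    "Extremely reduced respiration (>1 s between breaths)",
    "resp_quality",
    "Normal",
    "Brief periods of laboured breathing",
    "Laboured, no gasping",
    "Laboured with intermittent gasps",
    "Gasping",
    "temperature",
    "36-38 °C", "> 38 °C", "< 36 and ≥ 35 °C",
    "< 35 and ≥ 34 °C", "< 34 °C",
    "glycemia",
    "≥ 148 mg/dL", "< 148 and ≥ 122 mg/dL",
    "< 122 and ≥ 58 mg/dL", "< 58 and > 40 mg/dL", "≤ 40 mg/dL",
    "weight_loss",
    "≤ 5 %", "> 5 and ≤ 10 %", "> 10 and ≤ 15 %",
    "> 15 and ≤ 20 %", "> 20 %"
  )
}

#' @rdname amss_rubric
#' @export
export_rubric <- function(path) {
  r <- amss_rubric()
  esc <- function(x) gsub("|", "\\|", x, fixed = TRUE)
  lines <- c(
    "# Adapted Murine Sepsis Score (A-MSS) rubric",
    "",
    paste("Ten items, each scored 0-4. The seven observational items sum",
          "to the MSS subtotal (0-28); adding the three quantitative items",
          "gives the A-MSS total (0-40)."),
    "",
    "| Item | 0 | 1 | 2 | 3 | 4 |",
    "| --- | --- | --- | --- | --- | --- |",
    sprintf("| %s | %s | %s | %s | %s | %s |",
            esc(r$item), esc(r$score_0), esc(r$score_1), esc(r$score_2),
            esc(r$score_3), esc(r$score_4))
  )
  writeLines(lines, path)
  invisible(path)
}
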