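#' Derived hematological severity indices
#'
#' Computes, elementwise over vectors of counts, the derived indices used
#' as sepsis severity biomarkers:
#'
#' * `nlr` — neutrophil-to-lymphocyte ratio, `neut / lymph`;
#' * `plr` — platelet-to-lymphocyte ratio, `plt / lymph`;
#' * `mpv_pc` — mean platelet volume to platelet count ratio,
#'   `mpv / plt` (fL per 10^3 cells/uL), a microthrombosis-risk marker;
#' * `plt_relative_pct` — platelet count as a percent of the animal's
#'   baseline count, `100 * plt / baseline_plt`.
#'
#' An index is `NA` whenever an input is missing or its denominator is
#' zero; a zero denominator additionally sets the corresponding
#' `undefined_*` flag so it can be distinguished from plain missingness.
#' Negative counts are rejected.
#'
#' @param neut,lymph,plt Counts in 10^3 cells/uL.
#' @param mpv Mean platelet volume in fL.
#' @param baseline_plt The animal's baseline platelet count.
#' @return A tibble with columns `nlr`, `plr`, `mpv_pc`,
#'   `plt_relative_pct`, and logical flags `undefined_nlr`,
#'   `undefined_plr`, `undefined_mpv_pc`, `undefined_plt_relative`.
#' @examples
#' derive_indices(neut = 2, lymph = 1, plt = 400, mpv = 6,
#'                baseline_plt = 400)
#' @export
derive_indices <- function(neut = NA_real_, lymph = NA_real_,
                           plt = NA_real_, mpv = NA_real_,
                           baseline_plt = NA_real_) {
  args <- vctrs::vec_recycle_common(
    neut = as.numeric(neut), lymph = as.numeric(lymph),
    plt = as.numeric(plt), mpv = as.numeric(mpv),
    baseline_plt = as.numeric(baseline_plt)
  )
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      stop_validation("%s must be finite and >= 0 where present", nm)
    }
  }
  ratio <- function(num, den) {
    out <- num / den
    zero <- !is.na(den) & den == 0
    out[zero] <- NA_real_
    list(value = out, undefined = zero & !is.na(num))
  }
  r_nlr <- ratio(args$neut, args$lymph)
  r_plr <- ratio(args$plt, args$lymph)
  r_mpv <- ratio(args$mpv, args$plt)
  r_rel <- ratio(100 * args$plt, args$baseline_plt)
  tibble::tibble(
    nlr = r_nlr$value, plr = r_plr$value, mpv_pc = r_mpv$value,
    plt_relative_pct = r_rel$value,
    undefined_nlr = r_nlr$undefined, undefined_plr = r_plr$undefined,
    undefined_mpv_pc = r_mpv$undefined,
    undefined_plt_relative = r_rel$undefined
  )
}

#' Hematological index time-course for a cohort
#'
#' Computes the derived indices of [derive_indices()] for every
#' observation that carries any hematology, resolving each animal's
#' baseline platelet count from its earliest observation.
#'
#' @param data A cohort tibble (see [cohort_cols()]).
#' @return A tibble with one row per observation that has at least one
#'   hematology value: identifying columns, the raw counts, and the
#'   derived indices. Rows with no hematology at all are dropped, so a
#'   cohort without hematology yields an empty table.
#' @examples
#' idx <- index_timecourse(generate_cohort(default_config(seed = 1)))
#' dplyr::summarise(dplyr::group_by(idx, group, time_h), nlr = mean(nlr))
#' @export
index_timecourse <- function(data) {
  data <- validate_cohort(data)
  has_heme <- rowSums(!is.na(data[hematology_cols()])) > 0
  base <- data |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(
      baseline_plt_10e3_ul = .data$plt_10e3_ul[which.min(.data$time_h)]
    ) |>
    dplyr::ungroup()
  base <- base[has_heme, ]
  dplyr::bind_cols(
    base[c("mouse_id", "group", "time_h", hematology_cols(),
           "baseline_plt_10e3_ul")],
    derive_indices(
      neut = base$neut_10e3_ul, lymph = base$lymph_10e3_ul,
      plt = base$plt_10e3_ul, mpv = base$mpv_fl,
      baseline_plt = base$baseline_plt_10e3_ul
    )
  )
}
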