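#' Cohort table schema
#'
#' A cohort is an ordinary tibble with one row per animal and timepoint.
#' `cohort_cols()` returns the canonical column names; `empty_cohort()`
#' returns a zero-row cohort with the full schema, useful as a template.
#'
#' The columns are:
#' \describe{
#'   \item{mouse_id}{character animal identifier, unique within the study.}
#'   \item{group}{`"control"` or `"sepsis"` (case-insensitive on input).}
#'   \item{time_h}{hours since induction; non-negative. The study grid is
#'     0/4/12/24 h but arbitrary times are accepted.}
#'   \item{weight_g, temp_c, glycemia_mgdl}{body weight (g), rectal
#'     temperature (deg C, physiological range 20-45), blood glucose (mg/dL).}
#'   \item{item_appearance, item_consciousness, item_activity, item_stimulus,
#'     item_eyes, item_resp_rate, item_resp_quality}{the seven rater-assigned
#'     observational MSS items, each an integer 0-4.}
#'   \item{wbc_10e3_ul, neut_10e3_ul, lymph_10e3_ul, mono_10e3_ul,
#'     plt_10e3_ul}{blood counts in 10^3 cells/uL.}
#'   \item{mpv_fl}{mean platelet volume in fL.}
#' }
#' Any cell may be missing (`NA`); missing inputs propagate as undefined
#' scores, never as zeros.
#'
#' @return A character vector of column names, or a zero-row tibble.
#' @examples
#' cohort_cols()
#' empty_cohort()
#' @export
cohort_cols <- function() {
  c("mouse_id", "group", "time_h", "weight_g", "temp_c", "glycemia_mgdl",
    amss_item_cols(), hematology_cols())
}

#' @rdname cohort_cols
#' @export
empty_cohort <- function() {
  tpl <- c(mouse_id = "character", group = "character")
  out <- tibble::as_tibble(c(
    lapply(tpl, function(t) character(0)),
    lapply(setNames(nm = setdiff(cohort_cols(), names(tpl))),
           function(nm) numeric(0))
  ))
  out[amss_item_cols()] <- lapply(out[amss_item_cols()], as.integer)
  out
}

#' @rdname cohort_cols
#' @export
amss_item_cols <- function() {
  c("item_appearance", "item_consciousness", "item_activity",
    "item_stimulus", "item_eyes", "item_resp_rate", "item_resp_quality")
}

#' @rdname cohort_cols
#' @export
hematology_cols <- function() {
  c("wbc_10e3_ul", "neut_10e3_ul", "lymph_10e3_ul", "mono_10e3_ul",
    "plt_10e3_ul", "mpv_fl")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "amss_validation_error")
}

stop_parse <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "amss_parse_error")
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a longitudinal sepsis-monitoring
#' cohort: schema, group labels, non-negative unique timepoints per animal,
#' observational items integer in 0-4, physiological ranges, and
#' non-negative blood counts with the differential not exceeding the total
#' white count.
#'
#' @param data A cohort tibble (see [cohort_cols()]). Group labels are
#'   matched case-insensitively; hematology columns may be absent entirely.
#' @return The validated cohort, invisibly, with `group` normalised to
#'   lower case and missing hematology columns added as `NA`.
#' @examples
#' validate_cohort(generate_cohort(default_config(seed = 1)))
#' @export
validate_cohort <- function(data) {
  if (!is.data.frame(data)) {
    stop_validation("a cohort must be a data frame, not a %s", class(data)[1])
  }
  data <- tibble::as_tibble(data)
  required <- setdiff(cohort_cols(), hematology_cols())
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_validation("cohort is missing required column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  for (h in setdiff(hematology_cols(), names(data))) data[[h]] <- NA_real_
  data <- data[union(cohort_cols(), names(data))]

  data$mouse_id <- as.character(data$mouse_id)
  if (anyNA(data$mouse_id) || any(data$mouse_id == "")) {
    stop_validation("mouse_id must be present in every row")
  }
  data$group <- tolower(as.character(data$group))
  bad_group <- setdiff(unique(data$group), c("control", "sepsis"))
  if (length(bad_group) > 0 || anyNA(data$group)) {
    stop_validation("group must be 'control' or 'sepsis'; found: %s",
                    paste(bad_group, collapse = ", "))
  }
  one_group <- dplyr::summarise(dplyr::group_by(data, .data$mouse_id),
                                n_groups = dplyr::n_distinct(.data$group))
  if (any(one_group$n_groups > 1)) {
    stop_validation("mouse assigned to more than one group: %s",
                    paste(one_group$mouse_id[one_group$n_groups > 1],
                          collapse = ", "))
  }
  if (anyNA(data$time_h) || any(!is.finite(data$time_h)) ||
      any(data$time_h < 0)) {
    stop_validation("time_h must be finite and >= 0 in every row")
  }
  dup <- duplicated(data[c("mouse_id", "time_h")])
  if (any(dup)) {
    d <- data[dup, ]
    stop_validation("duplicate (mouse_id, time_h): %s",
                    paste(sprintf("%s@%gh", d$mouse_id, d$time_h),
                          collapse = ", "))
  }
  for (it in amss_item_cols()) {
    v <- data[[it]]
    ok <- is.na(v) | (is.finite(v) & v >= 0 & v <= 4 & v == round(v))
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop_validation(
        "%s must be an integer in 0-4: mouse %s at %g h has value %s",
        it, data$mouse_id[bad], data$time_h[bad], format(v[bad]))
    }
    data[[it]] <- as.integer(v)
  }
  check_range <- function(col, lo, hi, what) {
    v <- data[[col]]
    ok <- is.na(v) | (is.finite(v) & v > lo - 1e-12 & v <= hi)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop_validation("%s out of range (%s): mouse %s at %g h has %s",
                      col, what, data$mouse_id[bad], data$time_h[bad],
                      format(v[bad]))
    }
  }
  if (any(!is.na(data$weight_g) & data$weight_g <= 0)) {
    stop_validation("weight_g must be positive where present")
  }
  check_range("temp_c", 20, 45, "20-45 deg C")
  if (any(!is.na(data$glycemia_mgdl) & data$glycemia_mgdl <= 0)) {
    stop_validation("glycemia_mgdl must be positive where present")
  }
  for (h in hematology_cols()) {
    if (any(!is.na(data[[h]]) & (!is.finite(data[[h]]) | data[[h]] < 0))) {
      stop_validation("%s must be finite and >= 0 where present", h)
    }
  }
  full <- !is.na(data$wbc_10e3_ul) & !is.na(data$neut_10e3_ul) &
    !is.na(data$lymph_10e3_ul) & !is.na(data$mono_10e3_ul)
  diff_sum <- data$neut_10e3_ul + data$lymph_10e3_ul + data$mono_10e3_ul
  over <- full & diff_sum > data$wbc_10e3_ul * (1 + 1e-6) + 1e-9
  if (any(over)) {
    bad <- which(over)[1]
    stop_validation(
      "differential exceeds total white count: mouse %s at %g h (%g > %g)",
      data$mouse_id[bad], data$time_h[bad], diff_sum[bad],
      data$wbc_10e3_ul[bad])
  }
  invisible(data)
}

#' Read and write cohort CSV files
#'
#' `read_cohort_csv()` reads a monitoring CSV in the standard schema (see
#' [cohort_cols()]), validates it, and returns a cohort tibble. Unknown
#' columns are ignored; empty cells become `NA`. `write_cohort_csv()` writes
#' a cohort back out; the two functions are exact inverses on valid cohorts
#' (missing values round-trip as empty cells, never as zeros).
#'
#' @param path Path to a CSV file.
#' @param data A cohort tibble.
#' @return `read_cohort_csv()` returns a validated cohort tibble;
#'   `write_cohort_csv()` returns `data` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort_csv(generate_cohort(default_config(seed = 1)), f)
#' nrow(read_cohort_csv(f))
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  numeric_cols <- setdiff(cohort_cols(), c("mouse_id", "group"))
  spec <- do.call(readr::cols, c(
    list(mouse_id = readr::col_character(),
         group = readr::col_character(),
         .default = readr::col_character()),  # unknown columns tolerated
    setNames(rep(list(readr::col_double()), length(numeric_cols)),
             numeric_cols)
  ))
  data <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE,
                    show_col_types = FALSE, name_repair = "minimal")
  )
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    nm <- names(data)[p$col]
    stop_parse("malformed cell in %s: row %d, column %s (%s)",
               path, p$row, if (length(nm)) nm else as.character(p$col),
               p$expected)
  }
  if (nrow(data) == 0 && ncol(data) == 0) {
    stop_parse("empty file (no header): %s", path)
  }
  keep <- intersect(names(data), cohort_cols())
  missing_cols <- setdiff(setdiff(cohort_cols(), hematology_cols()), keep)
  if (length(missing_cols) > 0) {
    stop_parse("%s is missing required column(s): %s", path,
               paste(missing_cols, collapse = ", "))
  }
  validate_cohort(data[keep])
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(data, path) {
  data <- validate_cohort(data)
  readr::write_csv(data, path, na = "")
  invisible(data)
}

#' Relative body-weight loss from baseline
#'
#' Adds a `weight_loss_pct` column: the percent decrease of each animal's
#' weight from its baseline (its earliest observation), the quantity binned
#' by the tenth A-MSS item. Negative values mean weight gain. The value is
#' `NA` wherever the baseline weight or the current weight is missing.
#'
#' @param data A cohort tibble.
#' @return The cohort with `baseline_weight_g` and `weight_loss_pct`
#'   columns appended.
#' @examples
#' cohort <- generate_cohort(default_config(seed = 1))
#' dplyr::select(relative_weight_loss(cohort), mouse_id, time_h,
#'               weight_g, weight_loss_pct)
#' @export
relative_weight_loss <- function(data) {
  data <- validate_cohort(data)
  data |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(
      baseline_weight_g = .data$weight_g[which.min(.data$time_h)],
      weight_loss_pct = 100 * (.data$baseline_weight_g - .data$weight_g) /
        .data$baseline_weight_g
    ) |>
    dplyr::ungroup()
}
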