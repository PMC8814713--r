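# Random cohort builder independent of the package generator, used for
# round-trip and schema property tests. Sprinkles missing values unless
# na_rate = 0.
random_cohort <- function(n_control = 3, n_sepsis = 3,
                          times = c(0, 4, 12, 24), na_rate = 0.1) {
  ids <- c(sprintf("c%d", seq_len(n_control)),
           sprintf("s%d", seq_len(n_sepsis)))
  groups <- rep(c("control", "sepsis"), c(n_control, n_sepsis))
  rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(
      mouse_id = ids[i], group = groups[i], time_h = times,
      weight_g = runif(length(times), 18, 30),
      temp_c = runif(length(times), 30, 39),
      glycemia_mgdl = runif(length(times), 30, 250),
      item_appearance = sample(0:4, length(times), TRUE),
      item_consciousness = sample(0:4, length(times), TRUE),
      item_activity = sample(0:4, length(times), TRUE),
      item_stimulus = sample(0:4, length(times), TRUE),
      item_eyes = sample(0:4, length(times), TRUE),
      item_resp_rate = sample(0:4, length(times), TRUE),
      item_resp_quality = sample(0:4, length(times), TRUE),
      neut_10e3_ul = runif(length(times), 0.5, 8),
      lymph_10e3_ul = runif(length(times), 0.5, 8),
      mono_10e3_ul = runif(length(times), 0.05, 1),
      plt_10e3_ul = runif(length(times), 100, 1200),
      mpv_fl = runif(length(times), 4, 10)
    )
  }))
  rows$wbc_10e3_ul <- rows$neut_10e3_ul + rows$lymph_10e3_ul +
    rows$mono_10e3_ul + runif(nrow(rows), 0, 0.5)
  rows <- rows[c("mouse_id", "group", "time_h", "weight_g", "temp_c",
                 "glycemia_mgdl", amss::amss_item_cols(),
                 "wbc_10e3_ul", "neut_10e3_ul", "lymph_10e3_ul",
                 "mono_10e3_ul", "plt_10e3_ul", "mpv_fl")]
  if (na_rate > 0) {
    for (col in setdiff(names(rows), c("mouse_id", "group", "time_h",
                                       "wbc_10e3_ul"))) {
      hit <- runif(nrow(rows)) < na_rate
      rows[[col]][hit] <- NA
    }
  }
  tibble::as_tibble(rows)
}

# One fully specified observation row, overridable field by field.
one_obs <- function(...) {
  base <- tibble::tibble(
    mouse_id = "m1", group = "sepsis", time_h = 0, weight_g = 25,
    temp_c = 37, glycemia_mgdl = 150,
    item_appearance = 0L, item_consciousness = 0L, item_activity = 0L,
    item_stimulus = 0L, item_eyes = 0L, item_resp_rate = 0L,
    item_resp_quality = 0L,
    wbc_10e3_ul = NA_real_, neut_10e3_ul = NA_real_,
    lymph_10e3_ul = NA_real_, mono_10e3_ul = NA_real_,
    plt_10e3_ul = NA_real_, mpv_fl = NA_real_
  )
  dplyr::mutate(base, ...)
}

# All-pairs Mann-Whitney concordance with ties counted one half: the
# independent oracle for the trapezoidal AUC.
concordance_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}
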