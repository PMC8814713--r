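test_that("temperature bands match the rubric, including the boundaries", {
  expect_equal(score_temperature(37.0), 0L)
  expect_equal(score_temperature(33.9), 4L)
  # band edges: > 38 is strict, 36 and 38 belong to band 0; bands 2-4
  # are right-closed at 36/35/34
  expect_equal(score_temperature(c(38, 38.001, 36, 35.999, 35, 34.999,
                                   34, 33.999)),
               c(0L, 1L, 0L, 2L, 2L, 3L, 3L, 4L))
})

test_that("glycemia bands match the rubric; the 148 overlap scores low", {
  expect_equal(score_glycemia(40.0), 4L)
  expect_equal(score_glycemia(150.0), 0L)
  expect_equal(score_glycemia(148.0), 0L)
  expect_equal(score_glycemia(c(147.999, 122, 121.999, 58, 57.999,
                                40.001, 40)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
})

test_that("weight-loss bands are left-open/right-closed; gain scores 0", {
  expect_equal(score_weight_loss(12.0), 2L)
  expect_equal(score_weight_loss(22.0), 4L)
  expect_equal(score_weight_loss(-3.0), 0L)
  expect_equal(score_weight_loss(c(5, 5.001, 10, 10.001, 15, 15.001,
                                   20, 20.001)),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L))
})

test_that("quantitative scorers are total functions on a fine grid", {
  temps <- seq(25, 42, by = 0.05)
  glys <- seq(10, 300, by = 0.5)
  losses <- seq(-10, 40, by = 0.05)
  for (s in list(score_temperature(temps), score_glycemia(glys),
                 score_weight_loss(losses))) {
    expect_false(anyNA(s))
    expect_true(all(s %in% 0:4))
  }
  # monotone where the scale is monotone
  expect_true(all(diff(score_glycemia(glys)) <= 0))
  expect_true(all(diff(score_weight_loss(losses)) >= 0))
  below38 <- temps[temps <= 38]
  expect_true(all(diff(score_temperature(below38)) <= 0))
  expect_true(all(score_temperature(temps[temps > 38]) == 1L))
})

test_that("non-finite and non-positive inputs are rejected", {
  expect_error(score_temperature(Inf), class = "amss_validation_error")
  expect_error(score_glycemia(0), class = "amss_validation_error")
  expect_error(score_weight_loss(NaN), class = "amss_validation_error")
  expect_equal(score_temperature(NA_real_), NA_integer_)
})

test_that("score_cohort assembles the ten items into the documented totals", {
  mid <- one_obs(
    time_h = 4, weight_g = 22, temp_c = 34.5, glycemia_mgdl = 50,
    item_appearance = 2L, item_consciousness = 2L, item_activity = 2L,
    item_stimulus = 2L, item_eyes = 2L, item_resp_rate = 2L,
    item_resp_quality = 2L)
  cohort <- dplyr::bind_rows(one_obs(weight_g = 25), mid)
  # baseline 25 g, 22 g at 4 h -> 12% loss -> score 2; T 34.5 -> 3; G 50 -> 3
  sc <- score_cohort(cohort)
  expect_equal(sc$amss_total[sc$time_h == 0], 0L)
  expect_true(sc$complete[sc$time_h == 0])
  row <- sc[sc$time_h == 4, ]
  expect_equal(row$mss_subtotal, 14L)
  expect_equal(row$score_temperature, 3L)
  expect_equal(row$score_glycemia, 3L)
  expect_equal(row$score_weight_loss, 2L)
  expect_equal(row$amss_total, 22L)
})

test_that("the scale attains its extremes: 0 and 40", {
  worst <- one_obs(
    time_h = 24, weight_g = 25 * 0.75, temp_c = 33, glycemia_mgdl = 35,
    item_appearance = 4L, item_consciousness = 4L, item_activity = 4L,
    item_stimulus = 4L, item_eyes = 4L, item_resp_rate = 4L,
    item_resp_quality = 4L)
  cohort <- dplyr::bind_rows(one_obs(weight_g = 25), worst)
  sc <- score_cohort(cohort)
  expect_equal(sc$amss_total[sc$time_h == 24], 40L)
})

test_that("amss_total equals the brute-force per-item sum on random complete observations", {
  withr::local_seed(42)
  n <- 250
  cohort <- tibble::tibble(
    mouse_id = sprintf("m%d", seq_len(n)), group = "sepsis", time_h = 0,
    weight_g = runif(n, 15, 35), temp_c = runif(n, 28, 41),
    glycemia_mgdl = runif(n, 20, 250),
    item_appearance = sample(0:4, n, TRUE),
    item_consciousness = sample(0:4, n, TRUE),
    item_activity = sample(0:4, n, TRUE),
    item_stimulus = sample(0:4, n, TRUE),
    item_eyes = sample(0:4, n, TRUE),
    item_resp_rate = sample(0:4, n, TRUE),
    item_resp_quality = sample(0:4, n, TRUE)
  )
  sc <- score_cohort(cohort)
  manual <- rowSums(sc[amss_item_cols()]) + sc$score_temperature +
    sc$score_glycemia + sc$score_weight_loss
  expect_true(all(sc$complete))
  expect_equal(as.integer(manual), sc$amss_total)
  expect_true(all(sc$amss_total >= 0 & sc$amss_total <= 40))
  expect_true(all(sc$mss_subtotal >= 0 & sc$mss_subtotal <= 28))
})

test_that("a missing input leaves the total undefined rather than zero-filled", {
  cohort <- dplyr::bind_rows(
    one_obs(weight_g = 25),
    one_obs(time_h = 12, glycemia_mgdl = NA_real_))
  sc <- score_cohort(cohort)
  row <- sc[sc$time_h == 12, ]
  expect_false(row$complete)
  expect_true(is.na(row$amss_total))
  expect_equal(row$mss_subtotal, 0L)  # observational subtotal still defined
})

test_that("classification is strict at the cutoff, defaulting to 3.5", {
  expect_equal(as.character(classify(4)), "septic")
  expect_equal(as.character(classify(3)), "non_septic")
  expect_equal(as.character(classify(3.5, cutoff = 3.5)), "non_septic")
  expect_error(classify(4, cutoff = Inf), class = "amss_validation_error")
})

test_that("the rubric table has ten items with five descriptors each", {
  r <- amss_rubric()
  expect_equal(nrow(r), 10)
  expect_equal(names(r), c("item", paste0("score_", 0:4)))
  expect_false(any(is.na(unlist(r))))
  f <- withr::local_tempfile(fileext = ".md")
  export_rubric(f)
  lines <- readLines(f)
  expect_length(grep("^\\|", lines), 12)  # header + separator + 10 items
})
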