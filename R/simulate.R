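#' Simulation configuration for a two-arm sepsis cohort
#'
#' Builds the generator configuration emulating a fecal-induced peritonitis
#' study: a control arm and a sepsis arm observed at 0/4/12/24 h. Defaults
#' mirror the study design (7 control, 8 sepsis animals) and the
#' qualitative sepsis dynamics: glycemia falling from the normoglycemic
#' band into severe hypoglycemia by 24 h, progressive hypothermia below
#' 34 deg C, body-weight loss beyond 15% at 24 h, platelet decline, a
#' neutrophil peak at 12 h that recedes by 24 h, and 24 h lymphopenia,
#' monocytopenia, and leukopenia. Observational items follow a shared
#' latent severity curve per animal with item-specific offsets and noise,
#' which induces the inter-item correlation the MSS assumes. A per-animal
#' severity factor (normal, mean 1, SD `severity$animal_sd`, truncated at
#' `severity$animal_min`) scales both the severity curve and every
#' physiological sepsis deviation of that animal, producing realistic
#' weak and strong responders.
#'
#' Each variable has a trajectory: a baseline distribution across animals,
#' a per-hour control drift, additive sepsis deviations anchored at the
#' 0/4/12/24 h grid (linearly interpolated for other timepoints), and a
#' residual SD. `effect_scale` multiplies every sepsis deviation and the
#' severity curve (0 gives a null cohort with no group difference);
#' `noise_scale` multiplies every SD (0 gives a noise-free, fully
#' deterministic cohort).
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   the configuration, and every variable draws from its own derived
#'   stream, so adding a variable does not perturb the others.
#' @param n_control,n_sepsis Arm sizes (default 7 and 8).
#' @param timepoints_h Strictly increasing observation times starting
#'   at 0.
#' @param effect_scale,noise_scale Non-negative multipliers, see above.
#' @param hematology If `FALSE`, blood-count columns are left missing.
#' @return An `amss_sim_config` list, accepted by [generate_cohort()].
#' @examples
#' cfg <- default_config(seed = 42)
#' generate_cohort(cfg)
#' @export
default_config <- function(seed = 1L, n_control = 7L, n_sepsis = 8L,
                           timepoints_h = c(0, 4, 12, 24),
                           effect_scale = 1, noise_scale = 1,
                           hematology = TRUE) {
  grid <- c(0, 4, 12, 24)
  traj <- function(baseline_mean, baseline_sd, sepsis_delta, residual_sd,
                   control_drift = 0, min = 0, max = Inf) {
    list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         control_drift = control_drift,
         effect_time_h = grid, effect_delta = sepsis_delta,
         residual_sd = residual_sd, min = min, max = max)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_control = as.integer(n_control),
    n_sepsis = as.integer(n_sepsis),
    timepoints_h = as.numeric(timepoints_h),
    effect_scale = effect_scale,
    noise_scale = noise_scale,
    hematology = isTRUE(hematology),
    trajectories = list(
      weight_g = traj(25, 1.2, c(0, -0.4, -2.0, -4.0), 0.25, min = 5),
      temp_c = traj(37, 0.25, c(0, -0.9, -3.0, -4.0), 0.25,
                    min = 25, max = 42),
      glycemia_mgdl = traj(160, 7, c(0, -35, -90, -125), 5, min = 15),
      neut_10e3_ul = traj(1.5, 0.25, c(0, 1.5, 4.0, 0.5), 0.2),
      lymph_10e3_ul = traj(6.0, 0.7, c(0, -1.0, -2.0, -4.5), 0.35,
                           min = 0.2),
      mono_10e3_ul = traj(0.5, 0.08, c(0, -0.05, -0.15, -0.35), 0.04,
                          min = 0.02),
      wbc_extra_10e3_ul = traj(0.4, 0.08, c(0, 0, 0, 0), 0.05),
      plt_10e3_ul = traj(1000, 80, c(0, -150, -350, -600), 50, min = 50),
      mpv_fl = traj(6.0, 0.35, c(0, 0, 0, 0), 0.25, min = 3, max = 14)
    ),
    severity = list(
      curve_time_h = grid,
      curve = c(0, 0.8, 2.6, 3.4),
      animal_sd = 0.25,  # between-animal spread of sepsis response
      animal_min = 0.3,
      item_offsets = c(
        item_appearance = 0.06, item_consciousness = -0.06,
        item_activity = 0.12, item_stimulus = -0.12, item_eyes = 0.18,
        item_resp_rate = -0.18, item_resp_quality = 0
      ),
      item_sd = 0.45
    )
  )
  validate_config(structure(cfg, class = "amss_sim_config"))
}

#' Validate a simulation configuration
#'
#' @param config An `amss_sim_config`, or a bare list in the same shape
#'   (e.g. parsed from JSON), in which case missing entries are filled
#'   from [default_config()].
#' @return The validated configuration, invisibly.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "amss_sim_config")) {
    if (!is.list(config)) {
      stop_validation("config must be a list")
    }
    base <- default_config()
    config <- structure(modifyList(unclass(base), config),
                        class = "amss_sim_config")
  }
  if (config$n_control < 1 || config$n_sepsis < 1) {
    stop_validation("both arms need at least one animal (got %d control, %d sepsis)",
                    config$n_control, config$n_sepsis)
  }
  tp <- config$timepoints_h
  if (length(tp) < 1 || tp[1] != 0 || any(diff(tp) <= 0) ||
      any(!is.finite(tp))) {
    stop_validation("timepoints_h must be strictly increasing and start at 0")
  }
  if (config$effect_scale < 0 || config$noise_scale < 0) {
    stop_validation("effect_scale and noise_scale must be >= 0")
  }
  for (nm in names(config$trajectories)) {
    tr <- config$trajectories[[nm]]
    if (tr$baseline_sd < 0 || tr$residual_sd < 0) {
      stop_validation("trajectory %s has a negative SD", nm)
    }
    if (length(tr$effect_delta) != length(tr$effect_time_h)) {
      stop_validation("trajectory %s: effect_delta and effect_time_h differ in length",
                      nm)
    }
  }
  if (config$severity$item_sd < 0 || config$severity$animal_sd < 0) {
    stop_validation("severity item_sd and animal_sd must be >= 0")
  }
  invisible(config)
}

# deterministic per-stream seeds: one master seed, split by stream name
stream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 1048573 * 2039 + h) %% 2147483647)
}

stream_rnorm <- function(seed, name, n, mean = 0, sd = 1) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, name))
  stats::rnorm(n, mean = mean, sd = sd)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# round half away from zero, then clamp to the 0-4 item scale
round_item <- function(x) {
  pmin(4L, pmax(0L, as.integer(floor(x + 0.5))))
}

interp_at <- function(time_grid, values, t) {
  if (length(values) == 1) return(rep(values, length(t)))
  stats::approx(time_grid, values, xout = t, rule = 2)$y
}

#' Generate a synthetic two-arm sepsis cohort
#'
#' Draws a longitudinal cohort from an [default_config()] configuration.
#' Control animals fluctuate around their baselines; sepsis animals follow
#' the configured deviation trajectories, and their observational items
#' track a shared latent severity curve (rounded and clamped to the 0-4
#' scale). The total white count is the sum of the generated neutrophil,
#' lymphocyte, and monocyte counts plus a small unclassified-cell
#' component, so the differential never exceeds it. Output is a standard
#' cohort tibble; identical configurations produce identical cohorts.
#'
#' @param config An `amss_sim_config` from [default_config()], or a list
#'   in the same shape.
#' @return A validated cohort tibble with
#'   `(n_control + n_sepsis) * length(timepoints_h)` rows.
#' @examples
#' cohort <- generate_cohort(default_config(seed = 7))
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(config) {
  config <- validate_config(config)
  mice <- tibble::tibble(
    mouse_id = c(sprintf("C%02d", seq_len(config$n_control)),
                 sprintf("S%02d", seq_len(config$n_sepsis))),
    group = rep(c("control", "sepsis"),
                c(config$n_control, config$n_sepsis))
  )
  tp <- config$timepoints_h
  n_t <- length(tp)
  ns <- config$noise_scale
  es <- config$effect_scale

  # shared per-animal severity of the septic response: scales every sepsis
  # deviation and the latent item severity, so a weak responder is weak in
  # physiology, hematology, and observational items alike
  sev_min <- config$severity$animal_min %||% 0.3
  severity_factor <- setNames(vapply(mice$mouse_id, function(id) {
    max(sev_min,
        stream_rnorm(config$seed, paste0(id, "/severity"), 1, 1,
                     config$severity$animal_sd * ns))
  }, numeric(1)), mice$mouse_id)

  var_values <- function(var) {
    tr <- config$trajectories[[var]]
    delta <- interp_at(tr$effect_time_h, tr$effect_delta, tp) * es
    purrr::pmap_dfr(mice, function(mouse_id, group) {
      base <- stream_rnorm(config$seed, paste0(mouse_id, "/", var, "/base"),
                           1, tr$baseline_mean, tr$baseline_sd * ns)
      eps <- stream_rnorm(config$seed, paste0(mouse_id, "/", var, "/res"),
                          n_t, 0, tr$residual_sd * ns)
      eps[tp == 0] <- 0  # baseline draw is the time-zero measurement
      val <- base + tr$control_drift * tp +
        if (group == "sepsis") delta * severity_factor[[mouse_id]] else 0
      val <- pmin(tr$max, pmax(tr$min, val + eps))
      tibble::tibble(mouse_id = mouse_id, time_h = tp, value = val)
    })
  }

  values <- lapply(setNames(nm = names(config$trajectories)), var_values)

  sev_curve <- interp_at(config$severity$curve_time_h,
                         config$severity$curve, tp) * es
  items <- purrr::pmap_dfr(mice, function(mouse_id, group) {
    sev <- if (group == "sepsis") {
      sev_curve * severity_factor[[mouse_id]]
    } else {
      rep(0, n_t)
    }
    noise <- stream_rnorm(config$seed, paste0(mouse_id, "/items"),
                          n_t * 7, 0, config$severity$item_sd * ns)
    noise <- matrix(noise, nrow = n_t, ncol = 7)
    offs <- config$severity$item_offsets[amss_item_cols()]
    m <- round_item(sweep(sev + noise, 2, offs, `+`))
    out <- tibble::as_tibble(matrix(m, nrow = n_t,
                                    dimnames = list(NULL, amss_item_cols())))
    dplyr::bind_cols(tibble::tibble(mouse_id = mouse_id, time_h = tp), out)
  })

  pull_var <- function(var) values[[var]]$value
  cohort <- tibble::tibble(
    mouse_id = values$weight_g$mouse_id,
    time_h = values$weight_g$time_h
  ) |>
    dplyr::left_join(mice, by = "mouse_id") |>
    dplyr::mutate(
      weight_g = pull_var("weight_g"),
      temp_c = pull_var("temp_c"),
      glycemia_mgdl = pull_var("glycemia_mgdl"),
      neut_10e3_ul = pull_var("neut_10e3_ul"),
      lymph_10e3_ul = pull_var("lymph_10e3_ul"),
      mono_10e3_ul = pull_var("mono_10e3_ul"),
      wbc_10e3_ul = .data$neut_10e3_ul + .data$lymph_10e3_ul +
        .data$mono_10e3_ul + pmax(0, pull_var("wbc_extra_10e3_ul")),
      plt_10e3_ul = pull_var("plt_10e3_ul"),
      mpv_fl = pull_var("mpv_fl")
    ) |>
    dplyr::left_join(items, by = c("mouse_id", "time_h"))

  if (!config$hematology) {
    cohort[hematology_cols()] <- NA_real_
  }
  cohort <- cohort[c("mouse_id", "group", "time_h",
                     setdiff(cohort_cols(), c("mouse_id", "group",
                                              "time_h")))]
  validate_cohort(cohort)
}
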