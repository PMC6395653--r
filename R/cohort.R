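#' Design of a synthetic mouse cohort
#'
#' Describes the statistical structure of an in vivo xenograft group: number
#' of mice, treatment timing, caliper measurement schedule, initial-volume
#' distribution at the first measurement, per-mouse growth heterogeneity and
#' multiplicative measurement noise.
#'
#' Defaults mirror the emulated study: 10 mice per group, randomisation and
#' treatment start at day 12 (tumors around 130 mm^3), calipering every 3.5
#' days from day 10 to day 59, initial volume 154 +/- 16 mm^3 at day 10,
#' lognormal growth-rate heterogeneity (CV 8%) and lognormal caliper noise
#' (CV 5%).
#'
#' @param arm Scenario name (see [tumor_scenario()]).
#' @param n_mice Number of mice.
#' @param t_start_treatment Treatment start day.
#' @param measurement_days Increasing measurement schedule (days).
#' @param v0_mean,v0_sd Initial tumor volume distribution (mm^3), truncated
#'   at zero.
#' @param growth_cv Lognormal coefficient of variation of the per-mouse
#'   growth-rate multiplier (mean 1).
#' @param noise_cv Lognormal coefficient of variation of multiplicative
#'   measurement noise.
#' @param censor_at Volume (mm^3) above which a trajectory is flagged
#'   censored (lethal volume); `Inf` disables (default: disabled, the flag
#'   is informational).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(arm = "pbs", n_mice = 10, t_start_treatment = 12,
                          measurement_days = seq(10, 59, by = 3.5),
                          v0_mean = 154, v0_sd = 16,
                          growth_cv = 0.08, noise_cv = 0.05,
                          censor_at = Inf, seed = 1) {
  stopifnot(n_mice >= 1, growth_cv >= 0, noise_cv >= 0, v0_sd >= 0,
            all(diff(measurement_days) > 0))
  structure(
    list(arm = arm, n_mice = n_mice, t_start_treatment = t_start_treatment,
         measurement_days = measurement_days, v0_mean = v0_mean, v0_sd = v0_sd,
         growth_cv = growth_cv, noise_cv = noise_cv, censor_at = censor_at,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Generate a synthetic cohort
#'
#' For each mouse: draw a growth-rate multiplier (lognormal, mean 1, CV
#' `growth_cv`) and an initial volume (normal, truncated at zero), simulate
#' the kinetic model under the design's treatment arm, then apply
#' multiplicative lognormal measurement noise (mean 1, CV `noise_cv`) at the
#' measurement days.  Fully reproducible from `design$seed`.
#'
#' @param design A [cohort_design()].
#' @param model A `kinetic_model`.
#' @param perf,growth,death Scenario configuration (defaults: calibrated
#'   values); the per-mouse multiplier scales `growth$mu_max`.
#' @param ... Passed to [simulate_tumor()].
#' @return A `tumor_cohort` tibble: `mouse_id`, `time_day`, `volume_mm3`,
#'   `volume_true_mm3`, `censored`; attributes `design` and `ground_truth`
#'   (the scenario parameters and per-mouse draws).
#' @export
generate_cohort <- function(design, model = ll2_model(),
                            perf = perfusion_config(), growth = growth_law(),
                            death = death_law(), ...) {
  stopifnot(inherits(design, "cohort_design"))
  scenario <- tumor_scenario(design$arm, t_start = design$t_start_treatment,
                             t0 = min(design$measurement_days),
                             t_end = max(design$measurement_days))
  set.seed(design$seed)
  sdlog_g <- sqrt(log(1 + design$growth_cv^2))
  sdlog_n <- sqrt(log(1 + design$noise_cv^2))
  mult <- stats::rlnorm(design$n_mice, meanlog = -sdlog_g^2 / 2, sdlog = sdlog_g)
  v0 <- pmax(stats::rnorm(design$n_mice, design$v0_mean, design$v0_sd), 0)
  noise <- matrix(
    stats::rlnorm(design$n_mice * length(design$measurement_days),
                  meanlog = -sdlog_n^2 / 2, sdlog = sdlog_n),
    nrow = design$n_mice
  )
  rows <- vector("list", design$n_mice)
  for (i in seq_len(design$n_mice)) {
    gr <- growth
    gr$mu_max <- growth$mu_max * mult[i]
    st0 <- initial_tumor_state(model, V_tumor = v0[i])
    traj <- tryCatch(
      simulate_tumor(model, scenario, perf = perf, growth = gr, death = death,
                     state0 = st0, dt_out = 1, ...),
      error = function(e) stop("simulation failed for mouse ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    v_true <- stats::approx(traj$time_day, traj$V_tumor_mm3,
                            xout = design$measurement_days, rule = 2)$y
    v_obs <- v_true * noise[i, ]
    rows[[i]] <- tibble::tibble(
      mouse_id = i,
      time_day = design$measurement_days,
      volume_mm3 = v_obs,
      volume_true_mm3 = v_true,
      censored = cumsum(v_true > design$censor_at) > 0
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "design") <- design
  attr(out, "ground_truth") <- list(
    mu_max = growth$mu_max, F_in = perf$F_in, F_out = perf$F_out,
    k_d = death$k_d, multipliers = mult, v0 = v0
  )
  class(out) <- c("tumor_cohort", class(out))
  out
}

#' Summarise a cohort into a fit-ready series
#'
#' Mean and standard deviation of the observed volumes per measurement day;
#' the SD becomes the weight `sigma` for [fit_tumor_model()].  A single-mouse
#' cohort has no SD: it falls back to `noise_cv * mean` with a warning.
#'
#' @param cohort A `tumor_cohort`.
#' @return A [cohort_series()] (columns `time_day`, `volume_mm3` = mean,
#'   `sigma_mm3` = SD).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  design <- attr(cohort, "design")
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$time_day),
    mean_v = mean(.data$volume_mm3),
    sd_v = stats::sd(.data$volume_mm3),
    .groups = "drop"
  )
  tab <- dplyr::arrange(tab, .data$time_day)
  if (anyNA(tab$sd_v)) {
    warning("single-mouse cohort: sigma falls back to noise_cv * mean")
    tab$sd_v <- design$noise_cv * tab$mean_v
  }
  cohort_series(tab$time_day, tab$mean_v, pmax(tab$sd_v, 1e-9),
                arm = design$arm)
}

#' Write a cohort to CSV (plus a provenance sidecar)
#'
#' @param cohort A `tumor_cohort`.
#' @param path Output CSV (`mouse_id`, `time_day`, `volume_mm3`,
#'   `censored`); a JSON sidecar `<path>.provenance.json` records the design,
#'   seed and ground-truth parameters.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(
    tibble::as_tibble(cohort)[c("mouse_id", "time_day", "volume_mm3", "censored")],
    path
  )
  design <- attr(cohort, "design")
  gt <- attr(cohort, "ground_truth")
  jsonlite::write_json(
    list(design = unclass(design), ground_truth = gt),
    paste0(path, ".provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(cohort)
}
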