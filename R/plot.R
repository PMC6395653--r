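#' Plot a simulated trajectory
#'
#' Tumor volume over time; set `what` to add panels for blood glucose and
#' lactate, the NAD+/NADH ratio, or key fluxes (lactate dehydrogenase and
#' respiration).
#'
#' @param object A `tumor_trajectory`.
#' @param what Panels to draw: any of `"volume"`, `"blood"`, `"redox"`,
#'   `"fluxes"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tumor_trajectory <- function(object,
                                      what = c("volume", "blood", "redox", "fluxes"),
                                      ...) {
  what <- match.arg(what, several.ok = TRUE)
  tr <- tibble::as_tibble(object)
  panels <- list(
    volume = dplyr::transmute(tr, time_day = .data$time_day,
                              panel = "tumor volume (mm^3)",
                              series = "V_tumor", value = .data$V_tumor_mm3),
    blood = dplyr::bind_rows(
      dplyr::transmute(tr, time_day = .data$time_day, panel = "blood (mM)",
                       series = "glucose", value = .data$EGLC),
      dplyr::transmute(tr, time_day = .data$time_day, panel = "blood (mM)",
                       series = "lactate", value = .data$LAC)
    ),
    redox = dplyr::transmute(tr, time_day = .data$time_day,
                             panel = "NAD+/NADH", series = "NAD+/NADH",
                             value = .data$nad_nadh),
    fluxes = dplyr::bind_rows(
      dplyr::transmute(tr, time_day = .data$time_day, panel = "flux",
                       series = "VLDH", value = .data$r_VLDH),
      dplyr::transmute(tr, time_day = .data$time_day, panel = "flux",
                       series = "Vresp", value = .data$r_Vresp)
    )
  )
  dat <- dplyr::bind_rows(panels[what])
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_day, .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "days post-inoculation", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic cohort
#'
#' Thin lines per mouse, bold line for the cohort mean — the standard
#' per-animal tumor-growth display.
#'
#' @param object A `tumor_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tumor_cohort <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  mean_curve <- dplyr::summarise(
    dplyr::group_by(dat, .data$time_day),
    volume_mm3 = mean(.data$volume_mm3), .groups = "drop"
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_day, .data$volume_mm3)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$mouse_id),
                       linewidth = 0.3, alpha = 0.5) +
    ggplot2::geom_line(data = mean_curve, colour = "red", linewidth = 1.1) +
    ggplot2::labs(x = "days post-inoculation", y = "tumor volume (mm^3)",
                  title = attr(object, "design")$arm) +
    ggplot2::theme_minimal()
}

#' Plot objective profiles of a fit
#'
#' @param profiles Result of [profile_sensitivity()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(.data$value, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "weighted SSE") +
    ggplot2::theme_minimal()
}
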