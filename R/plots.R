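#' Plot a compartment trajectory
#'
#' Activity in blood, tumor, body organs, and excretion (plus the total) as a
#' function of time since injection.
#'
#' @param object A `compartment_trajectory` from [solve_compartments()] or
#'   [analytic_no_return()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compartment_trajectory <- function(object, ...) {
  labels <- c(R1 = "blood", R2 = "tumor", R3 = "body organs",
              R4 = "excretion", RT = "total")
  long <- tidyr::pivot_longer(as_tibble(object), -"t_h",
                              names_to = "compartment",
                              values_to = "activity_mbq")
  long$compartment <- factor(labels[long$compartment], levels = labels)
  ggplot2::ggplot(long, ggplot2::aes(.data$t_h, .data$activity_mbq,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since injection (h)", y = "activity (MBq)",
                  colour = NULL)
}

#' Plot a dose profile
#'
#' Tumor dose rate and cumulative absorbed dose against time.
#'
#' @param object A `dose_profile` from [dose_profile()], [dose_pulse()] or
#'   [superpose_schedule()].
#' @param ... Unused.
#' @return A ggplot object (two facets: rate, cumulative).
#' @export
autoplot.dose_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"t_h",
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity,
                          levels = c("dose_rate_gy_h", "cum_dose_gy"),
                          labels = c("dose rate (Gy/h)",
                                     "cumulative dose (Gy)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_h, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time since injection (h)", y = NULL)
}

#' Plot a tumor trajectory
#'
#' Total, live, and damaged tumor volume on a log scale against time.
#'
#' @param object A `tumor_trajectory` from [simulate_full()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tumor_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "t_day", "V", "V_L", "V_D"),
    -"t_day", names_to = "component", values_to = "volume_mm3")
  long$component <- factor(long$component, levels = c("V", "V_L", "V_D"),
                           labels = c("total", "live", "damaged"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_day, .data$volume_mm3,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time since treatment (days)", y = "volume (mm3)",
                  colour = NULL)
}

#' Plot a dose-response scenario family
#'
#' Simulated tumor-volume curves for a set of injected activities, one colour
#' per activity, on a log volume scale.
#'
#' @param scenarios A `trt_scenarios` tibble from [run_scenarios()].
#' @return A ggplot object.
#' @examples
#' sc <- run_scenarios(c(0, 1), horizon_days = 20, step_days = 1)
#' plot_scenarios(sc)
#' @export
plot_scenarios <- function(scenarios) {
  if (!all(c("activity_mbq", "t_day", "V") %in% names(scenarios))) {
    abort("`scenarios` must come from run_scenarios().",
          class = "trtsim_invalid_input")
  }
  ggplot2::ggplot(scenarios,
                  ggplot2::aes(.data$t_day, .data$V,
                               colour = factor(.data$activity_mbq))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time since treatment (days)", y = "tumor volume (mm3)",
                  colour = "activity (MBq)")
}

#' Plot a (synthetic) cohort table
#'
#' Per-animal tumor-volume series coloured by treatment group, the usual view
#' of a xenograft dose-response experiment.
#'
#' @param cohort A cohort table with columns `animal_id`, `activity_mbq`,
#'   `day`, `volume_mm3` (e.g. from [generate_cohort()]).
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort) {
  if (!all(c("animal_id", "activity_mbq", "day", "volume_mm3") %in%
           names(cohort))) {
    abort("`cohort` must have columns animal_id, activity_mbq, day, volume_mm3.",
          class = "trtsim_invalid_input")
  }
  ggplot2::ggplot(cohort,
                  ggplot2::aes(.data$day, .data$volume_mm3,
                               group = .data$animal_id,
                               colour = factor(.data$activity_mbq))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day", y = "tumor volume (mm3)",
                  colour = "activity (MBq)")
}
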