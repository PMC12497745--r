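#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Goodness-of-fit panels
#'
#' Four standard diagnostic panels: observations vs population predictions,
#' observations vs individual predictions, CWRES vs population predictions
#' and CWRES vs time.
#'
#' @param object A `clz_gof` from [gof()].
#' @param ... Unused.
#' @return A ggplot object (faceted panels).
#' @export
autoplot.clz_gof <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, panel = "DV vs PRED", x = .data$pred,
                     y = .data$dv),
    dplyr::transmute(object, panel = "DV vs IPRED", x = .data$ipred,
                     y = .data$dv),
    dplyr::transmute(object, panel = "CWRES vs PRED", x = .data$pred,
                     y = .data$cwres),
    dplyr::transmute(object, panel = "CWRES vs time", x = .data$time,
                     y = .data$cwres)
  )
  ref <- tibble::tibble(
    panel = c("DV vs PRED", "DV vs IPRED", "CWRES vs PRED", "CWRES vs time"),
    slope = c(1, 1, 0, 0), intercept = 0
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(
      data = ref,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' Visual predictive check plot
#'
#' Observed percentiles per time bin overlaid on the simulation-based 95%
#' confidence ribbons of the same percentiles.
#'
#' @param object A `clz_vpc` from [vpc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clz_vpc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_mid,
                                       group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_med),
                       colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)",
                  title = "Visual predictive check") +
    ggplot2::theme_bw()
}

#' Probability-of-target-attainment / toxicity heat lines
#'
#' PTA and toxicity-exceedance probability against daily dose, one line per
#' simulated body weight.
#'
#' @param object A `clz_pta_grid` from [pta_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clz_pta_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "weight", "dose_per_kg", "pta", "p_toxic"),
    cols = c("pta", "p_toxic"), names_to = "metric", values_to = "prob"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dose_per_kg, y = .data$prob,
                                     colour = factor(.data$weight))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~metric, nrow = 1) +
    ggplot2::labs(x = "Dose (mg/kg/day)", y = "Probability",
                  colour = "Weight (kg)") +
    ggplot2::theme_bw()
}

#' Individual concentration-time profiles
#'
#' Population and individual prediction curves with the subject's
#' observations, faceted by subject.
#'
#' @param object A `clz_profiles` from [individual_profiles()].
#' @param ids Optional subset of subject ids to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clz_profiles <- function(object, ids = NULL, ...) {
  if (!is.null(ids)) object <- dplyr::filter(object, .data$id %in% ids)
  curves <- dplyr::filter(object, .data$type == "curve")
  obs <- dplyr::filter(object, .data$type == "obs")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred), linetype = 2,
                       colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ipred), colour = "steelblue") +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$dv), size = 1) +
    ggplot2::facet_wrap(~id, scales = "free") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)") +
    ggplot2::theme_bw()
}
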