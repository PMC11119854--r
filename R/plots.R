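#' Plot a fitted FiO2-SaO2 shunt curve
#'
#' Shows the observed step-down points and the fitted forward-model curve,
#' with the no-defect (zero shunt, zero V:Q displacement) curve for reference.
#'
#' @param object A `shunt_fit`.
#' @param constants A [physio_constants()] object (must match the fit).
#' @param ... Ignored.
#' @return A ggplot object.
#' @examples
#' steps <- data.frame(fio2 = c(0.5, 0.4, 0.3, 0.21), paco2 = 40,
#'                     sao2 = predict_sao2(c(0.5, 0.4, 0.3, 0.21), 0.25, 20, 40))
#' autoplot(fit_shunt_vq(steps))
#' @importFrom ggplot2 autoplot
#' @method autoplot shunt_fit
#' @export
autoplot.shunt_fit <- function(object, constants = physio_constants(), ...) {
  paco2 <- mean(object$data$paco2)
  grid <- tibble::tibble(fio2 = seq(0.21, 1, by = 0.01))
  grid$fitted <- predict_sao2(grid$fio2, object$qs_qt, object$vq_shift, paco2,
                              constants = constants)
  grid$ideal <- predict_sao2(grid$fio2, 0, 0, paco2, constants = constants)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$fio2)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ideal), linetype = "dashed",
                       colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$fio2, y = .data$sao2), size = 2) +
    ggplot2::labs(
      x = "FiO2 (fraction)", y = "SaO2 (fraction)",
      title = sprintf("Qs/Qt = %.2f, V:Q shift = %.0f mmHg", object$qs_qt,
                      object$vq_shift)
    ) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Plot regional NIRS trajectories of a cohort
#'
#' Group-mean regional saturations (with SE ribbons) across the measurement
#' periods, one panel per NIRS site.
#'
#' @param cohort A `neonoxy_cohort`.
#' @return A ggplot object.
#' @export
plot_nirs_trends <- function(cohort) {
  stopifnot(inherits(cohort, "neonoxy_cohort"))
  long <- cohort$data |>
    tidyr::pivot_longer(dplyr::all_of(c("nirs_brain", "nirs_gut", "nirs_kidney")),
                        names_to = "site", names_prefix = "nirs_",
                        values_to = "rso2") |>
    dplyr::group_by(.data$group, .data$period, .data$site) |>
    dplyr::summarise(mean = mean(.data$rso2),
                     se = stats::sd(.data$rso2) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(period = factor(.data$period, levels = names(step_periods())))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$mean,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = NULL, y = "rSO2 (%)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot autoregulation class proportions by group and period
#'
#' Stacked-proportion bars of the autoregulation classes per group and FiO2
#' step, the shape of the study's attribution figure.
#'
#' @param counts Output of [attribute_cohort()].
#' @return A ggplot object.
#' @export
plot_autoreg_attribution <- function(counts) {
  stopifnot(all(c("group", "period", "autoreg", "n") %in% names(counts)))
  counts |>
    dplyr::mutate(period = factor(.data$period,
                                  levels = intersect(names(step_periods()),
                                                     unique(.data$period)))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$period, y = .data$n,
                                 fill = .data$autoreg)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "proportion of observations", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
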