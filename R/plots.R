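# ggplot2 displays for the main result types.

#' Bar chart of treatment means with significance letters
#'
#' Mean +/- SD bars per treatment, faceted by variable, with the Fisher-LSD
#' compact letters above each bar (same letter = not significantly
#' different).
#'
#' @param summaries Output of [treatment_summaries()] or
#'   [nutritional_yield_summary()] (the latter after renaming `nutrient`
#'   to `variable`).
#' @return A ggplot object.
#' @export
plot_treatment_summary <- function(summaries) {
  var_col <- if ("variable" %in% names(summaries)) "variable" else "nutrient"
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$treatment, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd), width = 0.25) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$mean + .data$sd, label = .data$letters),
      vjust = -0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(var_col, scales = "free_y") +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "Treatment", y = "Mean ± SD") +
    ggplot2::theme_minimal()
}

#' @rdname plot_treatment_summary
#' @param object An `ofs_lsd` object.
#' @param ... Unused.
#' @export
autoplot.ofs_lsd <- function(object, ...) {
  plot_treatment_summary(
    dplyr::mutate(object$summary, variable = "value", treatment = .data$group)
  )
}

#' Phytate molar ratios by treatment
#'
#' Boxplots of the per-plot PA/mineral molar ratios, faceted by mineral,
#' with the Zn (< 15) and Fe (< 1) bioavailability thresholds drawn as
#' dashed lines.
#'
#' @param ratios Output of [molar_ratio_table()].
#' @return A ggplot object.
#' @export
plot_molar_ratios <- function(ratios) {
  thresholds <- tibble::tibble(mineral = c("Fe", "Zn"), threshold = c(1, 15))
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = .data$treatment, y = .data$ratio)) +
    ggplot2::geom_boxplot(fill = "darkseagreen", alpha = 0.7) +
    ggplot2::geom_hline(data = thresholds,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap("mineral", scales = "free_y") +
    ggplot2::labs(x = "Treatment", y = "PA : mineral molar ratio") +
    ggplot2::theme_minimal()
}

#' DALYs saved by demographic group
#'
#' @param object An `ofs_health` object.
#' @param ... Unused.
#' @return A ggplot object: DALYs saved per group, faceted by nutrient and
#'   scenario, coloured by treatment.
#' @export
autoplot.ofs_health <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$group, y = .data$dalys_saved,
                               fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$nutrient),
      cols = ggplot2::vars(.data$scenario), scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "DALYs saved per year", fill = "Treatment") +
    ggplot2::theme_minimal()
}
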