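#' Plot a raster field
#'
#' @param object A [raster_field()].
#' @param ... Unused.
#' @return A ggplot: the raster surface with equal coordinates.
#' @importFrom ggplot2 autoplot
#' @method autoplot raster_field
#' @export
autoplot.raster_field <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("%s surface", object$kind)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic city
#'
#' Summary-index surface with facility points and, optionally, participant
#' locations overlaid.
#'
#' @param object A `uf_city` from [generate_city()].
#' @param cohort Optional cohort tibble with `x`, `y` (and `frail` if scored).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uf_city
#' @export
autoplot.uf_city <- function(object, cohort = NULL, ...) {
  surf <- urban_quality_surface(object$grid, object$layers)
  p <- autoplot(surf$index) +
    ggplot2::labs(title = "Urban-quality summary index")
  pts <- purrr::imap_dfr(object$layers, function(l, nm) {
    dplyr::mutate(l$points, facility_type = nm)
  })
  p <- p + ggplot2::geom_point(
    data = pts, ggplot2::aes(.data$x, .data$y, shape = .data$facility_type),
    inherit.aes = FALSE, size = 1, alpha = 0.7
  ) + ggplot2::scale_shape_manual(values = 1:7)
  if (!is.null(cohort)) {
    p <- p + ggplot2::geom_point(
      data = cohort, ggplot2::aes(.data$x, .data$y),
      inherit.aes = FALSE, size = 0.6, colour = "red", alpha = 0.6
    )
  }
  p
}

#' Plot a fitted index-score regression
#'
#' @param object A `uf_fit` from [linear_fit()].
#' @param ... Unused.
#' @return A ggplot: scatter with the least-squares line and the fit
#'   annotation.
#' @method autoplot uf_fit
#' @export
autoplot.uf_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = object$x_name, y = object$y_name,
      subtitle = sprintf("r = %.3f, p = %.4g, n = %d",
                         object$r, object$p_value, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot panels of an analysis report
#'
#' @param object A `uf_report` from [build_report()].
#' @param which One of `"distances"` (facility distances by frailty status,
#'   mean +/- SEM), `"correlations"` (the analyte correlation panel) or
#'   `"quartiles"` (frailty metrics by index quartile).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uf_report
#' @export
autoplot.uf_report <- function(object,
                               which = c("distances", "correlations", "quartiles"),
                               ...) {
  which <- match.arg(which)
  if (which == "distances") {
    df <- tidyr::pivot_longer(
      object$fig3,
      cols = c("mean_nonfrail", "mean_frail"),
      names_to = "status", names_prefix = "mean_", values_to = "mean"
    )
    df$sem <- ifelse(df$status == "frail", object$fig3$sem_frail[
      match(df$facility_type, object$fig3$facility_type)],
      object$fig3$sem_nonfrail[match(df$facility_type, object$fig3$facility_type)])
    ggplot2::ggplot(df, ggplot2::aes(.data$facility_type, .data$mean,
                                     fill = .data$status)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
        position = ggplot2::position_dodge(width = 0.9), width = 0.3
      ) +
      ggplot2::coord_flip() +
      ggplot2::labs(y = "distance to nearest facility (m)", x = NULL) +
      ggplot2::theme_minimal()
  } else if (which == "correlations") {
    df <- dplyr::arrange(object$table4, .data$rho)
    df$analyte <- factor(df$analyte, levels = df$analyte)
    ggplot2::ggplot(df, ggplot2::aes(.data$rho, .data$analyte,
                                     colour = .data$p_value < 0.05)) +
      ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::labs(x = "Spearman rho with summary index", y = NULL,
                    colour = "p < 0.05") +
      ggplot2::theme_minimal()
  } else {
    df <- object$table3$cells
    ggplot2::ggplot(df, ggplot2::aes(.data$quartile, .data$estimate)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$estimate - .data$sd,
                     ymax = .data$estimate + .data$sd), width = 0.3,
        na.rm = TRUE
      ) +
      ggplot2::facet_wrap(~variable, scales = "free_y") +
      ggplot2::labs(x = "summary-index quartile", y = NULL) +
      ggplot2::theme_minimal()
  }
}
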