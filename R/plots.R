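#' Forest plot of per-study and pooled odds ratios
#'
#' Studies are drawn top-to-bottom in table order with square markers
#' sized by pooling weight; the pooled estimate is the bottom diamond row
#' and the dashed line marks OR = 1.
#'
#' @param pooled A `pooled_or` object from [pool_effects()].
#' @return A ggplot object.
#' @examples
#' rs1564282_studies() |> study_effects() |> pool_effects() |> plot_forest()
#' @export
plot_forest <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_or"))
  eff <- dplyr::left_join(pooled$effects, pooled$weights, by = "study_id")
  rows <- dplyr::bind_rows(
    tibble(
      label = eff$study_id, or = eff$or,
      ci_low = eff$ci_low, ci_high = eff$ci_high,
      weight_pct = eff$weight_pct, kind = "study"
    ),
    tibble(
      label = sprintf("Pooled (%s)", pooled$model), or = pooled$or,
      ci_low = pooled$ci_low, ci_high = pooled$ci_high,
      weight_pct = 100, kind = "pooled"
    )
  )
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$weight_pct, shape = .data$kind),
      fill = "black"
    ) +
    ggplot2::scale_shape_manual(values = c(study = 22, pooled = 23), guide = "none") +
    ggplot2::scale_size_area(max_size = 5, guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_forest
#' @param object A `pooled_or` object.
#' @param ... Unused.
#' @export
autoplot.pooled_or <- function(object, ...) {
  plot_forest(object)
}

#' Funnel plot with pseudo-95% confidence limits
#'
#' Study effects against their standard errors, y axis inverted, with the
#' pooled reference line and the pseudo-95% funnel boundary from
#' [funnel_points()].
#'
#' @param funnel A tibble from [funnel_points()].
#' @return A ggplot object.
#' @examples
#' rs1564282_studies() |> study_effects() |> funnel_points() |> plot_funnel()
#' @export
plot_funnel <- function(funnel) {
  boundary <- attr(funnel, "boundary")
  reference <- attr(funnel, "reference")
  scale <- attr(funnel, "scale") %||% "or"
  p <- ggplot2::ggplot(as_tibble(funnel), ggplot2::aes(x = .data$x, y = .data$se)) +
    ggplot2::geom_path(
      data = tidyr::pivot_longer(boundary, c("low", "high"),
                                 names_to = "side", values_to = "x"),
      ggplot2::aes(group = .data$side), linetype = "dotted"
    ) +
    ggplot2::geom_vline(xintercept = reference, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(shape = 21, fill = "white", size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = if (scale == "or") "Odds ratio" else "log odds ratio",
      y = "Standard error of log OR"
    ) +
    ggplot2::theme_minimal()
  if (scale == "or") p <- p + ggplot2::scale_x_log10()
  p
}

#' Leave-one-out sensitivity plot
#'
#' Pooled odds ratio and CI after omitting each study in turn, with the
#' dashed null line at OR = 1.
#'
#' @param sensitivity A tibble from [leave_one_out()].
#' @return A ggplot object.
#' @examples
#' rs1564282_studies() |> leave_one_out() |> plot_leave_one_out()
#' @export
plot_leave_one_out <- function(sensitivity) {
  sensitivity$omitted_study_id <- factor(
    sensitivity$omitted_study_id, levels = rev(sensitivity$omitted_study_id)
  )
  ggplot2::ggplot(sensitivity,
                  ggplot2::aes(x = .data$or, y = .data$omitted_study_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Pooled OR omitting the study (log scale)",
                  y = "Omitted study") +
    ggplot2::theme_minimal()
}
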