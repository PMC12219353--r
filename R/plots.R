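#' Bias-curve plot for a study result
#'
#' Reproduces the study's standard layout: for one effect measure, an upper
#' panel with the true effect (line and ribbon) and the estimated effect per
#' definition (points with bootstrap intervals) against the treatment-induced
#' relapse reduction, and a lower panel with the bias (estimated minus true)
#' and its paired-bootstrap interval, with a dashed zero line.
#'
#' @param object A `pira_bias_study` tibble from [run_study()].
#' @param measure `"HR"` or `"RR"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pira_bias_study <- function(object, measure = "HR", ...) {
  df <- object[object$measure == measure, ]
  if (nrow(df) == 0) stop(sprintf("no results for measure '%s'", measure),
                          call. = FALSE)
  eff <- tibble::tibble(
    relapse_reduction = df$relapse_reduction, definition = df$definition,
    panel = "effect", value = df$est_point, lo = df$est_ci_low,
    hi = df$est_ci_high)
  bias <- tibble::tibble(
    relapse_reduction = df$relapse_reduction, definition = df$definition,
    panel = "bias", value = df$bias, lo = df$bias_ci_low,
    hi = df$bias_ci_high)
  truth <- dplyr::distinct(tibble::tibble(
    relapse_reduction = df$relapse_reduction, panel = "effect",
    value = df$true_point, lo = df$true_ci_low, hi = df$true_ci_high))
  ref <- tibble::tibble(panel = c("effect", "bias"), yint = c(1, 0))
  both <- dplyr::bind_rows(eff, bias)
  both$panel <- factor(both$panel, levels = c("effect", "bias"))
  truth$panel <- factor(truth$panel, levels = c("effect", "bias"))
  ref$panel <- factor(ref$panel, levels = c("effect", "bias"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$relapse_reduction,
                                     y = .data$value,
                                     colour = .data$definition)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$yint),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_ribbon(data = truth,
                         mapping = ggplot2::aes(x = .data$relapse_reduction,
                                                ymin = .data$lo,
                                                ymax = .data$hi),
                         inherit.aes = FALSE,
                         fill = "steelblue", alpha = 0.15) +
    ggplot2::geom_line(data = truth,
                       ggplot2::aes(x = .data$relapse_reduction,
                                    y = .data$value),
                       inherit.aes = FALSE, colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.03),
                             size = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "relapse-rate reduction in the treated arm",
                  y = measure, colour = "definition",
                  title = sprintf("True vs estimated %s for PIRA", measure)) +
    ggplot2::theme_minimal()
}
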