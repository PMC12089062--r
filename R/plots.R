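ribbon_plot <- function(curve, ylab) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$distance_km, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95,
                                      ymax = .data$upper95),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance to city center (km)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @method autoplot morph_cline_curve
#' @export
autoplot.morph_cline_curve <- function(object, ...) {
  ribbon_plot(object, "Proportion melanic")
}

#' @method autoplot difference_curve
#' @export
autoplot.difference_curve <- function(object, ...) {
  ribbon_plot(object, "Difference in proportion melanic (living - DOR)") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
}

#' Plot living and DOR clines with their posterior difference
#'
#' @param object A `cline_contrast` from [cline_difference_curves()].
#' @param ... Unused.
#' @return A ggplot; the living and DOR clines share one panel, the
#'   difference curve the other.
#' @method autoplot cline_contrast
#' @export
autoplot.cline_contrast <- function(object, ...) {
  both <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$living), panel = "cline",
                  group = "living"),
    dplyr::mutate(tibble::as_tibble(object$dor), panel = "cline",
                  group = "DOR"),
    dplyr::mutate(tibble::as_tibble(object$difference), panel = "difference",
                  group = "living - DOR")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$distance_km, y = .data$mean,
                                     fill = .data$group,
                                     colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95,
                                      ymax = .data$upper95),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Distance to city center (km)",
                  y = "Proportion melanic", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot DOR proportions by morph with Agresti-Coull intervals
#'
#' @param object A `contingency_2x2` (rows dead/alive, columns morphs).
#' @param level Confidence level.
#' @param ... Unused.
#' @return A ggplot of the proportion photographed dead per morph.
#' @method autoplot contingency_2x2
#' @export
autoplot.contingency_2x2 <- function(object, level = 0.95, ...) {
  tab <- unclass(as.matrix(object))
  ci <- agresti_coull_interval(tab["dead", ], colSums(tab), level = level)
  df <- tibble::tibble(morph = colnames(tab), estimate = ci$estimate,
                       lower = ci$lower, upper = ci$upper)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$morph, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.15) +
    ggplot2::labs(x = NULL, y = "Proportion dead on road") +
    ggplot2::theme_minimal()
}

#' Trace plot of posterior draws
#'
#' @param object A `posterior_samples` object.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot with one facet per parameter, colored by chain.
#' @method autoplot posterior_samples
#' @export
autoplot.posterior_samples <- function(object, parameters = NULL, ...) {
  df <- as_draws_df(object)
  if (!is.null(parameters)) {
    df <- dplyr::filter(df, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Retained iteration", y = NULL, colour = "Chain") +
    ggplot2::theme_minimal()
}
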