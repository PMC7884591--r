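#' Plot calibrated against original docking scores
#'
#' Scatter of calibrated vs original scores with the identity line; fallback
#' queries (returned unchanged) are marked. Points far off the diagonal are
#' the compounds for which similar references disagreed most with the raw
#' docking score.
#'
#' @param object A `dockcal_calibration` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dockcal_calibration
#' @export
autoplot.dockcal_calibration <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$original_score,
                                   .data$calibrated_score,
                                   colour = .data$fallback)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2166ac",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "original docking score (kcal/mol)",
                  y = "calibrated score (kcal/mol)",
                  colour = "fallback") +
    ggplot2::theme_minimal()
}

#' Plot benchmark metrics before and after calibration
#'
#' Mean metric values over the repeats with 95% CI error bars, faceted by
#' metric, one panel column per CSE exponent when several were swept.
#'
#' @param object A `dockcal_benchmark` object.
#' @param metrics Which metrics to show (default all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dockcal_benchmark
#' @export
autoplot.dockcal_benchmark <- function(object, metrics = NULL, ...) {
  df <- glance(object)
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  df <- dplyr::mutate(df, p_lab = paste0("p = ", .data$p))
  ggplot2::ggplot(df, ggplot2::aes(.data$fingerprint, .data$mean,
                                   fill = .data$phase)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$ci95,
                   ymax = .data$mean + .data$ci95),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::facet_grid(metric ~ p_lab, scales = "free_y") +
    ggplot2::labs(x = "fingerprint", y = "mean over repeats (95% CI)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve points for a scored, labelled compound set
#'
#' Convenience for plotting screening performance: returns the ROC curve of a
#' score column (more negative = predicted active) against activity labels.
#'
#' @param data Data frame.
#' @param predicted Score column (tidy-eval).
#' @param active Logical label column (tidy-eval).
#' @return Tibble with columns `fpr` and `tpr`, ordered along the curve.
#' @export
roc_points <- function(data, predicted, active) {
  p <- dplyr::pull(data, {{ predicted }})
  a <- dplyr::pull(data, {{ active }})
  check_paired(p, a)
  ord <- order(p)
  tibble::tibble(
    fpr = c(0, cumsum(!a[ord]) / sum(!a)),
    tpr = c(0, cumsum(a[ord]) / sum(a))
  )
}
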