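#' Plot the tissue-by-method cross-validation MAE grid
#'
#' A heat-map analog of the per-tissue method comparison: tissues on the
#' y axis, roster methods on the x axis, tiles shaded by mean CV MAE with
#' the per-tissue winner outlined.
#'
#' @param object A `tissue_registry`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tissue_registry
#' @export
autoplot.tissue_registry <- function(object, ...) {
  grid <- object$cv_grid
  grid$method <- factor(grid$method, levels = object$roster_names)
  winners <- dplyr::slice_min(dplyr::group_by(grid, .data$tissue),
                              .data$cv_mae, n = 1, with_ties = FALSE)
  ggplot2::ggplot(grid, ggplot2::aes(.data$method, .data$tissue,
                                     fill = .data$cv_mae)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = winners, fill = NA, colour = "black",
                       linewidth = 0.7) +
    ggplot2::scale_fill_viridis_c(name = "CV MAE", direction = -1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cross-validated MAE of log Kt:p by tissue and method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a phase-2 result
#'
#' Observed versus predicted log Vss on the external validation set, with
#' the identity line; the subtitle reports the external MAE and GMFE.
#'
#' @param object A `vss_phase2`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vss_phase2
#' @export
autoplot.vss_phase2 <- function(object, ...) {
  df <- object$external_predictions
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Observed log10 Vss (L/kg)", y = "Predicted log10 Vss (L/kg)",
      title = sprintf("External validation, mode '%s' (%s)",
                      object$mode, object$best_method),
      subtitle = sprintf("MAE %.3f log units, GMFE %.2f-fold (n = %d)",
                         object$external_mae, object$external_gmfe,
                         object$n_external)) +
    ggplot2::theme_minimal()
}

#' Plot an applicability-domain report
#'
#' Bar chart of how often each descriptor is the out-of-range offender, with
#' the overall outside fraction in the title.
#'
#' @param object An `ad_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ad_report
#' @export
autoplot.ad_report <- function(object, ...) {
  counts <- table(unlist(object$compounds$offending))
  df <- tibble::tibble(descriptor = names(counts),
                       n_compounds = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$descriptor,
                                                  .data$n_compounds),
                                   .data$n_compounds)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Compounds out of range",
      title = sprintf("Applicability domain: %d/%d compounds (%.1f%%) outside",
                      object$n_outside, object$n_total,
                      100 * object$fraction_outside)) +
    ggplot2::theme_minimal()
}
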