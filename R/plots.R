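#' Plot background-corrected growth curves
#'
#' Percent growth against log10 concentration for each plate, with the GI50
#' (50%) and TGI (0%) levels marked.
#'
#' @param plates Tibble in the [read_plate_file()] schema.
#' @return A ggplot.
#' @export
plot_growth_curves <- function(plates) {
  curves <- purrr::map_dfr(seq_len(nrow(plates)), function(i) {
    cv <- correct_background(plates[i, ])
    cv$treated |>
      mutate(growth = growth_percent(.data$signal, cv$t0, cv$control),
             cell_line = cv$cell_line, compound = cv$compound)
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = log10(.data$concentration),
                               y = .data$growth,
                               group = interaction(.data$cell_line,
                                                   .data$compound),
                               colour = .data$cell_line)) +
    ggplot2::geom_hline(yintercept = c(50, 0), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$compound)) +
    ggplot2::labs(x = "log10 concentration (M)", y = "percent growth") +
    ggplot2::theme_minimal()
}

#' Plot the per-split AUC distribution of an evaluation
#'
#' @param object An `evaluation` from [evaluate_multisplit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evaluation
#' @export
autoplot.evaluation <- function(object, ...) {
  ggplot2::ggplot(object$per_split, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_auc, colour = "firebrick") +
    ggplot2::labs(x = "test AUC", y = "splits",
                  title = sprintf("%s: mean AUC %.3f over %d splits",
                                  object$method, object$mean_auc,
                                  object$n_splits)) +
    ggplot2::theme_minimal()
}

#' Plot a probability distribution with its response cutoffs
#'
#' @param probabilities Predicted probabilities for a cohort.
#' @param cutoffs A `cutoff_pair` from [select_cutoffs()].
#' @return A ggplot.
#' @export
plot_cutoffs <- function(probabilities, cutoffs) {
  ggplot2::ggplot(tibble(p = probabilities), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_density(fill = "grey85") +
    ggplot2::geom_vline(xintercept = c(cutoffs$cutoff1, cutoffs$cutoff2),
                        colour = c("firebrick", "forestgreen")) +
    ggplot2::labs(x = "predicted probability of response", y = "density",
                  title = sprintf("cutoffs %.3f / %.3f (%s)",
                                  cutoffs$cutoff1, cutoffs$cutoff2,
                                  cutoffs$flag)) +
    ggplot2::theme_minimal()
}

#' Tile map of rescaled response probabilities in a cohort
#'
#' @param object A `prediction_report` from [predict_cohort()] /
#'   [rank_compounds()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prediction_report
#' @export
autoplot.prediction_report <- function(object, ...) {
  ggplot2::ggplot(object$ranking,
                  ggplot2::aes(x = .data$patient, y = .data$compound,
                               fill = .data$rescaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "navy",
                                  mid = "white", high = "firebrick",
                                  limits = c(0, 1)) +
    ggplot2::labs(fill = "rescaled\nprobability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
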