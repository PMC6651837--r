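#' Observed-versus-predicted scatter plot
#'
#' @param run A `pampa_run` bundle from [run_pampa_pipeline()].
#' @param models Which fitted models to show. Default all.
#' @return A ggplot object: observed log Pe against predicted, one
#'   facet per model, colored by set, with the identity line.
#' @export
plot_observed_predicted <- function(run, models = names(run$models)) {
  long <- run$predictions |>
    tidyr::pivot_longer(dplyr::all_of(paste0("pred_", models)),
                        names_to = "model", values_to = "predicted",
                        names_prefix = "pred_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                     color = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "predicted log Pe (cm/s)", y = "observed log Pe (cm/s)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Chemical-space plot
#'
#' @param space A `pampa_chemical_space` from [pca_project()].
#' @param partition Optional partition tibble (`id`, `set`) to color by.
#' @param dims Which two components to draw. Default `c(1, 2)`.
#' @return A ggplot object.
#' @export
plot_chemical_space <- function(space, partition = NULL, dims = c(1, 2)) {
  sc <- space$scores
  d <- tibble::tibble(id = sc$id,
                      x = sc[[dims[1] + 1L]], y = sc[[dims[2] + 1L]])
  if (!is.null(partition)) d$set <- partition$set[match(d$id, partition$id)]
  pct <- 100 * space$variance_explained
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", dims[1], pct[dims[1]]),
      y = sprintf("PC%d (%.1f%%)", dims[2], pct[dims[2]])) +
    ggplot2::theme_minimal()
  if (is.null(partition)) p + ggplot2::geom_point(alpha = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$set,
                                            shape = .data$set), alpha = 0.8)
}

#' @rdname plot_chemical_space
#' @param object A `pampa_chemical_space`.
#' @param ... Passed to [plot_chemical_space()].
#' @method autoplot pampa_chemical_space
#' @export
autoplot.pampa_chemical_space <- function(object, ...) {
  plot_chemical_space(object, ...)
}

#' Ion-class permeability box plot
#'
#' @param data A data frame with `logPe` and `ion_class` columns.
#' @return A ggplot box plot of log Pe per ion class with mean markers.
#' @export
plot_ion_class <- function(data) {
  stopifnot(all(c("logPe", "ion_class") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$ion_class, y = .data$logPe)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 3, color = "red") +
    ggplot2::labs(x = NULL, y = "log Pe (cm/s)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_observed_predicted
#' @param object A `pampa_run`.
#' @param ... Passed on.
#' @method autoplot pampa_run
#' @export
autoplot.pampa_run <- function(object, ...) {
  plot_observed_predicted(object, ...)
}
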