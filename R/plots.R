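# ggplot2 displays for the result objects.

#' Plot an accuracy-versus-features curve
#'
#' @param object An `accuracy_curve` from [accuracy_vs_nfeatures()].
#' @param ... Unused.
#' @return A ggplot object: overall and median per-variant accuracy on the
#'   validation and test splits against the number of features used.
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("validation_accuracy", "validation_median",
             "test_accuracy", "test_median"),
    names_to = c("split", "measure"), names_sep = "_",
    values_to = "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$accuracy,
                                     colour = .data$split,
                                     linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "features used (top-k by |beta|)",
                  y = "classification accuracy",
                  colour = "split", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-site attribution of the feature pool and the selection
#'
#' Mirrors the site-attribution bar chart: the feature pool per structural
#' site with the machine-learning-selected portion shaded.
#'
#' @param object A `dimer_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dimer_pipeline <- function(object, ...) {
  pool <- object$feature_spec$site_counts
  sel <- object$attribution
  df <- dplyr::bind_rows(
    tibble::tibble(site = pool$site, n = pool$n_features, what = "pool"),
    tibble::tibble(site = sel$site, n = sel$n_selected, what = "selected"))
  df$site <- factor(df$site, levels = site_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$n,
                                   fill = .data$what)) +
    ggplot2::geom_col(position = "identity", alpha = 0.75) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "features (log scale)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-variant distributions of selected features
#'
#' Density of each feature's standardized values per variant, solid lines for
#' class II and dashed for class I — the display used to compare selected
#' cross-interface distances between the two mechanistic classes.
#'
#' @param matrices Named list of standardized `feature_matrix` objects.
#' @param feature_ids Feature ids to display.
#' @param rows 1-based row indices to include.
#' @param labels Optional named class labels.
#' @return A ggplot object faceted by feature.
#' @export
plot_feature_distributions <- function(matrices, feature_ids, rows,
                                       labels = NULL) {
  check_matrix_list(matrices)
  labels <- labels %||% vapply(matrices, function(m) m$class_label, character(1))
  ids <- matrices[[1L]]$descriptors$feature_id
  cols <- match(feature_ids, ids)
  if (anyNA(cols)) abort("Unknown feature id(s).")
  long <- purrr::imap_dfr(matrices, function(m, v) {
    vals <- m$values[rows, cols, drop = FALSE]
    tibble::tibble(variant_id = v, class = unname(labels[[v]]),
                   feature_id = rep(feature_ids, each = length(rows)),
                   value = as.vector(vals))
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, colour = .data$variant_id,
                                     linetype = .data$class)) +
    ggplot2::geom_density() +
    ggplot2::scale_linetype_manual(values = c(I = "dashed", II = "solid")) +
    ggplot2::facet_wrap(~feature_id, scales = "free") +
    ggplot2::labs(x = "standardized distance", y = "density",
                  colour = "variant", linetype = "class") +
    ggplot2::theme_minimal()
}
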