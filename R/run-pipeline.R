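# End-to-end orchestration of the classification analysis.

#' Run the full variant-classification pipeline
#'
#' Featurizes every ensemble, fits standardization on the training snapshots
#' of all variants, runs the hyperparameter grid search, selects features at
#' the coefficient threshold (capped at `max_features`), refits without
#' regularization on the selection, and reports overall/per-variant/median
#' accuracies, per-site attribution and coefficient signs.
#'
#' Standardization scale and all model fitting use training rows only;
#' validation rows influence nothing but the hyperparameter choice, and test
#' rows nothing but the reported accuracies.
#'
#' @param ensembles Named list of `snapshot_ensemble` objects.
#' @param labels Named class labels (`"I"`/`"II"`); defaults to the labels
#'   carried by the ensembles.
#' @param atom_kind `"CA"` or `"CB"`.
#' @param feature_spec Feature specification; defaults to the full
#'   26-group specification for `atom_kind`.
#' @param split A [split_spec()].
#' @param lambda_grid,alpha_grid Grids for [grid_search()].
#' @param threshold Selection threshold on `|beta|` (default `10^-1.6`).
#' @param max_features Cap on the selection size (default 15).
#' @param weights Optional class weights; default inverse class frequency.
#' @param grid_tol,grid_max_iter Solver settings for the grid-search fits.
#' @param refit_tol,refit_max_iter Solver settings for unregularized refits.
#' @param curve_ks Optional feature counts for an accuracy-versus-features
#'   curve (skipped when `NULL`).
#' @return Object of class `dimer_pipeline`; see [tidy.dimer_pipeline()] and
#'   [glance.dimer_pipeline()].
#' @export
run_classification_pipeline <- function(ensembles, labels = NULL,
                                        atom_kind = c("CA", "CB"),
                                        feature_spec = NULL,
                                        split = split_spec(),
                                        lambda_grid = 10^seq(-4, 3),
                                        alpha_grid = seq(0, 1, by = 0.1),
                                        threshold = 10^-1.6,
                                        max_features = 15L,
                                        weights = NULL,
                                        grid_tol = 1e-6,
                                        grid_max_iter = 1000L,
                                        refit_tol = 1e-8,
                                        refit_max_iter = 2000L,
                                        curve_ks = NULL) {
  atom_kind <- match.arg(atom_kind)
  spec <- feature_spec %||% build_feature_spec(atom_kind, quiet = TRUE)

  raw <- purrr::map(ensembles, compute_features, spec = spec)
  n_snap <- min(vapply(raw, function(m) nrow(m$values), integer(1)))
  rows <- make_splits(n_snap, split)

  params <- fit_standardization(raw, rows$train)
  std <- purrr::map(raw, standardize_features, params = params)

  train <- assemble_dataset(std, labels, rows$train)
  validation <- assemble_dataset(std, labels, rows$validation)
  test <- assemble_dataset(std, labels, rows$test)
  weights <- weights %||% class_weights(train$y)

  groups <- std[[1L]]$descriptors$group_id
  grid <- grid_search(train, validation, groups, weights = weights,
                      lambda_grid = lambda_grid, alpha_grid = alpha_grid,
                      tol = grid_tol, max_iter = grid_max_iter)

  selection <- select_features(grid$best$model, threshold = threshold,
                               max_features = max_features)
  if (nrow(selection) == 0L) {
    abort("The tuned model selected no features above the threshold.")
  }
  cols <- selection$column
  refit <- fit_unregularized(train$X[, cols, drop = FALSE], train$y,
                             weights = weights, tol = refit_tol,
                             max_iter = refit_max_iter)

  pred_val <- predict(refit, validation$X[, cols, drop = FALSE], type = "class")
  pred_test <- predict(refit, test$X[, cols, drop = FALSE], type = "class")
  acc_val <- per_variant_accuracy(pred_val, validation$y, validation$variant)
  acc_test <- per_variant_accuracy(pred_test, test$y, test$variant)

  descriptors <- std[[1L]]$descriptors
  attribution <- attribute_sites(selection, descriptors)
  signs <- coefficient_sign_report(refit, selection, descriptors)

  curve <- NULL
  if (!is.null(curve_ks)) {
    curve <- accuracy_vs_nfeatures(grid$best$model, train, validation, test,
                                   ks = curve_ks, weights = weights,
                                   tol = refit_tol, max_iter = refit_max_iter)
  }

  structure(list(
    atom_kind = atom_kind, feature_spec = spec, split = split,
    standardization = params, matrices = std, raw_matrices = raw,
    grid = grid, threshold = threshold, max_features = max_features,
    selection = selection, refit = refit,
    accuracy = list(
      validation = list(overall = accuracy(pred_val, validation$y),
                        per_variant = acc_val$per_variant,
                        median = acc_val$median),
      test = list(overall = accuracy(pred_test, test$y),
                  per_variant = acc_test$per_variant,
                  median = acc_test$median)),
    attribution = attribution, signs = signs, curve = curve,
    weights = weights),
    class = "dimer_pipeline")
}

#' @export
print.dimer_pipeline <- function(x, ...) {
  cat("<dimer_pipeline> ", x$atom_kind, " features: ",
      nrow(x$feature_spec$descriptors), " in pool, ",
      nrow(x$selection), " selected (threshold ",
      format(x$threshold, digits = 3), ", cap ", x$max_features, ")\n",
      "  best lambda = ", x$grid$best$lambda, ", alpha = ", x$grid$best$alpha, "\n",
      "  median per-variant accuracy: validation ",
      format(x$accuracy$validation$median, digits = 4), ", test ",
      format(x$accuracy$test$median, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy the selected features of a pipeline run
#'
#' @param x A `dimer_pipeline`.
#' @param ... Unused.
#' @return Tibble: one row per selected feature with site, residue pair,
#'   SGL coefficient and refit coefficient/sign.
#' @export
tidy.dimer_pipeline <- function(x, ...) {
  dplyr::left_join(
    dplyr::rename(x$signs, refit_coefficient = "coefficient"),
    dplyr::select(x$selection, "feature", sgl_beta = "beta"),
    by = "feature")
}

#' One-row summary of a pipeline run
#'
#' @param x A `dimer_pipeline`.
#' @param ... Unused.
#' @return One-row tibble with the tuned hyperparameters, selection size,
#'   and overall/median accuracies.
#' @export
glance.dimer_pipeline <- function(x, ...) {
  tibble::tibble(
    atom_kind = x$atom_kind,
    n_features = nrow(x$feature_spec$descriptors),
    lambda = x$grid$best$lambda, alpha = x$grid$best$alpha,
    n_selected = nrow(x$selection),
    n_interface = x$attribution$n_selected[x$attribution$site == "interface"],
    validation_accuracy = x$accuracy$validation$overall,
    validation_median = x$accuracy$validation$median,
    test_accuracy = x$accuracy$test$overall,
    test_median = x$accuracy$test$median,
    frac_negative = mean(x$signs$sign == "negative")
  )
}

#' Write the report bundle of a pipeline run
#'
#' Emits delimited-text tables (grid results, per-variant accuracies,
#' selected features with site and sign, attribution, optional accuracy
#' curve) plus a plain-text run manifest.
#'
#' @param result A `dimer_pipeline`.
#' @param dir Output directory (created if missing).
#' @param seed Optional seed to echo into the manifest.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir, seed = NULL) {
  stopifnot(inherits(result, "dimer_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(tidy(result$grid), file.path(dir, "grid_results.tsv"))
  readr::write_tsv(tidy(result), file.path(dir, "selected_features.tsv"))
  readr::write_tsv(result$attribution, file.path(dir, "site_attribution.tsv"))
  acc <- dplyr::bind_rows(
    dplyr::mutate(result$accuracy$validation$per_variant, split = "validation"),
    dplyr::mutate(result$accuracy$test$per_variant, split = "test"))
  readr::write_tsv(acc, file.path(dir, "per_variant_accuracy.tsv"))
  if (!is.null(result$curve)) {
    readr::write_tsv(result$curve, file.path(dir, "accuracy_curve.tsv"))
  }
  manifest <- c(
    paste0("dimerclass version: ", as.character(utils::packageVersion("dimerclass"))),
    paste0("R version: ", R.version.string),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", seed %||% "not set"),
    paste0("atom kind: ", result$atom_kind),
    paste0("feature pool: ", nrow(result$feature_spec$descriptors),
           " features in ", nrow(result$feature_spec$groups), " groups"),
    paste0("site counts: ",
           paste(result$feature_spec$site_counts$site,
                 result$feature_spec$site_counts$n_features,
                 sep = "=", collapse = ", ")),
    paste0("threshold: ", result$threshold),
    paste0("max features: ", result$max_features),
    paste0("best lambda: ", result$grid$best$lambda),
    paste0("best alpha: ", result$grid$best$alpha),
    paste0("selected: ", nrow(result$selection)),
    paste0("validation median accuracy: ", result$accuracy$validation$median),
    paste0("test median accuracy: ", result$accuracy$test$median))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
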