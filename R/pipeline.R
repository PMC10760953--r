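# Pipeline: splits, hyperparameter search, feature selection, refitting,
# accuracy curves and attribution.

#' Snapshot split specification
#'
#' Defaults follow the modeled design: of 1,000 snapshots (0-based 0-999),
#' the first half is discarded as equilibration, and the stage is split into
#' training (snapshots 500-799), validation (800-899) and test (900-999) --
#' 300/100/100 snapshots per variant.
#'
#' @param train,validation,test Length-2 inclusive ranges of 0-based snapshot
#'   indices.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train = c(500L, 799L), validation = c(800L, 899L),
                       test = c(900L, 999L)) {
  parts <- list(train = as.integer(train), validation = as.integer(validation),
                test = as.integer(test))
  for (nm in names(parts)) {
    rg <- parts[[nm]]
    if (length(rg) != 2L || anyNA(rg) || rg[1L] > rg[2L] || rg[1L] < 0L) {
      abort(paste0("`", nm, "` must be a valid 0-based inclusive range."))
    }
  }
  idx <- lapply(parts, function(rg) seq.int(rg[1L], rg[2L]))
  if (length(unique(unlist(idx))) != length(unlist(idx))) {
    abort("Split ranges must be disjoint.")
  }
  structure(parts, class = "split_spec")
}

#' Proportional split for ensembles of any length
#'
#' Mirrors the default design at any trajectory length: the first half of the
#' snapshots is discarded as equilibration and the remaining stage is split
#' 3:1:1 into training, validation and test. With 1,000 snapshots this
#' reproduces [split_spec()]'s defaults exactly.
#'
#' @param n_snapshots Total snapshots per variant (must be a multiple of 10
#'   so the 3:1:1 stage split is exact).
#' @return A `split_spec`.
#' @export
proportional_split_spec <- function(n_snapshots) {
  n_snapshots <- as.integer(n_snapshots)
  if (n_snapshots < 10L || n_snapshots %% 10L != 0L) {
    abort("`n_snapshots` must be a positive multiple of 10.")
  }
  stage <- n_snapshots %/% 2L
  tr <- stage + (n_snapshots %/% 10L) * 3L
  va <- tr + n_snapshots %/% 10L
  split_spec(train = c(stage, tr - 1L),
             validation = c(tr, va - 1L),
             test = c(va, n_snapshots - 1L))
}

#' Materialize split row indices
#'
#' Converts the 0-based snapshot ranges of a [split_spec()] into 1-based row
#' indices (row `i` of a feature matrix is snapshot `i - 1`).
#'
#' @param n_snapshots Number of snapshots available per variant.
#' @param spec A `split_spec`.
#' @return List with integer vectors `train`, `validation`, `test`.
#' @export
make_splits <- function(n_snapshots, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  hi <- max(vapply(spec, function(rg) rg[2L], integer(1)))
  if (hi >= n_snapshots) {
    abort(paste0("Split needs snapshot ", hi, " but only 0..",
                 n_snapshots - 1L, " are available."))
  }
  lapply(unclass(spec), function(rg) seq.int(rg[1L] + 1L, rg[2L] + 1L))
}

#' Stack per-variant feature matrices into a design matrix
#'
#' Rows are stacked variant-major, snapshot-minor, keeping per-row variant
#' provenance so accuracies can be reported per variant.
#'
#' @param matrices Named list of standardized `feature_matrix` objects.
#' @param labels Named vector of class labels (`"I"` -> y = 0,
#'   `"II"` -> y = 1), one per variant; defaults to the labels carried by the
#'   matrices.
#' @param rows 1-based row indices selecting the snapshots of one split.
#' @return List with `X` (matrix), `y` (0/1), `variant` (character per row).
#' @export
assemble_dataset <- function(matrices, labels = NULL, rows) {
  check_matrix_list(matrices, standardized = TRUE)
  labels <- labels %||% vapply(matrices, function(m) m$class_label, character(1))
  missing_lab <- setdiff(names(matrices), names(labels))
  if (length(missing_lab) > 0L || anyNA(labels[names(matrices)])) {
    abort(paste0("Missing class label for variant(s): ",
                 paste(c(missing_lab,
                         names(matrices)[is.na(labels[names(matrices)])]),
                       collapse = ", ")))
  }
  if (!all(labels %in% c("I", "II"))) abort("Labels must be \"I\" or \"II\".")
  rows <- as.integer(rows)
  X <- do.call(rbind, lapply(matrices, function(m) m$values[rows, , drop = FALSE]))
  y <- rep(ifelse(labels[names(matrices)] == "II", 1L, 0L), each = length(rows))
  variant <- rep(names(matrices), each = length(rows))
  if (length(unique(y)) < 2L) {
    warn("Dataset contains a single class; it is unusable for training.")
  }
  rownames(X) <- NULL
  list(X = X, y = as.integer(y), variant = variant)
}

#' Hyperparameter grid search
#'
#' Fits the sparse-group-lasso logistic model for every (lambda, alpha) cell,
#' warm-starting along the descending lambda path within each alpha, and
#' scores each cell by overall validation accuracy (per-variant accuracies
#' and the nonzero-feature count are recorded too). The best cell maximizes
#' overall validation accuracy; ties are broken toward larger lambda (the
#' more regularized model), then toward the alpha closest to the balanced
#' mix 0.5 (remaining ties toward larger alpha). The balanced mix couples
#' group-level support recovery with within-group sparsity: a pure lasso
#' (alpha = 1) keeps an arbitrary minimal representative subset of equally
#' informative correlated features, and a pure group lasso (alpha = 0) keeps
#' whole groups without filtering uninformative members, both of which
#' mislead mechanistic attribution of the selected features.
#'
#' @param train,validation Datasets from [assemble_dataset()].
#' @param groups Group assignment per feature column.
#' @param weights Class weights; default inverse class frequency on the
#'   training labels.
#' @param lambda_grid,alpha_grid Hyperparameter grids; defaults are the
#'   log-uniform grid `10^(-4..3)` and the uniform grid `0, 0.1, ..., 1`.
#' @param tol,max_iter Solver settings used for the search fits.
#' @return Object of class `grid_search_result`: `results` tibble, `best`
#'   list with `lambda`, `alpha` and the fitted `model`.
#' @export
grid_search <- function(train, validation, groups,
                        weights = class_weights(train$y),
                        lambda_grid = 10^seq(-4, 3),
                        alpha_grid = seq(0, 1, by = 0.1),
                        tol = 1e-6, max_iter = 1000L) {
  if (length(lambda_grid) == 0L || length(alpha_grid) == 0L) {
    abort("Hyperparameter grids must be non-empty.")
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  results <- list()
  best <- NULL
  for (a in alpha_grid) {
    init <- NULL
    for (lam in lambda_grid) {
      fit <- tryCatch(
        fit_sgl(train$X, train$y, groups = groups, lambda = lam, alpha = a,
                weights = weights, tol = tol, max_iter = max_iter,
                init = init, warn_nonconverged = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) {
        results[[length(results) + 1L]] <- tibble::tibble(
          lambda = lam, alpha = a, failed = TRUE, accuracy = NA_real_,
          n_nonzero = NA_integer_, converged = NA,
          per_variant = list(NULL))
        next
      }
      init <- list(intercept = fit$intercept, beta = unname(fit$beta))
      pred <- predict(fit, validation$X, type = "class")
      acc <- accuracy(pred, validation$y)
      pv <- per_variant_accuracy(pred, validation$y, validation$variant)
      results[[length(results) + 1L]] <- tibble::tibble(
        lambda = lam, alpha = a, failed = FALSE, accuracy = acc,
        n_nonzero = sum(fit$beta != 0), converged = fit$converged,
        per_variant = list(pv$per_variant))
      better <- FALSE
      if (is.null(best) || acc > best$accuracy + 1e-12) {
        better <- TRUE
      } else if (abs(acc - best$accuracy) <= 1e-12) {
        if (lam > best$lambda) {
          better <- TRUE
        } else if (lam == best$lambda) {
          bal <- abs(a - 0.5) - abs(best$alpha - 0.5)
          better <- bal < -1e-12 || (abs(bal) <= 1e-12 && a > best$alpha)
        }
      }
      if (better) best <- list(lambda = lam, alpha = a, accuracy = acc, model = fit)
    }
  }
  if (is.null(best)) abort("Every grid cell failed.")
  structure(list(results = dplyr::bind_rows(results), best = best),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("<grid_search_result> ", nrow(x$results), " cells; best: lambda = ",
      x$best$lambda, ", alpha = ", x$best$alpha, " (validation accuracy ",
      format(x$best$accuracy, digits = 4), ", ",
      sum(x$best$model$beta != 0), " nonzero features)\n", sep = "")
  invisible(x)
}

#' @export
tidy.grid_search_result <- function(x, ...) {
  dplyr::select(x$results, -"per_variant")
}

#' Threshold-based feature selection
#'
#' Keeps features whose fitted `|beta|` exceeds the threshold (default
#' `10^-1.6`, the value balancing feature reduction against model accuracy),
#' ordered by descending `|beta|`, optionally capped at `max_features`.
#' The intercept is never selected. An empty selection is allowed but
#' flagged with a warning.
#'
#' @param model A fitted `sgl_model`.
#' @param threshold Positive magnitude threshold on coefficients.
#' @param max_features Optional cap on the number of selected features.
#' @return Tibble with `feature` (column name), `beta`, ordered by
#'   descending `|beta|`.
#' @export
select_features <- function(model, threshold = 10^-1.6, max_features = Inf) {
  stopifnot(inherits(model, "sgl_model"), threshold >= 0)
  b <- model$beta
  keep <- which(abs(b) > threshold)
  keep <- keep[order(abs(b[keep]), decreasing = TRUE)]
  if (length(keep) > max_features) keep <- keep[seq_len(max_features)]
  if (length(keep) == 0L) warn("No feature exceeds the selection threshold.")
  tibble::tibble(feature = names(b)[keep] %||% paste0("x", keep),
                 column = keep, beta = unname(b[keep]))
}

#' Per-variant accuracy and its median
#'
#' @param pred Predicted 0/1 labels.
#' @param y True labels.
#' @param variant Variant id per row.
#' @return List with `per_variant` (tibble: variant_id, n, accuracy) and
#'   `median` (median of the per-variant accuracies).
#' @export
per_variant_accuracy <- function(pred, y, variant) {
  stopifnot(length(pred) == length(y), length(y) == length(variant))
  tbl <- tibble::tibble(variant_id = variant, correct = pred == y) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                     .groups = "drop")
  empty <- setdiff(unique(variant), tbl$variant_id)
  if (length(empty) > 0L) warn(paste0("Variant(s) with zero rows excluded: ",
                                      paste(empty, collapse = ", ")))
  list(per_variant = tbl, median = median(tbl$accuracy))
}

#' Accuracy as a function of the number of features used
#'
#' For each feature count `k`: take the top-k features of the tuned model by
#' `|beta|`, refit without regularization on the training rows, and record
#' overall and median per-variant accuracy on the validation and test rows.
#' `k = 0` reports the majority-class baseline. `k` larger than the feature
#' pool is truncated with a warning. Fractions of the full feature pool are
#' emitted alongside counts.
#'
#' @param model Tuned `sgl_model` whose coefficients rank the features.
#' @param train,validation,test Datasets from [assemble_dataset()].
#' @param ks Integer vector of feature counts.
#' @param weights Class weights for the refits.
#' @param tol,max_iter Refit solver settings.
#' @return Tibble of class `accuracy_curve`.
#' @export
accuracy_vs_nfeatures <- function(model, train, validation, test,
                                  ks = c(0L, 1L, 2L, 3L, 5L, 8L, 11L, 15L,
                                         25L, 50L),
                                  weights = class_weights(train$y),
                                  tol = 1e-8, max_iter = 2000L) {
  stopifnot(inherits(model, "sgl_model"))
  p <- length(model$beta)
  ks <- sort(unique(as.integer(ks)))
  if (any(ks > p)) {
    warn(paste0("Feature counts above the pool size (", p, ") truncated."))
    ks <- unique(pmin(ks, p))
  }
  ord <- order(abs(model$beta), decreasing = TRUE)
  rows <- purrr::map_dfr(ks, function(k) {
    if (k == 0L) {
      maj <- as.integer(sum(train$y == 1L) >= sum(train$y == 0L))
      acc <- function(d) accuracy(rep(maj, length(d$y)), d$y)
      pv <- function(d) per_variant_accuracy(rep(maj, length(d$y)), d$y, d$variant)$median
      return(tibble::tibble(
        k = 0L, fraction = 0,
        validation_accuracy = acc(validation), validation_median = pv(validation),
        test_accuracy = acc(test), test_median = pv(test)))
    }
    cols <- ord[seq_len(k)]
    refit <- fit_unregularized(train$X[, cols, drop = FALSE], train$y,
                               weights = weights, tol = tol,
                               max_iter = max_iter)
    pv_val <- predict(refit, validation$X[, cols, drop = FALSE], type = "class")
    pv_test <- predict(refit, test$X[, cols, drop = FALSE], type = "class")
    tibble::tibble(
      k = k, fraction = k / p,
      validation_accuracy = accuracy(pv_val, validation$y),
      validation_median = per_variant_accuracy(pv_val, validation$y,
                                               validation$variant)$median,
      test_accuracy = accuracy(pv_test, test$y),
      test_median = per_variant_accuracy(pv_test, test$y, test$variant)$median)
  })
  structure(rows, class = c("accuracy_curve", class(rows)))
}

#' Attribute selected features to structural sites
#'
#' @param selection Selection tibble from [select_features()].
#' @param descriptors Feature descriptor table of the (standardized) matrix
#'   the model was trained on.
#' @return Tibble with one row per site (pocket, antagonist, interface):
#'   `n_selected`, `fraction`.
#' @export
attribute_sites <- function(selection, descriptors) {
  if (nrow(selection) == 0L) abort("Selection is empty; nothing to attribute.")
  idx <- match(selection$feature, feature_colnames(descriptors$feature_id))
  if (anyNA(idx)) {
    abort(paste0("Unknown feature id(s): ",
                 paste(selection$feature[is.na(idx)], collapse = ", ")))
  }
  tibble::tibble(site = factor(descriptors$site[idx], levels = site_levels)) |>
    dplyr::count(.data$site, .drop = FALSE, name = "n_selected") |>
    dplyr::mutate(site = as.character(.data$site),
                  fraction = .data$n_selected / sum(.data$n_selected))
}

#' Coefficient signs of the selected features, with interpretation
#'
#' Under the standardization convention (negative = closer than the initial
#' agonist-state structure), a negative coefficient on a distance feature
#' means the residue pair sits closer together in class II snapshots than in
#' class I.
#'
#' @param model Refit (or SGL) model whose coefficients are reported.
#' @param selection Selection tibble from [select_features()] (its rows must
#'   match the model's features when the model is a refit on the selection).
#' @param descriptors Feature descriptor table.
#' @return Tibble: feature, site, residue pair, coefficient, sign,
#'   interpretation.
#' @export
coefficient_sign_report <- function(model, selection, descriptors) {
  if (nrow(selection) == 0L) abort("Selection is empty.")
  coefs <- model$beta
  nm <- names(coefs) %||% selection$feature
  pos <- match(selection$feature, nm)
  if (anyNA(pos)) abort("Selection does not match the model's features.")
  idx <- match(selection$feature, feature_colnames(descriptors$feature_id))
  est <- unname(coefs[pos])
  tibble::tibble(
    feature = selection$feature,
    site = descriptors$site[idx],
    residue_a = descriptors$residue_a[idx],
    residue_b = descriptors$residue_b[idx],
    scope = descriptors$scope[idx],
    coefficient = est,
    sign = dplyr::case_when(est < 0 ~ "negative", est > 0 ~ "positive",
                            TRUE ~ "none"),
    interpretation = dplyr::case_when(
      est < 0 ~ "closer in class II than in class I",
      est > 0 ~ "farther in class II than in class I",
      TRUE ~ "no contribution")
  )
}

#' Raw distance differences between classes or named variants
#'
#' Reports, per feature, the mean unstandardized distance of each variant
#' over the given rows, the class-II-minus-class-I gap of the class means,
#' and the pairwise differences between every (class II, class I) variant
#' pair -- all in Angstrom.
#'
#' @param matrices Named list of **raw** (unstandardized) `feature_matrix`
#'   objects.
#' @param feature_ids Feature ids to report.
#' @param rows 1-based row indices to average over.
#' @param labels Optional named class labels; defaults to those carried by
#'   the matrices.
#' @return List with `per_variant`, `class_gap`, `pairwise` tibbles.
#' @export
class_distance_difference <- function(matrices, feature_ids, rows, labels = NULL) {
  check_matrix_list(matrices, standardized = FALSE)
  labels <- labels %||% vapply(matrices, function(m) m$class_label, character(1))
  ids <- matrices[[1L]]$descriptors$feature_id
  if (!all(feature_ids %in% ids)) {
    abort(paste0("Feature id(s) not found: ",
                 paste(setdiff(feature_ids, ids), collapse = ", ")))
  }
  cols <- match(feature_ids, ids)
  rows <- as.integer(rows)
  per_variant <- purrr::imap_dfr(matrices, function(m, v) {
    vals <- m$values[rows, cols, drop = FALSE]
    tibble::tibble(variant_id = v, class = unname(labels[[v]]),
                   feature_id = feature_ids,
                   mean_distance = unname(colMeans(vals)))
  })
  class_gap <- per_variant |>
    dplyr::group_by(.data$feature_id, .data$class) |>
    dplyr::summarise(mean = mean(.data$mean_distance), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "mean",
                       names_prefix = "class_") |>
    dplyr::mutate(gap = .data$class_II - .data$class_I)
  v2 <- per_variant[per_variant$class == "II", ]
  v1 <- per_variant[per_variant$class == "I", ]
  pairwise <- dplyr::inner_join(
    dplyr::rename(v2, variant_ii = "variant_id", mean_ii = "mean_distance"),
    dplyr::rename(v1, variant_i = "variant_id", mean_i = "mean_distance"),
    by = "feature_id", relationship = "many-to-many") |>
    dplyr::transmute(.data$feature_id, .data$variant_ii, .data$variant_i,
                     difference = .data$mean_ii - .data$mean_i)
  list(per_variant = per_variant, class_gap = class_gap, pairwise = pairwise)
}
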