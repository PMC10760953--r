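# Featurization: symmetry-averaged pairwise distances and standardization.

#' Compute raw distance features for one ensemble
#'
#' Every feature is a Euclidean distance between the anchor atoms (C-alpha or
#' C-beta, per the spec) of a residue pair, averaged over the two equivalent
#' chain orderings of the homodimer:
#'
#' * intra-chain features average the within-chain distance over the two
#'   chains;
#' * inter-chain features average `d(a@chain1, b@chain2)` and
#'   `d(a@chain2, b@chain1)`.
#'
#' The average makes every feature invariant to swapping the chain labels,
#' and distances are inherently invariant to rigid rotation/translation of
#' each snapshot. Residues lacking a C-beta coordinate fall back to C-alpha
#' (reported in the result's `fallback`); a residue missing entirely is a
#' fatal error naming the residue, chain and atom.
#'
#' @param ensemble A `snapshot_ensemble`.
#' @param spec A `feature_spec` from [build_feature_spec()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (snapshots x features numeric matrix, Angstrom), `descriptors`,
#'   `variant_id`, `class_label`, `standardized = FALSE`, `atom_kind`,
#'   `fallback`.
#' @export
compute_features <- function(ensemble, spec) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"), inherits(spec, "feature_spec"))
  desc <- spec$descriptors
  kind <- spec$atom_kind
  ch1 <- ensemble$chains[1L]
  ch2 <- ensemble$chains[2L]

  residues <- sort(unique(c(desc$residue_a, desc$residue_b)))
  r1 <- resolve_atoms(ensemble, ch1, residues, kind)
  r2 <- resolve_atoms(ensemble, ch2, residues, kind)
  idx1 <- setNames(r1$idx, residues)
  idx2 <- setNames(r2$idx, residues)
  fallback <- dplyr::bind_rows(r1$fallback, r2$fallback)

  ra <- as.character(desc$residue_a)
  rb <- as.character(desc$residue_b)
  intra <- desc$scope == "intra_chain"
  # first symmetric copy: (a@1, b@1) within-chain, (a@1, b@2) cross-chain
  p <- idx1[ra]
  q <- ifelse(intra, idx1[rb], idx2[rb])
  # second symmetric copy: (a@2, b@2) within-chain, (a@2, b@1) cross-chain
  r <- idx2[ra]
  s <- ifelse(intra, idx2[rb], idx1[rb])

  n_snap <- dim(ensemble$coords)[1L]
  arr <- ensemble$coords
  edist <- function(i, j) {
    dx <- arr[, i, 1L] - arr[, j, 1L]
    dy <- arr[, i, 2L] - arr[, j, 2L]
    dz <- arr[, i, 3L] - arr[, j, 3L]
    sqrt(dx * dx + dy * dy + dz * dz)
  }
  values <- matrix(0.5 * (edist(p, q) + edist(r, s)),
                   nrow = n_snap, ncol = length(p))
  if (anyNA(values)) abort("Non-finite feature values; ensemble has missing coordinates.")
  colnames(values) <- feature_colnames(desc$feature_id)
  rownames(values) <- seq_len(nrow(values)) - 1L

  structure(list(values = values, descriptors = desc,
                 variant_id = ensemble$variant_id,
                 class_label = ensemble$class_label,
                 standardized = FALSE, atom_kind = kind,
                 fallback = fallback),
            class = "feature_matrix")
}

feature_colnames <- function(ids) sprintf("f%04d", ids)

# column-wise sample standard deviations (n - 1 denominator)
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  out <- sqrt(pmax(colSums(x * x) - n * mu * mu, 0) / (n - 1L))
  setNames(out, colnames(x))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> variant ", x$variant_id, ": ", nrow(x$values),
      " snapshots x ", ncol(x$values), " ", x$atom_kind, " features",
      if (x$standardized) " (standardized)" else " (raw, Angstrom)", "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(variant_id = x$variant_id,
                   snapshot = seq_len(nrow(x$values)) - 1L),
    tibble::as_tibble(x$values)
  )
}

#' Fit standardization parameters from training snapshots
#'
#' Each feature is later standardized by subtracting its value in that
#' variant's initial snapshot (snapshot 0) and dividing by a single scale:
#' the sample standard deviation of the feature pooled across the training
#' snapshots of all variants. Features whose pooled scale falls below
#' `tol` Angstrom carry no information and are dropped with a warning.
#'
#' @param matrices Named list of raw `feature_matrix` objects (one per
#'   variant, identical descriptors).
#' @param training_rows Integer vector of 1-based row indices (row `i` is
#'   snapshot `i - 1`) used for the pooled scale; the same rows are used for
#'   every variant. At least two pooled rows are required.
#' @param tol Zero-variance tolerance in Angstrom.
#' @return Object of class `standardization_params`: list with `reference`
#'   (variant x feature matrix of snapshot-0 values), `scale`, `kept`
#'   (feature ids retained) and `dropped`.
#' @export
fit_standardization <- function(matrices, training_rows, tol = 1e-9) {
  check_matrix_list(matrices, standardized = FALSE)
  training_rows <- as.integer(training_rows)
  n_snap <- nrow(matrices[[1L]]$values)
  if (length(training_rows) == 0L || any(training_rows < 1L | training_rows > n_snap)) {
    abort("`training_rows` must be non-empty 1-based row indices within the ensembles.")
  }
  if (length(training_rows) * length(matrices) < 2L) {
    abort("At least two pooled training rows are required to estimate a scale.")
  }
  pooled <- do.call(rbind, lapply(matrices, function(m) m$values[training_rows, , drop = FALSE]))
  scale <- col_sds(pooled)
  reference <- do.call(rbind, lapply(matrices, function(m) m$values[1L, ]))
  rownames(reference) <- names(matrices)

  ids <- matrices[[1L]]$descriptors$feature_id
  dropped <- ids[scale < tol]
  if (length(dropped) > 0L) {
    warn(paste0(length(dropped), " feature(s) dropped for pooled scale < ", tol,
                " Angstrom: ", paste(head(dropped, 10L), collapse = ", "),
                if (length(dropped) > 10L) ", ..."))
  }
  structure(list(reference = reference, scale = scale,
                 kept = setdiff(ids, dropped), dropped = dropped, tol = tol),
            class = "standardization_params")
}

#' Standardize a feature matrix
#'
#' Applies `(value - reference[variant]) / scale` per feature, where the
#' reference is the variant's snapshot-0 value. After standardization the
#' snapshot-0 row is exactly zero, and a negative (positive) value means the
#' residue pair is closer (farther) than in the initial agonist-state
#' structure. Features dropped at fitting time are removed.
#'
#' @param matrix A raw `feature_matrix`.
#' @param params `standardization_params` from [fit_standardization()].
#' @return A standardized `feature_matrix`.
#' @export
standardize_features <- function(matrix, params) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(params, "standardization_params"))
  if (matrix$standardized) abort("Feature matrix is already standardized.")
  if (!matrix$variant_id %in% rownames(params$reference)) {
    abort(paste0("No standardization reference for variant '", matrix$variant_id, "'."))
  }
  if (ncol(matrix$values) != length(params$scale)) {
    abort("Descriptor mismatch between feature matrix and standardization parameters.")
  }
  keep <- matrix$descriptors$feature_id %in% params$kept
  ref <- params$reference[matrix$variant_id, keep]
  sc <- params$scale[keep]
  vals <- sweep(matrix$values[, keep, drop = FALSE], 2L, ref, `-`)
  vals <- sweep(vals, 2L, sc, `/`)
  out <- matrix
  out$values <- vals
  out$descriptors <- matrix$descriptors[keep, ]
  out$standardized <- TRUE
  out
}

check_matrix_list <- function(matrices, standardized = NULL) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    abort("`matrices` must be a non-empty named list of feature_matrix objects.")
  }
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    abort("`matrices` must be named by variant id.")
  }
  for (m in matrices) {
    if (!inherits(m, "feature_matrix")) abort("All elements must be feature_matrix objects.")
    if (!is.null(standardized) && m$standardized != standardized) {
      abort(paste0("Feature matrices must ", if (standardized) "" else "not ",
                   "be standardized here."))
    }
  }
  ref_ids <- matrices[[1L]]$descriptors$feature_id
  for (m in matrices) {
    if (!identical(m$descriptors$feature_id, ref_ids)) {
      abort("All feature matrices must share identical descriptors.")
    }
  }
  invisible(TRUE)
}

#' Summarize per-variant feature distributions
#'
#' Produces the per-variant location/spread summaries used to inspect
#' selected features (distribution plots by class), plus the class-level
#' mean difference (class II minus class I) per feature.
#'
#' @param matrices Named list of standardized `feature_matrix` objects.
#' @param feature_ids Feature ids to summarize.
#' @param rows 1-based row indices to summarize over (non-empty).
#' @param labels Optional named vector of class labels (`"I"`/`"II"`) per
#'   variant; defaults to the labels carried by the matrices.
#' @return List with `summary` (tibble: variant, class, feature_id, mean, sd,
#'   quantiles, degenerate flag) and `class_difference` (tibble: feature_id,
#'   mean_class_I, mean_class_II, difference).
#' @export
summarize_feature_distributions <- function(matrices, feature_ids, rows,
                                            labels = NULL) {
  check_matrix_list(matrices)
  rows <- as.integer(rows)
  if (length(rows) == 0L) abort("`rows` must be a non-empty index set.")
  labels <- labels %||% vapply(matrices, function(m) m$class_label, character(1))
  ids <- matrices[[1L]]$descriptors$feature_id
  if (!all(feature_ids %in% ids)) {
    abort(paste0("Unknown feature id(s): ",
                 paste(setdiff(feature_ids, ids), collapse = ", ")))
  }
  cols <- match(feature_ids, ids)
  summary <- purrr::imap_dfr(matrices, function(m, v) {
    vals <- m$values[rows, cols, drop = FALSE]
    qs <- apply(vals, 2L, quantile, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                names = FALSE)
    tibble::tibble(
      variant_id = v, class = unname(labels[[v]]), feature_id = feature_ids,
      mean = colMeans(vals), sd = apply(vals, 2L, sd),
      q05 = qs[1L, ], q25 = qs[2L, ], median = qs[3L, ],
      q75 = qs[4L, ], q95 = qs[5L, ],
      degenerate = length(rows) < 2L
    )
  })
  if (any(summary$degenerate)) {
    warn("Single-row summaries: standard deviations reported as 0 (degenerate).")
    summary$sd[is.na(summary$sd)] <- 0
  }
  class_diff <- summary |>
    dplyr::group_by(.data$feature_id, .data$class) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "mean",
                       names_prefix = "mean_class_") |>
    dplyr::mutate(difference = .data$mean_class_II - .data$mean_class_I)
  list(summary = summary, class_difference = class_diff)
}

#' Export a feature matrix as tab-separated text
#'
#' First column is the 0-based snapshot index; remaining columns are named by
#' feature id. If the matrix is standardized and `params_path` is given, the
#' standardization parameters (per-feature scale and this variant's
#' reference) are written alongside.
#'
#' @param matrix A `feature_matrix`.
#' @param path Output path for the value table.
#' @param params Optional `standardization_params`.
#' @param params_path Optional output path for the parameter table.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path, params = NULL, params_path = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  readr::write_tsv(as_tibble(matrix)[-1L], path)
  if (!is.null(params) && !is.null(params_path)) {
    keep <- feature_colnames(matrix$descriptors$feature_id)
    readr::write_tsv(tibble::tibble(
      feature_id = matrix$descriptors$feature_id,
      reference = params$reference[matrix$variant_id, match(keep, colnames(params$reference))],
      scale = params$scale[match(keep, names(params$scale))]
    ), params_path)
  }
  invisible(path)
}
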