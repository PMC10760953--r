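# Weighted logistic regression with a sparse group lasso penalty.
#
# Objective (minimized):
#   F(b0, b) = (1/n) sum_i w_{y_i} * CE_i(b0, b)
#              + lambda * [ (1 - alpha) * sum_l sqrt(p_l) ||b_(l)||_2
#                           + alpha * ||b||_1 ]
#              + (ridge / 2) * ||b||_2^2
# with CE_i the binary cross entropy of p_i = sigma(b0 + x_i . b). The data
# term is averaged over samples so the lambda grid keeps the same meaning
# across dataset sizes. The intercept is never penalized. Solved by monotone
# FISTA (accelerated proximal gradient with backtracking line search and
# restart on objective increase), deterministic zero initialization.

#' Overflow-safe logistic function
#'
#' @param z Numeric vector.
#' @return `1 / (1 + exp(-z))`, computed without overflow for large `|z|`.
#' @export
logistic <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

check_labels <- function(y) {
  if (length(y) == 0L) abort("Empty label vector.")
  if (!all(y %in% c(0, 1))) abort("Labels must be binary 0 (class I) / 1 (class II).")
  invisible(TRUE)
}

#' Default inverse-frequency class weights
#'
#' `w_c = n_total / (2 * n_c)`, so the minority class is up-weighted and a
#' balanced dataset gets unit weights.
#'
#' @param y Binary 0/1 label vector.
#' @return Named numeric vector `c(w0, w1)`.
#' @export
class_weights <- function(y) {
  check_labels(y)
  n <- length(y)
  n1 <- sum(y == 1)
  n0 <- n - n1
  if (n0 == 0L || n1 == 0L) abort("Both classes must be present to derive class weights.")
  c(w0 = n / (2 * n0), w1 = n / (2 * n1))
}

#' Weighted binary cross-entropy loss
#'
#' Mean over samples of `-(w1 * y * log(p) + w0 * (1 - y) * log(1 - p))` with
#' `p = logistic(intercept + X beta)`. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` inside the logarithms.
#'
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param intercept Scalar intercept.
#' @param X Numeric matrix of (standardized) features.
#' @param y Binary labels.
#' @param weights Length-2 vector `c(w0, w1)`; defaults to [class_weights()].
#' @return Non-negative scalar.
#' @export
weighted_cross_entropy <- function(beta, intercept, X, y,
                                   weights = class_weights(y)) {
  check_labels(y)
  if (nrow(X) != length(y)) abort("`X` rows must match `y` length.")
  p <- logistic(drop(intercept + X %*% beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  w <- ifelse(y == 1, weights[[2L]], weights[[1L]])
  -mean(w * (y * log(p) + (1 - y) * log1p(-p)))
}

group_sizes <- function(groups) {
  tab <- table(groups)
  setNames(as.numeric(tab), names(tab))
}

#' Sparse group lasso penalty
#'
#' `lambda * ((1 - alpha) * sum_l sqrt(p_l) * ||beta_(l)||_2 + alpha * ||beta||_1)`
#' where `p_l` is the size of group `l`. The intercept is not part of `beta`
#' here and is never penalized.
#'
#' @param beta Coefficient vector (no intercept).
#' @param groups Integer/character vector assigning each coefficient to one
#'   group.
#' @param lambda Overall regularization strength (>= 0).
#' @param alpha Balance in `[0, 1]` between feature sparsity (`alpha = 1`,
#'   pure lasso) and group sparsity (`alpha = 0`, pure group lasso).
#' @return Non-negative scalar.
#' @export
sgl_penalty <- function(beta, groups, lambda, alpha) {
  stopifnot(length(beta) == length(groups), lambda >= 0, alpha >= 0, alpha <= 1)
  if (lambda == 0) return(0)
  gnorm <- sqrt(rowsum(beta^2, groups, reorder = TRUE))
  psizes <- group_sizes(groups)[rownames(gnorm)]
  lambda * ((1 - alpha) * sum(sqrt(psizes) * gnorm) + alpha * sum(abs(beta)))
}

#' Proximal operator of the sparse group lasso penalty
#'
#' For each group: elementwise soft-threshold at `step * lambda * alpha`, then
#' group soft-threshold
#' `u <- max(0, 1 - step * lambda * (1 - alpha) * sqrt(p_l) / ||u||) * u`.
#' This is the exact proximal map of [sgl_penalty()] (the two penalties'
#' proximal operators compose in this order).
#'
#' @param v Coefficient vector (no intercept).
#' @inheritParams sgl_penalty
#' @param step Positive step size.
#' @return Numeric vector of the same length as `v`.
#' @export
prox_sgl <- function(v, step, groups, lambda, alpha) {
  stopifnot(step > 0, length(v) == length(groups))
  if (lambda == 0) return(v)
  u <- sign(v) * pmax(abs(v) - step * lambda * alpha, 0)
  if (alpha < 1) {
    gnorm <- sqrt(rowsum(u^2, groups, reorder = TRUE))
    psizes <- group_sizes(groups)[rownames(gnorm)]
    shrink <- pmax(0, 1 - step * lambda * (1 - alpha) * sqrt(psizes) /
                     pmax(drop(gnorm), .Machine$double.eps))
    u <- u * shrink[match(as.character(groups), rownames(gnorm))]
  }
  unname(u)
}

#' Fit a weighted logistic regression with sparse group lasso
#'
#' Minimizes the weighted cross entropy plus the sparse group lasso penalty
#' by monotone FISTA with backtracking line search, starting from zero
#' coefficients. Deterministic: no randomness is involved.
#'
#' @param X Numeric matrix of standardized features (no intercept column; the
#'   intercept is handled as an unpenalized coefficient).
#' @param y Binary 0/1 labels (at least two samples of each class).
#' @param groups Group assignment per column of `X`.
#' @param lambda,alpha Penalty hyperparameters, see [sgl_penalty()].
#' @param weights Length-2 class weights `c(w0, w1)`; default inverse class
#'   frequency.
#' @param tol Convergence tolerance on the relative objective change.
#' @param max_iter Iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE` and a warning.
#' @param ridge Optional small L2 term (used by the separation fallback of
#'   [fit_unregularized()]).
#' @param init Optional warm start: list with `intercept` and `beta`.
#' @param warn_nonconverged Emit a warning when the iteration cap is reached.
#' @param trace Record the objective value at every accepted iterate (in the
#'   `objective_trace` element of the result).
#' @return Object of class `sgl_model`.
#' @export
fit_sgl <- function(X, y, groups = rep(1L, ncol(X)), lambda = 0, alpha = 0.5,
                    weights = class_weights(y), tol = 1e-8, max_iter = 20000L,
                    ridge = 0, init = NULL, warn_nonconverged = TRUE,
                    trace = FALSE) {
  X <- as.matrix(X)
  check_labels(y)
  if (nrow(X) != length(y)) abort("`X` rows must match `y` length.")
  if (sum(y == 0) < 2L || sum(y == 1) < 2L) {
    abort("At least two samples per class are required.")
  }
  if (!all(is.finite(X))) abort("Non-finite feature values in `X`.")
  if (length(groups) != ncol(X)) abort("`groups` must assign every column of `X`.")
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1, ridge >= 0)

  n <- nrow(X)
  p <- ncol(X)
  wv <- ifelse(y == 1, weights[[2L]], weights[[1L]])

  smooth_obj <- function(z) {
    # weighted CE at linear predictor z, plus ridge added by caller
    pr <- pmin(pmax(logistic(z), 1e-12), 1 - 1e-12)
    -mean(wv * (y * log(pr) + (1 - y) * log1p(-pr)))
  }
  grad <- function(b0, b, z) {
    r <- wv * (logistic(z) - y) / n
    list(g0 = sum(r), g = drop(crossprod(X, r)) + ridge * b)
  }

  b <- init$beta %||% numeric(p)
  b0 <- init$intercept %||% 0
  zb <- drop(b0 + X %*% b)
  fb <- smooth_obj(zb) + (ridge / 2) * sum(b^2)
  Fb <- fb + sgl_penalty(b, groups, lambda, alpha)

  best <- list(b0 = b0, b = b, F = Fb)
  yb0 <- b0; yb <- b; zy <- zb
  t_k <- 1
  step <- 1
  converged <- FALSE
  iter <- 0L
  just_restarted <- FALSE
  obj_trace <- if (trace) Fb else NULL

  while (iter < max_iter) {
    iter <- iter + 1L
    fy <- smooth_obj(zy) + (ridge / 2) * sum(yb^2)
    gr <- grad(yb0, yb, zy)
    repeat {
      cand <- prox_sgl(yb - step * gr$g, step, groups, lambda, alpha)
      cand0 <- yb0 - step * gr$g0
      zc <- drop(cand0 + X %*% cand)
      fc <- smooth_obj(zc) + (ridge / 2) * sum(cand^2)
      db <- cand - yb
      db0 <- cand0 - yb0
      quad <- fy + sum(gr$g * db) + gr$g0 * db0 +
        (sum(db^2) + db0^2) / (2 * step)
      if (fc <= quad + 1e-12 * abs(quad) || step < 1e-12) break
      step <- step / 2
    }
    Fc <- fc + sgl_penalty(cand, groups, lambda, alpha)

    if (Fc > Fb) {
      if (just_restarted) {
        # a plain proximal-gradient step from the best iterate cannot
        # improve the objective: numerically stationary
        converged <- TRUE
        break
      }
      # monotone restart: re-anchor momentum at the last accepted iterate
      yb0 <- b0; yb <- b; zy <- zb
      t_k <- 1
      just_restarted <- TRUE
      next
    }
    just_restarted <- FALSE

    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    mom <- (t_k - 1) / t_next
    yb <- cand + mom * (cand - b)
    yb0 <- cand0 + mom * (cand0 - b0)
    zy <- drop(yb0 + X %*% yb)
    t_k <- t_next

    delta <- Fb - Fc
    b <- cand; b0 <- cand0; zb <- zc
    Fb <- Fc
    if (trace) obj_trace <- c(obj_trace, Fb)
    if (Fb < best$F) best <- list(b0 = b0, b = b, F = Fb)
    if (delta <= tol * max(1, abs(Fb))) {
      converged <- TRUE
      break
    }
    step <- step * 1.25
  }

  if (!converged && warn_nonconverged) {
    warn(paste0("fit_sgl did not converge in ", max_iter,
                " iterations (relative objective change tol = ", tol, ")."))
  }
  out <- new_sgl_model(intercept = best$b0, beta = best$b, colnames = colnames(X),
                       groups = groups, lambda = lambda, alpha = alpha,
                       weights = weights, ridge = ridge, converged = converged,
                       n_iter = iter, final_loss = best$F)
  if (trace) out$objective_trace <- obj_trace
  out
}

new_sgl_model <- function(intercept, beta, colnames, groups, lambda, alpha,
                          weights, ridge, converged, n_iter, final_loss,
                          separation = FALSE) {
  if (!is.finite(final_loss)) abort("Final loss is not finite.")
  structure(list(intercept = intercept,
                 beta = setNames(beta, colnames),
                 groups = groups, lambda = lambda, alpha = alpha,
                 weights = c(w0 = unname(weights[[1L]]), w1 = unname(weights[[2L]])),
                 ridge = ridge, converged = converged, n_iter = n_iter,
                 final_loss = final_loss, separation = separation),
            class = "sgl_model")
}

#' Refit a weighted logistic regression without sparsity regularization
#'
#' Maximum-likelihood (weighted) logistic fit on a set of selected features,
#' i.e. [fit_sgl()] at `lambda = 0`. If complete separation is detected (all
#' fitted margins have the correct sign and the coefficients have grown very
#' large, so the MLE diverges), the model is refit with a tiny ridge penalty
#' (`1e-8`) and flagged via `separation = TRUE`.
#'
#' @param X Matrix of the selected feature columns (at least one).
#' @inheritParams fit_sgl
#' @return An `sgl_model` with `lambda = 0`.
#' @export
fit_unregularized <- function(X, y, weights = class_weights(y), tol = 1e-8,
                              max_iter = 20000L) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) abort("At least one selected feature is required.")
  fit <- fit_sgl(X, y, groups = rep(1L, ncol(X)), lambda = 0,
                 weights = weights, tol = tol, max_iter = max_iter,
                 warn_nonconverged = FALSE)
  z <- drop(fit$intercept + X %*% fit$beta)
  separated <- all((2 * y - 1) * z > 0) && max(abs(fit$beta)) > 10
  if (separated) {
    fit2 <- fit_sgl(X, y, groups = rep(1L, ncol(X)), lambda = 0,
                    weights = weights, tol = tol, max_iter = max_iter,
                    ridge = 1e-8, warn_nonconverged = FALSE)
    fit2$separation <- TRUE
    return(fit2)
  }
  if (!fit$converged) {
    warn(paste0("Unregularized refit did not converge in ", max_iter, " iterations."))
  }
  fit
}

#' Predict from a fitted model
#'
#' @param object An `sgl_model`.
#' @param newdata Matrix whose columns match the model's features, or a
#'   standardized `feature_matrix`.
#' @param type `"prob"` for probabilities of class II, `"class"` for hard
#'   0/1 labels (`p > 0.5` is labeled 1; the tie `p = 0.5` is labeled 0,
#'   deterministically).
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer labels.
#' @export
predict.sgl_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta)) {
    abort(paste0("Column mismatch: model has ", length(object$beta),
                 " features, newdata has ", ncol(newdata), "."))
  }
  if (!is.null(colnames(newdata)) && !is.null(names(object$beta)) &&
      !identical(colnames(newdata), names(object$beta))) {
    abort("Column names of `newdata` do not match the model's features.")
  }
  p <- logistic(drop(object$intercept + newdata %*% object$beta))
  if (type == "prob") p else as.integer(p > 0.5)
}

#' Classification accuracy
#'
#' @param labels Predicted 0/1 labels.
#' @param truth True 0/1 labels.
#' @return Fraction of exact matches in `[0, 1]`.
#' @export
accuracy <- function(labels, truth) {
  if (length(labels) == 0L || length(labels) != length(truth)) {
    abort("`labels` and `truth` must be non-empty and of equal length.")
  }
  mean(labels == truth)
}

#' @export
print.sgl_model <- function(x, ...) {
  cat("<sgl_model> ", length(x$beta), " features, lambda = ", x$lambda,
      ", alpha = ", x$alpha, ", ", sum(x$beta != 0), " nonzero\n",
      "  converged: ", x$converged, " (", x$n_iter, " iterations), objective ",
      format(x$final_loss, digits = 6),
      if (x$separation) ", separation fallback (ridge 1e-8)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sgl_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$beta) %||% paste0("x", seq_along(x$beta))),
    estimate = c(x$intercept, unname(x$beta)),
    group = c(NA, as.character(x$groups))
  )
}

#' @export
glance.sgl_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, alpha = x$alpha,
                 n_features = length(x$beta), n_nonzero = sum(x$beta != 0),
                 converged = x$converged, n_iter = x$n_iter,
                 objective = x$final_loss, separation = x$separation)
}

#' Serialize a fitted model as structured text
#'
#' Key-value text with full (17 significant digit) precision so that a
#' read-back model reproduces predictions exactly.
#'
#' @param model An `sgl_model`.
#' @param path File path.
#' @return `path` invisibly; `read_sgl_model()` returns the model.
#' @export
write_sgl_model <- function(model, path) {
  stopifnot(inherits(model, "sgl_model"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# dimerclass sgl_model v1",
    paste0("intercept\t", num(model$intercept)),
    paste0("lambda\t", num(model$lambda)),
    paste0("alpha\t", num(model$alpha)),
    paste0("ridge\t", num(model$ridge)),
    paste0("w0\t", num(model$weights[["w0"]])),
    paste0("w1\t", num(model$weights[["w1"]])),
    paste0("converged\t", model$converged),
    paste0("separation\t", model$separation),
    paste0("n_iter\t", model$n_iter),
    paste0("final_loss\t", num(model$final_loss)),
    "coefficients\tname\tgroup\tvalue",
    paste0("coef\t", names(model$beta) %||% paste0("x", seq_along(model$beta)),
           "\t", model$groups, "\t", num(unname(model$beta)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sgl_model
#' @export
read_sgl_model <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1L], "# dimerclass sgl_model v1")) {
    abort("Not a dimerclass sgl_model file.")
  }
  kv <- strsplit(lines[-1L], "\t", fixed = TRUE)
  get1 <- function(key) {
    hit <- kv[vapply(kv, function(x) x[1L] == key, logical(1))]
    if (length(hit) != 1L) abort(paste0("Missing field '", key, "'."))
    hit[[1L]][2L]
  }
  coefs <- kv[vapply(kv, function(x) x[1L] == "coef", logical(1))]
  beta <- vapply(coefs, function(x) as.numeric(x[4L]), numeric(1))
  nms <- vapply(coefs, function(x) x[2L], character(1))
  grp <- vapply(coefs, function(x) x[3L], character(1))
  grp_i <- suppressWarnings(as.integer(grp))
  new_sgl_model(
    intercept = as.numeric(get1("intercept")), beta = beta, colnames = nms,
    groups = if (anyNA(grp_i)) grp else grp_i,
    lambda = as.numeric(get1("lambda")), alpha = as.numeric(get1("alpha")),
    weights = c(as.numeric(get1("w0")), as.numeric(get1("w1"))),
    ridge = as.numeric(get1("ridge")),
    converged = as.logical(get1("converged")),
    n_iter = as.integer(get1("n_iter")),
    final_loss = as.numeric(get1("final_loss")),
    separation = as.logical(get1("separation")))
}
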