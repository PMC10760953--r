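test_that("logistic is exact, symmetric and overflow-safe", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(1000), 1)
  expect_equal(logistic(-1000), 0)
  z <- seq(-30, 30, by = 0.7)
  expect_equal(logistic(-z), 1 - logistic(z))
})

test_that("weighted cross entropy has its closed-form anchors", {
  X <- matrix(0, 10, 2)
  y <- rep(c(0L, 1L), 5)
  expect_equal(weighted_cross_entropy(c(0, 0), 0, X, y, weights = c(1, 1)),
               log(2))
  expect_equal(weighted_cross_entropy(c(0, 0), 0, X, y, weights = c(2, 2)),
               2 * log(2))  # linear in the weights
  # near-perfect confident predictions drive the loss toward 0
  X2 <- matrix(ifelse(y == 1, 40, -40), ncol = 1)
  expect_lt(weighted_cross_entropy(1, 0, X2, y), 1e-10)
  expect_error(weighted_cross_entropy(c(0, 0), 0, X, c(y[-1], 2)), "binary")
})

test_that("sgl penalty reduces to its limiting forms", {
  b <- c(3, 4, 0, 0)
  g <- rep(1L, 4)
  expect_equal(sgl_penalty(rep(0, 4), g, lambda = 2, alpha = 0.3), 0)
  expect_equal(sgl_penalty(b, g, lambda = 2, alpha = 1), 2 * sum(abs(b)))
  # one group of size 4, alpha = 0: lambda * sqrt(4) * ||b|| = 10 lambda
  expect_equal(sgl_penalty(b, g, lambda = 2, alpha = 0), 2 * 10)
  # additive over groups
  g2 <- c(1L, 1L, 2L, 2L)
  b2 <- c(3, 4, 1, 2)
  expect_equal(sgl_penalty(b2, g2, 1, 0),
               sqrt(2) * 5 + sqrt(2) * sqrt(5))
})

test_that("prox_sgl matches its closed-form pieces", {
  expect_equal(prox_sgl(c(1, -2), 0.5, c(1L, 1L), lambda = 0, alpha = 0.5),
               c(1, -2))
  # pure lasso soft threshold: 0.5 - 0.2 = 0.3
  expect_equal(prox_sgl(0.5, 1, 1L, lambda = 0.2, alpha = 1), 0.3)
  # pure group shrinkage on (3, 4): threshold step*lambda*sqrt(2)
  v <- c(3, 4)
  thr <- 2.5 / sqrt(2)   # so that step*lambda*(1-alpha)*sqrt(p) = 2.5
  out <- prox_sgl(v, 1, c(1L, 1L), lambda = thr, alpha = 0)
  expect_equal(out, (1 - 2.5 / 5) * v)
  thr2 <- 5 / sqrt(2)
  expect_equal(prox_sgl(v, 1, c(1L, 1L), lambda = thr2, alpha = 0), c(0, 0))
})

test_that("prox_sgl agrees with brute-force numerical proximal minimization", {
  # The prox objective 0.5||u - v||^2 + step * penalty(u) is 1-strongly
  # convex, so ||u1 - u2|| <= sqrt(2 (F(u1) - F*)) + sqrt(2 (F(u2) - F*)).
  # We require the prox to (a) never be beaten by restarted Nelder-Mead and
  # (b) agree with it to 1e-6 up to the certified suboptimality of the
  # numerical minimizer.
  set.seed(7)
  for (i in 1:8) {
    p <- sample(2:6, 1)
    grp <- sort(sample(1:2, p, replace = TRUE))
    v <- rnorm(p, sd = 1.5)
    st <- runif(1, 0.1, 2)
    lam <- runif(1, 0.05, 1)
    al <- runif(1)
    obj <- function(u) 0.5 * sum((u - v)^2) + st * sgl_penalty(u, grp, lam, al)
    mine <- prox_sgl(v, st, grp, lam, al)
    best <- NULL
    for (s in list(v, rep(0, p))) {
      o <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-16))
      for (r in 1:6) o <- optim(o$par, obj, method = "Nelder-Mead",
                                control = list(maxit = 50000, reltol = 1e-16))
      if (is.null(best) || o$value < best$value) best <- o
    }
    expect_lte(obj(mine), best$value + 1e-9)
    slack <- sqrt(2 * max(0, best$value - obj(mine)))
    expect_lt(max(abs(mine - best$par)), 1e-6 + slack)
  }
})

test_that("fit_sgl at lambda = 0 matches the reference logistic optimizer", {
  for (seed in 1:5) {
    d <- random_logistic_data(seed)
    ref <- glm_oracle(d$X, d$y)
    fit <- fit_sgl(d$X, d$y, lambda = 0, tol = 1e-12, max_iter = 50000)
    expect_lt(max(abs(c(fit$intercept, unname(fit$beta)) - ref)), 1e-4)
    expect_true(fit$converged)
  }
})

test_that("a huge lambda zeroes every penalized coefficient", {
  d <- random_logistic_data(3, n = 200, p = 8)
  w <- c(w0 = 1, w1 = 2)
  fit <- fit_sgl(d$X, d$y, groups = rep(1:2, each = 4), lambda = 1e3,
                 alpha = 0.5, weights = w)
  expect_identical(sum(fit$beta != 0), 0L)
  # stationarity of the intercept: logit of the weighted positive fraction
  expect_equal(fit$intercept,
               qlogis(2 * sum(d$y) / (2 * sum(d$y) + sum(d$y == 0))),
               tolerance = 1e-4)
})

test_that("the objective trace is non-increasing (monotone solver)", {
  d <- random_logistic_data(9)
  fit <- fit_sgl(d$X, d$y, groups = rep(1:2, c(2, 3)), lambda = 0.05,
                 alpha = 0.4, trace = TRUE)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
})

test_that("the returned solution satisfies subgradient optimality", {
  d <- random_logistic_data(13)
  lam <- 0.03; al <- 0.6
  grp <- rep(1:2, c(2, 3))
  fit <- fit_sgl(d$X, d$y, groups = grp, lambda = lam, alpha = al, tol = 1e-12,
                 max_iter = 50000)
  # numerical gradient of the smooth part at the solution
  w <- class_weights(d$y)
  f <- function(b) weighted_cross_entropy(b, fit$intercept, d$X, d$y, w)
  g <- numeric(5)
  h <- 1e-6
  for (j in 1:5) {
    e <- numeric(5); e[j] <- h
    g[j] <- (f(unname(fit$beta) + e) - f(unname(fit$beta) - e)) / (2 * h)
  }
  for (j in 1:5) {
    bj <- unname(fit$beta[j])
    gl <- grp[j]
    bl <- unname(fit$beta[grp == gl])
    pl <- sum(grp == gl)
    if (bj != 0) {
      sub <- g[j] + lam * al * sign(bj) +
        lam * (1 - al) * sqrt(pl) * bj / sqrt(sum(bl^2))
      expect_lt(abs(sub), 1e-4)
    } else {
      # zero coordinate: |smooth gradient| bounded by available threshold
      expect_lt(abs(g[j]), lam * al + lam * (1 - al) * sqrt(pl) + 1e-4)
    }
  }
})

test_that("permuting features (with group bookkeeping) leaves predictions unchanged", {
  d <- random_logistic_data(21)
  grp <- c(1L, 1L, 2L, 2L, 2L)
  fit <- fit_sgl(d$X, d$y, groups = grp, lambda = 0.02, alpha = 0.5, tol = 1e-10)
  set.seed(2)
  perm <- sample.int(5)
  fit2 <- fit_sgl(d$X[, perm], d$y, groups = grp[perm], lambda = 0.02,
                  alpha = 0.5, tol = 1e-10)
  expect_equal(predict(fit2, d$X[, perm]), predict(fit, d$X), tolerance = 1e-6)
})

test_that("warm starts converge to the cold-start solution", {
  d <- random_logistic_data(31)
  grp <- rep(1:2, c(2, 3))
  cold <- fit_sgl(d$X, d$y, groups = grp, lambda = 0.05, alpha = 0.5, tol = 1e-12)
  pre <- fit_sgl(d$X, d$y, groups = grp, lambda = 0.5, alpha = 0.5, tol = 1e-12)
  warm <- fit_sgl(d$X, d$y, groups = grp, lambda = 0.05, alpha = 0.5, tol = 1e-12,
                  init = list(intercept = pre$intercept, beta = unname(pre$beta)))
  expect_equal(unname(warm$beta), unname(cold$beta), tolerance = 1e-5)
})

test_that("predict applies the deterministic tie rule and monotonicity", {
  X <- matrix(c(1, -1, 0), ncol = 1, dimnames = list(NULL, "f1"))
  zero <- fit_sgl(matrix(rnorm(20), 10, 2), rep(c(0L, 1L), 5), lambda = 1e3)
  expect_true(all(predict(zero, matrix(0, 4, 2)) == 0.5))
  expect_true(all(predict(zero, matrix(0, 4, 2), type = "class") == 0L))
  # hand-computed two-feature case
  m <- structure(list(intercept = 0.5, beta = c(a = 1, b = -2),
                      groups = c(1L, 1L), lambda = 0, alpha = 0.5,
                      weights = c(w0 = 1, w1 = 1), ridge = 0, converged = TRUE,
                      n_iter = 1L, final_loss = 0.1, separation = FALSE),
                 class = "sgl_model")
  Xh <- matrix(c(1, 0.5, 2, -1), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(m, Xh), plogis(0.5 + c(1 * 1 + 2 * -2, 0.5 - 2 * -1)))
  # increasing a positively weighted feature never decreases p
  X1 <- matrix(seq(-2, 2, length.out = 9), ncol = 1, dimnames = list(NULL, "a"))
  m1 <- m; m1$beta <- c(a = 1); m1$groups <- 1L
  expect_false(is.unsorted(predict(m1, X1)))
  expect_error(predict(m, Xh[, 1, drop = FALSE]), "mismatch")
})

test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracy(c(1, 0, 1, 1), c(1, 0, 0, 1)), 0.75)
  expect_equal(accuracy(rep(1, 3), rep(1, 3)), 1)
  expect_equal(accuracy(rep(1, 3), rep(0, 3)), 0)
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
})

test_that("fit_unregularized handles uninformative and separable designs", {
  set.seed(4)
  y <- rep(c(0L, 1L), each = 30)
  X <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "f1"))
  fit <- fit_unregularized(X, y, weights = c(1, 1))
  ref <- glm_oracle(X, y, weights = c(1, 1))
  expect_lt(abs(fit$intercept - ref[1]), 1e-4)
  expect_lt(abs(unname(fit$beta) - ref[2]), 1e-4)
  # complete separation triggers the ridge fallback flag
  Xs <- matrix(ifelse(y == 1, 1, -1) + rnorm(60, sd = 0.01), ncol = 1,
               dimnames = list(NULL, "f1"))
  fit_sep <- suppressWarnings(fit_unregularized(Xs, y, max_iter = 20000))
  expect_true(fit_sep$separation)
  expect_equal(fit_sep$ridge, 1e-8)
  expect_error(fit_unregularized(X[, 0, drop = FALSE], y), "least one")
})

test_that("model serialization round-trips exactly", {
  d <- random_logistic_data(17)
  fit <- fit_sgl(d$X, d$y, groups = rep(1:2, c(2, 3)), lambda = 0.07, alpha = 0.3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_sgl_model(fit, path)
  back <- read_sgl_model(path)
  expect_identical(back$beta, fit$beta)
  expect_identical(back$intercept, fit$intercept)
  expect_identical(back$weights, fit$weights)
  expect_identical(predict(back, d$X), predict(fit, d$X))
})
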