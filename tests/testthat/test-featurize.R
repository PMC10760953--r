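test_that("features are symmetry-averaged over the two chain orderings", {
  # break the C2 symmetry of the toy system so the two copies differ
  tb <- toy_coords()
  tb$x[tb$chain == "B" & tb$residue == 11] <- -6   # was -3
  ens <- snapshot_ensemble(tb)
  spec <- toy_spec()
  fm <- compute_features(ens, spec)
  d <- spec$descriptors
  pos <- function(ch, r) unname(get_atom(ens, 0, ch, r, "CA"))
  for (i in seq_len(nrow(d))) {
    a <- d$residue_a[i]; b <- d$residue_b[i]
    expected <- if (d$scope[i] == "intra_chain") {
      (sqrt(sum((pos("A", a) - pos("A", b))^2)) +
       sqrt(sum((pos("B", a) - pos("B", b))^2))) / 2
    } else {
      (sqrt(sum((pos("A", a) - pos("B", b))^2)) +
       sqrt(sum((pos("B", a) - pos("A", b))^2))) / 2
    }
    expect_equal(unname(fm$values[1, i]), expected)
  }
  # chain relabeling leaves every feature unchanged
  tb2 <- dplyr::mutate(tb, chain = ifelse(.data$chain == "A", "B", "A"))
  fm2 <- compute_features(snapshot_ensemble(tb2), spec)
  expect_equal(fm$values, fm2$values)
})

test_that("an inter-chain pair with symmetric distances 3 and 5 averages to 4", {
  tb <- tibble::tibble(
    snapshot = 0L,
    chain = c("A", "A", "B", "B"),
    residue = c(1L, 11L, 1L, 11L),
    atom = "CA",
    x = c(0, 3, 10, 5),   # d(1A,11B) = 5, d(1B,11A) = 3... see below
    y = 0, z = 0
  )
  patches <- list(pocket = list(), antagonist = NULL,
                  interface = list(list(name = "g",
                                        a = residue_patch("a", 1L),
                                        b = residue_patch("b", 11L))))
  spec <- build_feature_spec("CA", patches = patches, quiet = TRUE)
  fm <- compute_features(snapshot_ensemble(tb), spec)
  # d(res1@A, res11@B) = |0 - 5| = 5; d(res1@B, res11@A) = |10 - 3| = 7 -> 6
  expect_equal(unname(fm$values[1, 1]), 6)
})

test_that("features are invariant to rigid rotation and translation", {
  spec <- ca_spec_cache
  fm <- compute_features(tpl_cache, spec)
  set.seed(11)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  moved <- tpl_cache
  moved$coords[1, , ] <- tpl_cache$coords[1, , ] %*% (Rx %*% Rz) +
    matrix(c(5, -3, 11), nrow(tpl_cache$atoms), 3, byrow = TRUE)
  fm2 <- compute_features(moved, spec)
  expect_lt(max(abs(fm2$values - fm$values)), 1e-9)
})

test_that("standardization matches its definition and is guarded", {
  # two variants, 3 snapshots, one feature pair; hand-checkable numbers
  mk <- function(vals, id) {
    tb <- purrr::map_dfr(seq_along(vals) - 1L, function(s) {
      tibble::tibble(snapshot = s, chain = c("A", "A", "B", "B"),
                     residue = c(1L, 11L, 1L, 11L), atom = "CA",
                     x = c(0, vals[s + 1L], 10, 10 - vals[s + 1L]),
                     y = 0, z = 0)
    })
    compute_features(snapshot_ensemble(tb, variant_id = id), toy_minimal_spec)
  }
  patches <- list(pocket = setNames(list(residue_patch("a", 1L),
                                         residue_patch("b", 11L)), c("a", "b")),
                  antagonist = NULL, interface = NULL)
  toy_minimal_spec <- build_feature_spec("CA", patches = patches, quiet = TRUE)
  # intra-chain distance equals vals (both chains identical by construction)
  m1 <- mk(c(10, 1, 3), "v1")
  m2 <- mk(c(10, 2, 4), "v2")
  params <- fit_standardization(list(v1 = m1, v2 = m2), training_rows = 2:3)
  # pooled sample sd of {1, 3, 2, 4}
  expect_equal(unname(params$scale[1]), sd(c(1, 3, 2, 4)))
  expect_equal(unname(params$reference["v1", 1]), 10)
  s1 <- standardize_features(m1, params)
  expect_equal(unname(s1$values[1, 1]), 0)            # snapshot 0 row is zero
  expect_equal(unname(s1$values[2, 1]), (1 - 10) / sd(c(1, 3, 2, 4)))
  expect_true(s1$values[2, 1] < 0)                    # closer => negative
  expect_error(standardize_features(s1, params), "already standardized")
  # single-variant, two training rows with values 1 and 3 -> sample sd
  p2 <- fit_standardization(list(v1 = m1), training_rows = 2:3)
  expect_equal(unname(p2$scale[1]), sd(c(1, 3)))
})

test_that("zero-variance features are dropped with a warning", {
  ens <- toy_ensemble(n_snap = 3L)  # all snapshots identical
  fm <- compute_features(ens, toy_spec())
  expect_warning(
    params <- fit_standardization(list(toy = fm), training_rows = 2:3),
    "dropped")
  expect_identical(length(params$kept), 0L)
})

test_that("standardization scale ignores non-training rows (no leakage)", {
  coh <- scaled_cohort(5, n_snapshots = 40L)
  spec <- toy_spec()  # cheap features
  raw <- lapply(coh$ensembles[1:2], compute_features, spec = ca_spec_cache)
  params <- fit_standardization(raw, training_rows = 21:30)
  raw2 <- raw
  raw2[[1]]$values[31:40, ] <- raw2[[1]]$values[31:40, ] + 100
  params2 <- fit_standardization(raw2, training_rows = 21:30)
  expect_identical(params$scale, params2$scale)
})

test_that("distribution summaries report class differences with planted sign", {
  eff <- default_planted_effects()
  coh <- scaled_cohort(7, n_snapshots = 60L)
  raw <- lapply(coh$ensembles, compute_features, spec = ca_spec_cache)
  params <- fit_standardization(raw, training_rows = 31:48)
  std <- lapply(raw, standardize_features, params = params)
  res <- summarize_feature_distributions(std, coh$ground_truth$feature_id,
                                         rows = 49:60)
  expect_identical(nrow(res$summary), 7L * nrow(eff))
  gap <- res$class_difference
  gt <- coh$ground_truth
  expect_setequal(gap$feature_id, gt$feature_id)
  m <- match(gt$feature_id, gap$feature_id)
  expect_true(all(sign(gap$difference[m]) == sign(gt$delta)))
  # single snapshot: sd degenerate, flagged
  expect_warning(
    one <- summarize_feature_distributions(std, gap$feature_id[1], rows = 50L),
    "degenerate")
  expect_true(all(one$summary$sd == 0))
  expect_error(summarize_feature_distributions(std, gap$feature_id[1],
                                               rows = integer(0)), "non-empty")
})
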