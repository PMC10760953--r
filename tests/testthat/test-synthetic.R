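test_that("the template dimer satisfies its construction contract", {
  spec <- ca_spec_cache
  fm <- compute_features(tpl_cache, spec)
  expect_identical(nrow(fm$fallback), 0L)          # no missing atoms
  expect_true(all(fm$values > 1))                  # every feature > 1 Angstrom
  # exact two-fold symmetry: chain swap leaves raw features unchanged
  tb <- tibble::as_tibble(tpl_cache)
  tb$chain <- ifelse(tb$chain == "A", "B", "A")
  fm2 <- compute_features(snapshot_ensemble(tb), spec)
  expect_equal(fm2$values, fm$values)
  # deterministic
  expect_identical(template_dimer()$coords, tpl_cache$coords)
})

test_that("zero noise and no effects reproduce the template in every snapshot", {
  ss <- suppressWarnings(synthetic_spec(
    variants = tibble::tibble(variant_id = "v", class = "I"),
    n_snapshots = 4L, noise_sd = 0, ar1_rho = 0,
    effects = default_planted_effects()[0, ]))
  ens <- suppressWarnings(simulate_ensemble(ss, "v", seed = 1,
                                            template = tpl_cache))
  for (s in 1:4) expect_equal(ens$coords[s, , ], tpl_cache$coords[1, , ])
})

test_that("a single planted effect shifts exactly the targeted feature", {
  eff <- tibble::tibble(residue_a = 430L, residue_b = 462L,
                        scope = "inter_chain", atom_kind = "CA",
                        delta = -6.4, onset_fraction = 0)
  ss <- synthetic_spec(variants = tibble::tibble(variant_id = c("c1", "c2"),
                                                 class = c("I", "II")),
                       n_snapshots = 4L, noise_sd = 0, ar1_rho = 0,
                       effects = eff)
  ens <- simulate_ensemble(ss, "c2", seed = 1, template = tpl_cache)
  fm <- compute_features(ens, ca_spec_cache)
  base <- compute_features(tpl_cache, ca_spec_cache)$values[1, ]
  shift <- sweep(fm$values, 2L, base)
  id <- dimerclass:::match_planted_feature(eff, ca_spec_cache)
  expect_equal(unname(shift[1, id]), 0)                     # snapshot 0: template
  expect_equal(unname(shift[2:4, id]), rep(-6.4, 3))        # exact from snapshot 1
  expect_lt(max(abs(shift[, -id])), 1e-8)                   # no other feature moves
})

test_that("default effects are realized exactly and ramp to the onset", {
  coh_spec <- suppressWarnings(synthetic_spec(
    variants = tibble::tibble(variant_id = "x", class = "II"),
    n_snapshots = 11L, noise_sd = 0, ar1_rho = 0))
  ens <- suppressWarnings(simulate_ensemble(coh_spec, "x", seed = 1,
                                            template = tpl_cache))
  fm <- compute_features(ens, ca_spec_cache)
  base <- compute_features(tpl_cache, ca_spec_cache)$values[1, ]
  eff <- default_planted_effects()
  ids <- vapply(seq_len(nrow(eff)), function(i) {
    dimerclass:::match_planted_feature(eff[i, ], ca_spec_cache)
  }, integer(1))
  # onset 0.5 of 11 snapshots: full delta from snapshot 5 onward; half at
  # snapshot 2.5 -> check end state and monotone ramp
  shift_end <- fm$values[11, ids] - base[ids]
  expect_equal(unname(shift_end), eff$delta, tolerance = 1e-8)
  expect_equal(unname(fm$values[7, ids] - base[ids]), eff$delta,
               tolerance = 1e-8)
  ramp_path <- fm$values[1:6, ids[1]] - base[ids[1]]
  expect_true(all(diff(ramp_path) < 0))
  # standardized planted value equals delta / scale after onset
  params <- suppressWarnings(fit_standardization(list(x = fm), training_rows = 2:7))
  std <- standardize_features(fm, params)
  keep_col <- match(ids[1], std$descriptors$feature_id)
  expect_equal(unname(std$values[11, keep_col]),
               eff$delta[1] / params$scale[[ids[1]]])
})

test_that("noise matches the closed-form distance-jitter model within 20%", {
  ss <- suppressWarnings(synthetic_spec(
    variants = tibble::tibble(variant_id = "v", class = "I"),
    n_snapshots = 400L, noise_sd = 1, ar1_rho = 0,
    effects = default_planted_effects()[0, ]))
  ens <- suppressWarnings(simulate_ensemble(ss, "v", seed = 42,
                                            template = tpl_cache))
  fm <- compute_features(ens, ca_spec_cache)
  base <- compute_features(tpl_cache, ca_spec_cache)$values[1, ]
  # Monte-Carlo oracle: a feature is the mean of two independent distances
  # between points jittered by N(0, 1) per coordinate
  mc_sd <- function(d0, m = 40000) {
    e <- matrix(rnorm(m * 6), m, 6)
    d <- sqrt((d0 + e[, 1] - e[, 4])^2 + (e[, 2] - e[, 5])^2 +
                (e[, 3] - e[, 6])^2)
    e2 <- matrix(rnorm(m * 6), m, 6)
    d2 <- sqrt((d0 + e2[, 1] - e2[, 4])^2 + (e2[, 2] - e2[, 5])^2 +
                 (e2[, 3] - e2[, 6])^2)
    sd((d + d2) / 2)
  }
  set.seed(99)
  cols <- sample(ncol(fm$values), 12)
  emp <- apply(fm$values[-1, cols], 2, sd)
  oracle <- vapply(base[cols], mc_sd, numeric(1))
  expect_true(all(abs(emp - oracle) / oracle < 0.2))
})

test_that("AR(1) noise has the requested lag-1 correlation and marginal sd", {
  ss <- suppressWarnings(synthetic_spec(
    variants = tibble::tibble(variant_id = "v", class = "I"),
    n_snapshots = 2000L, noise_sd = 1, ar1_rho = 0.5,
    effects = default_planted_effects()[0, ]))
  ens <- suppressWarnings(simulate_ensemble(ss, "v", seed = 5,
                                            template = tpl_cache))
  e <- ens$coords[-1, 1, 1] - tpl_cache$coords[1, 1, 1]
  expect_equal(sd(e), 1, tolerance = 0.1)
  expect_equal(cor(e[-1], e[-length(e)]), 0.5, tolerance = 0.1)
})

test_that("cohort generation is reproducible and carries ground truth", {
  coh1 <- scaled_cohort(3, n_snapshots = 20L)
  coh2 <- scaled_cohort(3, n_snapshots = 20L)
  expect_identical(names(coh1$ensembles), default_variants()$variant_id)
  expect_identical(coh1$ensembles$S463P$coords, coh2$ensembles$S463P$coords)
  coh3 <- scaled_cohort(4, n_snapshots = 20L)
  expect_false(identical(coh1$ensembles$S463P$coords, coh3$ensembles$S463P$coords))
  # ground truth ids exist in the default spec and class labels match
  expect_true(all(coh1$ground_truth$feature_id %in%
                    ca_spec_cache$descriptors$feature_id))
  expect_identical(unname(coh1$labels[c("Y537S", "S463P")]), c("I", "II"))
  # class I ensembles carry no planted displacement: snapshot 0 is template
  expect_equal(coh1$ensembles$Y537S$coords[1, , ], tpl_cache$coords[1, , ])
  expect_error(
    generate_cohort(synthetic_spec(
      variants = tibble::tibble(variant_id = c("a", "a"),
                                class = c("I", "II")))),
    "Duplicate")
})

test_that("unphysical planted shifts are fatal", {
  eff <- tibble::tibble(residue_a = 430L, residue_b = 462L,
                        scope = "inter_chain", atom_kind = "CA",
                        delta = -15.5, onset_fraction = 0)
  ss <- synthetic_spec(variants = tibble::tibble(variant_id = c("a", "b"),
                                                 class = c("I", "II")),
                       n_snapshots = 3L, noise_sd = 0, effects = eff)
  expect_error(simulate_ensemble(ss, "b", seed = 1, template = tpl_cache),
               "infeasible|0.5 Angstrom")
})
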