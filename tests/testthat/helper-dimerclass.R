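# Shared fixtures, built in code.

# cached template and default CA spec (deterministic, reused across files)
tpl_cache <- template_dimer()
ca_spec_cache <- build_feature_spec("CA", quiet = TRUE)

# a tiny two-chain, toy-patch system: chain A residues 1:2 and 11:13, chain B
# mirrored across x = 0; returns coords for `n_snap` identical snapshots
toy_coords <- function(n_snap = 1L) {
  base <- tibble::tibble(
    residue = c(1L, 2L, 11L, 12L, 13L),
    x = c(4, 5, 3, 4, 5),
    y = c(0, 3, 8, 10, 12),
    z = c(0, 2, -1, 1, 3)
  )
  one <- dplyr::bind_rows(
    dplyr::mutate(base, chain = "A"),
    dplyr::mutate(base, chain = "B", x = -.data$x, y = -.data$y)
  )
  purrr::map_dfr(seq_len(n_snap) - 1L, function(s) {
    dplyr::mutate(one, snapshot = s, atom = "CA")
  })
}

toy_ensemble <- function(n_snap = 1L, variant_id = "toy",
                         class_label = NA_character_) {
  snapshot_ensemble(toy_coords(n_snap), variant_id = variant_id,
                    class_label = class_label)
}

# toy patch set: one pocket pair (2 x 3 residues), no antagonist group, one
# inter-chain interface group on the same patches
toy_patches <- function() {
  list(
    pocket = setNames(
      list(residue_patch("pa", 1:2), residue_patch("pb", 11:13)),
      c("pa", "pb")),
    antagonist = NULL,
    interface = list(
      list(name = "pa_x_pb",
           a = residue_patch("pa", 1:2), b = residue_patch("pb", 11:13))
    )
  )
}

toy_spec <- function(atom_kind = "CA") {
  build_feature_spec(atom_kind, patches = toy_patches(), quiet = TRUE)
}

# small synthetic cohort + pipeline inputs used by several test files
scaled_cohort <- function(seed, n_snapshots = 200L, ...) {
  generate_cohort(synthetic_spec(n_snapshots = n_snapshots, seed = seed, ...),
                  template = tpl_cache)
}

# nonseparable weighted logistic test problem
random_logistic_data <- function(seed, n = 120L, p = 5L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  y <- rbinom(n, 1, stats::plogis(0.3 + drop(X %*% rnorm(p)) * 0.5))
  # ensure both classes present twice
  if (sum(y == 0) < 2L) y[1:2] <- 0L
  if (sum(y == 1) < 2L) y[3:4] <- 1L
  list(X = X, y = y)
}

# reference weighted logistic MLE via stats::glm.fit (independent oracle)
glm_oracle <- function(X, y, weights = class_weights(y)) {
  wv <- ifelse(y == 1, weights[[2L]], weights[[1L]])
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y, weights = wv,
                                         family = stats::binomial()))
  unname(fit$coefficients)
}
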