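# Synthetic two-chain conformational ensembles with planted class structure.
#
# The generator stands in for molecular-dynamics trajectories of the seven
# activating variants: every variant starts from a shared idealized template
# dimer (snapshot 0), accumulates AR(1)-correlated Gaussian positional noise,
# and -- for class II variants -- expresses planted cross-interface distance
# contractions in coordinate space, so that featurization itself is exercised
# end to end. Nothing here aims at physical realism beyond positive distances
# and temporally correlated jitter.

rot_c2 <- function(m) {
  # two-fold rotation about the z axis
  m[, 1L] <- -m[, 1L]
  m[, 2L] <- -m[, 2L]
  m
}

template_segments <- function() {
  seg <- function(lo, hi, from, to) list(lo = lo, hi = hi, from = from, to = to)
  list(
    seg(342L, 354L, c(20, -10,  -8), c(20,  -2,   8)),
    seg(355L, 381L, c(24,  -8, -10), c(24,  10,  10)),
    seg(382L, 394L, c(27,   8,  -9), c(27,  -6,   9)),
    seg(395L, 401L, c(23,  12,  -4), c(20,  14,   4)),
    seg(402L, 410L, c(17,  14,  -6), c(17,   6,   8)),
    seg(411L, 417L, c(14,   4,   8), c(12,   0,  -8)),
    # H8 and its interface residues: three short pieces so that 427, 430 and
    # 434 form a well-conditioned (non-collinear) triangle at the inner face.
    # The inner-face segment endpoints were laid out numerically so that the
    # default planted contractions are geometrically realizable by residue
    # translations without steric clashes in either the template or the
    # fully displaced structure.
    seg(418L, 427L, c(16.634, -8.201, -10), c(7.246, -11.342, -5.396)),
    seg(428L, 430L, c(13.588, -4.867, 1.521), c(4.015, -4.36, 13.438)),
    seg(431L, 434L, c(3.627, 1.302, 3.487), c(3.537, -2.099, -7.726)),
    seg(435L, 454L, c(10, -14,   8), c(16, -16,  -8)),
    seg(455L, 465L, c(3.524, 2.745, -15.527), c(3.651, 15.793, 3.633)),
    seg(466L, 478L, c(10,  18,   2), c(14,  18,  -4)),
    seg(479L, 487L, c(7.327, -16.418, 2.059), c(5.989, -11.333, 8.653)),
    seg(488L, 496L, c(10,   8,  10), c(12,   2,  12)),
    seg(497L, 516L, c(8.039, -0.724, -14.864), c(6.66, 2.458, 12.884)),
    seg(517L, 528L, c(7,    6,   9), c(13,  10,  -6)),
    seg(529L, 538L, c(16,   0, -10), c(18,   6,  -2)),
    seg(539L, 547L, c(21,   4,   0), c(21,  12,   8))
  )
}

#' Idealized template dimer
#'
#' Builds a deterministic, exactly two-fold-symmetric coarse backbone trace
#' of the ligand-binding-domain dimer: chain A residues 342-547 are placed on
#' piecewise-linear segments with a helical wiggle (3.6 residues per turn,
#' 1.2 Angstrom radius), C-beta pseudo-atoms 1.5 Angstrom off each C-alpha,
#' and chain B is chain A rotated by 180 degrees about the z axis. The
#' dimer-interface patches (H8 residues 427/430/434, the H9-H10 loop, H11)
#' sit on the inner face so cross-chain distances fall in a realistic
#' 8-30 Angstrom range, while pocket patches sit farther out. Every residue
#' referenced by [default_patches()] gets finite CA and CB coordinates.
#'
#' @param variant_id,class_label,time_step_ns Passed to [snapshot_ensemble()].
#' @return A single-snapshot `snapshot_ensemble` with chains `"A"` and `"B"`.
#' @export
template_dimer <- function(variant_id = "template", class_label = NA_character_,
                           time_step_ns = 0.1) {
  rows <- purrr::map_dfr(template_segments(), function(s) {
    res <- seq.int(s$lo, s$hi)
    nres <- length(res)
    tfrac <- if (nres == 1L) 0 else (seq_len(nres) - 1L) / (nres - 1L)
    u <- s$to - s$from
    u <- u / sqrt(sum(u^2))
    w <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p1 <- c(u[2L] * w[3L] - u[3L] * w[2L],
            u[3L] * w[1L] - u[1L] * w[3L],
            u[1L] * w[2L] - u[2L] * w[1L])
    p1 <- p1 / sqrt(sum(p1^2))
    p2 <- c(u[2L] * p1[3L] - u[3L] * p1[2L],
            u[3L] * p1[1L] - u[1L] * p1[3L],
            u[1L] * p1[2L] - u[2L] * p1[1L])
    theta <- 2 * pi * (res - s$lo) / 3.6
    ca <- outer(rep(1, nres), s$from) + outer(tfrac, s$to - s$from) +
      1.2 * (outer(cos(theta), p1) + outer(sin(theta), p2))
    cb_dir <- outer(cos(theta + 2), p1) + outer(sin(theta + 2), p2) +
      outer(rep(0.3, nres), u)
    cb_dir <- cb_dir / sqrt(rowSums(cb_dir^2))
    cb <- ca + 1.5 * cb_dir
    tibble::tibble(residue = rep(res, 2L),
                   atom = rep(c("CA", "CB"), each = nres),
                   x = c(ca[, 1L], cb[, 1L]),
                   y = c(ca[, 2L], cb[, 2L]),
                   z = c(ca[, 3L], cb[, 3L]))
  })
  xyz_a <- as.matrix(rows[, c("x", "y", "z")])
  xyz_b <- rot_c2(xyz_a)
  coords <- tibble::tibble(
    snapshot = 0L,
    chain = rep(c("A", "B"), each = nrow(rows)),
    residue = rep(rows$residue, 2L),
    atom = rep(rows$atom, 2L),
    x = c(xyz_a[, 1L], xyz_b[, 1L]),
    y = c(xyz_a[, 2L], xyz_b[, 2L]),
    z = c(xyz_a[, 3L], xyz_b[, 3L])
  )
  snapshot_ensemble(coords, variant_id = variant_id, class_label = class_label,
                    time_step_ns = time_step_ns)
}

#' Default variant cohort
#'
#' The seven activating variants with their mechanistic classes: class I
#' (helix-12 repositioning) Y537S and D538G; class II (dimer-interface)
#' V422del, G442R, F461V, S463P and L469V.
#'
#' @return Tibble with columns `variant_id`, `class`.
#' @export
default_variants <- function() {
  tibble::tibble(
    variant_id = c("Y537S", "D538G", "V422del", "G442R", "F461V", "S463P", "L469V"),
    class = c("I", "I", "II", "II", "II", "II", "II")
  )
}

#' Default planted interface effects
#'
#' Six cross-chain contractions among the H8 interface residues (427, 430,
#' 434) and the loop between H9 and H10 (462, 464, 465), spanning 3 to 6.4
#' Angstrom, expressed by class II variants. The two headline pairs carry the
#' largest shifts (430-462: -6.4, 430-464: -5.6). Negative `delta` means the
#' pair ends up closer in class II; `onset_fraction = 0.5` ramps the shift in
#' linearly over the first half of the trajectory, so it is fully expressed
#' throughout the modeled stage (the last half of the snapshots).
#'
#' @return Tibble with columns `residue_a`, `residue_b`, `scope`, `atom_kind`,
#'   `delta`, `onset_fraction`.
#' @export
default_planted_effects <- function() {
  tibble::tibble(
    residue_a = c(430L, 430L, 434L, 427L, 434L, 427L),
    residue_b = c(462L, 464L, 464L, 462L, 465L, 465L),
    scope = "inter_chain",
    atom_kind = "CA",
    delta = c(-6.4, -5.6, -4.8, -4.0, -3.5, -3.0),
    onset_fraction = 0.5
  )
}

#' Specification of a synthetic cohort
#'
#' Bundles every knob of the generator. Defaults mirror the modeled study
#' design: 7 variants (2 class I, 5 class II), 1,000 snapshots at 0.1 ns,
#' isotropic per-coordinate Gaussian noise of 1 Angstrom with lag-1 temporal
#' correlation 0.5, and the six planted interface contractions of
#' [default_planted_effects()] applied to class II variants.
#'
#' @param variants Tibble with `variant_id`, `class` columns.
#' @param n_snapshots Snapshots per variant (snapshot 0 is the template).
#' @param time_step_ns Snapshot spacing, ns.
#' @param noise_sd Per-atom, per-coordinate Gaussian noise SD, Angstrom.
#' @param ar1_rho Lag-1 autocorrelation of the noise, in `[0, 1)`; 0 gives
#'   independent snapshots.
#' @param effects Planted-effect tibble (see [default_planted_effects()]).
#' @param seed Integer master seed for [generate_cohort()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(variants = default_variants(),
                           n_snapshots = 1000L,
                           time_step_ns = 0.1,
                           noise_sd = 1.0,
                           ar1_rho = 0.5,
                           effects = default_planted_effects(),
                           seed = 1L) {
  stopifnot(n_snapshots >= 1L, time_step_ns > 0, noise_sd >= 0,
            ar1_rho >= 0, ar1_rho < 1)
  if (!all(c("variant_id", "class") %in% names(variants))) {
    abort("`variants` must have columns variant_id and class.")
  }
  if (anyDuplicated(variants$variant_id)) abort("Duplicate variant ids.")
  if (!all(variants$class %in% c("I", "II"))) abort("Classes must be \"I\" or \"II\".")
  if (length(unique(variants$class)) < 2L) {
    warn("Cohort has a single class; it will not be trainable.")
  }
  if (nrow(effects) > 0L) {
    stopifnot(all(effects$scope %in% c("intra_chain", "inter_chain")),
              all(effects$atom_kind %in% c("CA", "CB")),
              all(effects$onset_fraction >= 0 & effects$onset_fraction <= 1))
  }
  structure(list(variants = tibble::as_tibble(variants),
                 n_snapshots = as.integer(n_snapshots),
                 time_step_ns = time_step_ns, noise_sd = noise_sd,
                 ar1_rho = ar1_rho, effects = tibble::as_tibble(effects),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", nrow(x$variants), " variants (",
      sum(x$variants$class == "I"), " class I / ", sum(x$variants$class == "II"),
      " class II), ", x$n_snapshots, " snapshots, noise ", x$noise_sd,
      " A (rho = ", x$ar1_rho, "), ", nrow(x$effects), " planted effects\n",
      sep = "")
  invisible(x)
}

# Solve for the translation u of a point p such that its distances to fixed
# anchors q (rows) hit the given targets: Gauss-Newton on the residuals
# |q_j - (p + u)| - t_j, started at u = 0 with a minimal-norm step (so an
# underdetermined single constraint moves p along the connecting line).
solve_translation <- function(p, q, targets, tol = 1e-10, max_iter = 500L) {
  resid <- function(u) {
    diff <- sweep(q, 2L, p + u)
    d <- sqrt(rowSums(diff^2))
    list(r = d - targets, diff = diff, d = d)
  }
  u <- c(0, 0, 0)
  st <- resid(u)
  mu <- 1e-3                              # Levenberg-Marquardt damping
  for (it in seq_len(max_iter)) {
    if (max(abs(st$r)) < tol) return(u)
    J <- -st$diff / st$d
    g <- crossprod(J, st$r)
    jtj <- crossprod(J)
    repeat {
      step <- tryCatch(drop(solve(jtj + diag(mu, 3L), g)), error = function(e) NULL)
      if (is.null(step)) { mu <- mu * 10; next }
      cand <- u - step
      stc <- resid(cand)
      if (sum(stc$r^2) < sum(st$r^2)) {
        u <- cand; st <- stc; mu <- max(mu / 3, 1e-12)
        break
      }
      mu <- mu * 10
      if (mu > 1e12) break
    }
    if (mu > 1e12) break
  }
  if (max(abs(st$r)) < 1e-6) return(u)
  abort(paste0("Planted effects are geometrically infeasible: target ",
               "distances cannot be realized by translating the residue ",
               "(residual ", format(max(abs(st$r)), digits = 3), " Angstrom)."))
}

# Per-atom displacement matrix realizing a set of effects that share one
# onset fraction, at full expression. For each distinct target residue
# (residue_b), the residue is translated so that every planted pair distance
# shifts by exactly its delta while every OTHER distance feature involving
# that residue (its partner residues in the feature specification) is held
# unchanged -- when the combined constraint count per residue is at most
# three. With more constraints than degrees of freedom, only the planted
# constraints are imposed and a warning notes possible side effects. Anchor
# residues (residue_a) never move. The mirrored displacement is applied on
# the swapped chains so the structure stays exactly two-fold symmetric and
# the symmetry-averaged features shift by the full deltas.
effects_displacement <- function(template, effects) {
  atoms <- template$atoms
  ch <- template$chains
  disp <- matrix(0, nrow = nrow(atoms), ncol = 3L)
  pos <- function(chain, residue, kind) {
    res <- resolve_atoms(template, chain, as.integer(residue), kind)
    template$coords[1L, res$idx, ]
  }

  specs <- lapply(unique(effects$atom_kind), function(k) {
    build_feature_spec(k, quiet = TRUE)$descriptors
  })
  names(specs) <- unique(effects$atom_kind)

  keys <- paste(effects$residue_b, effects$scope, effects$atom_kind, sep = "|")
  for (key in unique(keys)) {
    sub <- effects[keys == key, ]
    b <- sub$residue_b[1L]
    scope <- sub$scope[1L]
    kind <- sub$atom_kind[1L]
    b_chain <- if (scope == "inter_chain") ch[2L] else ch[1L]
    a_chain <- ch[1L]

    # partner residues of b in the active feature spec, same scope
    d <- specs[[kind]]
    partners <- unique(c(d$residue_a[d$residue_b == b & d$scope == scope],
                         d$residue_b[d$residue_a == b & d$scope == scope]))
    partners <- setdiff(partners, b)
    extra <- setdiff(partners, sub$residue_a)
    anchors <- c(sub$residue_a, extra)
    deltas <- c(sub$delta, rep(0, length(extra)))
    if (length(anchors) > 3L) {
      warn(paste0("Residue ", b, " has ", length(anchors), " distance ",
                  "constraints; only the planted pairs are imposed and other ",
                  "features sharing the residue may shift as a side effect."))
      anchors <- sub$residue_a
      deltas <- sub$delta
    }

    pb <- pos(b_chain, b, kind)
    q <- do.call(rbind, lapply(anchors, function(a) pos(a_chain, a, kind)))
    d0 <- sqrt(rowSums(sweep(q, 2L, pb)^2))
    u <- solve_translation(pb, q, d0 + deltas)

    rows_b <- which(atoms$chain == b_chain & atoms$residue == b)
    disp[rows_b, ] <- disp[rows_b, , drop = FALSE] +
      matrix(u, nrow = length(rows_b), ncol = 3L, byrow = TRUE)
    # mirrored copy on the swapped chain
    other <- setdiff(ch, b_chain)
    rows_m <- which(atoms$chain == other & atoms$residue == b)
    um <- drop(rot_c2(matrix(u, 1L)))
    disp[rows_m, ] <- disp[rows_m, , drop = FALSE] +
      matrix(um, nrow = length(rows_m), ncol = 3L, byrow = TRUE)
  }
  disp
}

#' Simulate one variant's ensemble
#'
#' Snapshot 0 is the template exactly (all variants share the same initial
#' structure). Snapshots t >= 1 add stationary AR(1) Gaussian displacements
#' (marginal SD `noise_sd`, lag-1 correlation `ar1_rho`) to every atom
#' coordinate. For class II variants each planted effect translates the two
#' anchor residues toward (or away from) each other, half the shift on each
#' endpoint, mirrored onto the swapped chains, ramped linearly until
#' `onset_fraction` of the trajectory and held thereafter; with zero noise
#' the symmetry-averaged feature of the targeted pair therefore shifts by
#' exactly `delta` once the ramp completes. A shift that would push any
#' atom pair of the displaced template below 0.5 Angstrom is fatal.
#'
#' @param spec A `synthetic_spec`.
#' @param variant_id One of `spec$variants$variant_id`.
#' @param seed Optional integer seed (set internally by [generate_cohort()]).
#' @param template Template ensemble; defaults to [template_dimer()].
#' @return A `snapshot_ensemble` with the variant's class label attached.
#' @export
simulate_ensemble <- function(spec, variant_id, seed = NULL,
                              template = template_dimer()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  row <- which(spec$variants$variant_id == variant_id)
  if (length(row) != 1L) abort(paste0("Unknown variant '", variant_id, "'."))
  cls <- spec$variants$class[row]
  if (!is.null(seed)) set.seed(seed)

  n_snap <- spec$n_snapshots
  n_atom <- nrow(template$atoms)
  base <- template$coords[1L, , ]

  effects <- if (cls == "II") spec$effects else spec$effects[0L, ]
  disp_list <- list()
  onsets <- numeric(0)
  if (nrow(effects) > 0L) {
    onsets <- sort(unique(effects$onset_fraction))
    if (length(onsets) > 1L) {
      bt <- split(effects$residue_b, effects$onset_fraction)
      if (length(Reduce(intersect, bt)) > 0L ||
          anyDuplicated(unlist(lapply(bt, unique)))) {
        abort("A target residue cannot carry planted effects with different onset fractions.")
      }
    }
    disp_list <- lapply(onsets, function(o) {
      effects_displacement(template, effects[effects$onset_fraction == o, ])
    })
    displaced <- base + Reduce(`+`, disp_list)
    if (min(stats::dist(displaced)) <= 0.5) {
      abort("Planted effects push atoms below 0.5 Angstrom apart (unphysical).")
    }
  }

  coords <- array(0, dim = c(n_snap, n_atom, 3L),
                  dimnames = dimnames(template$coords))
  tvec <- seq_len(n_snap) - 1L
  tfrac <- if (n_snap > 1L) tvec / (n_snap - 1L) else tvec
  for (k in 1:3) coords[, , k] <- matrix(base[, k], n_snap, n_atom, byrow = TRUE)

  for (i in seq_along(disp_list)) {
    onset <- onsets[i]
    ramp <- if (onset <= 0) as.numeric(tvec > 0L) else pmin(1, tfrac / onset)
    ramp[1L] <- 0
    nz <- which(rowSums(disp_list[[i]] != 0) > 0L)
    for (k in 1:3) {
      coords[, nz, k] <- coords[, nz, k] + outer(ramp, disp_list[[i]][nz, k])
    }
  }

  if (spec$noise_sd > 0 && n_snap > 1L) {
    rho <- spec$ar1_rho
    z <- matrix(rnorm((n_snap - 1L) * n_atom * 3L, sd = spec$noise_sd),
                nrow = n_snap - 1L)
    if (rho > 0) {
      innov_sd <- sqrt(1 - rho^2)
      for (t in seq_len(n_snap - 1L)) {
        if (t == 1L) next
        z[t, ] <- rho * z[t - 1L, ] + innov_sd * z[t, ]
      }
    }
    e <- array(0, dim = c(n_snap, n_atom, 3L))
    e[-1L, , ] <- z
    coords <- coords + e
  }

  out <- template
  out$variant_id <- variant_id
  out$class_label <- cls
  out$time_step_ns <- spec$time_step_ns
  out$coords <- coords
  out
}

#' Generate a labeled synthetic cohort
#'
#' One ensemble per variant, each simulated with its own sub-seed derived
#' from `spec$seed`, plus a ground-truth record of the planted effects
#' (including the feature ids they map to in the default feature
#' specification of the effects' atom kind) for recovery scoring.
#'
#' @param spec A `synthetic_spec`.
#' @param template Template ensemble shared by all variants.
#' @return List with `ensembles` (named list of `snapshot_ensemble`),
#'   `labels` (named class vector) and `ground_truth` (effects tibble with
#'   `feature_id` of each planted pair).
#' @export
generate_cohort <- function(spec, template = template_dimer()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(spec$variants))
  ensembles <- purrr::map2(
    spec$variants$variant_id, sub_seeds,
    function(v, s) simulate_ensemble(spec, v, seed = s, template = template))
  names(ensembles) <- spec$variants$variant_id

  ground_truth <- spec$effects
  if (nrow(ground_truth) > 0L) {
    kinds <- unique(ground_truth$atom_kind)
    ground_truth$feature_id <- NA_integer_
    for (k in kinds) {
      fs <- build_feature_spec(k, quiet = TRUE)
      idx <- which(ground_truth$atom_kind == k)
      ground_truth$feature_id[idx] <- vapply(idx, function(i) {
        match_planted_feature(ground_truth[i, ], fs)
      }, integer(1))
    }
    if (anyNA(ground_truth$feature_id)) {
      abort("A planted effect does not correspond to any feature in the default spec.")
    }
  }

  list(ensembles = ensembles,
       labels = setNames(spec$variants$class, spec$variants$variant_id),
       ground_truth = ground_truth)
}

match_planted_feature <- function(effect, spec) {
  d <- spec$descriptors
  hit <- which(d$scope == effect$scope &
                 ((d$residue_a == effect$residue_a & d$residue_b == effect$residue_b) |
                  (d$residue_a == effect$residue_b & d$residue_b == effect$residue_a)))
  if (length(hit) == 0L) return(NA_integer_)
  d$feature_id[hit[1L]]
}
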