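# Snapshot ensembles: ordered conformational snapshots of a two-chain structure.

#' Construct a snapshot ensemble from a long coordinate table
#'
#' A snapshot ensemble holds the per-snapshot C-alpha/C-beta coordinates of a
#' two-chain structure. Snapshots are indexed from 0 (snapshot 0 is the
#' initial structure used as the standardization reference) and must be
#' contiguous. Internally coordinates are stored as a dense
#' `snapshots x atoms x 3` array for fast featurization; [tibble::as_tibble()]
#' recovers the long form.
#'
#' @param coords Data frame with columns `snapshot` (0-based integer),
#'   `chain`, `residue`, `atom` (`"CA"`/`"CB"`), `x`, `y`, `z` (Angstrom).
#' @param variant_id Single string identifying the variant.
#' @param class_label Optional `"I"` or `"II"` mechanistic class label.
#' @param time_step_ns Positive spacing between snapshots in nanoseconds.
#' @return An object of class `snapshot_ensemble`.
#' @export
snapshot_ensemble <- function(coords, variant_id = "variant",
                              class_label = NA_character_,
                              time_step_ns = 0.1) {
  required <- c("snapshot", "chain", "residue", "atom", "x", "y", "z")
  missing_cols <- setdiff(required, names(coords))
  if (length(missing_cols) > 0L) {
    abort(paste0("Coordinate table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(coords) == 0L) abort("Coordinate table is empty.")
  if (!is.numeric(time_step_ns) || length(time_step_ns) != 1L || time_step_ns <= 0) {
    abort("`time_step_ns` must be a single positive number.")
  }
  if (!is.na(class_label) && !class_label %in% c("I", "II")) {
    abort("`class_label` must be \"I\", \"II\" or NA.")
  }
  coords <- tibble::as_tibble(coords)
  coords$snapshot <- as.integer(coords$snapshot)
  coords$residue <- as.integer(coords$residue)
  coords$chain <- as.character(coords$chain)
  coords$atom <- as.character(coords$atom)
  if (!all(coords$atom %in% c("CA", "CB"))) {
    abort("`atom` must be \"CA\" or \"CB\"; only these anchor distance features.")
  }
  snaps <- sort(unique(coords$snapshot))
  if (snaps[1L] != 0L || !identical(snaps, seq.int(0L, length(snaps) - 1L))) {
    abort("Snapshot indices must be contiguous and start at 0.")
  }
  chains <- sort(unique(coords$chain))
  if (length(chains) != 2L) {
    abort(paste0("Exactly two chains are required; found: ",
                 paste(chains, collapse = ", ")))
  }

  key <- paste(coords$chain, coords$residue, coords$atom, sep = "|")
  dup <- duplicated(cbind(coords$snapshot, key))
  if (any(dup)) {
    d <- coords[dup, ][1L, ]
    abort(paste0("Duplicate coordinate for snapshot ", d$snapshot, ", chain ",
                 d$chain, ", residue ", d$residue, ", atom ", d$atom, "."))
  }

  atoms <- coords |>
    dplyr::distinct(.data$chain, .data$residue, .data$atom) |>
    dplyr::arrange(.data$chain, .data$residue, .data$atom)
  atom_key <- paste(atoms$chain, atoms$residue, atoms$atom, sep = "|")

  per_snap <- table(coords$snapshot)
  if (length(unique(per_snap)) != 1L || per_snap[[1L]] != nrow(atoms)) {
    abort("Every snapshot must provide the same set of (chain, residue, atom) coordinates.")
  }

  n_snap <- length(snaps)
  arr <- array(NA_real_, dim = c(n_snap, nrow(atoms), 3L),
               dimnames = list(NULL, atom_key, c("x", "y", "z")))
  row_i <- coords$snapshot + 1L
  col_i <- match(key, atom_key)
  arr[cbind(row_i, col_i, 1L)] <- coords$x
  arr[cbind(row_i, col_i, 2L)] <- coords$y
  arr[cbind(row_i, col_i, 3L)] <- coords$z

  structure(list(variant_id = variant_id, class_label = class_label,
                 time_step_ns = time_step_ns, chains = chains,
                 atoms = atoms, coords = arr),
            class = "snapshot_ensemble")
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  cat("<snapshot_ensemble> variant ", x$variant_id,
      if (!is.na(x$class_label)) paste0(" (class ", x$class_label, ")"),
      ": ", n_snapshots(x), " snapshots x ", nrow(x$atoms), " atoms, chains ",
      paste(x$chains, collapse = "/"), ", dt = ", x$time_step_ns, " ns\n", sep = "")
  invisible(x)
}

#' Number of snapshots in an ensemble
#' @param ensemble A `snapshot_ensemble`.
#' @return Integer count.
#' @export
n_snapshots <- function(ensemble) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  dim(ensemble$coords)[1L]
}

#' @export
as_tibble.snapshot_ensemble <- function(x, ...) {
  n_snap <- n_snapshots(x)
  n_atom <- nrow(x$atoms)
  xs <- as.vector(x$coords[, , 1L])
  ys <- as.vector(x$coords[, , 2L])
  zs <- as.vector(x$coords[, , 3L])
  tibble::tibble(
    snapshot = rep(seq_len(n_snap) - 1L, times = n_atom),
    chain = rep(x$atoms$chain, each = n_snap),
    residue = rep(x$atoms$residue, each = n_snap),
    atom = rep(x$atoms$atom, each = n_snap),
    x = xs, y = ys, z = zs
  ) |>
    dplyr::arrange(.data$snapshot, .data$chain, .data$residue, .data$atom)
}

# Resolve atom column indices for (chain, residue, kind) with the C-beta
# fallback rule: a residue lacking CB (e.g. glycine) contributes its CA
# coordinate instead. Returns list(idx, fallback tibble). Errors name every
# unresolvable residue.
resolve_atoms <- function(ensemble, chain, residues, kind) {
  keys <- dimnames(ensemble$coords)[[2L]]
  want <- paste(chain, residues, kind, sep = "|")
  idx <- match(want, keys)
  fb <- tibble::tibble(chain = character(), residue = integer(),
                       requested = character(), used = character())
  if (kind == "CB" && anyNA(idx)) {
    miss <- which(is.na(idx))
    alt <- match(paste(chain, residues[miss], "CA", sep = "|"), keys)
    ok <- !is.na(alt)
    idx[miss[ok]] <- alt[ok]
    if (any(ok)) {
      fb <- tibble::tibble(chain = chain, residue = residues[miss[ok]],
                           requested = "CB", used = "CA")
    }
  }
  if (anyNA(idx)) {
    bad <- residues[is.na(idx)]
    abort(paste0("Missing ", kind, " coordinate (no fallback available) for chain ",
                 chain, ", residue(s) ", paste(bad, collapse = ", "), "."))
  }
  list(idx = idx, fallback = fb)
}

#' Look up one atom coordinate
#'
#' Returns the stored coordinate of an atom in one snapshot. Requesting `CB`
#' on a residue that lacks a C-beta atom (glycine, or a coarse model) falls
#' back to the C-alpha coordinate; the substitution is reported in the
#' `fallback` attribute of the result.
#'
#' @param ensemble A `snapshot_ensemble`.
#' @param snapshot 0-based snapshot index.
#' @param chain Chain identifier.
#' @param residue Residue number.
#' @param kind `"CA"` or `"CB"`.
#' @return Numeric length-3 vector (x, y, z in Angstrom); attribute
#'   `fallback` is `TRUE` if the C-alpha substitution was used.
#' @export
get_atom <- function(ensemble, snapshot, chain, residue, kind = c("CA", "CB")) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  kind <- match.arg(kind)
  if (snapshot < 0L || snapshot >= n_snapshots(ensemble)) {
    abort(paste0("Snapshot ", snapshot, " out of range 0..",
                 n_snapshots(ensemble) - 1L, "."))
  }
  if (!chain %in% ensemble$chains) {
    abort(paste0("Chain '", chain, "' not present (chains: ",
                 paste(ensemble$chains, collapse = ", "), ")."))
  }
  res <- resolve_atoms(ensemble, chain, as.integer(residue), kind)
  out <- ensemble$coords[snapshot + 1L, res$idx, ]
  attr(out, "fallback") <- nrow(res$fallback) > 0L
  out
}
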