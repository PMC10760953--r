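# Reading and writing multi-model structural ensembles.

#' Read a multi-model PDB file into a snapshot ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one snapshot, in file order, starting
#' at snapshot index 0; a file without `MODEL` records yields a single
#' snapshot. Only `ATOM` records with atom names `CA` or `CB` on the two
#' requested chains are kept. Alternate locations are resolved by keeping the
#' first listed altLoc; occupancies are ignored. Parsing is delegated to
#' [bio3d::read.pdb()].
#'
#' A residue that is required by a feature specification but absent from the
#' file does not fail here; the error is raised at featurization, naming the
#' residue, chain and atom.
#'
#' @param path Path to a PDB file.
#' @param chains Character vector of exactly two chain identifiers.
#' @param variant_id,class_label,time_step_ns Passed to [snapshot_ensemble()].
#' @return A `snapshot_ensemble`.
#' @export
read_multimodel_pdb <- function(path, chains = c("A", "B"),
                                variant_id = "variant",
                                class_label = NA_character_,
                                time_step_ns = 0.1) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (length(chains) != 2L) abort("`chains` must name exactly two chains.")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety %in% c("CA", "CB") & at$chain %in% chains
  if (!all(chains %in% at$chain)) {
    missing_chain <- setdiff(chains, unique(at$chain))
    abort(paste0("Chain(s) not present in ", path, ": ",
                 paste(missing_chain, collapse = ", ")))
  }
  at_idx <- which(keep)
  # first listed altLoc wins
  key <- paste(at$chain[at_idx], at$resno[at_idx], at$elety[at_idx], sep = "|")
  at_idx <- at_idx[!duplicated(key)]
  if (length(at_idx) == 0L) {
    abort(paste0("No CA/CB atoms found on chains ",
                 paste(chains, collapse = "/"), " in ", path))
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_model <- nrow(xyz)
  n_atom <- length(at_idx)
  coords <- tibble::tibble(
    snapshot = rep(seq_len(n_model) - 1L, each = n_atom),
    chain = rep(at$chain[at_idx], times = n_model),
    residue = rep(as.integer(at$resno[at_idx]), times = n_model),
    atom = rep(at$elety[at_idx], times = n_model),
    x = as.vector(t(xyz[, 3L * (at_idx - 1L) + 1L, drop = FALSE])),
    y = as.vector(t(xyz[, 3L * (at_idx - 1L) + 2L, drop = FALSE])),
    z = as.vector(t(xyz[, 3L * (at_idx - 1L) + 3L, drop = FALSE]))
  )
  snapshot_ensemble(coords, variant_id = variant_id, class_label = class_label,
                    time_step_ns = time_step_ns)
}

#' Write a snapshot ensemble as a multi-model PDB file
#'
#' Writes standard fixed-column `ATOM` records, one `MODEL`/`ENDMDL` block per
#' snapshot. Output is bit-stable for identical input. Residues are written
#' with residue name `ALA` (residue identity is not tracked by the ensemble
#' container); coordinates are written at the PDB precision of 0.001 Angstrom.
#'
#' @param ensemble A `snapshot_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  if (any(abs(ensemble$coords) > 9999.999)) {
    abort("Coordinate magnitude exceeds the PDB fixed-column limit (9999.999 A).")
  }
  atoms <- ensemble$atoms
  ord <- order(atoms$chain, atoms$residue, atoms$atom)
  n_snap <- n_snapshots(ensemble)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  serial <- seq_along(ord)
  for (s in seq_len(n_snap)) {
    writeLines(sprintf("MODEL     %4d", s), con)
    xyz <- ensemble$coords[s, ord, , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    lines <- sprintf(
      "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
      serial, atoms$atom[ord], "ALA", atoms$chain[ord], atoms$residue[ord],
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1.00, 0.00, "C")
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read or write a snapshot ensemble as a tab-separated coordinate table
#'
#' The table format is a plain-text alternative to multi-model PDB: a header
#' row `snapshot chain residue atom x y z` followed by one row per atom per
#' snapshot, coordinates in Angstrom. The two formats produce identical
#' feature matrices downstream (up to the 0.001 Angstrom PDB precision).
#'
#' @param path File path.
#' @param variant_id,class_label,time_step_ns Passed to [snapshot_ensemble()].
#' @return A `snapshot_ensemble` for the reader; `path` invisibly for the
#'   writer.
#' @export
read_coordinate_table <- function(path, variant_id = "variant",
                                  class_label = NA_character_,
                                  time_step_ns = 0.1) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           snapshot = "i", chain = "c", residue = "i",
                           atom = "c", x = "d", y = "d", z = "d"))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0L) {
    abort(paste0("Malformed coordinate table ", path, " at line ",
                 probs$row[1L] + 1L, ": expected ", probs$expected[1L],
                 ", got ", probs$actual[1L], "."))
  }
  if (nrow(tbl) == 0L) abort(paste0("Coordinate table is empty: ", path))
  snapshot_ensemble(tbl, variant_id = variant_id, class_label = class_label,
                    time_step_ns = time_step_ns)
}

#' @rdname read_coordinate_table
#' @param ensemble A `snapshot_ensemble`.
#' @export
write_coordinate_table <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  readr::write_tsv(as_tibble(ensemble), path)
  invisible(path)
}
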