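# Feature specification: groups of pairwise-distance features at three sites.

site_levels <- c("pocket", "antagonist", "interface")

#' Build the distance-feature specification
#'
#' Enumerates every pairwise-distance feature from a set of residue patches:
#'
#' * **pocket** site: all 21 unordered pairs of the 7 pocket patches, one
#'   group per patch pair, with one intra-chain feature per cross-patch
#'   residue pair (2,403 features for the default patches);
#' * **antagonist** site: one intra-chain group pairing H12 with its H3/H5
#'   partners (36 features);
#' * **interface** site: four inter-chain groups. For groups with distinct
#'   patches every `|A| x |B|` residue pair appears once (the two chain
#'   orderings of each pair are symmetry-averaged at featurization, not
#'   enumerated twice). For the H11-against-H11 group, whose two patches are
#'   identical, the unique symmetry classes are the unordered residue pairs
#'   including same-residue cross-chain pairs: `choose(13, 2) + 13 = 91`.
#'   This convention yields 181 interface features for the default patches.
#'   Setting `h11_convention = "unreduced"` instead enumerates all ordered
#'   H11 pairs (169), for 259 interface features; the per-site counts are
#'   reported via a message either way.
#'
#' Feature ids are assigned deterministically: by site (pocket, antagonist,
#' interface), then group id, then ascending `(residue_a, residue_b)`.
#'
#' @param atom_kind `"CA"` or `"CB"`: which atom anchors the distances.
#' @param patches Patch set as returned by [default_patches()].
#' @param h11_convention `"unique"` (default) or `"unreduced"`; see Details.
#' @param quiet Suppress the feature-count message.
#' @return An object of class `feature_spec`: a list with `descriptors`
#'   (tibble: `feature_id`, `site`, `group_id`, `group_name`, `residue_a`,
#'   `residue_b`, `atom_kind`, `scope`), `groups` (one row per group),
#'   `atom_kind`, `site_counts`, and `h11_convention`.
#' @export
#' @examples
#' spec <- build_feature_spec("CA", quiet = TRUE)
#' nrow(spec$descriptors)
build_feature_spec <- function(atom_kind = c("CA", "CB"),
                               patches = default_patches(),
                               h11_convention = c("unique", "unreduced"),
                               quiet = FALSE) {
  atom_kind <- match.arg(atom_kind)
  h11_convention <- match.arg(h11_convention)

  groups <- list()
  gid <- 0L

  # pocket: all unordered pairs of pocket patches, intra-chain
  pk <- patches$pocket
  npk <- length(pk)
  if (npk >= 2L) {
    for (i in seq_len(npk - 1L)) {
      for (j in seq.int(i + 1L, npk)) {
        gid <- gid + 1L
        groups[[gid]] <- list(group_id = gid, site = "pocket",
                              name = paste0(patch_name(pk[[i]]), "_x_", patch_name(pk[[j]])),
                              a = pk[[i]], b = pk[[j]], scope = "intra_chain")
      }
    }
  }

  # antagonist: single intra-chain group
  if (!is.null(patches$antagonist)) {
    gid <- gid + 1L
    groups[[gid]] <- list(group_id = gid, site = "antagonist",
                          name = paste0(patch_name(patches$antagonist$a), "_x_",
                                        patch_name(patches$antagonist$b)),
                          a = patches$antagonist$a, b = patches$antagonist$b,
                          scope = "intra_chain")
  }

  # interface: inter-chain groups
  for (gr in patches$interface %||% list()) {
    gid <- gid + 1L
    groups[[gid]] <- list(group_id = gid, site = "interface", name = gr$name,
                          a = gr$a, b = gr$b, scope = "inter_chain")
  }

  desc <- purrr::map_dfr(groups, function(g) {
    a <- unclass(g$a); b <- unclass(g$b)
    if (g$scope == "intra_chain" && length(intersect(a, b)) > 0L) {
      abort(paste0("Intra-chain group '", g$name, "' has residues shared between ",
                   "its two patches (", paste(intersect(a, b), collapse = ", "),
                   "); this would create zero-distance self pairs."))
    }
    if (g$scope == "inter_chain" && identical(a, b) && h11_convention == "unique") {
      # unique symmetry classes: unordered pairs incl. same-residue cross-chain
      idx <- which(outer(a, b, `<=`), arr.ind = TRUE)
      pairs <- tibble::tibble(residue_a = a[idx[, 1L]], residue_b = b[idx[, 2L]])
    } else {
      pairs <- tidyr::expand_grid(residue_a = a, residue_b = b)
    }
    pairs <- dplyr::arrange(pairs, .data$residue_a, .data$residue_b)
    tibble::tibble(site = g$site, group_id = g$group_id, group_name = g$name,
                   residue_a = pairs$residue_a, residue_b = pairs$residue_b,
                   scope = g$scope)
  })

  desc <- desc |>
    dplyr::mutate(site = factor(.data$site, levels = site_levels)) |>
    dplyr::arrange(.data$site, .data$group_id, .data$residue_a, .data$residue_b) |>
    dplyr::mutate(feature_id = dplyr::row_number(),
                  atom_kind = atom_kind,
                  site = as.character(.data$site)) |>
    dplyr::select("feature_id", "site", "group_id", "group_name",
                  "residue_a", "residue_b", "atom_kind", "scope")

  group_tbl <- desc |>
    dplyr::count(.data$site, .data$group_id, .data$group_name, .data$scope,
                 name = "n_features") |>
    dplyr::arrange(.data$group_id)

  site_counts <- desc |>
    dplyr::count(site = factor(.data$site, levels = site_levels),
                 .drop = FALSE, name = "n_features") |>
    dplyr::mutate(site = as.character(.data$site))

  if (!quiet) {
    cnt <- setNames(site_counts$n_features, site_counts$site)
    inform(paste0(
      "Feature spec (", atom_kind, "): ", nrow(desc), " features in ",
      nrow(group_tbl), " groups [pocket ", cnt[["pocket"]],
      ", antagonist ", cnt[["antagonist"]],
      ", interface ", cnt[["interface"]],
      "; H11xH11 convention: ", h11_convention, "]"))
  }

  structure(list(descriptors = desc, groups = group_tbl,
                 atom_kind = atom_kind, site_counts = site_counts,
                 h11_convention = h11_convention),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec> ", nrow(x$descriptors), " ", x$atom_kind,
      " distance features in ", nrow(x$groups), " groups\n", sep = "")
  print(x$site_counts)
  invisible(x)
}

#' Export or import a feature specification as tab-separated text
#'
#' One row per feature descriptor; the group table is recomputed on read.
#'
#' @param spec A `feature_spec`.
#' @param path File path.
#' @return `write_feature_spec()` returns `path` invisibly;
#'   `read_feature_spec()` returns a `feature_spec`.
#' @export
write_feature_spec <- function(spec, path) {
  stopifnot(inherits(spec, "feature_spec"))
  readr::write_tsv(spec$descriptors, path)
  invisible(path)
}

#' @rdname write_feature_spec
#' @export
read_feature_spec <- function(path) {
  desc <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            feature_id = "i", site = "c", group_id = "i",
                            group_name = "c", residue_a = "i", residue_b = "i",
                            atom_kind = "c", scope = "c"))
  if (!identical(desc$feature_id, seq_len(nrow(desc)))) {
    abort("Feature ids must be contiguous and start at 1.")
  }
  atom_kind <- unique(desc$atom_kind)
  if (length(atom_kind) != 1L || !atom_kind %in% c("CA", "CB")) {
    abort("Feature spec must use a single atom kind, CA or CB.")
  }
  group_tbl <- desc |>
    dplyr::count(.data$site, .data$group_id, .data$group_name, .data$scope,
                 name = "n_features") |>
    dplyr::arrange(.data$group_id)
  site_counts <- desc |>
    dplyr::count(site = factor(.data$site, levels = site_levels),
                 .drop = FALSE, name = "n_features") |>
    dplyr::mutate(site = as.character(.data$site))
  structure(list(descriptors = desc, groups = group_tbl, atom_kind = atom_kind,
                 site_counts = site_counts, h11_convention = "as_read"),
            class = "feature_spec")
}
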