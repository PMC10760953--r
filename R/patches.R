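# Residue patches defining the distance-feature groups.

#' Construct a residue patch
#'
#' A residue patch is a named, strictly increasing set of residue numbers
#' (author numbering of the ligand-binding domain; no renumbering is ever
#' applied). Patches are the building blocks of distance-feature groups:
#' every feature is a pairwise distance between one residue of each patch
#' of a group.
#'
#' @param name Single string naming the patch (e.g. `"h12"`).
#' @param residues Integer vector of residue numbers; must be non-empty,
#'   strictly increasing and duplicate-free.
#' @return An integer vector of class `residue_patch` with a `name` attribute.
#' @export
#' @examples
#' residue_patch("h12", 539:547)
residue_patch <- function(name, residues) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    abort("`name` must be a single non-empty string.")
  }
  residues <- as.integer(residues)
  if (length(residues) == 0L) abort(paste0("Patch '", name, "' is empty."))
  if (anyNA(residues)) abort(paste0("Patch '", name, "' contains NA residues."))
  if (is.unsorted(residues, strictly = TRUE)) {
    abort(paste0("Patch '", name, "' must be strictly increasing with no duplicates."))
  }
  structure(residues, name = name, class = "residue_patch")
}

#' @export
print.residue_patch <- function(x, ...) {
  cat("<residue_patch> ", attr(x, "name"), ": ",
      paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

patch_name <- function(x) attr(x, "name")

#' Default residue patches of the ERalpha ligand-binding domain
#'
#' Returns the residue sets used to build the default feature specification:
#' seven pocket patches whose cross-patch distances describe the agonist-state
#' ligand-binding pocket, the H3/H5 partner residues whose distances to H12
#' describe the antagonist-state geometry, and six interface sets paired into
#' the four cross-chain dimer-interface groups (H11 against H11, H9 and H10
#' against an H11 subset, and the three H8 interface residues against the
#' loop between H9 and H10).
#'
#' Residue 422 is excluded from the H8-and-preceding-loop pocket patch because
#' it is deleted in the V422del variant; keeping it out makes the feature set
#' identical across all variants.
#'
#' @return A list with elements:
#'   * `pocket`: list of 7 `residue_patch` objects (sizes 13, 12, 9, 10, 12, 10, 9),
#'   * `antagonist`: list with patches `a` (H12) and `b` (H3/H5 partners),
#'   * `interface`: list of 4 groups, each a list with `name`, `a`, `b`.
#' @export
#' @examples
#' p <- default_patches()
#' lengths(p$pocket)
default_patches <- function() {
  pocket <- list(
    residue_patch("h3",        342:354),
    residue_patch("h6",        383:394),
    residue_patch("s1_s2",     402:410),
    residue_patch("h8_loop",   setdiff(418:428, 422L)),
    residue_patch("h11",       517:528),
    residue_patch("loop_11_12", 529:538),
    residue_patch("h12",       539:547)
  )
  names(pocket) <- vapply(pocket, patch_name, character(1))

  antagonist <- list(
    a = residue_patch("h12",   539:547),
    b = residue_patch("h3_h5", c(358L, 372L, 376L, 380L))
  )

  interface <- list(
    list(name = "h11_x_h11",
         a = residue_patch("h11_dimer", c(497L, 504L, 505L, 508L, 509L, 511L,
                                          512L, 513L, 515L, 516L, 519L, 520L, 523L)),
         b = residue_patch("h11_dimer", c(497L, 504L, 505L, 508L, 509L, 511L,
                                          512L, 513L, 515L, 516L, 519L, 520L, 523L))),
    list(name = "h9_x_h11",
         a = residue_patch("h9", c(455L, 456L, 458L, 459L)),
         b = residue_patch("h11_partner", c(498L, 501L, 502L, 505L, 506L,
                                            509L, 510L, 513L))),
    list(name = "h10_x_h11",
         a = residue_patch("h10", c(479L, 480L, 483L, 484L, 487L)),
         b = residue_patch("h11_partner", c(498L, 501L, 502L, 505L, 506L,
                                            509L, 510L, 513L))),
    list(name = "h8_x_h9h10loop",
         a = residue_patch("h8_interface", c(427L, 430L, 434L)),
         b = residue_patch("h9_h10_loop", c(459L, 460L, 461L, 462L, 464L, 465L)))
  )

  list(pocket = pocket, antagonist = antagonist, interface = interface)
}
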