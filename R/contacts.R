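#' Heavy-atom van der Waals radii for the overlap contact criterion
#'
#' Radii follow the standard protein heavy-atom parametrization used by
#' structure-based coarse-grained models: sp3 carbon 1.88 A, aromatic carbon
#' 1.76 A, carbonyl carbon 1.61 A, nitrogen 1.64 A, carbonyl oxygen 1.42 A,
#' hydroxyl oxygen 1.46 A, sulfur 1.77 A. Two residues are in contact when at
#' least one pair of heavy atoms (one from each) has spheres, enlarged by
#' `enlargement`, that overlap. The enlargement factor 1.24 is the established
#' companion of this radii set in the contact-map literature.
#'
#' @param enlargement Dimensionless multiplier applied to every radius
#'   (default 1.24).
#' @return List with `radii` (named lookup, per atom name), `fallback`
#'   (per-element radii) and `enlargement`.
#' @export
default_radii <- function(enlargement = 1.24) {
  stopifnot(enlargement >= 1)
  aromatic <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "CZ2", "CZ3",
                "CH2", "CE3", "ND1", "NE2.HIS")
  radii <- c(
    N = 1.64, CA = 1.88, C = 1.61, O = 1.42, OXT = 1.42,
    CB = 1.88, CG = 1.88, CG1 = 1.88, CG2 = 1.88, CD = 1.88,
    CD1 = 1.88, CD2 = 1.88, CE = 1.88, CE1 = 1.76, CE2 = 1.76,
    CE3 = 1.76, CZ = 1.76, CZ2 = 1.76, CZ3 = 1.76, CH2 = 1.76,
    ND1 = 1.64, ND2 = 1.64, NE = 1.64, NE1 = 1.64, NE2 = 1.64,
    NH1 = 1.64, NH2 = 1.64, NZ = 1.64,
    OD1 = 1.42, OD2 = 1.42, OE1 = 1.42, OE2 = 1.42,
    OG = 1.46, OG1 = 1.46, OH = 1.46,
    SD = 1.77, SG = 1.77
  )
  list(radii = radii,
       fallback = c(C = 1.88, N = 1.64, O = 1.42, S = 1.77),
       enlargement = enlargement)
}

atom_radii <- function(elety, table) {
  r <- unname(table$radii[elety])
  miss <- is.na(r)
  if (any(miss)) {
    el <- substr(elety[miss], 1, 1)
    r[miss] <- unname(table$fallback[el])
  }
  if (anyNA(r)) stop("unknown heavy-atom type: ",
                     paste(unique(elety[is.na(r)]), collapse = ", "))
  r * table$enlargement
}

#' Build the native contact map of a conformer
#'
#' A residue pair (i, j) with `j - i >= min_separation` is a native contact
#' when at least one heavy-atom pair (one atom from each residue) has a
#' center-center distance smaller than the sum of their enlarged van der
#' Waals radii. The reference CA-CA distance of every contact is recorded;
#' it becomes the minimum of the corresponding Lennard-Jones potential in the
#' structure-based model.
#'
#' @param x A `conformer` with heavy atoms (backbone-only synthetic conformers
#'   are accepted; the mode is recorded).
#' @param radii Radii table from [default_radii()].
#' @param min_separation Minimal sequence separation `j - i` (default 3).
#' @return A tibble of class `contact_map` with columns `i`, `j`,
#'   `native_distance` (CA-CA, A) and `sep` (= j - i); attributes
#'   `n_residues`, `min_separation`, `mode`.
#' @export
build_contact_map <- function(x, radii = default_radii(), min_separation = 3L) {
  stopifnot(inherits(x, "conformer"))
  at <- x$atoms
  heavy <- !grepl("^H", at$elety)
  at <- at[heavy, ]
  n <- n_residues(x)
  mode <- if (all(at$elety %in% c("N", "CA", "C", "O", "OXT")))
    "backbone" else "heavy"
  r <- atom_radii(at$elety, radii)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dd <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+")
  overlap <- dd < thr
  ri <- at$resid
  sep_ok <- abs(outer(ri, ri, "-")) >= min_separation
  hit <- overlap & sep_ok
  idx <- which(hit, arr.ind = TRUE)
  pairs <- unique(data.frame(i = pmin(ri[idx[, 1]], ri[idx[, 2]]),
                             j = pmax(ri[idx[, 1]], ri[idx[, 2]])))
  ca <- ca_coords(x)
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    nd <- sqrt(rowSums((ca[pairs$i, , drop = FALSE] -
                          ca[pairs$j, , drop = FALSE])^2))
  } else nd <- numeric(0)
  out <- tibble::tibble(i = as.integer(pairs$i), j = as.integer(pairs$j),
                        native_distance = nd,
                        sep = as.integer(pairs$j - pairs$i))
  class(out) <- c("contact_map", class(out))
  attr(out, "n_residues") <- n
  attr(out, "min_separation") <- as.integer(min_separation)
  attr(out, "mode") <- mode
  out
}

#' Write a contact map as 3-column text (i, j, native distance; 1-based)
#' @param cmap A `contact_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contact_map <- function(cmap, path) {
  utils::write.table(as.data.frame(cmap[, c("i", "j", "native_distance")]),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
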