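#' Construct a conformer
#'
#' A conformer is a single-chain protein structure: an ordered set of residues,
#' each carrying named heavy atoms with coordinates in Angstrom. It is the
#' substrate of every structural descriptor in the package. Residue and atom
#' order is preserved exactly as given; indices are 1-based everywhere.
#'
#' @param atoms Data frame with columns `resid` (integer residue index,
#'   consecutive from 1), `elety` (atom name: "N", "CA", "C", "O", ...),
#'   `x`, `y`, `z` (Angstrom).
#' @param sequence Character vector of one-letter residue codes, one per
#'   residue. Defaults to poly-glutamine ("Q").
#' @param id Text label.
#' @param timestamp Optional frame time in ps (for trajectory frames).
#' @return Object of class `conformer`.
#' @export
conformer <- function(atoms, sequence = NULL, id = "conf", timestamp = NA_real_) {
  stopifnot(is.data.frame(atoms),
            all(c("resid", "elety", "x", "y", "z") %in% names(atoms)))
  atoms <- tibble::as_tibble(atoms)
  atoms$resid <- as.integer(atoms$resid)
  n <- length(unique(atoms$resid))
  if (n < 2L) stop("a conformer needs at least 2 residues")
  if (!identical(sort(unique(atoms$resid)), seq_len(n)))
    stop("residue indices must be consecutive integers starting at 1")
  if (is.null(sequence)) sequence <- rep("Q", n)
  if (length(sequence) == 1L && nchar(sequence) == n)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) != n)
    stop("sequence length (", length(sequence), ") != residue count (", n, ")")
  ca <- atoms[atoms$elety == "CA", ]
  missing_ca <- setdiff(seq_len(n), ca$resid)
  if (length(missing_ca) > 0L)
    stop("residue ", missing_ca[1L], " has no CA atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  structure(
    list(id = id, sequence = sequence, atoms = atoms, timestamp = timestamp),
    class = "conformer"
  )
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer>", x$id, "-", n_residues(x), "residues,",
      nrow(x$atoms), "atoms")
  if (!is.na(x$timestamp)) cat(", t =", x$timestamp, "ps")
  cat("\n")
  invisible(x)
}

#' Number of residues in a conformer
#' @param x A `conformer`.
#' @return Integer count.
#' @export
n_residues <- function(x) {
  stopifnot(inherits(x, "conformer"))
  length(x$sequence)
}

#' Extract CA coordinates as a matrix
#'
#' @param x A `conformer`.
#' @return Numeric n x 3 matrix of CA coordinates (Angstrom), in residue order.
#' @export
ca_coords <- function(x) {
  stopifnot(inherits(x, "conformer"))
  ca <- x$atoms[x$atoms$elety == "CA", ]
  ca <- ca[order(ca$resid), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Build a CA-only conformer from a coordinate matrix
#'
#' @param xyz n x 3 matrix of CA positions (Angstrom).
#' @inheritParams conformer
#' @return A `conformer` carrying only CA atoms.
#' @export
conformer_from_ca <- function(xyz, sequence = NULL, id = "conf",
                              timestamp = NA_real_) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  atoms <- tibble::tibble(
    resid = seq_len(nrow(xyz)), elety = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  conformer(atoms, sequence = sequence, id = id, timestamp = timestamp)
}

#' Apply a rigid motion to a conformer
#'
#' @param x A `conformer`.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return Transformed `conformer`.
#' @export
transform_conformer <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(x, "conformer"))
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  m <- m %*% t(rotation) + matrix(translation, nrow(m), 3, byrow = TRUE)
  x$atoms$x <- m[, 1]; x$atoms$y <- m[, 2]; x$atoms$z <- m[, 3]
  x
}

#' Construct an ensemble of conformers
#'
#' @param conformers List of `conformer` objects.
#' @param is_time_ordered Logical; if `TRUE`, timestamps must be strictly
#'   increasing.
#' @param time_unit Unit of timestamps (default "ps").
#' @return Object of class `ensemble` (a list of conformers with attributes).
#' @export
ensemble <- function(conformers, is_time_ordered = FALSE, time_unit = "ps") {
  stopifnot(is.list(conformers),
            all(vapply(conformers, inherits, logical(1), "conformer")))
  if (is_time_ordered) {
    ts <- vapply(conformers, function(c) c$timestamp, numeric(1))
    if (anyNA(ts) || any(diff(ts) <= 0))
      stop("time-ordered ensemble requires strictly increasing timestamps")
  }
  structure(conformers, class = "ensemble",
            is_time_ordered = is_time_ordered, time_unit = time_unit)
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> of", length(x), "conformers")
  if (isTRUE(attr(x, "is_time_ordered")))
    cat(" (time-ordered, ", attr(x, "time_unit"), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
`[.ensemble` <- function(x, i) {
  ensemble(unclass(x)[i], is_time_ordered = attr(x, "is_time_ordered"),
           time_unit = attr(x, "time_unit"))
}

#' Timestamps of an ensemble
#' @param x An `ensemble`.
#' @return Numeric vector of frame times (ps; `NA` where absent).
#' @export
timestamps <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  vapply(unclass(x), function(c) c$timestamp, numeric(1))
}

# run code under a local, restored RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
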