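#' Minimal RMSD after optimal superposition
#'
#' Computes the root-mean-square deviation between two conformers after the
#' optimal rigid-body superposition (Kabsch): both coordinate sets are
#' centered and the rotation minimizing the RMSD is obtained in closed form
#' from the SVD of the covariance matrix. Reflections are disallowed (the
#' rotation determinant is forced positive), so mirror images do not give 0.
#'
#' @param a,b `conformer` objects with equal residue counts.
#' @param atom_set Atom name(s) to superpose on (default `"CA"`).
#' @return RMSD in Angstrom (single number, symmetric in `a` and `b`).
#' @export
superpose_rmsd <- function(a, b, atom_set = "CA") {
  pa <- atom_matrix(a, atom_set)
  pb <- atom_matrix(b, atom_set)
  if (nrow(pa) != nrow(pb))
    stop("conformers have different numbers of '", paste(atom_set, collapse = ","),
         "' atoms (", nrow(pa), " vs ", nrow(pb), ")")
  kabsch_rmsd(pa, pb)
}

atom_matrix <- function(x, atom_set) {
  stopifnot(inherits(x, "conformer"))
  sel <- x$atoms[x$atoms$elety %in% atom_set, ]
  if (nrow(sel) == 0L)
    stop("no atoms of type '", paste(atom_set, collapse = ","), "' in conformer ", x$id)
  sel <- sel[order(sel$resid, match(sel$elety, atom_set)), ]
  m <- as.matrix(sel[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

# Kabsch RMSD of two n x 3 matrices
kabsch_rmsd <- function(p, q) {
  p <- sweep(p, 2, colMeans(p))
  q <- sweep(q, 2, colMeans(q))
  s <- svd(crossprod(p, q))
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  dif <- p %*% r - q
  sqrt(sum(dif^2) / nrow(p))
}

# RMSD of raw coordinates (no superposition); used by perturbation checks
raw_rmsd <- function(p, q) sqrt(sum((p - q)^2) / nrow(p))
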