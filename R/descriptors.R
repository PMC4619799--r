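#' Radius of gyration of the CA trace
#'
#' Root-mean-square distance of the CA atoms from their centroid, in
#' Angstrom. Invariant under rigid motions.
#'
#' @param x A `conformer`.
#' @return R_g in Angstrom.
#' @export
radius_of_gyration <- function(x) {
  m <- ca_coords(x)
  ctr <- colMeans(m)
  sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
}

#' Gyration-tensor shape parameter w
#'
#' From the eigenvalues lambda1 >= lambda2 >= lambda3 of the CA gyration
#' tensor, with mean lambda-bar, returns
#' \deqn{w = \prod_i (\lambda_i - \bar\lambda) / \bar\lambda^3,}
#' the normalized prolateness: ~0 for globular shapes, positive for elongated
#' ones (a thin rod gives 2), negative for flattened ones (a thin disk gives
#' -0.25).
#'
#' @param x A `conformer`.
#' @return Dimensionless shape parameter.
#' @export
shape_parameter_w <- function(x) {
  m <- ca_coords(x)
  m <- sweep(m, 2, colMeans(m))
  gt <- crossprod(m) / nrow(m)
  ev <- eigen(gt, symmetric = TRUE, only.values = TRUE)$values
  lb <- mean(ev)
  if (lb <= 0) stop("degenerate gyration tensor: all points coincident")
  prod(ev - lb) / lb^3
}

#' Mean coordination number of a contact map
#'
#' Each residue is coordinated to its sequence neighbors through the peptide
#' bond (1 for chain ends, 2 otherwise) plus the residues it contacts.
#' With no contacts the mean is 2(N-1)/N.
#'
#' @param cmap A `contact_map` from [build_contact_map()].
#' @return Mean coordination number (dimensionless).
#' @export
mean_coordination <- function(cmap) {
  n <- attr(cmap, "n_residues")
  z <- rep(2, n)
  z[c(1, n)] <- 1
  if (nrow(cmap) > 0) {
    tab <- table(factor(c(cmap$i, cmap$j), levels = seq_len(n)))
    z <- z + as.numeric(tab)
  }
  mean(z)
}

#' Relative contact order
#'
#' \deqn{CO = \frac{1}{L \cdot N} \sum_k S_k} with L the chain length, N the
#' number of contacts and S_k the sequence separation of contact k.
#'
#' @param cmap A `contact_map`.
#' @return Contact order in (0, 1).
#' @export
contact_order <- function(cmap) {
  if (nrow(cmap) == 0) stop("contact order is undefined with zero contacts")
  sum(cmap$sep) / (attr(cmap, "n_residues") * nrow(cmap))
}

#' Finite-size Maxwell stiffness threshold on the mean coordination number
#'
#' A 3D frame of N particles with z contacts per particle on average has
#' N z / 2 constraints; mechanical rigidity requires N z / 2 >= 3N - 6,
#' i.e. z >= 6 - 12/N. The large-N limit is the classical Maxwell value 6;
#' small chains have a reduced threshold.
#'
#' @param n_residues Chain length (>= 3).
#' @return Threshold on the mean coordination number.
#' @export
stiff_limit <- function(n_residues) {
  stopifnot(n_residues >= 3)
  6 - 12 / n_residues
}

#' Volatility flag from the Maxwell criterion
#'
#' A conformer is volatile (mechanically floppy) when its mean coordination
#' number falls strictly below the finite-size stiffness threshold; a value
#' exactly at the threshold counts as stiff.
#'
#' @param z_mean Mean coordination number.
#' @param n_residues Chain length.
#' @return Logical.
#' @export
is_volatile <- function(z_mean, n_residues) {
  z_mean < stiff_limit(n_residues)
}

#' Per-conformer descriptor row
#'
#' Computes every structural descriptor for one conformer: R_g, shape
#' parameter w, secondary-structure percentages, mean coordination, contact
#' order, contact count and the Maxwell volatility flag.
#'
#' @param x A `conformer` (backbone atoms are rebuilt from the CA trace if
#'   N/C/O are absent).
#' @param radii Radii table for the contact criterion.
#' @param min_separation Minimal contact sequence separation.
#' @return One-row tibble.
#' @export
describe_conformer <- function(x, radii = default_radii(), min_separation = 3L) {
  stopifnot(inherits(x, "conformer"))
  if (!all(c("N", "C", "O") %in% x$atoms$elety)) x <- backbone_from_ca(x)
  cmap <- build_contact_map(x, radii = radii, min_separation = min_separation)
  ss <- assign_secondary_structure(x)
  n <- n_residues(x)
  z <- mean_coordination(cmap)
  tibble::tibble(
    id = x$id, n = n,
    r_g = radius_of_gyration(x),
    w = shape_parameter_w(x),
    ss_alpha = ss$ss_alpha, ss_beta = ss$ss_beta,
    ss_turn = ss$ss_turn, ss_total = ss$ss_total,
    z_mean = z,
    co = if (nrow(cmap) > 0) contact_order(cmap) else NA_real_,
    n_contacts = nrow(cmap),
    volatile = is_volatile(z, n),
    contact_mode = attr(cmap, "mode")
  )
}

#' Descriptor table for a whole ensemble
#'
#' @param x An `ensemble`.
#' @inheritParams describe_conformer
#' @return Tibble with one row per conformer (see [describe_conformer()]).
#' @export
describe_ensemble <- function(x, radii = default_radii(), min_separation = 3L) {
  stopifnot(inherits(x, "ensemble"))
  purrr::map_dfr(unclass(x), describe_conformer,
                 radii = radii, min_separation = min_separation)
}
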