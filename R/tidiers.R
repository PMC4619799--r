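#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-length rows of a length scan
#'
#' @param x A `length_scan`.
#' @param ... Unused.
#' @return Tibble with one row per chain length.
#' @method tidy length_scan
#' @export
tidy.length_scan <- function(x, ...) x$rows

#' One-row fit summary of a length scan
#'
#' @param x A `length_scan`.
#' @param ... Unused.
#' @return Tibble with the fitted constants of chi_F(n) = a log(n/b) and
#'   F^M_max(n) = c n^d and their standard errors.
#' @method glance length_scan
#' @export
glance.length_scan <- function(x, ...) {
  dplyr::bind_cols(x$fit_chi, x$fit_fmax,
                   tibble::tibble(chi_converged = x$converged[["chi"]],
                                  fmax_converged = x$converged[["fmax"]]))
}

#' Tidy the per-conformer table of an ensemble summary
#'
#' @param x An `ensemble_summary`.
#' @param ... Unused.
#' @return The per-conformer descriptor tibble.
#' @method tidy ensemble_summary
#' @export
tidy.ensemble_summary <- function(x, ...) x$table

#' One-row statistics of an ensemble summary
#'
#' @param x An `ensemble_summary`.
#' @param ... Unused.
#' @return Tibble with ensemble-level fractions and errors.
#' @method glance ensemble_summary
#' @export
glance.ensemble_summary <- function(x, ...) {
  tibble::tibble(
    n_conformers = nrow(x$table), n_residues = x$n,
    zero_peak_fraction = x$zero_peak_fraction %||% NA_real_,
    zero_peak_se = x$zero_peak_se %||% NA_real_,
    knotted_fraction = x$knotted_fraction %||% NA_real_,
    knotted_se = x$knotted_se %||% NA_real_
  )
}

#' Tidy a knot report
#'
#' @param x A `knot_report` or `knot_core`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy knot_report
#' @export
tidy.knot_report <- function(x, ...) {
  tibble::tibble(knot_type = x$knot_type, closure_votes = x$closure_votes)
}

#' @rdname tidy.knot_report
#' @method tidy knot_core
#' @export
tidy.knot_core <- function(x, ...) {
  tibble::tibble(knot_type = x$knot_type, k_minus = x$k_minus,
                 k_plus = x$k_plus, delta_k = x$delta_k)
}

#' Tidy a sieve result
#'
#' @param x A `sieve_result`.
#' @param ... Unused.
#' @return One row per time cluster, with an `independent` flag on the
#'   representatives retained by the RMSD stage.
#' @method tidy sieve_result
#' @export
tidy.sieve_result <- function(x, ...) {
  cl <- x$clusters
  if (nrow(cl) == 0) return(cl)
  cl$independent <- cl$representative %in% x$independent_idx
  cl
}

#' @rdname tidy.sieve_result
#' @method glance sieve_result
#' @export
glance.sieve_result <- function(x, ...) {
  tibble::tibble(n_input_frames = x$n_input_frames,
                 n_structured_frames = x$n_structured_frames,
                 n_clusters = nrow(x$clusters),
                 n_independent = length(x$independent_idx))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
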