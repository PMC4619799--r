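#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_col geom_tile labs theme_minimal .data
#' @export
ggplot2::autoplot

#' Plot a force-displacement curve with its detected peaks
#'
#' @param object A `force_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot force_curve
#' @export
autoplot.force_curve <- function(object, ...) {
  p <- ggplot(object$curve, aes(x = .data$d, y = .data$force)) +
    geom_line(color = "grey30") +
    labs(x = "displacement d (Å)", y = "F (ε/Å)",
         title = sprintf("F_max = %.2f ε/Å, n_p = %d",
                         object$f_max, object$n_p)) +
    theme_minimal()
  if (nrow(object$peaks) > 0)
    p <- p + geom_point(data = object$peaks,
                        aes(x = .data$d, y = .data$height),
                        color = "firebrick", size = 2)
  p
}

#' Plot an escape-probability curve
#'
#' @param object An `escape_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot escape_curve
#' @export
autoplot.escape_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$p_e)) +
    geom_step(color = "grey20") +
    labs(x = "time", y = expression(P[e](t))) +
    theme_minimal()
}

#' Plot the F_max histogram of an ensemble summary
#'
#' Conformers with no force peaks are not drawn but contribute to the
#' normalization, so the drawn mass integrates to 1 minus the zero-peak
#' fraction.
#'
#' @param object An `ensemble_summary` (with pulling results).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ensemble_summary
#' @export
autoplot.ensemble_summary <- function(object, ...) {
  if (is.null(object$fmax_hist)) stop("summary has no pulling results")
  h <- object$fmax_hist
  ggplot(h, aes(x = (.data$left + .data$right) / 2, y = .data$density)) +
    geom_col(width = h$right[1] - h$left[1], fill = "steelblue",
             color = "grey30") +
    labs(x = "F_max (ε/Å)", y = "probability density",
         title = sprintf("zero-peak fraction %.2f ± %.2f",
                         object$zero_peak_fraction, object$zero_peak_se)) +
    theme_minimal()
}

#' Plot chain-length trends and their fits
#'
#' @param object A `length_scan`.
#' @param ... Unused.
#' @return A ggplot of chi_F and the maximal F_max versus chain length, with
#'   the fitted logarithmic and power laws.
#' @method autoplot length_scan
#' @export
autoplot.length_scan <- function(object, ...) {
  rows <- object$rows
  grid <- tibble::tibble(n = seq(min(rows$n), max(rows$n), length.out = 100))
  grid$chi_f <- object$fit_chi$a * log(grid$n / object$fit_chi$b)
  grid$fmax_m <- object$fit_fmax$c * grid$n^object$fit_fmax$d
  long <- tidyr::pivot_longer(rows[, c("n", "chi_f", "fmax_m")],
                              c("chi_f", "fmax_m"),
                              names_to = "quantity", values_to = "value")
  fit_long <- tidyr::pivot_longer(grid, c("chi_f", "fmax_m"),
                                  names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$n, y = .data$value)) +
    geom_line(data = fit_long, linetype = "dotted", color = "grey40") +
    geom_point(color = "firebrick") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    labs(x = "chain length n", y = NULL) +
    theme_minimal()
}

#' Plot a contact map
#'
#' @param cmap A `contact_map`.
#' @return A ggplot with one tile per native contact.
#' @export
plot_contact_map <- function(cmap) {
  stopifnot(inherits(cmap, "contact_map"))
  n <- attr(cmap, "n_residues")
  df <- tibble::as_tibble(cmap)
  ggplot(rbind(df, stats::setNames(df[, c(2, 1, 3, 4)], names(df))),
         aes(x = .data$i, y = .data$j)) +
    geom_tile(fill = "grey20") +
    ggplot2::coord_fixed(xlim = c(1, n), ylim = c(1, n)) +
    labs(x = "residue i", y = "residue j") +
    theme_minimal()
}
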