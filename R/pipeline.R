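#' Full structural/mechanical characterization of an ensemble
#'
#' For every conformer: all structural descriptors, the Go-model pulling
#' response (median F_max and peak count over `n_seeds` pulls) and the knot
#' classification. Ensemble-level statistics follow: the zero-peak fraction
#' and the knotted fraction (both with bootstrap standard errors) and the
#' normalized F_max histogram, in which conformers without force peaks are
#' not binned but count towards the normalization.
#'
#' @param x An `ensemble` of equal-length conformers.
#' @param params [go_params()] for the pulls.
#' @param n_seeds Pulls per conformer; the reported F_max is the median
#'   (default 3).
#' @param run_pulling,run_knots Switch off the expensive stages if only
#'   descriptors are needed.
#' @param breaks Histogram bin edges for F_max in eps/A (default
#'   `seq(0, 3, 0.2)`).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Master seed (pull seeds and bootstrap derive from it).
#' @return List of class `ensemble_summary`: `table` (per-conformer tibble),
#'   `zero_peak_fraction`, `zero_peak_se`, `knotted_fraction`, `knotted_se`,
#'   `fmax_hist` (tibble `left`, `right`, `density`), `n`.
#' @export
characterize_ensemble <- function(x, params = go_params(), n_seeds = 3L,
                                  run_pulling = TRUE, run_knots = TRUE,
                                  breaks = seq(0, 3, 0.2), n_boot = 2000L,
                                  seed = 1L) {
  stopifnot(inherits(x, "ensemble"), length(x) >= 1)
  ns <- vapply(unclass(x), n_residues, integer(1))
  if (length(unique(ns)) > 1) stop("conformers have mixed chain lengths")
  rows <- purrr::imap_dfr(unclass(x), function(cf, k) {
    if (!all(c("N", "C", "O") %in% cf$atoms$elety)) cf <- backbone_from_ca(cf)
    d <- describe_conformer(cf)
    if (run_pulling) {
      cmap <- build_contact_map(cf)
      model <- build_go_model(cf, cmap, params)
      pulls <- vapply(seq_len(n_seeds), function(s) {
        p <- params
        p$seed <- as.integer(seed * 10000L + k * 100L + s)
        fc <- pull_constant_speed(model, p)
        c(fc$f_max, fc$n_p)
      }, numeric(2))
      d$f_max <- stats::median(pulls[1, ])
      d$n_p <- round(stats::median(pulls[2, ]))
    } else {
      d$f_max <- NA_real_; d$n_p <- NA_integer_
    }
    if (run_knots) {
      kr <- classify_knot(cf, seed = seed + k)
      d$knot_type <- kr$knot_type
      if (kr$knot_type != "0_1") {
        kc <- knot_core(cf, seed = seed + k)
        d$delta_k <- kc$delta_k
      } else d$delta_k <- NA_integer_
    } else {
      d$knot_type <- NA_character_; d$delta_k <- NA_integer_
    }
    d
  })
  out <- list(table = rows, n = unique(ns))
  if (run_pulling) {
    zp <- fraction_with_bootstrap(rows$f_max == 0, n_boot = n_boot, seed = seed)
    out$zero_peak_fraction <- zp$fraction
    out$zero_peak_se <- zp$se
    pos <- rows$f_max[rows$f_max > 0]
    h <- graphics::hist(pmin(pos, max(breaks)), breaks = breaks, plot = FALSE)
    # normalize including the zero-peak mass: total probability 1
    dens <- h$counts / nrow(rows) / diff(breaks)
    out$fmax_hist <- tibble::tibble(left = breaks[-length(breaks)],
                                    right = breaks[-1], density = dens)
  }
  if (run_knots) {
    kf <- fraction_with_bootstrap(rows$knot_type != "0_1", n_boot = n_boot,
                                  seed = seed + 1L)
    out$knotted_fraction <- kf$fraction
    out$knotted_se <- kf$se
  }
  structure(out, class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary>", nrow(x$table), "conformers of length", x$n, "\n")
  if (!is.null(x$zero_peak_fraction))
    cat("  zero-peak fraction:", sprintf("%.3f +/- %.3f", x$zero_peak_fraction,
                                         x$zero_peak_se), "\n")
  if (!is.null(x$knotted_fraction))
    cat("  knotted fraction:  ", sprintf("%.3f +/- %.3f", x$knotted_fraction,
                                         x$knotted_se), "\n")
  invisible(x)
}

#' Fraction of TRUE flags with a bootstrap standard error
#'
#' Point estimate is the sample mean; the error is the standard deviation of
#' the mean over `n_boot` resamples with replacement. Deterministic per seed.
#'
#' @param flags Logical vector (nonempty).
#' @param n_boot Number of resamples (default 2000).
#' @param seed Integer seed.
#' @return List: `fraction`, `se`.
#' @export
fraction_with_bootstrap <- function(flags, n_boot = 2000L, seed = 1L) {
  if (length(flags) == 0) stop("empty flag vector")
  flags <- as.logical(flags)
  n <- length(flags)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(flags[sample.int(n, n, replace = TRUE)]), numeric(1)))
  list(fraction = mean(flags), se = stats::sd(boot))
}

#' Chain-length scan with logarithmic and power-law fits
#'
#' Assembles per-length ensemble statistics and fits the two laws that
#' summarize how mechanical stability grows with chain length: the fraction
#' of mechanically stable conformers chi_F(n) = a log(n / b), and the set
#' maximum of F_max, F^M_max(n) = c n^d. Fits are nonlinear least squares
#' (with a log-linear fallback for the power law).
#'
#' @param rows Tibble with one row per chain length: columns `n`, `chi_f`,
#'   `fmax_m` (and optionally `mean_rg`, `mean_w`, `knotted_fraction`).
#'   Alternatively a named list of `ensemble_summary` objects keyed by n.
#' @return List of class `length_scan`: `rows`, `fit_chi` (tibble a, b with
#'   SEs), `fit_fmax` (tibble c, d with SEs), `converged`.
#' @export
length_scan <- function(rows) {
  if (is.list(rows) && !is.data.frame(rows) &&
      all(vapply(rows, inherits, logical(1), "ensemble_summary"))) {
    rows <- purrr::imap_dfr(rows, function(s, nm) {
      tb <- s$table
      tibble::tibble(n = s$n,
                     chi_f = mean(tb$f_max > 0),
                     fmax_m = max(tb$f_max),
                     mean_rg = mean(tb$r_g), mean_w = mean(tb$w),
                     knotted_fraction = mean(tb$knot_type != "0_1"))
    })
  }
  rows <- dplyr::arrange(tibble::as_tibble(rows), .data$n)
  if (nrow(rows) < 3) stop("need >= 3 chain lengths for fitting")
  conv <- c(chi = TRUE, fmax = TRUE)

  fit_chi <- tryCatch({
    fl <- stats::nls(chi_f ~ a * log(n / b), data = rows,
                     start = list(a = 0.3, b = min(rows$n) / 2))
    co <- summary(fl)$coefficients
    tibble::tibble(a = co["a", 1], a_se = co["a", 2],
                   b = co["b", 1], b_se = co["b", 2])
  }, error = function(e) {
    conv["chi"] <<- FALSE
    # chi = a log n - a log b is linear in log n
    lf <- stats::lm(chi_f ~ log(n), data = rows)
    a <- stats::coef(lf)[2]
    tibble::tibble(a = unname(a), a_se = NA_real_,
                   b = unname(exp(-stats::coef(lf)[1] / a)), b_se = NA_real_)
  })

  fit_fmax <- tryCatch({
    fl <- stats::nls(fmax_m ~ c * n^d, data = rows,
                     start = list(c = 0.3, d = 0.5))
    co <- summary(fl)$coefficients
    tibble::tibble(c = co["c", 1], c_se = co["c", 2],
                   d = co["d", 1], d_se = co["d", 2])
  }, error = function(e) {
    conv["fmax"] <<- FALSE
    lf <- stats::lm(log(fmax_m) ~ log(n), data = rows[rows$fmax_m > 0, ])
    tibble::tibble(c = unname(exp(stats::coef(lf)[1])), c_se = NA_real_,
                   d = unname(stats::coef(lf)[2]), d_se = NA_real_)
  })

  structure(list(rows = rows, fit_chi = fit_chi, fit_fmax = fit_fmax,
                 converged = conv),
            class = "length_scan")
}

#' @export
print.length_scan <- function(x, ...) {
  cat("<length_scan>", nrow(x$rows), "chain lengths\n")
  cat(sprintf("  chi_F(n) = %.3f ln(n / %.3f)\n", x$fit_chi$a, x$fit_chi$b))
  cat(sprintf("  F^M_max(n) = %.3f n^%.3f\n", x$fit_fmax$c, x$fit_fmax$d))
  invisible(x)
}

#' Sup gap between the joint CDF and the product of marginals
#'
#' Evaluates sup over the sample grid of |F_xy(a, b) - F_x(a) F_y(b)|, a
#' direct check of statistical independence of two descriptors. Values near
#' zero indicate independence; comonotone variables reach 0.25.
#'
#' @param x,y Equal-length samples (n >= 20).
#' @return The gap, in [0, 1].
#' @export
independence_cdf_gap <- function(x, y) {
  if (length(x) != length(y)) stop("samples differ in length")
  n <- length(x)
  if (n < 20) stop("need at least 20 paired samples")
  ox <- outer(x, x, "<=")          # ox[i,k]: x_i <= x_k
  oy <- outer(y, y, "<=")
  fx <- colMeans(ox)
  fy <- colMeans(oy)
  joint <- crossprod(ox, oy) / n   # joint[k,l] = P(x <= x_k, y <= y_l)
  max(abs(joint - outer(fx, fy)))
}

#' Ordinary least-squares screen of a descriptor pair
#'
#' Regresses y on x and reports the statistics used to judge whether the
#' association is real but weak (significant slope, low R^2) or absent.
#'
#' @param x,y Equal-length numeric samples (n >= 3).
#' @return One-row tibble: `r_squared`, `slope`, `slope_se`, `p_value`,
#'   `intercept`.
#' @export
correlation_screen <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need matched n >= 3")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact linear input is legitimate
  co <- sm$coefficients
  tibble::tibble(r_squared = sm$r.squared,
                 slope = co["x", "Estimate"], slope_se = co["x", "Std. Error"],
                 p_value = co["x", "Pr(>|t|)"],
                 intercept = co["(Intercept)", "Estimate"])
}

#' Null probability of a homopolymeric tract
#'
#' Probability that a specific run of `length` identical residues occurs
#' under the uniform 20-letter null: (1/20)^length.
#'
#' @param length Tract length (>= 1).
#' @return Probability.
#' @export
tract_null_probability <- function(length) {
  if (any(length < 1)) stop("tract length must be >= 1")
  (1 / 20)^length
}

#' Scan sequences for homopolymeric tracts
#'
#' Finds maximal runs of identical residues of at least `min_length`.
#'
#' @param sequences Character vector of residue strings (20-letter alphabet),
#'   optionally named.
#' @param min_length Minimal reported run length (default 5).
#' @return Tibble: `seq_id`, `residue`, `start` (1-based), `length`.
#' @export
scan_homopolymer_tracts <- function(sequences, min_length = 5L) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  purrr::map2_dfr(sequences, ids, function(s, id) {
    ch <- strsplit(toupper(s), "")[[1]]
    bad <- which(!ch %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    if (length(bad) > 0)
      stop("invalid residue '", ch[bad[1]], "' at position ", bad[1],
           " of ", id)
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_length
    tibble::tibble(seq_id = id, residue = r$values[keep],
                   start = starts[keep], length = r$lengths[keep])
  })
}
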