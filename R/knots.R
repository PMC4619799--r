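# Knot detection and localization in open CA chains: KMT chain reduction,
# stochastic closure to a sphere, Alexander-invariant classification.

# segment/triangle intersection, vectorized over segments.
# tri: 3 x 3 matrix (rows A, B, C); p0, p1: m x 3 segment endpoints.
# Conservative on degeneracies (counts touching as intersecting).
segments_cross_triangle <- function(tri, p0, p1) {
  a <- tri[1, ]; b <- tri[2, ]; cc <- tri[3, ]
  nv <- vcross(b - a, cc - a)
  nn <- vnorm(nv)
  if (nn < 1e-12) return(rep(FALSE, nrow(p0)))  # degenerate triangle
  d0 <- (p0[, 1] - a[1]) * nv[1] + (p0[, 2] - a[2]) * nv[2] + (p0[, 3] - a[3]) * nv[3]
  d1 <- (p1[, 1] - a[1]) * nv[1] + (p1[, 2] - a[2]) * nv[2] + (p1[, 3] - a[3]) * nv[3]
  tol <- 1e-9 * nn
  out <- rep(FALSE, nrow(p0))
  touching <- (abs(d0) <= tol) | (abs(d1) <= tol)
  crossing <- (d0 > tol & d1 < -tol) | (d0 < -tol & d1 > tol)
  idx <- which(crossing)
  if (length(idx) > 0) {
    tt <- d0[idx] / (d0[idx] - d1[idx])
    xpt <- p0[idx, , drop = FALSE] + tt * (p1[idx, , drop = FALSE] - p0[idx, , drop = FALSE])
    # barycentric test in the triangle plane
    v0 <- cc - a; v1 <- b - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    v2 <- sweep(xpt, 2, a)
    d02 <- v2 %*% v0; d12 <- v2 %*% v1
    inv <- 1 / (d00 * d11 - d01 * d01)
    u <- (d11 * d02 - d01 * d12) * inv
    v <- (d00 * d12 - d01 * d02) * inv
    inside <- (u >= -1e-9) & (v >= -1e-9) & (u + v <= 1 + 1e-9)
    out[idx] <- as.vector(inside)
  }
  out | touching
}

#' KMT reduction of a polyline
#'
#' Iteratively removes an interior vertex whenever the triangle spanned by it
#' and its two neighbors is crossed by no other segment of the chain, which
#' preserves the (closure) topology while shrinking the chain. Endpoints are
#' never removed. Idempotent once no vertex is removable.
#'
#' @param xyz n x 3 coordinate matrix (open polyline) or a `conformer`.
#' @return Reduced m x 3 matrix (m <= n) with attribute `"kept"` holding the
#'   original vertex indices.
#' @export
kmt_reduce <- function(xyz) {
  if (inherits(xyz, "conformer")) xyz <- ca_coords(xyz)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  if (nrow(xyz) < 3) {
    attr(xyz, "kept") <- seq_len(nrow(xyz))
    return(xyz)
  }
  kept <- seq_len(nrow(xyz))
  repeat {
    n <- nrow(xyz)
    if (n <= 3) break
    removed <- FALSE
    i <- 2L
    while (i < nrow(xyz)) {
      n <- nrow(xyz)
      tri <- xyz[(i - 1):(i + 1), ]
      segs <- cbind(seq_len(n - 1), 2:n)
      # exclude segments sharing a vertex with the triangle: they can meet it
      # only at the shared corner, never cross its interior
      segs <- segs[segs[, 1] < i - 2 | segs[, 1] > i + 1, , drop = FALSE]
      if (nrow(segs) == 0 ||
          !any(segments_cross_triangle(tri, xyz[segs[, 1], , drop = FALSE],
                                       xyz[segs[, 2], , drop = FALSE]))) {
        xyz <- xyz[-i, , drop = FALSE]
        kept <- kept[-i]
        removed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!removed) break
  }
  attr(xyz, "kept") <- kept
  xyz
}

#' Stochastic closures of an open chain
#'
#' Extends both termini radially away from the chain centroid to a bounding
#' sphere of radius 10 times the radius of gyration, then joins them through
#' a point drawn uniformly on that sphere. Far closures leave the knotted
#' core untouched, so the vote over many closures reflects the chain's own
#' topology. Deterministic per seed.
#'
#' @param xyz n x 3 CA matrix or `conformer`.
#' @param n_closures Number of closures (default 64).
#' @param seed Integer seed.
#' @return List of closed polylines (matrices; last vertex connects to first).
#' @export
close_chain <- function(xyz, n_closures = 64L, seed = 1L) {
  if (inherits(xyz, "conformer")) xyz <- ca_coords(xyz)
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) >= 3)
  ctr <- colMeans(xyz)
  rg <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
  R <- max(10 * rg, 10)
  ext <- function(p) {
    d <- p - ctr
    nd <- vnorm(d)
    if (nd < 1e-6) d <- c(1, 0, 0) else d <- d / nd
    ctr + R * d
  }
  e_start <- ext(xyz[1, ])
  e_end <- ext(xyz[nrow(xyz), ])
  with_seed(seed, {
    lapply(seq_len(n_closures), function(k) {
      u <- stats::rnorm(3)
      s <- ctr + R * u / vnorm(u)
      rbind(xyz, e_end, s, e_start)
    })
  })
}

# 2D crossings of a closed polyline projected on xy.
# Returns NULL if the projection is degenerate (needs a retry).
diagram_crossings <- function(xyz) {
  n <- nrow(xyz)
  nxt <- c(2:n, 1L)
  p <- xyz[, 1:2, drop = FALSE]
  z <- xyz[, 3]
  cross_list <- list()
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip segments adjacent through the wrap
    if (length(js) == 0) next
    a0 <- p[i, ]; a1 <- p[nxt[i], ]
    r <- a1 - a0
    b0 <- p[js, , drop = FALSE]; b1 <- p[nxt[js], , drop = FALSE]
    s1 <- b1[, 1] - b0[, 1]; s2 <- b1[, 2] - b0[, 2]
    den <- r[1] * s2 - r[2] * s1
    qp1 <- b0[, 1] - a0[1]; qp2 <- b0[, 2] - a0[2]
    tnum <- qp1 * s2 - qp2 * s1
    unum <- qp1 * r[2] - qp2 * r[1]
    par <- abs(den) < 1e-12
    tt <- ifelse(par, NA, tnum / den)
    uu <- ifelse(par, NA, unum / den)
    hit <- !par & tt > 1e-9 & tt < 1 - 1e-9 & uu > 1e-9 & uu < 1 - 1e-9
    near <- !par & tt > -1e-6 & tt < 1 + 1e-6 & uu > -1e-6 & uu < 1 + 1e-6 & !hit
    if (any(near, na.rm = TRUE)) return(NULL)  # endpoint grazing: not generic
    for (k in which(hit)) {
      j <- js[k]
      zi <- z[i] + tt[k] * (z[nxt[i]] - z[i])
      zj <- z[j] + uu[k] * (z[nxt[j]] - z[j])
      if (abs(zi - zj) < 1e-9) return(NULL)
      over_first <- zi > zj
      # crossing sign from the 2D orientation of (over dir, under dir)
      ro <- if (over_first) r else c(s1[k], s2[k])
      ru <- if (over_first) c(s1[k], s2[k]) else r
      sgn <- sign(ro[1] * ru[2] - ro[2] * ru[1])
      cross_list[[length(cross_list) + 1L]] <- data.frame(
        s_over = (if (over_first) i + tt[k] else j + uu[k]),
        s_under = (if (over_first) j + uu[k] else i + tt[k]),
        sign = sgn)
    }
  }
  do.call(rbind, c(cross_list, list(data.frame(s_over = numeric(),
                                               s_under = numeric(),
                                               sign = numeric()))))
}

#' Alexander-invariant pair of a closed polyline
#'
#' Computes |Delta(-1)| and the odd part of |Delta(-2)| from the crossing
#' matrix of a generic planar projection (the projection direction is
#' re-randomized until generic). The pair separates the unknot and the 3_1,
#' 4_1, 5_1 and 5_2 knots: (1,1), (3,7), (5,11), (5,31), (7,1).
#'
#' @param xyz Closed polyline as an n x 3 matrix (last vertex joins the
#'   first).
#' @param seed Seed for the projection-direction retries.
#' @return Integer vector `c(det1, det2)`.
#' @export
alexander_invariants <- function(xyz, seed = 1L) {
  xyz <- as.matrix(xyz)
  with_seed(seed, {
    for (attempt in 1:25) {
      rot <- random_rotation()
      cr <- diagram_crossings(xyz %*% rot)
      if (!is.null(cr)) return(alexander_from_crossings(cr))
    }
  })
  stop("no generic projection found after bounded retries")
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

odd_part <- function(v) {
  v <- round(abs(v))
  if (v == 0) return(0)
  while (v %% 2 == 0) v <- v / 2
  v
}

alexander_from_crossings <- function(cr) {
  n <- nrow(cr)
  if (n == 0) return(c(1L, 1L))
  o <- order(cr$s_under)
  cr <- cr[o, ]
  s_under <- cr$s_under
  # generator arc containing a chain position (arc j ends at underpass j)
  arc_of <- function(p) {
    idx <- findInterval(p, s_under)
    if (idx == 0 || idx == n) 1L else idx + 1L
  }
  det_at <- function(t) {
    M <- matrix(0, n, n)
    for (k in seq_len(n)) {
      i <- arc_of(cr$s_over[k])
      k1 <- if (k == n) 1L else k + 1L
      if (i == k || i == k1) {
        M[k, k] <- M[k, k] - 1
        M[k, k1] <- M[k, k1] + 1
      } else if (cr$sign[k] > 0) {
        M[k, k] <- M[k, k] + 1
        M[k, k1] <- M[k, k1] - t
        M[k, i] <- M[k, i] + t - 1
      } else {
        M[k, k] <- M[k, k] - t
        M[k, k1] <- M[k, k1] + 1
        M[k, i] <- M[k, i] + t - 1
      }
    }
    if (n == 1) return(1)
    det(M[-n, -n, drop = FALSE])
  }
  d1 <- round(abs(det_at(-1)))
  d2 <- odd_part(det_at(-2))
  c(as.integer(d1), as.integer(d2))
}

invariants_to_type <- function(inv) {
  d1 <- inv[1]; d2 <- inv[2]
  if (d1 == 1 && d2 == 1) return("0_1")
  if (d1 == 3) return("3_1")
  if (d1 == 5 && d2 == 11) return("4_1")
  if (d1 == 5 && d2 == 31) return("5_1")
  if (d1 == 7) return("5_2")
  "other"
}

#' Classify the knot type of an open CA chain
#'
#' KMT-reduces the chain, closes it stochastically many times, computes the
#' Alexander-invariant pair of each closure and takes the majority vote.
#' Ties vote "other".
#'
#' @param x A `conformer` or n x 3 CA matrix.
#' @param n_closures Number of stochastic closures (default 64).
#' @param seed Integer seed (drives closures and projections).
#' @return List of class `knot_report`: `knot_type`, `closure_votes`
#'   (fraction agreeing with the winner), `votes` (table).
#' @export
classify_knot <- function(x, n_closures = 64L, seed = 1L) {
  xyz <- if (inherits(x, "conformer")) ca_coords(x) else as.matrix(x)
  red <- kmt_reduce(xyz)
  if (nrow(red) <= 3)   # a fully reducible (planar) chain cannot be knotted
    return(structure(list(knot_type = "0_1", closure_votes = 1,
                          votes = stats::setNames(n_closures, "0_1"),
                          n_closures = n_closures),
                     class = "knot_report"))
  closures <- close_chain(red, n_closures = n_closures, seed = seed)
  types <- vapply(seq_along(closures), function(k) {
    inv <- alexander_invariants(closures[[k]], seed = seed + 7919L * k)
    invariants_to_type(inv)
  }, character(1))
  tab <- sort(table(types), decreasing = TRUE)
  winner <- if (length(tab) > 1 && tab[1] == tab[2]) "other" else names(tab)[1]
  votes <- if (winner %in% names(tab)) unname(tab[winner]) / length(types) else 0
  structure(list(knot_type = winner, closure_votes = votes,
                 votes = tab, n_closures = n_closures),
            class = "knot_report")
}

#' @export
print.knot_report <- function(x, ...) {
  cat("<knot_report>", x$knot_type,
      sprintf("(%.0f%% of %d closures)\n", 100 * x$closure_votes, x$n_closures))
  invisible(x)
}

#' Localize the knot core by bidirectional trimming
#'
#' Removes residues one at a time from the N-terminus while the remaining
#' subchain still classifies to the original knot type, then likewise from
#' the C-terminus. The surviving span [k_minus, k_plus] is the knot core;
#' its extension is delta_k = k_plus - k_minus + 1 residues.
#'
#' @param x A `conformer` or CA matrix, already knotted.
#' @param n_closures Closures per classification (default 48).
#' @param seed Integer seed.
#' @return List of class `knot_core`: `knot_type`, `k_minus`, `k_plus`,
#'   `delta_k`.
#' @export
knot_core <- function(x, n_closures = 48L, seed = 1L) {
  xyz <- if (inherits(x, "conformer")) ca_coords(x) else as.matrix(x)
  full <- classify_knot(xyz, n_closures = n_closures, seed = seed)
  if (full$knot_type == "0_1") stop("knot_core on an unknotted chain")
  target <- full$knot_type
  n <- nrow(xyz)
  k_minus <- 1L
  while (k_minus < n - 3) {
    sub <- xyz[(k_minus + 1):n, , drop = FALSE]
    cl <- classify_knot(sub, n_closures = n_closures, seed = seed + k_minus)
    if (cl$knot_type == target) k_minus <- k_minus + 1L else break
  }
  k_plus <- n
  while (k_plus > k_minus + 3) {
    sub <- xyz[k_minus:(k_plus - 1), , drop = FALSE]
    cl <- classify_knot(sub, n_closures = n_closures, seed = seed + 31L * k_plus)
    if (cl$knot_type == target) k_plus <- k_plus - 1L else break
  }
  structure(list(knot_type = target, k_minus = k_minus, k_plus = k_plus,
                 delta_k = k_plus - k_minus + 1L),
            class = "knot_core")
}

#' @export
print.knot_core <- function(x, ...) {
  cat("<knot_core>", x$knot_type, "core", x$k_minus, "-", x$k_plus,
      "(delta_k =", x$delta_k, "residues)\n")
  invisible(x)
}

#' Fraction of pulling runs that untie a knotted conformer
#'
#' Stretches the model once per seed and classifies the final conformation;
#' a run "unties" when the final chain classifies as the unknot. Reports the
#' untied fraction with its binomial standard error.
#'
#' @param model A `go_model` built from a knotted conformer.
#' @param params A [go_params()] list.
#' @param n_seeds Number of independent pulls (default 10).
#' @param base_seed First seed; runs use `base_seed + 0:(n_seeds-1)`.
#' @return List: `fraction_untied`, `se` (binomial), `final_types`.
#' @export
untying_under_stretch <- function(model, params = go_params(), n_seeds = 10L,
                                  base_seed = 1L) {
  stopifnot(inherits(model, "go_model"))
  init <- classify_knot(model$coords, seed = base_seed)
  if (init$knot_type == "0_1")
    stop("untying_under_stretch requires an initially knotted conformer")
  types <- vapply(seq_len(n_seeds), function(k) {
    p <- params
    p$seed <- as.integer(base_seed + k - 1L)
    fc <- pull_constant_speed(model, p)
    classify_knot(fc$final_coords, seed = base_seed + 1000L + k)$knot_type
  }, character(1))
  frac <- mean(types == "0_1")
  se <- sqrt(frac * (1 - frac) / n_seeds)
  list(fraction_untied = frac, se = se, final_types = types,
       initial_type = init$knot_type)
}
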