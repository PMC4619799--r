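#' @useDynLib polyknot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal geometry helpers ----------------------------------------------

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
vnorm <- function(a) sqrt(sum(a^2))
vunit <- function(a) a / vnorm(a)

# NeRF: place atom D given A, B, C, bond |C-D|, angle B-C-D (deg),
# dihedral A-B-C-D (deg)
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  c(c + m %*% d2)
}

# standard backbone geometry (Engh-Huber-like ideal values, Angstrom/deg)
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_c_n_ca = 121.9, a_ca_c_o = 120.8,
  omega = 180
)

# build full backbone (N, CA, C, O per residue) from phi/psi lists
backbone_from_dihedrals <- function(phi, psi, id = "conf", sequence = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  g <- .bb
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi[i])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c, g$a_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n)) {
    # carbonyl O in the peptide plane, anti to the next amide N
    psi_o <- if (i < n) psi[i] + 180 else 0
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi_o)
  }
  atoms_from_backbone(N, CA, C, O, id = id, sequence = sequence)
}

atoms_from_backbone <- function(N, CA, C, O, id, sequence = NULL,
                                timestamp = NA_real_) {
  n <- nrow(CA)
  atoms <- tibble::tibble(
    resid = rep(seq_len(n), each = 4L),
    elety = rep(c("N", "CA", "C", "O"), n),
    x = as.vector(t(cbind(N[, 1], CA[, 1], C[, 1], O[, 1]))),
    y = as.vector(t(cbind(N[, 2], CA[, 2], C[, 2], O[, 2]))),
    z = as.vector(t(cbind(N[, 3], CA[, 3], C[, 3], O[, 3])))
  )
  conformer(atoms, sequence = sequence, id = id, timestamp = timestamp)
}

# ---- ideal secondary-structure motifs ---------------------------------------

#' Build an idealized conformer
#'
#' Deterministic reference structures with full backbone (N, CA, C, O):
#' `"helix"` uses ideal alpha-helical dihedrals (phi = -57, psi = -47),
#' `"hairpin"` is two antiparallel strands joined by a tight two-residue turn,
#' `"extended"` is a near-colinear chain with ~3.8 A CA spacing.
#'
#' @param kind One of `"helix"`, `"hairpin"`, `"extended"`.
#' @param n Number of residues (>= 6 for helix/hairpin, >= 2 for extended).
#' @return A `conformer` with backbone heavy atoms.
#' @export
make_ideal <- function(kind = c("helix", "hairpin", "extended"), n) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (kind %in% c("helix", "hairpin") && n < 6L)
    stop("'", kind, "' needs n >= 6")
  if (n < 2L) stop("n too small")
  if (kind == "helix") {
    phi <- rep(-57, n); psi <- rep(-47, n)
  } else if (kind == "extended") {
    phi <- rep(-180, n); psi <- rep(180, n)
  } else {
    # antiparallel hairpin: strand / type-I' turn / strand
    n1 <- (n - 2L) %/% 2L
    n2 <- n - 2L - n1
    phi <- c(rep(-120, n1), 60, 90, rep(-120, n2))
    psi <- c(rep(130, n1), 30, 0, rep(130, n2))
  }
  backbone_from_dihedrals(phi, psi, id = paste0("ideal_", kind, "_", n))
}

# ---- self-avoiding coil -----------------------------------------------------

#' Generate a self-avoiding random CA coil
#'
#' Grows a CA chain with fixed 3.8 A bonds and uniformly random directions,
#' rejecting any step that brings a non-bonded CA pair closer than 4.0 A
#' (with backtracking restarts). Bitwise reproducible per seed.
#'
#' @param n Number of residues (>= 4).
#' @param seed Integer seed; fully determines the output.
#' @param bond_length CA-CA bond length in Angstrom (default 3.8).
#' @param min_dist Minimal allowed non-bonded CA-CA distance (default 4.0 A).
#' @return A CA-only `conformer`.
#' @export
make_self_avoiding_coil <- function(n, seed, bond_length = 3.8, min_dist = 4.0) {
  n <- as.integer(n)
  if (n < 4L) stop("n must be >= 4")
  with_seed(seed, {
    for (attempt in 1:200) {
      xyz <- matrix(NA_real_, n, 3)
      xyz[1, ] <- c(0, 0, 0)
      xyz[2, ] <- c(bond_length, 0, 0)
      ok <- TRUE
      i <- 3L
      while (i <= n) {
        placed <- FALSE
        for (try in 1:60) {
          u <- stats::rnorm(3)
          cand <- xyz[i - 1L, ] + bond_length * u / sqrt(sum(u^2))
          d2 <- rowSums((xyz[seq_len(i - 2L), , drop = FALSE] -
                           matrix(cand, i - 2L, 3, byrow = TRUE))^2)
          if (all(d2 >= min_dist^2)) {
            xyz[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
        i <- i + 1L
      }
      if (ok) return(conformer_from_ca(xyz, id = paste0("coil_", n, "_s", seed)))
    }
    stop("self-avoiding coil generation failed after bounded retries")
  })
}

# ---- knotted chains ---------------------------------------------------------

# closed parametric curves for the standard knots (unit-scale polylines)
knot_parametric_curve <- function(knot_type, n_points = 600L) {
  t <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  xyz <- switch(knot_type,
    "0_1" = cbind(cos(t), sin(t), 0 * t),
    "3_1" = cbind(sin(t) + 2 * sin(2 * t),
                  cos(t) - 2 * cos(2 * t),
                  -sin(3 * t)),
    "4_1" = cbind((2 + cos(2 * t)) * cos(3 * t),
                  (2 + cos(2 * t)) * sin(3 * t),
                  sin(4 * t)),
    "5_1" = cbind((2 + cos(5 * t)) * cos(2 * t),
                  (2 + cos(5 * t)) * sin(2 * t),
                  sin(5 * t)),
    "5_2" = braid_closure_curve(c(1, 1, 1, 2, -1, 2), 3L),
    stop("unsupported knot type: ", knot_type)
  )
  xyz
}

# Closed curve of the closure of a braid word in B_k, embedded in an annulus:
# strand rows live on concentric circles of radii R0 + (row-1) dr, the braid
# axis runs around the circle, and the closure is the identification of angle
# 0 with 2 pi (the curve winds once per row until it returns to its start).
# At letter +g the strand entering at row g passes over (positive z bump);
# -g the opposite. Row swaps are cosine-eased, so the curve is smooth and
# keeps clearances of order dr everywhere -- it survives coarse resampling.
braid_closure_curve <- function(word, n_strands, R0 = 4, dr = 1.5,
                                zb = 0.7, pts_per_window = 40L) {
  m <- length(word)
  # row permutation of one full revolution
  perm <- seq_len(n_strands)
  for (t in seq_len(m)) {
    g <- abs(word[t])
    perm[c(g, g + 1L)] <- perm[c(g + 1L, g)]
  }
  # follow the strand starting at row 1 through revolutions until it returns
  curve <- NULL
  row <- 1L
  n_rev <- 0L
  repeat {
    for (t in seq_len(m)) {
      g <- abs(word[t])
      f <- seq(0, 1, length.out = pts_per_window + 1L)[-(pts_per_window + 1L)]
      th <- (n_rev + (t - 1 + f) / m) * 2 * pi
      if (row == g || row == g + 1L) {
        row_to <- if (row == g) g + 1L else g
        ease <- (1 - cos(pi * f)) / 2
        r_now <- R0 + (row - 1 + (row_to - row) * ease) * dr
        over <- (word[t] > 0) == (row == g)   # entering-lower strand over iff +g
        z <- (if (over) zb else -zb) * sin(pi * f)
        row <- row_to
      } else {
        r_now <- rep(R0 + (row - 1) * dr, length(f))
        z <- rep(0, length(f))
      }
      curve <- rbind(curve, cbind(r_now * cos(th), r_now * sin(th), z))
    }
    n_rev <- n_rev + 1L
    if (row == 1L) break
    if (n_rev > n_strands) stop("braid closure produced a link, not a knot")
  }
  curve
}

# Chaikin corner cutting; keeps topology, rounds sharp corners
chaikin_smooth <- function(xyz, iterations = 4L, closed = TRUE) {
  for (it in seq_len(iterations)) {
    p <- if (closed) rbind(xyz, xyz[1, ]) else xyz
    a <- 0.75 * p[-nrow(p), , drop = FALSE] + 0.25 * p[-1, , drop = FALSE]
    b <- 0.25 * p[-nrow(p), , drop = FALSE] + 0.75 * p[-1, , drop = FALSE]
    new <- matrix(NA_real_, 2 * nrow(a), 3)
    new[seq(1, nrow(new), 2), ] <- a
    new[seq(2, nrow(new), 2), ] <- b
    if (!closed) new <- rbind(xyz[1, ], new, xyz[nrow(xyz), ])
    xyz <- new
  }
  xyz
}

# resample a polyline (closed or open) at equal arc-length spacing
resample_polyline <- function(xyz, n_out, closed = FALSE) {
  if (closed) xyz <- rbind(xyz, xyz[1, ])
  seg <- sqrt(rowSums(diff(xyz)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_out + if (closed) 1L else 0L)
  if (closed) target <- target[-length(target)]
  out <- matrix(NA_real_, length(target), 3)
  for (k in seq_along(target)) {
    i <- findInterval(target[k], s, rightmost.closed = TRUE)
    i <- min(i, nrow(xyz) - 1L)
    f <- (target[k] - s[i]) / (s[i + 1] - s[i])
    out[k, ] <- (1 - f) * xyz[i, ] + f * xyz[i + 1, ]
  }
  out
}

#' Generate a CA chain with a planted knot
#'
#' Resamples a standard closed representative of the requested knot (the
#' classical parametric curves for 3_1, 4_1 and 5_1; the minimal braid-word
#' closure for 5_2; an open arc for 0_1) at 3.8 A arc spacing, opens it by a
#' short gap, and appends straight tails pointing radially away from the
#' centroid so stochastic closures preserve the knot type.
#'
#' @param n Total residue count, including tails.
#' @param knot_type One of `"0_1"`, `"3_1"`, `"4_1"`, `"5_1"`, `"5_2"`.
#' @param tail_lengths Length-2 integer vector: residues appended before and
#'   after the knotted core.
#' @param seed Integer seed (small deterministic jitter that breaks exact
#'   collinearities in projections).
#' @return A CA-only `conformer`. Attribute `"planted_span"` holds the
#'   1-based residue span of the resampled knot curve; `"planted_core"` the
#'   tight entangled span (the interior vertices that KMT reduction cannot
#'   remove), the ground truth for core-localization tests.
#' @export
make_knotted_chain <- function(n, knot_type = "3_1", tail_lengths = c(5L, 5L),
                               seed = 1L) {
  n <- as.integer(n)
  tail_lengths <- as.integer(tail_lengths)
  stopifnot(length(tail_lengths) == 2L, all(tail_lengths >= 0L))
  n_core <- n - sum(tail_lengths)
  min_core <- switch(knot_type, "0_1" = 4L, "3_1" = 20L, "4_1" = 26L,
                     "5_1" = 30L, "5_2" = 70L, 4L)
  if (n_core < min_core)
    stop("n too small to host a ", knot_type, " core plus tails (need core >= ",
         min_core, ")")
  bond <- 3.8
  if (knot_type == "0_1") {
    # open three-quarter circle: trivially unknotted
    t <- seq(0, 1.5 * pi, length.out = 400L)
    open_curve <- cbind(cos(t), sin(t), 0.05 * t)
  } else {
    curve <- knot_parametric_curve(knot_type)
    # open the closed curve by dropping a short arc at its most peripheral
    # point, so the cut never lands inside the knotted tangle
    closed <- resample_polyline(curve, 600L, closed = TRUE)
    far <- which.max(rowSums(sweep(closed, 2, colMeans(closed))^2))
    closed <- closed[c(far:600L, seq_len(far - 1L)), , drop = FALSE]
    gap <- 18L                               # ~3% of the curve removed
    open_curve <- closed[seq_len(600L - gap), ]
  }
  # iterate scale + equal-arc resampling until chord lengths settle at `bond`
  core <- resample_polyline(open_curve, n_core, closed = FALSE)
  for (it in 1:6) {
    seg <- sqrt(rowSums(diff(core)^2))
    core <- core * (bond / mean(seg))
    core <- resample_polyline(core, n_core, closed = FALSE)
  }
  seg <- sqrt(rowSums(diff(core)^2))
  core <- core * (bond / mean(seg))
  ctr <- colMeans(core)
  add_tail <- function(endpoint, k) {
    if (k == 0L) return(NULL)
    dir <- vunit(endpoint - ctr)
    t(sapply(seq_len(k), function(j) endpoint + j * bond * dir))
  }
  head_tail <- add_tail(core[1, ], tail_lengths[1])
  tail_tail <- add_tail(core[n_core, ], tail_lengths[2])
  xyz <- rbind(if (!is.null(head_tail)) head_tail[rev(seq_len(nrow(head_tail))), , drop = FALSE],
               core, tail_tail)
  jitter <- with_seed(seed, matrix(stats::runif(3 * n, -0.02, 0.02), n, 3))
  xyz <- xyz + jitter
  out <- conformer_from_ca(xyz, id = paste0("knot_", knot_type, "_", n, "_s", seed))
  attr(out, "planted_span") <- c(tail_lengths[1] + 1L, tail_lengths[1] + n_core)
  if (knot_type != "0_1") {
    # tight entangled span: interior vertices the KMT reduction cannot remove
    kept <- attr(kmt_reduce(xyz), "kept")
    interior <- kept[kept != 1L & kept != n]
    if (length(interior) >= 2)
      attr(out, "planted_core") <- c(min(interior), max(interior))
  }
  attr(out, "knot_type") <- knot_type
  out
}

# ---- backbone reconstruction from CA traces ---------------------------------

#' Rebuild an ideal-geometry backbone on a CA trace
#'
#' Places N, C and O atoms around each CA using ideal trans-peptide geometry
#' (C-N bond 1.33 A, standard bond lengths/angles), leaving CA positions
#' untouched. Used so CA-only synthetic conformers can feed the heavy-atom
#' contact and secondary-structure operators.
#'
#' @param trace A `conformer` (its CA trace is used).
#' @return A `conformer` with N, CA, C, O per residue.
#' @export
backbone_from_ca <- function(trace) {
  ca <- ca_coords(trace)
  n <- nrow(ca)
  if (n < 3L) stop("need at least 3 residues")
  d <- sqrt(rowSums(diff(ca)^2))
  if (any(d < 2.5 | d > 4.5))
    stop("CA spacing outside [2.5, 4.5] A (bond ", which.max(d < 2.5 | d > 4.5), ")")
  # virtual flanking CAs for terminal peptide units
  ext <- rbind(2 * ca[1, ] - ca[2, ], ca, 2 * ca[n, ] - ca[n - 1, ])
  N <- matrix(NA_real_, n, 3); C <- N; O <- N
  for (i in seq_len(n)) {
    # peptide unit between extended CAs i+1 and i+2 (C_i, O_i, N_{i+1});
    # here we place C_i/O_i from bond i and N_i from bond i-1
    place_unit <- function(p, q, pprev) {
      u <- vunit(q - p)
      D <- vnorm(q - p)
      # in-plane perpendicular from local chain plane
      nv <- vcross(p - pprev, u)
      if (vnorm(nv) < 1e-8) nv <- vcross(u, c(0, 0, 1))
      if (vnorm(nv) < 1e-8) nv <- vcross(u, c(0, 1, 0))
      dv <- vunit(vcross(nv, u))
      c1 <- (1.525^2 + D^2 - 2.43^2) / (2 * D)
      h1 <- sqrt(max(1.525^2 - c1^2, 0.02))
      x2 <- (2.43^2 + D^2 - 1.458^2) / (2 * D)
      h2 <- sqrt(max(2.43^2 - x2^2, 0.02))
      Ci <- p + c1 * u + h1 * dv
      Ni <- p + x2 * u - h2 * dv
      Oi <- Ci + 1.231 * vunit(2 * Ci - p - Ni)
      list(C = Ci, N = Ni, O = Oi)
    }
    un <- place_unit(ext[i + 1, ], ext[i + 2, ], ext[i, ])
    C[i, ] <- un$C; O[i, ] <- un$O
    up <- place_unit(ext[i, ], ext[i + 1, ], if (i >= 2) ext[i - 1, ] else 2 * ext[i, ] - ext[i + 1, ])
    N[i, ] <- up$N
  }
  out <- atoms_from_backbone(N, ca, C, O, id = trace$id,
                             sequence = trace$sequence,
                             timestamp = trace$timestamp)
  for (a in c("planted_core", "knot_type")) {
    if (!is.null(attr(trace, a))) attr(out, a) <- attr(trace, a)
  }
  out
}

# ---- perturbation and sieve fixtures ----------------------------------------

#' Add isotropic Gaussian noise to all atom coordinates
#'
#' @param x A `conformer`.
#' @param amplitude Per-coordinate standard deviation of the displacement (A).
#' @param seed Integer seed; same seed gives identical output.
#' @return Perturbed `conformer`.
#' @export
perturb_conformer <- function(x, amplitude, seed) {
  stopifnot(inherits(x, "conformer"), amplitude >= 0)
  if (amplitude == 0) return(x)
  m <- nrow(x$atoms)
  noise <- with_seed(seed, matrix(stats::rnorm(3 * m, sd = amplitude), m, 3))
  x$atoms$x <- x$atoms$x + noise[, 1]
  x$atoms$y <- x$atoms$y + noise[, 2]
  x$atoms$z <- x$atoms$z + noise[, 3]
  x
}

#' Build a time-ordered trajectory with planted secondary-structure clusters
#'
#' Emits bursts of frames realizing a planned cluster structure: each plan row
#' gives a time interval (ps) and the secondary-structure content (%) of its
#' frames. Bursts are separated in time; frames within one burst are small
#' perturbations of a shared base coil, and different bursts use structurally
#' distant bases, so both the time-gap clustering and the RMSD independence
#' stage see the planted truth.
#'
#' @param cluster_plan Data frame with columns `start`, `end` (ps) and `ss`
#'   (%); intervals must be disjoint and increasing.
#' @param frame_dt Frame spacing within a burst (ps, default 10).
#' @param n_residues Residues per frame (default 20).
#' @param seed Integer seed.
#' @return List with `ensemble` (time-ordered), `ss` (per-frame %),
#'   `burst` (per-frame plan-row index) and `n_clusters_true`.
#' @export
make_sieve_fixture <- function(cluster_plan, frame_dt = 10, n_residues = 20L,
                               seed = 1L) {
  cp <- as.data.frame(cluster_plan)
  stopifnot(all(c("start", "end", "ss") %in% names(cp)))
  if (any(cp$end < cp$start)) stop("plan interval with end < start")
  if (nrow(cp) > 1) {
    o <- order(cp$start)
    cp <- cp[o, ]
    if (any(cp$start[-1] <= cp$end[-nrow(cp)]))
      stop("overlapping plan intervals")
  }
  frames <- list(); ss <- numeric(0); burst <- integer(0)
  for (b in seq_len(nrow(cp))) {
    base <- make_self_avoiding_coil(n_residues, seed = seed * 1000L + b)
    ts <- seq(cp$start[b], cp$end[b], by = frame_dt)
    for (k in seq_along(ts)) {
      f <- perturb_conformer(base, amplitude = 0.1,
                             seed = seed * 100000L + b * 100L + k)
      f$timestamp <- ts[k]
      f$id <- sprintf("burst%02d_frame%03d", b, k)
      frames[[length(frames) + 1L]] <- f
      ss <- c(ss, cp$ss[b])
      burst <- c(burst, b)
    }
  }
  list(ensemble = ensemble(frames, is_time_ordered = TRUE),
       ss = ss, burst = burst, n_clusters_true = nrow(cp))
}
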