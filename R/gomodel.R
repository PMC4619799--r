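#' Parameters of the structure-based coarse-grained model
#'
#' Reduced units: energies in eps (the common depth of all native-contact
#' potentials), lengths in Angstrom, times in tau (of order 1 ns physically),
#' mass 1, k_B = 1. Force is reported in eps/A; the calibration eps = 110
#' pN A converts to piconewtons (see [eps_to_pN()]).
#'
#' @param epsilon Contact depth (energy unit; keep 1 in reduced units).
#' @param temperature Thermostat temperature in eps/k_B (default 0.3).
#' @param v_pull Pulling speed in A/tau (default 5e-3).
#' @param timestep Integration step in tau (default 0.005).
#' @param damping Langevin friction in 1/tau (default 2).
#' @param bond_k Backbone bond stiffness, eps/A^2 (default 100).
#' @param chirality_k Chirality stiffness, eps (default 1).
#' @param repulsive_sigma Excluded-volume diameter, A (default 4).
#' @param spring_k Pulling-spring stiffness, eps/A^2 (default 0.12).
#' @param noise_level Force-peak detection threshold, eps/A (default 0.1).
#' @param break_factor Contact-rupture criterion: broken when the CA-CA
#'   distance exceeds `break_factor` times the native distance (default 1.5).
#' @param end_fraction Pulling stops when the end-to-end extension reaches
#'   this fraction of the contour length (default 0.95).
#' @param eps_pN_A Energy-unit calibration in pN.Angstrom (default 110).
#' @param seed Integer seed for the Langevin noise.
#' @return Named list of class `go_params`.
#' @export
go_params <- function(epsilon = 1, temperature = 0.3, v_pull = 5e-3,
                      timestep = 0.005, damping = 2, bond_k = 100,
                      chirality_k = 1, repulsive_sigma = 4.0, spring_k = 0.12,
                      noise_level = 0.1, break_factor = 1.5,
                      end_fraction = 0.95, eps_pN_A = 110, seed = 1L) {
  p <- list(epsilon = epsilon, temperature = temperature, v_pull = v_pull,
            timestep = timestep, damping = damping, bond_k = bond_k,
            chirality_k = chirality_k, repulsive_sigma = repulsive_sigma,
            spring_k = spring_k, noise_level = noise_level,
            break_factor = break_factor, end_fraction = end_fraction,
            eps_pN_A = eps_pN_A, seed = as.integer(seed))
  num <- unlist(p[setdiff(names(p), c("seed", "temperature", "damping"))])
  if (any(num <= 0)) stop("all Go-model parameters must be positive")
  if (temperature < 0 || damping < 0)
    stop("temperature and damping must be >= 0")
  structure(p, class = "go_params")
}

#' Convert force from reduced units to piconewton
#'
#' @param f Force in eps/A.
#' @param eps_pN_A Calibration of the energy unit (default 110 pN.A).
#' @return Force in pN.
#' @export
eps_to_pN <- function(f, eps_pN_A = 110) f * eps_pN_A

#' Build a structure-based CA model from a conformer and its contact map
#'
#' The model ties each native contact to a 12-6 Lennard-Jones potential of
#' depth eps whose minimum sits exactly at the native CA-CA distance,
#' harmonic bonds at native lengths between consecutive CAs, a harmonic
#' chirality term on every quadruplet of consecutive CAs (penalizing
#' deviation from the native signed chirality), and truncated repulsion
#' between all remaining pairs with sequence separation >= 3. At the native
#' coordinates the potential energy is exactly -eps times the contact count.
#'
#' @param x The reference `conformer`.
#' @param cmap Contact map built from the same conformer.
#' @param params A [go_params()] list.
#' @return List of class `go_model`.
#' @export
build_go_model <- function(x, cmap = NULL, params = go_params()) {
  stopifnot(inherits(x, "conformer"))
  if (is.null(cmap)) cmap <- build_contact_map(x)
  n <- n_residues(x)
  if (attr(cmap, "n_residues") != n)
    stop("contact map was built for a different chain length")
  ca <- ca_coords(x)
  bond_r0 <- sqrt(rowSums(diff(ca)^2))
  d0 <- mean(bond_r0)
  chir0 <- native_chirality(ca, d0)
  structure(list(
    coords = ca, bond_r0 = bond_r0,
    contact_i = cmap$i, contact_j = cmap$j, contact_r0 = cmap$native_distance,
    chir0 = chir0, d0 = d0,
    eps = params$epsilon, bond_k = params$bond_k,
    chir_k = params$chirality_k, rep_sigma = params$repulsive_sigma,
    n_residues = n, id = x$id
  ), class = "go_model")
}

# signed chirality C_i = ((v_i x v_{i+1}) . v_{i+2}) / d0^3 per CA quadruplet
native_chirality <- function(ca, d0) {
  n <- nrow(ca)
  if (n < 4) return(numeric(0))
  v <- diff(ca)
  vapply(seq_len(n - 3), function(i) {
    a <- v[i, ]; b <- v[i + 1, ]; cc <- v[i + 2, ]
    sum(vcross(a, b) * cc) / d0^3
  }, numeric(1))
}

#' Potential energy of a Go model at given coordinates
#'
#' @param model A `go_model`.
#' @param coords n x 3 CA coordinate matrix (defaults to the native ones).
#' @return Potential energy in eps.
#' @export
go_energy <- function(model, coords = model$coords) {
  stopifnot(inherits(model, "go_model"))
  cpp_go_energy(unclass(model), as.matrix(coords))
}

#' Free Langevin dynamics of a Go model
#'
#' Velocity-Verlet integration with a BAOAB Langevin thermostat; with
#' `temperature = 0` and `damping = 0` it reduces to plain (energy
#' conserving) velocity Verlet. Deterministic per seed.
#'
#' @param model A `go_model`.
#' @param params A [go_params()] list (temperature, damping, timestep, seed).
#' @param n_steps Number of integration steps.
#' @param traj_stride Snapshot stride in steps (0 = none).
#' @param sample_stride Energy-sampling stride in steps (default 100).
#' @return List of class `go_trajectory`: `frames` (list of n x 3 matrices),
#'   `times` (tau), `energy` and `kinetic` samples, `final_coords`.
#' @export
run_langevin <- function(model, params = go_params(), n_steps,
                         traj_stride = 0L, sample_stride = 100L) {
  stopifnot(inherits(model, "go_model"))
  res <- cpp_go_run(unclass(model), params$temperature, params$damping,
                    params$timestep, as.double(n_steps), params$seed, 0L,
                    0, 0, 1, params$break_factor,
                    as.integer(traj_stride), as.integer(sample_stride), 1)
  if (isTRUE(res$diverged))
    stop("Langevin integration diverged at step ", res$diverge_step)
  frames <- traj_to_frames(res$traj, model$n_residues)
  structure(list(frames = frames, times = res$traj_t,
                 energy = res$energy, kinetic = res$kinetic,
                 sample_times = res$sample_t,
                 final_coords = res$final_coords,
                 n_residues = model$n_residues),
            class = "go_trajectory")
}

traj_to_frames <- function(traj, n) {
  if (length(traj) == 0) return(list())
  nf <- length(traj) / (3 * n)
  lapply(seq_len(nf), function(k) {
    m <- matrix(traj[((k - 1) * 3 * n + 1):(k * 3 * n)], ncol = 3, byrow = TRUE)
    m
  })
}

#' Stretch a Go model at constant speed
#'
#' One terminus is tethered to a fixed harmonic anchor; the other to a
#' harmonic spring whose anchor moves at `v_pull` along the initial
#' end-to-end axis. The measured force is the moving-spring extension along
#' the pulling axis times `spring_k`, boxcar-averaged over 1 A of anchor
#' displacement. The run ends when the end-to-end extension reaches
#' `end_fraction` of the contour length.
#'
#' @param model A `go_model`.
#' @param params A [go_params()] list.
#' @param traj_stride Snapshot stride in steps (0 = none).
#' @param max_steps Safety cap on steps (default covers the full extension).
#' @return List of class `force_curve`: tibble `curve` (columns `d`, `force`),
#'   `peaks` (tibble `d`, `height`), `f_max`, `n_p`, `contour_length`,
#'   `final_coords`, `scenario_raw` (per-contact last-rupture displacement),
#'   `params`.
#' @export
pull_constant_speed <- function(model, params = go_params(),
                                traj_stride = 0L, max_steps = NULL) {
  stopifnot(inherits(model, "go_model"))
  contour <- sum(model$bond_r0)
  if (is.null(max_steps)) {
    travel <- contour + 20
    max_steps <- ceiling(travel / (params$v_pull * params$timestep))
  }
  res <- cpp_go_run(unclass(model), params$temperature, params$damping,
                    params$timestep, as.double(max_steps), params$seed, 1L,
                    params$spring_k, params$v_pull, params$end_fraction,
                    params$break_factor, as.integer(traj_stride), 0L, 1.0)
  if (isTRUE(res$diverged))
    stop("pulling simulation diverged at step ", res$diverge_step)
  keep <- res$force_cnt > 0
  curve <- tibble::tibble(
    d = (which(keep) - 0.5) * res$force_bin,
    force = res$force_sum[keep] / res$force_cnt[keep]
  )
  pk <- detect_force_peaks(curve, noise_level = params$noise_level)
  structure(list(curve = curve, peaks = pk$peaks, f_max = pk$f_max,
                 n_p = pk$n_p, contour_length = res$contour,
                 final_coords = res$final_coords,
                 frames = traj_to_frames(res$traj, model$n_residues),
                 frame_times = res$traj_t,
                 scenario_raw = res$last_break,
                 contact_i = model$contact_i, contact_j = model$contact_j,
                 params = params),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat("<force_curve> F_max =", round(x$f_max, 3), "eps/A, n_p =", x$n_p,
      ", contour =", round(x$contour_length, 1), "A\n")
  invisible(x)
}

#' Detect articulated force peaks in a force-displacement curve
#'
#' Local maxima of the (already boxcar-averaged) curve whose height and
#' topographic prominence both exceed the thermal noise level. The terminal
#' monotone rise towards full extension articulates no local maximum and is
#' therefore never counted. With no qualifying peak, `f_max` is 0 by
#' convention.
#'
#' @param curve Data frame with increasing `d` and `force` columns.
#' @param noise_level Minimal height and prominence, eps/A (default 0.1).
#' @param smooth_window Running-mean half-width in samples applied before
#'   peak picking (default 1, i.e. a 3-sample window); 0 disables.
#' @return List: `peaks` (tibble `d`, `height`), `f_max`, `n_p`.
#' @export
detect_force_peaks <- function(curve, noise_level = 0.1, smooth_window = 1L) {
  if (nrow(curve) == 0) stop("empty force curve")
  if (is.unsorted(curve$d, strictly = TRUE)) stop("d must be increasing")
  f <- curve$force
  d <- curve$d
  if (smooth_window > 0 && length(f) > 2 * smooth_window) {
    w <- 2L * smooth_window + 1L
    f <- stats::filter(f, rep(1 / w, w), sides = 2)
    edge <- c(seq_len(smooth_window), length(f) - seq_len(smooth_window) + 1L)
    f[edge] <- curve$force[edge]
    f <- as.numeric(f)
  }
  n <- length(f)
  peaks <- tibble::tibble(d = numeric(), height = numeric())
  if (n >= 3) {
    for (k in 2:(n - 1)) {
      if (f[k] > f[k - 1] && f[k] >= f[k + 1]) {
        # prominence: drop to the lowest valley separating this peak from
        # higher ground on each side
        left <- f[1:(k - 1)]
        higher_l <- which(left > f[k])
        base_l <- if (length(higher_l) > 0) min(f[(max(higher_l) + 1):(k - 1)])
          else min(left)
        right <- f[(k + 1):n]
        higher_r <- which(right > f[k])
        base_r <- if (length(higher_r) > 0) min(f[(k + 1):(k + min(higher_r) - 1)])
          else min(right)
        prom <- f[k] - max(base_l, base_r)
        if (f[k] > noise_level && prom > noise_level)
          peaks <- tibble::add_row(peaks, d = d[k], height = f[k])
      }
    }
  }
  list(peaks = peaks,
       f_max = if (nrow(peaks) > 0) max(peaks$height) else 0,
       n_p = nrow(peaks))
}

#' Contact-rupture scenario of a pulling run
#'
#' For every native contact, reports the anchor displacement at which its
#' CA-CA distance last exceeded `break_factor` times the native distance
#' (i.e. the last rupture; transient re-formation is ignored). Contacts that
#' never break are flagged unbroken.
#'
#' @param fc A `force_curve` from [pull_constant_speed()].
#' @return Tibble: `i`, `j`, `sep`, `d_break` (A, `NA` if unbroken),
#'   `broken`.
#' @export
unfolding_scenario <- function(fc) {
  stopifnot(inherits(fc, "force_curve"))
  tibble::tibble(i = fc$contact_i, j = fc$contact_j,
                 sep = abs(fc$contact_j - fc$contact_i),
                 d_break = fc$scenario_raw,
                 broken = !is.na(fc$scenario_raw))
}
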