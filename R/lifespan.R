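#' RMSD time series of a trajectory relative to its first frame
#'
#' Superposed CA RMSD of every frame against frame 1. The series quantifies
#' how long a conformer persists near its initial conformation under free
#' dynamics.
#'
#' @param x A time-ordered `ensemble` (>= 2 frames), or a `go_trajectory`
#'   from [run_langevin()].
#' @param time_scale Multiplier applied to frame times (e.g. tau -> ns
#'   conversion); default 1.
#' @return Tibble of class `rmsd_series`: `time`, `rmsd` (A); `rmsd[1] = 0`.
#' @export
rmsd_series <- function(x, time_scale = 1) {
  if (inherits(x, "go_trajectory")) {
    frames <- x$frames
    times <- x$times * time_scale
    if (length(frames) < 2) stop("need at least 2 frames")
    ref <- frames[[1]]
    r <- vapply(frames, function(m) kabsch_rmsd(m, ref), numeric(1))
  } else {
    stopifnot(inherits(x, "ensemble"))
    if (length(x) < 2) stop("need at least 2 frames")
    times <- timestamps(x) * time_scale
    ref <- x[[1]]
    r <- vapply(unclass(x), function(cf) superpose_rmsd(cf, ref), numeric(1))
  }
  out <- tibble::tibble(time = times, rmsd = r)
  class(out) <- c("rmsd_series", class(out))
  out
}

#' Residence time of a conformer
#'
#' The residence time t_R is the last sampled time at which the RMSD to the
#' initial structure is at or below the threshold. A series that never rises
#' above the threshold by the end of the run is censored: the conformer never
#' left its initial state within the simulated window.
#'
#' @param series An `rmsd_series` (or data frame with `time`, `rmsd`).
#' @param threshold RMSD threshold in Angstrom (default 2).
#' @return One-row tibble: `t_r`, `censored`, `t_sim`.
#' @export
residence_time <- function(series, threshold = 2) {
  stopifnot(all(c("time", "rmsd") %in% names(series)))
  below <- which(series$rmsd <= threshold)
  t_sim <- max(series$time)
  if (length(below) == 0) {
    # never below threshold after t = 0 (rmsd[1] = 0 normally prevents this)
    return(tibble::tibble(t_r = series$time[1], censored = FALSE, t_sim = t_sim))
  }
  t_r <- series$time[max(below)]
  censored <- series$rmsd[nrow(series)] <= threshold
  tibble::tibble(t_r = t_r, censored = censored, t_sim = t_sim)
}

#' Escape-probability curve of an ensemble of conformers
#'
#' P_e(t) is the fraction of conformers that left their initial conformation
#' before time t: the share of non-censored residence times strictly below
#' t, with all conformers (censored included) in the denominator. A step
#' function evaluated on the union of event times.
#'
#' @param residences Data frame with columns `t_r` and `censored` (one row
#'   per conformer), e.g. stacked [residence_time()] rows.
#' @return Tibble of class `escape_curve`: `time`, `p_e` (non-decreasing,
#'   in [0, 1]).
#' @export
escape_probability <- function(residences) {
  stopifnot(all(c("t_r", "censored") %in% names(residences)),
            nrow(residences) >= 1)
  n <- nrow(residences)
  events <- sort(unique(residences$t_r))
  grid <- c(0, events, max(residences$t_r) * 1.05)
  p <- vapply(grid, function(t)
    sum(!residences$censored & residences$t_r < t) / n, numeric(1))
  out <- tibble::tibble(time = grid, p_e = p)
  class(out) <- c("escape_curve", class(out))
  out
}
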