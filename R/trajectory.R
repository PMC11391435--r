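#' Construct a trajectory
#'
#' Bundles a frame stack with its topology. Coordinates are stored as an
#' `A x 3 x F` array in Angstrom; per-frame times are in nanoseconds and
#' must be strictly increasing.
#'
#' @param topology an [md_topology()]
#' @param coords numeric array `A x 3 x F` (a single `A x 3` matrix is
#'   promoted to one frame)
#' @param times per-frame times in ns, or `NULL` to synthesize
#'   `0, dt, 2*dt, ...`
#' @param dt frame spacing in ns used when `times` is `NULL`
#' @param provenance optional integer per frame recording the source
#'   replicate (kept through [concatenate_trajectories()])
#' @return an object of class `md_trajectory`
#' @export
md_trajectory <- function(topology, coords, times = NULL, dt = 0.1,
                          provenance = NULL) {
  if (!inherits(topology, "md_topology")) stop("topology must be an md_topology")
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[3] < 1L) stop("trajectory has zero frames")
  if (dim(coords)[1] != n_atoms(topology)) {
    stop(sprintf("topology mismatch: %d atoms in frames vs %d in topology",
                 dim(coords)[1], n_atoms(topology)))
  }
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1L) * dt
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(provenance) && length(provenance) != nf) {
    stop("provenance length must equal frame count")
  }
  structure(list(topology = topology, coords = coords, times = as.numeric(times),
                 provenance = provenance),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, t = [%.3f, %.3f] ns\n",
              n_frames(x), n_atoms(x$topology),
              x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an A x 3 coordinate matrix
#' @param traj an `md_trajectory`
#' @param i frame index
#' @return numeric `A x 3` matrix (Angstrom)
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i]
}

#' Evenly sample frames from a time window
#'
#' Returns `n_samples` frames at evenly spaced indices within the
#' closed time window `[t0, t1]`. When `n_samples >= 2` the first and
#' last in-window frames are included; frames are never duplicated.
#' This implements the sampling conventions used throughout the
#' pipeline (e.g. 500 frames for energy analysis, 5000 for contact
#' features, all drawn from the final portion of each replicate).
#'
#' @param traj an `md_trajectory`
#' @param time_window numeric `c(t0, t1)` in ns with `t0 < t1`
#' @param n_samples number of frames to return (`>= 1`)
#' @return an `md_trajectory` with `n_samples` frames, order preserved
#' @export
window_frames <- function(traj, time_window, n_samples) {
  stopifnot(length(time_window) == 2L)
  t0 <- time_window[1]; t1 <- time_window[2]
  if (!(t0 < t1)) stop("time window must satisfy t0 < t1")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  idx <- which(traj$times >= t0 & traj$times <= t1)
  if (!length(idx)) stop("time window does not overlap the trajectory")
  if (n_samples == 1L) {
    pick <- idx[1L]
  } else {
    if (n_samples > length(idx)) {
      stop(sprintf("requested %d samples but only %d frames fall in the window",
                   n_samples, length(idx)))
    }
    pick <- idx[round(seq(1L, length(idx), length.out = n_samples))]
    pick <- unique(pick)
    stopifnot(length(pick) == n_samples)
  }
  md_trajectory(traj$topology,
                traj$coords[, , pick, drop = FALSE],
                times = traj$times[pick],
                provenance = traj$provenance[pick])
}

#' Concatenate trajectories sharing one topology
#'
#' Frames are kept in input order; times are re-indexed so the combined
#' series stays strictly increasing with the first trajectory's frame
#' spacing. The source replicate of each frame is retained in
#' `provenance`, so [split_by_provenance()] recovers the originals.
#'
#' @param trajs list of `md_trajectory` objects with identical topologies
#' @return a single `md_trajectory`
#' @export
concatenate_trajectories <- function(trajs) {
  if (inherits(trajs, "md_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  top <- trajs[[1L]]$topology
  for (t in trajs) {
    if (!identical(t$topology$atoms[c("elety", "resno", "chain")],
                   top$atoms[c("elety", "resno", "chain")])) {
      stop("topology mismatch: all trajectories must share one topology")
    }
  }
  if (length(trajs) == 1L) {
    out <- trajs[[1L]]
    if (is.null(out$provenance)) out$provenance <- rep(1L, n_frames(out))
    return(out)
  }
  nf <- vapply(trajs, n_frames, integer(1))
  A <- n_atoms(top)
  coords <- array(0, dim = c(A, 3L, sum(nf)))
  times <- numeric(sum(nf))
  prov <- integer(sum(nf))
  dt <- if (nf[1] > 1L) diff(trajs[[1L]]$times)[1] else 0.1
  off <- 0L; t_end <- -dt
  for (k in seq_along(trajs)) {
    f <- nf[k]
    coords[, , off + seq_len(f)] <- trajs[[k]]$coords
    tk <- trajs[[k]]$times
    times[off + seq_len(f)] <- tk - tk[1] + t_end + dt
    prov[off + seq_len(f)] <- k
    t_end <- times[off + f]
    off <- off + f
  }
  md_trajectory(top, coords, times = times, provenance = prov)
}

#' Split a concatenated trajectory back into its source replicates
#' @param traj an `md_trajectory` carrying `provenance`
#' @return list of `md_trajectory`, one per source replicate
#' @export
split_by_provenance <- function(traj) {
  if (is.null(traj$provenance)) stop("trajectory carries no provenance")
  lapply(unique(traj$provenance), function(k) {
    i <- which(traj$provenance == k)
    md_trajectory(traj$topology, traj$coords[, , i, drop = FALSE],
                  times = traj$times[i] - traj$times[i][1])
  })
}

#' Bundle replicate trajectories of one simulated state
#'
#' @param state_label e.g. `"holo"`, `"holo-G323E"`, `"holo-p"`
#' @param replicates list of `md_trajectory` sharing one topology
#' @return object of class `md_ensemble`
#' @export
md_ensemble <- function(state_label, replicates) {
  stopifnot(is.character(state_label), length(replicates) >= 1L)
  top <- replicates[[1L]]$topology
  for (r in replicates) {
    if (!identical(r$topology$atoms$elety, top$atoms$elety)) {
      stop("all replicates must share one topology")
    }
  }
  structure(list(state_label = state_label, replicates = replicates,
                 topology = top),
            class = "md_ensemble")
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat(sprintf("md_ensemble '%s': %d replicates x %d frames\n",
              x$state_label, length(x$replicates),
              n_frames(x$replicates[[1L]])))
  invisible(x)
}
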