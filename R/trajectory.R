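# Trajectory container: constant atom roster + per-frame coordinates.

#' Assemble a trajectory from frames
#'
#' @param frames list of `cb_frame` objects sharing one atom roster.
#' @param times frame time stamps (ns); default `0, dt, 2dt, ...`.
#' @param frame_dt frame spacing used when `times` is absent (ns).
#' @param provenance free-form list recorded with the trajectory (e.g.
#'   generating script and seed).
#' @return A `cb_traj`.
#' @export
cb_trajectory <- function(frames, times = NULL, frame_dt = 0.5,
                          provenance = list()) {
  stopifnot(length(frames) >= 1)
  a0 <- frames[[1]]$atoms
  for (k in seq_along(frames))
    if (!identical(frames[[k]]$atoms[c("peptide", "resid", "atom")],
                   a0[c("peptide", "resid", "atom")]))
      stop("inconsistent atom roster in frame ", k)
  if (is.null(times)) times <- (seq_along(frames) - 1) * frame_dt
  stopifnot(length(times) == length(frames), !is.unsorted(times))
  structure(list(atoms = a0,
                 coords = lapply(frames, function(f) f$xyz),
                 times = times,
                 termini = frames[[1]]$termini,
                 provenance = provenance),
            class = "cb_traj")
}

#' Number of frames in a trajectory
#' @param traj a `cb_traj`.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Extract one frame of a trajectory
#' @param traj a `cb_traj`.
#' @param k frame index (1-based).
#' @return A `cb_frame`.
#' @export
frame_at <- function(traj, k) {
  stopifnot(k >= 1, k <= n_frames(traj))
  cb_frame(traj$atoms, traj$coords[[k]], time = traj$times[k],
           termini = traj$termini)
}

#' @export
print.cb_traj <- function(x, ...) {
  cat(sprintf("cb_traj: %d frames (%g-%g ns), %d atoms, %d peptides [%s]\n",
              n_frames(x), x$times[1], x$times[n_frames(x)],
              nrow(x$atoms), length(unique(x$atoms$peptide)),
              paste(unique(x$atoms$peptide), collapse = "")))
  if (!is.null(x$provenance$scenario))
    cat("  scenario:", x$provenance$scenario, "\n")
  if (!is.null(x$provenance$seed))
    cat("  seed:", x$provenance$seed, "\n")
  invisible(x)
}

# time step between frames (assumed uniform; falls back to 0.5 ns)
.traj_dt <- function(traj) {
  if (n_frames(traj) < 2) return(0.5)
  diff(traj$times[1:2])
}
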