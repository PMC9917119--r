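# trajectory container: frames of coordinates + spring state + per-term
# energy breakdown at a fixed frame interval.

#' @export
print.mp_trajectory <- function(x, ...) {
  nf <- length(x$steps)
  cat(sprintf("Pulling trajectory: %d frames (steps 0..%d every %d), %s %s\n",
              nf, x$steps[nf], x$protocol$frame_interval,
              x$protocol$geometry, x$protocol$mode))
  cat(sprintf("  %d residues, seed %d, max force %.2f kBT/A (%.1f pN at 300 K)\n",
              nrow(x$topology$residues), x$seed,
              max(x$force, na.rm = TRUE),
              map_force_units(max(x$force, na.rm = TRUE))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `mp_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$steps)

#' Extract one frame as a conformation
#' @param traj an `mp_trajectory`.
#' @param frame frame index (1-based).
#' @return an `mp_conformation`.
#' @export
get_frame <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  conf_from_cpp(traj$coords[, , frame])
}

# cached per-frame helix metrics (NH projections, helicity, contacts,
# native-H-bond counts, helix centroid depth) computed in one C++ pass
traj_metrics <- function(traj) {
  cached <- attr(traj, "metrics")
  if (!is.null(cached)) return(cached)
  cpp_traj_metrics(traj$coords, topo_cpp(traj$topology),
                   pack_params(traj$params, traj$membrane),
                   helices_cpp(traj$topology))
}

#' Precompute per-frame metrics
#'
#' Computes and caches the per-frame helix metrics used by several analysis
#' operators so that repeated analyses do not rescan the coordinates.
#'
#' @param traj an `mp_trajectory`.
#' @return the trajectory with a `"metrics"` attribute attached.
#' @export
with_metrics <- function(traj) {
  attr(traj, "metrics") <- traj_metrics(traj)
  traj
}

#' First frame at which each helix has left the membrane
#'
#' A helix has exited once the absolute depth of its C-alpha centroid
#' exceeds `thickness / 2 + margin`.
#'
#' @param traj an `mp_trajectory`.
#' @param margin extra clearance beyond the membrane surface, Angstrom.
#' @return integer vector (one entry per helix; NA if it never exits).
#' @export
helix_exit_frames <- function(traj, margin = 5) {
  m <- traj_metrics(traj)
  half <- traj$topology$membrane_thickness / 2 + margin
  apply(m$com_z, 2, function(z) {
    i <- which(abs(z) > half)
    if (length(i)) i[1] else NA_integer_
  })
}

#' Write a trajectory to CSV
#'
#' One row per frame: step, extension, spring force (reduced units and pN at
#' the 300 K mapping), spring energy, and one column per energy-breakdown
#' component.
#'
#' @param traj an `mp_trajectory`.
#' @param path output file.
#' @return invisibly the data.frame written.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(step = traj$steps,
                   extension_A = traj$extension,
                   force_kT_per_A = traj$force,
                   force_pN_300K = map_force_units(traj$force),
                   spring_energy_kT = traj$spring_energy)
  bk <- as.data.frame(traj$breakdown)
  df <- cbind(df, bk)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write trajectory snapshots as PDB files
#'
#' Writes every `every`-th frame through the PDB snapshot writer.
#'
#' @param traj an `mp_trajectory`.
#' @param dir output directory (created if missing).
#' @param every frame stride.
#' @return invisibly the written file paths.
#' @export
write_trajectory_snapshots <- function(traj, dir, every = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- seq(1, n_frames(traj), by = every)
  paths <- character(0)
  for (i in idx) {
    p <- file.path(dir, sprintf("frame_%06d.pdb", traj$steps[i]))
    write_pdb(get_frame(traj, i), traj$topology, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
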