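# Trajectory ensemble container and atom-selection helpers.
# Frames are rows of an (n_frames x 3*n_atoms) coordinate matrix in nm,
# ordered x1,y1,z1,x2,... as in bio3d xyz matrices.

#' Construct a trajectory ensemble
#'
#' @param xyz Numeric matrix, one frame per row, `3 * n_atoms` columns (nm).
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`
#'   describing the (identical) atom ordering of every frame.
#' @param dt Time between stored frames (ps), > 0.
#' @param metadata Optional list (e.g. generator ground truth).
#' @return An object of class `helix_trajectory`.
#' @export
helix_trajectory <- function(xyz, atoms, dt = 100, metadata = list()) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns but atoms table describes ",
         nrow(atoms), " atoms", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  structure(list(xyz = xyz, atoms = atoms, dt = dt, metadata = metadata),
            class = "helix_trajectory")
}

#' @export
print.helix_trajectory <- function(x, ...) {
  cat(sprintf("<helix_trajectory> %d frames x %d atoms, dt = %g ps\n",
              nrow(x$xyz), nrow(x$atoms), x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `helix_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Select atom indices by chain, atom name and/or residue number
#'
#' @param traj A `helix_trajectory` (or any list with an `atoms` table).
#' @param chain,elety,resno Optional filters; `NULL` means no restriction.
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(traj, chain = NULL, elety = NULL, resno = NULL) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  which(keep)
}

#' Coordinates of one frame as an n_atoms x 3 matrix
#'
#' @param traj A `helix_trajectory`.
#' @param frame Frame index (1-based).
#' @param atom_idx Optional atom indices to extract.
#' @return Numeric matrix (nm), columns x/y/z.
#' @export
frame_coords <- function(traj, frame = 1L, atom_idx = NULL) {
  v <- traj$xyz[frame, ]
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  if (!is.null(atom_idx)) m <- m[atom_idx, , drop = FALSE]
  m
}

# xyz-column indices (x,y,z interleaved) for a set of atom indices
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

#' Restrict a trajectory to a subset of frames
#'
#' @param traj A `helix_trajectory`.
#' @param frames Integer vector of frame indices to keep (in order).
#' @return A `helix_trajectory`; `dt` is rescaled when the subset is an
#'   evenly strided grid.
#' @export
subset_frames <- function(traj, frames) {
  dt <- traj$dt
  if (length(frames) > 1L) {
    d <- diff(frames)
    if (all(d == d[1L])) dt <- traj$dt * d[1L]
  }
  helix_trajectory(traj$xyz[frames, , drop = FALSE], traj$atoms, dt,
                   traj$metadata)
}

#' Build a single-frame trajectory from a trimer model
#'
#' @param model A `trimer_model` (see [build_trimer()]).
#' @param dt Nominal frame spacing (ps).
#' @return A `helix_trajectory` with one frame.
#' @export
as_trajectory <- function(model, dt = 100) {
  stopifnot(inherits(model, "trimer_model"))
  helix_trajectory(matrix(as.vector(t(model$coords)), nrow = 1L),
                   model$atoms, dt = dt,
                   metadata = list(model_id = model$id))
}
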