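# Two-chain trajectory container.
#
# A trajectory is a fixed atom roster (a data.frame of atom records) plus a
# 3-D coordinate array of dimension n_atoms x 3 x n_frames, in Angstrom.
# All frames share the roster; this mirrors how trajectory formats store
# topology once and coordinates per frame.

#' Construct a trajectory
#'
#' @param atoms data.frame with columns `atom_name`, `element`,
#'   `residue_index` (1-based within chain), `residue_name` (3-letter code),
#'   `chain_id` (single character).
#' @param xyz numeric array `n_atoms x 3 x n_frames` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param time optional per-frame times in ps.
#' @param topology optional named list mapping chain id to a
#'   [peptide_spec()].
#' @return object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, time = NULL, topology = NULL) {
  req <- c("atom_name", "element", "residue_index", "residue_name", "chain_id")
  if (!all(req %in% names(atoms))) {
    stop("atoms must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L,
            dim(xyz)[1] == nrow(atoms))
  if (dim(xyz)[3] < 1L) stop("a trajectory needs at least one frame", call. = FALSE)
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  if (!is.null(time)) {
    stopifnot(length(time) == dim(xyz)[3], all(time >= 0))
  }
  atoms$residue_index <- as.integer(atoms$residue_index)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz, time = time, topology = topology),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$xyz)[3]
}

#' Chain identifiers of a trajectory
#' @param traj a [trajectory()].
#' @return character vector of chain ids, lexically sorted.
#' @export
chain_ids <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sort(unique(traj$atoms$chain_id))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frame(s), %d atoms, chains %s\n",
              n_frames(x), nrow(x$atoms),
              paste(chain_ids(x), collapse = "/")))
  invisible(x)
}

#' Extract one frame of a trajectory
#'
#' @param traj a [trajectory()].
#' @param i 1-based frame index.
#' @return object of class `traj_frame`: the atom roster plus an
#'   `n_atoms x 3` coordinate matrix.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) {
    stop(sprintf("frame index %d out of range (1..%d)", i, n_frames(traj)),
         call. = FALSE)
  }
  structure(list(atoms = traj$atoms, xyz = traj$xyz[, , i, drop = TRUE],
                 frame_index = i),
            class = "traj_frame")
}

#' @export
print.traj_frame <- function(x, ...) {
  cat(sprintf("<traj_frame> #%d, %d atoms, chains %s\n", x$frame_index,
              nrow(x$atoms), paste(sort(unique(x$atoms$chain_id)), collapse = "/")))
  invisible(x)
}

#' Heavy-atom view of a trajectory or frame
#'
#' Removes all hydrogen atoms. Every distance-based analysis in this
#' package (close contacts, SASA) operates on the heavy-atom universe, in
#' line with the definition of a close contact as a pair of heavy atoms
#' less than the cutoff apart. Idempotent; atom order is preserved.
#'
#' @param x a [trajectory()] or a frame from [get_frame()].
#' @return object of the same class with hydrogens removed.
#' @export
heavy_atom_view <- function(x) {
  UseMethod("heavy_atom_view")
}

#' @export
heavy_atom_view.trajectory <- function(x) {
  keep <- toupper(x$atoms$element) != "H"
  trajectory(x$atoms[keep, , drop = FALSE],
             x$xyz[keep, , , drop = FALSE],
             time = x$time, topology = x$topology)
}

#' @export
heavy_atom_view.traj_frame <- function(x) {
  keep <- toupper(x$atoms$element) != "H"
  structure(list(atoms = x$atoms[keep, , drop = FALSE],
                 xyz = x$xyz[keep, , drop = FALSE],
                 frame_index = x$frame_index),
            class = "traj_frame")
}

#' Single-chain view of a frame
#'
#' @param frame a frame from [get_frame()].
#' @param chain_id chain identifier present in the frame.
#' @return a `traj_frame` containing only that chain, order preserved.
#' @export
chain_view <- function(frame, chain_id) {
  stopifnot(inherits(frame, "traj_frame"))
  present <- unique(frame$atoms$chain_id)
  if (!chain_id %in% present) {
    stop(sprintf("unknown chain id '%s' (present: %s)", chain_id,
                 paste(sort(present), collapse = ", ")), call. = FALSE)
  }
  keep <- frame$atoms$chain_id == chain_id
  structure(list(atoms = frame$atoms[keep, , drop = FALSE],
                 xyz = frame$xyz[keep, , drop = FALSE],
                 frame_index = frame$frame_index),
            class = "traj_frame")
}

# internal: subsample frames by stride (keeps frame 1, then every stride-th)
stride_view <- function(traj, stride = 1L) {
  stopifnot(inherits(traj, "trajectory"), stride >= 1L)
  idx <- seq(1L, n_frames(traj), by = as.integer(stride))
  trajectory(traj$atoms, traj$xyz[, , idx, drop = FALSE],
             time = traj$time[idx], topology = traj$topology)
}
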