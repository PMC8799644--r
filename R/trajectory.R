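# Trajectories: ordered coordinate frames over one structure topology.
#
# Frames are stored bio3d-style as an n_frames x (3 * n_atoms) matrix so DCD
# input plugs in directly; fixtures use a plain-text multi-frame XYZ dialect.

new_trajectory <- function(structure, xyz, stride_ns = 1) {
  stopifnot(stride_ns > 0)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(structure$atoms))
    stop("each frame must have one position per atom")
  structure(list(structure = structure, xyz = xyz, stride_ns = stride_ns),
            class = "restime_trajectory")
}

#' @export
print.restime_trajectory <- function(x, ...) {
  cat("restime trajectory:", nrow(x$xyz), "frames x",
      ncol(x$xyz) / 3, "atoms, stride", x$stride_ns, "ns\n")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

# coordinates of frame i as an n_atoms x 3 matrix
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

# structure with coordinates of frame i
frame_structure <- function(traj, i) set_coords(traj$structure, frame_coords(traj, i))

#' Read a trajectory
#'
#' DCD files are read through bio3d; the plain-text multi-frame XYZ dialect
#' (`<natoms>` / comment / `element x y z` blocks) is parsed directly and is
#' the fixture format the synthetic generators write.
#'
#' @param path trajectory file (`.dcd` or text XYZ).
#' @param structure topology `restime_structure`.
#' @param stride_ns time between stored frames in ns (default 1, matching an
#'   analysis stride of one frame per nanosecond).
#' @export
read_trajectory <- function(path, structure, stride_ns = 1) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    return(new_trajectory(structure, xyz, stride_ns))
  }
  lines <- readLines(path, warn = FALSE)
  nat <- nrow(structure$atoms)
  per <- nat + 2
  if (length(lines) %% per != 0)
    stop("XYZ trajectory length not a multiple of natoms+2")
  nf <- length(lines) %/% per
  xyz <- matrix(NA_real_, nf, 3 * nat)
  for (f in seq_len(nf)) {
    off <- (f - 1) * per
    if (as.integer(trimws(lines[off + 1])) != nat)
      stop("frame ", f, ": atom count mismatch")
    flds <- strsplit(trimws(lines[off + 2 + seq_len(nat)]), "\\s+")
    m <- t(vapply(flds, function(v) as.numeric(v[2:4]), numeric(3)))
    xyz[f, ] <- as.vector(t(m))
  }
  new_trajectory(structure, xyz, stride_ns)
}

#' Write a trajectory as multi-frame XYZ text
#'
#' @param traj a `restime_trajectory`.
#' @param path output file.
#' @export
write_trajectory_xyz <- function(traj, path) {
  el <- traj$structure$atoms$element
  nat <- length(el)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    writeLines(c(as.character(nat), paste("frame", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
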