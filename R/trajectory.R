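# Data model for periodic-box multi-frame molecular coordinates with explicit
# molecule grouping, plus the minimum-image metric used throughout.

#' Molecule grouping topology
#'
#' Describes how flat per-frame coordinate arrays decompose into molecules,
#' and which atoms form each aromatic ring. All indices are 1-based global
#' atom indices into the frame coordinate matrix.
#'
#' @param molecules list of molecule descriptors; each a list with `id`
#'   (string), `atoms` (integer vector), optional `elements` (character vector,
#'   same length), and `rings` (list of integer vectors, each a subset of
#'   `atoms` with >= 5 atoms).
#' @return object of class `mol_topology`.
#' @export
mol_topology <- function(molecules) {
  if (!length(molecules)) abort("topology must contain at least one molecule")
  seen <- integer()
  ids <- character(length(molecules))
  for (i in seq_along(molecules)) {
    m <- molecules[[i]]
    if (is.null(m$id)) molecules[[i]]$id <- m$id <- sprintf("mol%d", i)
    ids[i] <- m$id
    if (!length(m$atoms)) abort("molecule '%s' has no atoms", m$id)
    if (any(m$atoms %in% seen))
      abort("molecule '%s' shares atoms with another molecule", m$id)
    seen <- c(seen, m$atoms)
    for (ring in m$rings %||% list()) {
      if (length(ring) < 5L)
        abort("molecule '%s': rings must have >= 5 atoms", m$id)
      if (!all(ring %in% m$atoms))
        abort("molecule '%s': ring references atoms outside the molecule", m$id)
    }
  }
  if (anyDuplicated(ids)) abort("duplicate molecule ids in topology")
  structure(list(molecules = molecules, n_atoms = length(seen)),
            class = "mol_topology")
}

#' @export
print.mol_topology <- function(x, ...) {
  cat(sprintf("<mol_topology> %d molecule(s), %d atom(s)\n",
              length(x$molecules), x$n_atoms))
  invisible(x)
}

topology_ids <- function(topology) {
  vapply(topology$molecules, `[[`, character(1), "id")
}

get_molecule <- function(topology, id) {
  ids <- topology_ids(topology)
  i <- match(id, ids)
  if (is.na(i)) abort("unknown molecule id '%s'", id)
  topology$molecules[[i]]
}

#' A single trajectory frame
#'
#' @param time frame time, ps.
#' @param box orthorhombic box edge lengths, Angstrom (length 3, all > 0).
#' @param coords numeric matrix, n_atoms x 3, Angstrom.
#' @return object of class `traj_frame`.
#' @export
traj_frame <- function(time, box, coords) {
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3)
  if (length(box) != 3L || any(is.na(box)) || any(box <= 0))
    abort("frame box must be three positive edge lengths")
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) abort("frame coordinates must be an n x 3 matrix")
  structure(list(time = as.numeric(time), box = box, coords = coords),
            class = "traj_frame")
}

#' A molecular trajectory: topology plus ordered frames
#'
#' @param topology a [mol_topology()].
#' @param frames list of [traj_frame()]; times must be strictly increasing and
#'   every frame must carry one coordinate row per topology atom.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, frames) {
  if (!inherits(topology, "mol_topology")) abort("'topology' must be a mol_topology")
  if (!length(frames)) abort("trajectory must contain at least one frame")
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(times) <= 0))
    abort("frame times must be strictly increasing (got %s)",
          paste(utils::head(times, 8), collapse = ", "))
  max_atom <- max(unlist(lapply(topology$molecules, `[[`, "atoms")))
  for (f in frames)
    if (nrow(f$coords) < max_atom)
      abort("frame at t=%g has %d coordinate rows but topology references atom %d",
            f$time, nrow(f$coords), max_atom)
  structure(list(topology = topology, frames = frames), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  times <- vapply(x$frames, `[[`, numeric(1), "time")
  cat(sprintf("<trajectory> %d frame(s) (t = %g..%g ps), %d molecule(s)\n",
              length(x$frames), min(times), max(times), length(x$topology$molecules)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")

# wrap displacement components into [-L/2, L/2)
min_image_disp <- function(d, box) {
  if (is.matrix(d)) {
    sweep(d, 2, box, function(dd, L) dd - L * floor(dd / L + 0.5))
  } else {
    d - box * floor(d / box + 0.5)
  }
}

#' Minimum-image distance under periodic boundary conditions
#'
#' Euclidean distance between two points after wrapping each Cartesian
#' displacement component into `[-L/2, L/2)` for the corresponding box edge.
#'
#' @param p,q points, Angstrom (length-3 vectors).
#' @param box orthorhombic box edge lengths, Angstrom.
#' @return distance in Angstrom.
#' @examples
#' minimum_image_distance(c(1, 0, 0), c(9.5, 0, 0), c(10, 10, 10))  # 1.5
#' @export
minimum_image_distance <- function(p, q, box) {
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3)
  if (any(box <= 0)) abort("box edges must be positive")
  d <- min_image_disp(as.numeric(q) - as.numeric(p), box)
  sqrt(sum(d^2))
}

# minimum-image distances from one point to each row of a matrix
min_image_dist_many <- function(p, pts, box) {
  d <- min_image_disp(sweep(pts, 2, p), box)
  sqrt(rowSums(d^2))
}
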