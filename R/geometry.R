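# Per-molecule geometry: periodic unwrapping, centroids and best-fit ring
# planes. Molecules may be stored wrapped across the box boundary; every
# routine here first shifts all atoms to the periodic image nearest the
# molecule's first atom.

# Unwrap a coordinate block across periodic images, anchored on its first row.
unwrap_coords <- function(coords, box) {
  anchor <- coords[1, ]
  disp <- min_image_disp(sweep(coords, 2, anchor), box)
  sweep(disp, 2, anchor, `+`)
}

#' Molecule centroid under periodic boundary conditions
#'
#' Mean of the molecule's atom positions after unwrapping the molecule across
#' periodic images. The geometric (unweighted) mean is the default; the
#' mass-weighted mean uses standard atomic masses looked up from the
#' molecule's element labels. The returned point is wrapped into `[0, L)`.
#'
#' @param frame a [traj_frame()].
#' @param mol a molecule descriptor from a [mol_topology()].
#' @param weighting `"geometric"` (default) or `"mass"`.
#' @return length-3 point, Angstrom.
#' @export
molecule_centroid <- function(frame, mol, weighting = c("geometric", "mass")) {
  weighting <- match.arg(weighting)
  if (!length(mol$atoms)) abort("molecule has no atoms")
  xyz <- unwrap_coords(frame$coords[mol$atoms, , drop = FALSE], frame$box)
  w <- if (weighting == "mass") {
    if (is.null(mol$elements))
      abort("mass weighting requires element labels on molecule '%s'", mol$id)
    m <- ATOMIC_MASSES[mol$elements]
    if (anyNA(m)) abort("unknown element(s) %s on molecule '%s'",
                        paste(unique(mol$elements[is.na(m)]), collapse = ", "), mol$id)
    m
  } else {
    rep(1, nrow(xyz))
  }
  cen <- colSums(xyz * w) / sum(w)
  cen - frame$box * floor(cen / frame$box)
}

# centroids for all molecules of a topology in one frame (rows = molecules)
all_centroids <- function(frame, topology, weighting = "geometric") {
  t(vapply(topology$molecules, molecule_centroid,
           numeric(3), frame = frame, weighting = weighting))
}

#' Best-fit plane of an aromatic ring
#'
#' Returns the ring centroid and the unit normal of the least-squares plane
#' through the (periodically unwrapped) ring atoms, computed by singular value
#' decomposition of the centered coordinates. The normal's sign is arbitrary.
#'
#' @param frame a [traj_frame()].
#' @param ring_atoms integer vector of >= 3 atom indices.
#' @return list with `centroid` (length-3) and `normal` (unit length-3).
#' @export
ring_plane <- function(frame, ring_atoms) {
  if (length(ring_atoms) < 3L) abort("a ring plane needs >= 3 atoms")
  xyz <- unwrap_coords(frame$coords[ring_atoms, , drop = FALSE], frame$box)
  cen <- colMeans(xyz)
  centered <- sweep(xyz, 2, cen)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-30))
    abort("degenerate ring geometry: atoms are (nearly) collinear")
  list(centroid = cen, normal = sv$v[, 3])
}

# Best-fit plane over all ring atoms of a molecule (used for conformer typing
# in molecule-centroid mode). Falls back to all atoms if no rings are defined.
molecule_plane <- function(frame, mol) {
  atoms <- unique(unlist(mol$rings %||% list()))
  if (length(atoms) < 3L) atoms <- mol$atoms
  if (length(atoms) < 3L)
    abort("molecule '%s' has too few atoms for a plane fit", mol$id)
  ring_plane(frame, atoms)
}

# interplanar angle folded to [0, 90] degrees
interplanar_angle <- function(n1, n2) {
  c_ <- abs(sum(unit3(n1) * unit3(n2)))
  acos(min(1, c_)) * 180 / pi
}

# lateral offset: component of the (minimum-image) centroid separation vector
# perpendicular to the mean plane normal
lateral_offset <- function(d_vec, n1, n2) {
  n1 <- unit3(n1); n2 <- unit3(n2)
  if (sum(n1 * n2) < 0) n2 <- -n2
  n <- unit3(n1 + n2)
  perp <- d_vec - sum(d_vec * n) * n
  sqrt(sum(perp^2))
}
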