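# Synthetic conformation and trajectory generators. These produce every input
# the census pipeline needs without any molecular dynamics engine: single
# frames with clusters planted in a chosen stacking geometry, and
# dynamic-equilibrium trajectories in which the cluster-size census is
# constant while cluster membership exchanges between frames.

#' Rigid hexagonal ring template
#'
#' A planar six-carbon ring (benzene-like, 1.40 A edge by default) in the
#' z = 0 plane, used as the template molecule for all planted fixtures:
#' conformer geometry, not chemistry, is what the census detectors see.
#'
#' @param edge ring edge length, A (the circumradius of a regular hexagon
#'   equals its edge).
#' @return 6 x 3 coordinate matrix.
#' @export
hexagon_template <- function(edge = 1.40) {
  ang <- (0:5) * pi / 3
  cbind(edge * cos(ang), edge * sin(ang), 0)
}

#' Specification of a planted-cluster conformation
#'
#' @param n_molecules total solute molecules in the box.
#' @param box cubic box edge, A.
#' @param clusters list of planted clusters, each a list with `size` (>= 2),
#'   `conformer` (`"face-to-face"`, `"offset-face-to-face"` or
#'   `"edge-to-face"`) and `distance` (intra-cluster adjacent centroid
#'   distance, A; must fall below the conformer's cutoff). See
#'   [planted_dimers()] for a shorthand.
#' @param min_sep minimum inter-cluster centroid separation, A; must exceed
#'   the edge-to-face cutoff so planted monomers stay monomers.
#' @param template molecule template coordinate matrix (rows = atoms, in the
#'   z = 0 plane, centered on the origin); defaults to [hexagon_template()].
#' @param seed RNG seed for deterministic placement.
#' @param criteria the [stacking_criteria()] the plant must satisfy.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(n_molecules, box = 40, clusters = list(), min_sep = 6,
                       template = hexagon_template(), seed = 1,
                       criteria = stacking_criteria()) {
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) abort("'n_molecules' must be >= 1")
  if (box <= 0) abort("'box' must be positive")
  if (min_sep <= criteria$cutoff_e2f)
    abort("'min_sep' (%.1f) must exceed the edge-to-face cutoff (%.1f)",
          min_sep, criteria$cutoff_e2f)
  total <- 0L
  for (cl in clusters) {
    if (is.null(cl$size) || cl$size < 2L) abort("planted clusters must have size >= 2")
    conf <- cl$conformer %||% "face-to-face"
    if (!conf %in% c("face-to-face", "offset-face-to-face", "edge-to-face"))
      abort("unknown conformer '%s'", conf)
    d <- cl$distance %||% switch(conf, `face-to-face` = 3.5,
                                 `offset-face-to-face` = 3.7, `edge-to-face` = 4.5)
    cutoff <- switch(conf, `face-to-face` = criteria$cutoff_f2f,
                     `offset-face-to-face` = criteria$cutoff_offset,
                     `edge-to-face` = criteria$cutoff_e2f)
    if (d >= cutoff)
      abort("planted %s distance %.2f A is not below its cutoff %.2f A", conf, d, cutoff)
    total <- total + as.integer(cl$size)
  }
  if (total > n_molecules)
    abort("planted cluster sizes sum to %d but only %d molecules requested",
          total, n_molecules)
  clusters <- lapply(clusters, function(cl) {
    conf <- cl$conformer %||% "face-to-face"
    list(size = as.integer(cl$size), conformer = conf,
         distance = cl$distance %||% switch(conf, `face-to-face` = 3.5,
                                            `offset-face-to-face` = 3.7,
                                            `edge-to-face` = 4.5))
  })
  structure(list(n_molecules = n_molecules, box = box, clusters = clusters,
                 min_sep = min_sep, template = template, seed = seed,
                 criteria = criteria),
            class = "plant_spec")
}

#' Shorthand for n planted face-to-face dimers
#'
#' @param n number of dimers.
#' @param distance intra-dimer centroid distance, A.
#' @param conformer stacking conformer for every dimer.
#' @return list of cluster descriptors for [plant_spec()].
#' @export
planted_dimers <- function(n, distance = 3.5, conformer = "face-to-face") {
  rep(list(list(size = 2L, conformer = conformer, distance = distance)), n)
}

# orientation-resolved member offsets and normals for one planted cluster
cluster_geometry <- function(cl, criteria) {
  axis <- random_unit3()
  lat_dir <- unit3(orthogonal_to(axis))
  size <- cl$size
  steps <- seq_len(size) - (size + 1) / 2
  if (cl$conformer == "face-to-face") {
    rel <- outer(steps * cl$distance, axis)
    normals <- matrix(axis, size, 3, byrow = TRUE)
  } else if (cl$conformer == "offset-face-to-face") {
    lat <- max(criteria$offset_lateral_min + 0.4, 0.4 * cl$distance)
    if (lat >= cl$distance) lat <- cl$distance * 0.6
    axial <- sqrt(cl$distance^2 - lat^2)
    step_vec <- axial * axis + lat * lat_dir
    rel <- outer(steps, step_vec)
    normals <- matrix(axis, size, 3, byrow = TRUE)
  } else {  # edge-to-face: alternate perpendicular ring planes along the axis
    rel <- outer(steps * cl$distance, axis)
    normals <- t(vapply(seq_len(size), function(m) {
      if (m %% 2L == 1L) axis else lat_dir
    }, numeric(3)))
  }
  list(rel = rel, normals = normals)
}

# a vector orthogonal to v (deterministic given RNG state)
orthogonal_to <- function(v) {
  u <- random_unit3()
  w <- u - sum(u * v) * v
  while (sqrt(sum(w^2)) < 1e-6) {
    u <- random_unit3()
    w <- u - sum(u * v) * v
  }
  w
}

# place molecule template at centroid `at` with plane normal `normal` and a
# spin angle about the normal
place_molecule <- function(template, at, normal, spin) {
  rz <- matrix(c(cos(spin), sin(spin), 0, -sin(spin), cos(spin), 0, 0, 0, 1), 3, 3)
  r <- rotation_to(normal) %*% rz
  sweep(template %*% t(r), 2, at, `+`)
}

# Core builder: consumes the current RNG stream. `assign` maps site slots to
# molecule indices (used by the equilibrium generator to exchange membership).
build_conformation_impl <- function(spec, assign = NULL) {
  n <- spec$n_molecules
  box <- rep(spec$box, 3)
  clusters <- spec$clusters
  n_clustered <- sum(vapply(clusters, `[[`, integer(1), "size"))
  n_mono <- n - n_clustered
  # one anchor per cluster and per monomer; extent = how far members reach
  extents <- c(vapply(clusters, function(cl) (cl$size - 1) * cl$distance / 2,
                      numeric(1)), rep(0, n_mono))
  n_sites <- length(extents)
  anchors <- matrix(NA_real_, n_sites, 3)
  for (s in seq_len(n_sites)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      cand <- stats::runif(3) * box
      ok <- TRUE
      if (s > 1L) {
        d <- min_image_dist_many(cand, anchors[seq_len(s - 1L), , drop = FALSE], box)
        ok <- all(d > spec$min_sep + extents[s] + extents[seq_len(s - 1L)])
      }
      if (ok) { anchors[s, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      abort("packing failed after bounded attempts; try a larger box (edge %.0f A, %d sites)",
            spec$box, n_sites)
  }
  # realize molecules site by site
  centroids <- matrix(NA_real_, n, 3)
  normals <- matrix(NA_real_, n, 3)
  slot <- 0L
  site_of <- integer(n)   # which site each slot belongs to (cluster id or 0)
  for (ci in seq_along(clusters)) {
    geom <- cluster_geometry(clusters[[ci]], spec$criteria)
    for (m in seq_len(clusters[[ci]]$size)) {
      slot <- slot + 1L
      centroids[slot, ] <- anchors[ci, ] + geom$rel[m, ]
      normals[slot, ] <- geom$normals[m, ]
      site_of[slot] <- ci
    }
  }
  for (mi in seq_len(n_mono)) {
    slot <- slot + 1L
    centroids[slot, ] <- anchors[length(clusters) + mi, ]
    normals[slot, ] <- random_unit3()
    site_of[slot] <- 0L
  }
  spins <- stats::runif(n, 0, 2 * pi)
  if (is.null(assign)) assign <- seq_len(n)   # molecule index occupying each slot
  apm <- nrow(spec$template)
  coords <- matrix(NA_real_, n * apm, 3)
  for (slot in seq_len(n)) {
    mol_idx <- assign[slot]
    rows <- (mol_idx - 1L) * apm + seq_len(apm)
    xyz <- place_molecule(spec$template, centroids[slot, ], normals[slot, ], spins[slot])
    coords[rows, ] <- xyz - spec$box * floor(xyz / spec$box)  # wrap into the box
  }
  membership <- lapply(seq_along(clusters), function(ci)
    sort(sprintf("mol%d", assign[site_of == ci])))
  list(coords = coords, membership = membership)
}

plant_topology <- function(spec) {
  apm <- nrow(spec$template)
  mol_topology(lapply(seq_len(spec$n_molecules), function(i) {
    atoms <- (i - 1L) * apm + seq_len(apm)
    list(id = sprintf("mol%d", i), atoms = atoms,
         elements = rep("C", apm), rings = list(atoms))
  }))
}

#' Build a single-frame conformation with planted clusters
#'
#' Realizes the spec's clusters in their requested stacking geometry
#' (parallel eclipsed stacks for face-to-face, parallel laterally slipped
#' stacks for offset face-to-face, alternating perpendicular planes for
#' edge-to-face) and scatters the remaining molecules as monomers, all
#' inter-cluster centroid distances above `min_sep`. Deterministic under the
#' spec's seed. Coordinates are wrapped into the box, so molecules may be
#' split across the periodic boundary.
#'
#' @param spec a [plant_spec()].
#' @return a single-frame [trajectory()]; attribute `planted` carries the
#'   planted cluster-size multiset and attribute `membership` the molecule
#'   ids of each planted cluster.
#' @export
build_conformation <- function(spec) {
  if (!inherits(spec, "plant_spec")) abort("'spec' must be a plant_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  built <- build_conformation_impl(spec)
  traj <- trajectory(plant_topology(spec),
                     list(traj_frame(0, spec$box, built$coords)))
  attr(traj, "planted") <- sort(vapply(spec$clusters, `[[`, integer(1), "size"))
  attr(traj, "membership") <- built$membership
  traj
}

#' Build a dynamic-equilibrium trajectory
#'
#' Every frame carries exactly the planted cluster-size multiset, but which
#' molecules occupy which cluster changes between frames through seeded
#' random identity swaps, and every frame's positions are freshly drawn. This
#' emulates a system at dynamic equilibrium of aggregation and segregation:
#' the census is time-constant while individual molecules associate and
#' dissociate.
#'
#' @param spec a [plant_spec()].
#' @param n_frames number of frames (times 0, 1, ..., n_frames - 1 ps).
#' @param exchange_rate number of random identity swaps applied between
#'   consecutive frames; 0 freezes membership.
#' @return a [trajectory()]; attribute `membership` is a per-frame list of
#'   planted cluster membership (molecule ids).
#' @export
build_equilibrium_trajectory <- function(spec, n_frames = 6, exchange_rate = 2) {
  if (!inherits(spec, "plant_spec")) abort("'spec' must be a plant_spec")
  if (n_frames < 1L) abort("'n_frames' must be >= 1")
  if (exchange_rate < 0L) abort("'exchange_rate' must be >= 0")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_molecules
  assign <- seq_len(n)
  frames <- vector("list", n_frames)
  membership <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1L && exchange_rate > 0L && n > 1L) {
      for (k in seq_len(exchange_rate)) {
        ij <- sample.int(n, 2L)
        assign[ij] <- assign[rev(ij)]
      }
    }
    built <- build_conformation_impl(spec, assign)
    frames[[f]] <- traj_frame(f - 1, spec$box, built$coords)
    membership[[f]] <- built$membership
  }
  traj <- trajectory(plant_topology(spec), frames)
  attr(traj, "planted") <- sort(vapply(spec$clusters, `[[`, integer(1), "size"))
  attr(traj, "membership") <- membership
  traj
}
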