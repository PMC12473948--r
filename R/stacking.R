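# Recognition of pi-stacked pairs and clustering of contacts into aggregates.
#
# A stacked dimer is recognized when the centroid distance of two molecules is
# below a conformer-specific cutoff: 3.8 A for face-to-face, 3.9 A for offset
# face-to-face, 5.0 A for edge-to-face. The conformer itself is decided
# geometrically: pairs whose ring planes are within `parallel_angle_max` of
# parallel belong to the parallel family, subdivided by the lateral slip of
# one centroid against the shared plane normal; steeper pairs are T-shaped
# (edge-to-face).

#' Stacking recognition criteria
#'
#' @param cutoff_f2f centroid-distance cutoff for face-to-face stacks, A.
#' @param cutoff_offset cutoff for offset face-to-face stacks, A.
#' @param cutoff_e2f cutoff for edge-to-face (T-shaped) stacks, A.
#' @param parallel_angle_max interplanar angle (degrees) below which a pair
#'   counts as parallel.
#' @param offset_lateral_min lateral slip (A) below which a parallel pair is
#'   eclipsed (face-to-face) rather than offset.
#' @param mode `"molecule-centroid"` (default: the tested distance is between
#'   whole-molecule centroids) or `"ring-pair"` (every ring pair is tested and
#'   the closest qualifying ring pair decides).
#' @return object of class `stacking_criteria`.
#' @export
stacking_criteria <- function(cutoff_f2f = 3.8, cutoff_offset = 3.9,
                              cutoff_e2f = 5.0, parallel_angle_max = 50,
                              offset_lateral_min = 1.0,
                              mode = c("molecule-centroid", "ring-pair")) {
  mode <- match.arg(mode)
  cut <- c(cutoff_f2f, cutoff_offset, cutoff_e2f)
  if (any(!is.finite(cut)) || any(cut <= 0)) abort("cutoffs must be positive")
  if (cutoff_f2f > cutoff_offset || cutoff_offset > cutoff_e2f)
    abort("cutoffs must satisfy f2f <= offset <= e2f")
  if (parallel_angle_max <= 0 || parallel_angle_max >= 90)
    abort("'parallel_angle_max' must lie in (0, 90) degrees")
  structure(list(cutoff_f2f = cutoff_f2f, cutoff_offset = cutoff_offset,
                 cutoff_e2f = cutoff_e2f, parallel_angle_max = parallel_angle_max,
                 offset_lateral_min = offset_lateral_min, mode = mode),
            class = "stacking_criteria")
}

#' @export
print.stacking_criteria <- function(x, ...) {
  cat(sprintf(paste0("<stacking_criteria> f2f < %.1f A, offset < %.1f A, ",
                     "e2f < %.1f A; parallel if angle <= %.0f deg, ",
                     "eclipsed if slip < %.1f A; mode = %s\n"),
              x$cutoff_f2f, x$cutoff_offset, x$cutoff_e2f,
              x$parallel_angle_max, x$offset_lateral_min, x$mode))
  invisible(x)
}

# classify one candidate geometry (distance + two plane normals + separation
# vector) against the criteria; NULL if no conformer's cutoff admits it
classify_geometry <- function(dist, d_vec, n1, n2, criteria) {
  gamma <- interplanar_angle(n1, n2)
  if (gamma <= criteria$parallel_angle_max) {
    off <- lateral_offset(d_vec, n1, n2)
    if (off < criteria$offset_lateral_min && dist < criteria$cutoff_f2f)
      return(list(conformer = "face-to-face", angle = gamma, offset = off))
    if (dist < criteria$cutoff_offset)
      return(list(conformer = "offset-face-to-face", angle = gamma, offset = off))
    return(NULL)
  }
  if (dist < criteria$cutoff_e2f)
    return(list(conformer = "edge-to-face", angle = gamma,
                offset = lateral_offset(d_vec, n1, n2)))
  NULL
}

#' Classify a molecule pair as a stacked contact
#'
#' In `molecule-centroid` mode the tested distance is the minimum-image
#' distance between whole-molecule centroids and the planes are each
#' molecule's best-fit ring plane. In `ring-pair` mode every ring pair is
#' tested on ring centroids/planes and the closest qualifying ring pair
#' decides. Face-to-face is tested before offset face-to-face, and both
#' before edge-to-face, so the most specific conformer wins.
#'
#' @param frame a [traj_frame()].
#' @param mol_a,mol_b molecule descriptors from the topology.
#' @param criteria a [stacking_criteria()].
#' @return a `pair_contact` list (`pair`, `conformer`, `distance`, `angle`,
#'   `offset`) or `NULL` when the pair is not in contact.
#' @export
classify_pair <- function(frame, mol_a, mol_b, criteria = stacking_criteria()) {
  if (identical(mol_a$id, mol_b$id)) abort("cannot classify a molecule against itself")
  if (criteria$mode == "molecule-centroid") {
    ca <- molecule_centroid(frame, mol_a)
    cb <- molecule_centroid(frame, mol_b)
    d_vec <- min_image_disp(cb - ca, frame$box)
    dist <- sqrt(sum(d_vec^2))
    if (dist >= criteria$cutoff_e2f) return(NULL)  # cheap reject
    pa <- molecule_plane(frame, mol_a)
    pb <- molecule_plane(frame, mol_b)
    cl <- classify_geometry(dist, d_vec, pa$normal, pb$normal, criteria)
    if (is.null(cl)) return(NULL)
    return(structure(c(list(pair = c(mol_a$id, mol_b$id), distance = dist), cl),
                     class = "pair_contact"))
  }
  # ring-pair mode
  rings_a <- mol_a$rings %||% list()
  rings_b <- mol_b$rings %||% list()
  if (!length(rings_a) || !length(rings_b))
    abort("ring-pair mode requires ring definitions on both molecules ('%s', '%s')",
          mol_a$id, mol_b$id)
  best <- NULL
  for (ra in rings_a) for (rb in rings_b) {
    pa <- ring_plane(frame, ra)
    pb <- ring_plane(frame, rb)
    d_vec <- min_image_disp(pb$centroid - pa$centroid, frame$box)
    dist <- sqrt(sum(d_vec^2))
    if (dist >= criteria$cutoff_e2f) next
    cl <- classify_geometry(dist, d_vec, pa$normal, pb$normal, criteria)
    if (!is.null(cl) && (is.null(best) || dist < best$distance))
      best <- c(list(pair = c(mol_a$id, mol_b$id), distance = dist), cl)
  }
  if (is.null(best)) NULL else structure(best, class = "pair_contact")
}

#' @export
print.pair_contact <- function(x, ...) {
  cat(sprintf("<pair_contact> %s -- %s: %s, d = %.2f A, angle = %.1f deg, slip = %.2f A\n",
              x$pair[1], x$pair[2], x$conformer, x$distance, x$angle, x$offset))
  invisible(x)
}

#' Cluster one frame into aggregates
#'
#' Builds the undirected contact graph from [classify_pair()] over all
#' molecule pairs and takes its connected components as aggregates; isolated
#' molecules are monomers.
#'
#' @param frame a [traj_frame()].
#' @param topology a [mol_topology()].
#' @param criteria a [stacking_criteria()].
#' @return object of class `cluster_set`: `time`, `clusters` (list of
#'   molecule-id character vectors), `n_molecules`, `contacts` (list of
#'   `pair_contact`).
#' @export
cluster_frame <- function(frame, topology, criteria = stacking_criteria()) {
  mols <- topology$molecules
  n <- length(mols)
  if (!n) abort("no molecules to cluster")
  contacts <- list()
  edges <- integer()
  if (n > 1L) {
    # precompute centroids once for the cheap distance prefilter
    cents <- all_centroids(frame, topology)
    for (i in seq_len(n - 1L)) {
      dists <- min_image_dist_many(cents[i, ], cents[(i + 1L):n, , drop = FALSE],
                                   frame$box)
      for (jrel in which(dists < criteria$cutoff_e2f + 4)) {
        j <- i + jrel
        ct <- classify_pair(frame, mols[[i]], mols[[j]], criteria)
        if (!is.null(ct)) {
          contacts[[length(contacts) + 1L]] <- ct
          edges <- c(edges, i, j)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  ids <- topology_ids(topology)
  clusters <- unname(split(ids, memb))
  structure(list(time = frame$time, clusters = clusters, n_molecules = n,
                 contacts = contacts),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- sort(lengths(x$clusters), decreasing = TRUE)
  cat(sprintf("<cluster_set> t = %g ps: %d molecules in %d cluster(s); sizes %s\n",
              x$time, x$n_molecules, length(x$clusters),
              paste(sizes, collapse = " ")))
  invisible(x)
}
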