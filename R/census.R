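# Aggregate census: per-frame percentages of molecules found as monomers,
# dimers, trimers and larger aggregates, time series over checkpoints,
# pair distance traces, equilibrium detection and a geometric hydrogen-bond
# counter.

CENSUS_SPECIES <- c("monomer", "dimer", "trimer", "polymer")

#' Aggregate census of one clustered frame
#'
#' For each aggregate size k, the percentage of molecules residing in size-k
#' clusters is `100 * k * n_k / N`, rounded half-up to one decimal. Sizes
#' k >= 4 are pooled as "polymer"; the exact size distribution is kept in
#' `counts`.
#'
#' @param clusters a `cluster_set` from [cluster_frame()].
#' @return object of class `aggregate_census`: `time`, `n_molecules`,
#'   `percent` (named numeric: monomer/dimer/trimer/polymer, 1 decimal),
#'   `counts` (named integer vector: number of clusters of each exact size).
#' @examples
#' # 34 molecules as 17 monomers, 7 dimers and 1 trimer
#' cs <- structure(list(time = 50, n_molecules = 34,
#'                      clusters = c(as.list(paste0("m", 1:17)),
#'                                   split(paste0("d", 1:14), rep(1:7, each = 2)),
#'                                   list(paste0("t", 1:3)))),
#'                 class = "cluster_set")
#' census(cs)$percent  # 50.0 / 41.2 / 8.8 / 0.0
#' @export
census <- function(clusters) {
  if (!inherits(clusters, "cluster_set")) abort("'clusters' must be a cluster_set")
  n <- clusters$n_molecules
  if (!n) abort("census of an empty system")
  sizes <- lengths(clusters$clusters)
  if (sum(sizes) != n)
    abort("cluster sizes sum to %d but the system has %d molecules", sum(sizes), n)
  tab <- table(sizes)
  counts <- stats::setNames(as.integer(tab), names(tab))
  pct_of <- function(pred) {
    k <- as.integer(names(counts))
    sel <- pred(k)
    round_half_up(100 * sum(k[sel] * counts[sel]) / n, 1)
  }
  percent <- c(monomer = pct_of(function(k) k == 1L),
               dimer = pct_of(function(k) k == 2L),
               trimer = pct_of(function(k) k == 3L),
               polymer = pct_of(function(k) k >= 4L))
  structure(list(time = clusters$time, n_molecules = n,
                 percent = percent, counts = counts),
            class = "aggregate_census")
}

#' @export
print.aggregate_census <- function(x, ...) {
  cat(sprintf("<aggregate_census> t = %g ps, N = %d\n", x$time, x$n_molecules))
  cat(sprintf("  %-8s %5.1f%%\n", names(x$percent), x$percent), sep = "")
  invisible(x)
}

#' @export
as.data.frame.aggregate_census <- function(x, ...) {
  data.frame(time = x$time, n_molecules = x$n_molecules,
             monomer = x$percent[["monomer"]], dimer = x$percent[["dimer"]],
             trimer = x$percent[["trimer"]], polymer = x$percent[["polymer"]])
}

#' Census time series over trajectory checkpoints
#'
#' Runs [cluster_frame()] + [census()] at the frame nearest each requested
#' checkpoint time (no interpolation; the matched frame time is reported so
#' any mismatch is visible). Checkpoints outside the trajectory's time span
#' are an error.
#'
#' @param traj a [trajectory()].
#' @param checkpoints numeric vector of times, ps.
#' @param criteria a [stacking_criteria()].
#' @return data.frame with one row per checkpoint: `checkpoint`, `time`
#'   (matched frame time), `n_molecules`, `monomer`, `dimer`, `trimer`,
#'   `polymer`; the full census objects are attached as attribute `censuses`.
#' @export
census_timeseries <- function(traj, checkpoints, criteria = stacking_criteria()) {
  if (!inherits(traj, "trajectory")) abort("'traj' must be a trajectory")
  if (!length(traj$frames)) abort("empty trajectory")
  if (!length(checkpoints)) abort("no checkpoints given")
  times <- frame_times(traj)
  span <- range(times)
  out <- vector("list", length(checkpoints))
  for (i in seq_along(checkpoints)) {
    cp <- checkpoints[i]
    if (cp < span[1] - 1e-9 || cp > span[2] + 1e-9)
      abort("checkpoint %g outside trajectory span [%g, %g]", cp, span[1], span[2])
    k <- which.min(abs(times - cp))
    cs <- cluster_frame(traj$frames[[k]], traj$topology, criteria)
    out[[i]] <- census(cs)
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  df <- cbind(checkpoint = checkpoints, df)
  rownames(df) <- NULL
  attr(df, "censuses") <- out
  df
}

#' Centroid distance trace of one molecule pair
#'
#' Per-frame minimum-image distance between the two molecules' centroids,
#' with the fraction of frames falling below each stacking cutoff.
#'
#' @param traj a [trajectory()].
#' @param id_a,id_b distinct molecule ids.
#' @param criteria a [stacking_criteria()] supplying the cutoffs.
#' @return data.frame (`time`, `distance`); attribute `below_cutoff` is a
#'   named vector of fractions of frames below the f2f / offset / e2f cutoffs.
#' @export
pair_distance_trace <- function(traj, id_a, id_b,
                                criteria = stacking_criteria()) {
  if (identical(id_a, id_b)) abort("the two molecules must differ")
  ma <- get_molecule(traj$topology, id_a)
  mb <- get_molecule(traj$topology, id_b)
  d <- vapply(traj$frames, function(f) {
    minimum_image_distance(molecule_centroid(f, ma), molecule_centroid(f, mb), f$box)
  }, numeric(1))
  out <- data.frame(time = frame_times(traj), distance = d)
  attr(out, "below_cutoff") <- c(
    f2f = mean(d < criteria$cutoff_f2f),
    offset = mean(d < criteria$cutoff_offset),
    e2f = mean(d < criteria$cutoff_e2f))
  out
}

#' Earliest stable checkpoint of a census series
#'
#' Scans for the earliest checkpoint from which every species percentage
#' stays within `tol` percentage points (max minus min) through the end of
#' the series; at least `window` checkpoints must remain from that point.
#' Returns `NA` when the series never stabilizes.
#'
#' @param series data.frame from [census_timeseries()] (or any data.frame
#'   with columns `monomer`, `dimer`, `trimer`, `polymer`).
#' @param window minimum number of trailing checkpoints required (>= 2).
#' @param tol allowed percentage-point variation per species.
#' @return the row index of the earliest stable checkpoint, or `NA_integer_`.
#' @export
detect_equilibrium <- function(series, window = 2L, tol = 5.0) {
  if (window < 2L) abort("'window' must be >= 2")
  n <- nrow(series)
  if (window > n) abort("'window' (%d) exceeds series length (%d)", window, n)
  species <- intersect(CENSUS_SPECIES, names(series))
  for (j in seq_len(n - window + 1L)) {
    rng <- vapply(species, function(s) {
      v <- series[[s]][j:n]
      max(v) - min(v)
    }, numeric(1))
    if (all(rng <= tol)) return(j)
  }
  NA_integer_
}

#' Geometric hydrogen-bond count in a frame
#'
#' Counts donor-H...acceptor triples with H...A minimum-image distance at
#' most `d_max` and D-H...A angle at least `angle_min` (angle at the
#' hydrogen, computed on minimum-image displacement vectors).
#'
#' @param frame a [traj_frame()].
#' @param donors two-column integer matrix of (donor heavy atom, hydrogen)
#'   index pairs.
#' @param acceptors integer vector of acceptor atom indices.
#' @param d_max H...A distance cutoff, A.
#' @param angle_min D-H...A angle cutoff, degrees.
#' @return integer count.
#' @export
count_hbonds <- function(frame, donors, acceptors, d_max = 3.5, angle_min = 130) {
  donors <- matrix(as.integer(donors), ncol = 2)
  if (anyNA(donors)) abort("donor (D, H) pairs must be complete; missing hydrogen?")
  acceptors <- as.integer(acceptors)
  n <- 0L
  for (k in seq_len(nrow(donors))) {
    d_idx <- donors[k, 1]; h_idx <- donors[k, 2]
    hd <- min_image_disp(frame$coords[d_idx, ] - frame$coords[h_idx, ], frame$box)
    for (a_idx in setdiff(acceptors, c(d_idx, h_idx))) {
      ha <- min_image_disp(frame$coords[a_idx, ] - frame$coords[h_idx, ], frame$box)
      r <- sqrt(sum(ha^2))
      if (r > d_max) next
      cosang <- sum(hd * ha) / (sqrt(sum(hd^2)) * r)
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang >= angle_min) n <- n + 1L
    }
  }
  n
}
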