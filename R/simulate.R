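# Square-well Metropolis Monte Carlo toy model of reversible solute
# association. Point particles with a hard core and a short-ranged attractive
# well stand in for aromatic solutes; the model is used to reproduce the
# qualitative trends of aggregation -- more aggregates at higher particle
# concentration and at stronger attraction -- not any quantitative percentage.

#' Parameters of the association Monte Carlo toy model
#'
#' @param n_particles number of particles.
#' @param box cubic box edge, A.
#' @param sigma hard-core diameter, A.
#' @param epsilon attractive well depth, kcal/mol (>= 0).
#' @param well_range outer edge of the attractive well, A; also the single
#'   distance cutoff used for the aggregate census. Must exceed `sigma`.
#' @param temperature absolute temperature, K.
#' @param sweeps number of Monte Carlo sweeps (one attempted move per
#'   particle per sweep).
#' @param step maximum per-axis trial displacement, A.
#' @param record_every record a frame and census every this many sweeps.
#' @param seed RNG seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_particles, box = 30, sigma = 3.5, epsilon = 1.0,
                       well_range = 5.0, temperature = 298, sweeps = 200,
                       step = 2.0, record_every = 1, seed = 1) {
  if (n_particles < 2L) abort("'n_particles' must be >= 2")
  if (box <= 0 || sigma <= 0 || step <= 0) abort("geometry parameters must be positive")
  if (well_range <= sigma) abort("'well_range' must exceed 'sigma'")
  if (epsilon < 0) abort("'epsilon' must be >= 0 (well depth)")
  if (temperature <= 0) abort("'temperature' must be positive")
  if (sweeps < 1L) abort("'sweeps' must be >= 1")
  structure(list(n_particles = as.integer(n_particles), box = box, sigma = sigma,
                 epsilon = epsilon, well_range = well_range,
                 temperature = temperature, sweeps = as.integer(sweeps),
                 step = step, record_every = as.integer(record_every),
                 seed = seed),
            class = "sim_params")
}

#' Map stacking interaction energies to well depths
#'
#' Scales the magnitude of per-pair aromatic interaction energies into
#' Metropolis well depths: `epsilon = scale * |energy|`. The default scale
#' 0.10 keeps `epsilon / k_B T` near 1.6--1.9 at 298 K so association stays
#' reversible at desk scale; full-strength energies would freeze aggregates.
#'
#' @param energies interaction energies, kcal/mol (typically negative).
#' @param scale dimensionless scale factor.
#' @return well depths in kcal/mol, same order as `energies`.
#' @export
epsilon_from_energy <- function(energies, scale = 0.10) {
  if (scale <= 0) abort("'scale' must be positive")
  scale * abs(energies)
}

# cluster point particles by a single distance cutoff; returns cluster_set
cluster_by_cutoff <- function(positions, box, cutoff, time = 0) {
  n <- nrow(positions)
  edges <- integer()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d <- min_image_dist_many(positions[i, ], positions[(i + 1L):n, , drop = FALSE], box)
      for (jrel in which(d < cutoff)) edges <- c(edges, i, i + jrel)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  structure(list(time = time, clusters = unname(split(sprintf("p%d", seq_len(n)), memb)),
                 n_molecules = n, contacts = NULL),
            class = "cluster_set")
}

#' Run the square-well association Monte Carlo
#'
#' Particles start from a random non-overlapping placement; each sweep
#' attempts one single-particle displacement per particle, accepted with
#' probability `min(1, exp(-dU / k_B T))`. The pair energy is infinite inside
#' the hard core, `-epsilon` inside the well and zero beyond. Frames and the
#' single-cutoff aggregate census are recorded every `record_every` sweeps
#' (plus the initial configuration).
#'
#' @param params a [sim_params()].
#' @return list with `params`, `trajectory` (point particles, one atom per
#'   molecule), `census` (data.frame: `sweep`, species percentages,
#'   `aggregate_fraction`), and `acceptance` (proposal/acceptance counts,
#'   split by whether the trial overlapped a hard core).
#' @export
simulate_aggregation <- function(params) {
  if (!inherits(params, "sim_params")) abort("'params' must be sim_params")
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_particles
  box <- rep(params$box, 3)
  kt <- KB_KCAL * params$temperature
  # random sequential non-overlapping initial placement
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(10000L)) {
      cand <- stats::runif(3) * box
      if (i == 1L ||
          all(min_image_dist_many(cand, pos[seq_len(i - 1L), , drop = FALSE], box)
              >= params$sigma)) {
        pos[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) abort("could not place %d non-overlapping particles in a %g A box",
                   n, params$box)
  }
  proposed <- 0L; accepted <- 0L
  nonoverlap_proposed <- 0L; nonoverlap_accepted <- 0L
  frames <- list(); censuses <- list()
  record <- function(sweep) {
    cs <- cluster_by_cutoff(pos, box, params$well_range, time = sweep)
    cen <- census(cs)
    frames[[length(frames) + 1L]] <<- traj_frame(sweep, box, pos)
    censuses[[length(censuses) + 1L]] <<- cbind(
      sweep = sweep, as.data.frame(cen)[, -1],
      aggregate_fraction = 1 - cen$percent[["monomer"]] / 100)
  }
  record(0)
  for (sweep in seq_len(params$sweeps)) {
    for (i in seq_len(n)) {
      trial <- pos[i, ] + stats::runif(3, -params$step, params$step)
      trial <- trial - box * floor(trial / box)
      others <- pos[-i, , drop = FALSE]
      d_new <- min_image_dist_many(trial, others, box)
      proposed <- proposed + 1L
      if (any(d_new < params$sigma)) next  # hard-core rejection
      nonoverlap_proposed <- nonoverlap_proposed + 1L
      d_old <- min_image_dist_many(pos[i, ], others, box)
      du <- -params$epsilon * (sum(d_new < params$well_range) -
                               sum(d_old < params$well_range))
      if (du <= 0 || stats::runif(1) < exp(-du / kt)) {
        pos[i, ] <- trial
        accepted <- accepted + 1L
        nonoverlap_accepted <- nonoverlap_accepted + 1L
      }
    }
    if (sweep %% params$record_every == 0L) record(sweep)
  }
  topo <- mol_topology(lapply(seq_len(n), function(i)
    list(id = sprintf("p%d", i), atoms = i, elements = "C", rings = list())))
  census_df <- do.call(rbind, censuses)
  rownames(census_df) <- NULL
  list(params = params,
       trajectory = trajectory(topo, frames),
       census = census_df,
       acceptance = list(proposed = proposed, accepted = accepted,
                         nonoverlap_proposed = nonoverlap_proposed,
                         nonoverlap_accepted = nonoverlap_accepted))
}

#' Mean equilibrium aggregate fraction of a simulation
#'
#' Averages `aggregate_fraction` over the final portion of the census series
#' (the default discards the first half as burn-in).
#'
#' @param sim result of [simulate_aggregation()].
#' @param burn_in fraction of the series to discard from the front.
#' @return mean fraction of particles residing in clusters of size >= 2.
#' @export
mean_aggregate_fraction <- function(sim, burn_in = 0.5) {
  v <- sim$census$aggregate_fraction
  keep <- v[seq.int(floor(length(v) * burn_in) + 1L, length(v))]
  mean(keep)
}
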