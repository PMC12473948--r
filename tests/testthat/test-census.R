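crit <- stacking_criteria()

# cluster_set built directly, bypassing detection
make_cluster_set <- function(sizes, n = sum(sizes), time = 0) {
  ids <- sprintf("m%d", seq_len(sum(sizes)))
  clusters <- split(ids, rep(seq_along(sizes), sizes))
  structure(list(time = time, clusters = unname(clusters), n_molecules = n),
            class = "cluster_set")
}

test_that("census percentages reproduce the published worked examples", {
  # 34 molecules: 17 monomers, 7 dimers, 1 trimer
  cen <- census(make_cluster_set(c(rep(1, 17), rep(2, 7), 3)))
  expect_equal(unname(cen$percent[c("monomer", "dimer", "trimer")]),
               c(50.0, 41.2, 8.8))
  # 15 molecules with 3 dimers
  cen <- census(make_cluster_set(c(rep(1, 9), rep(2, 3))))
  expect_equal(cen$percent[["dimer"]], 40.0)
  # 61 molecules with 4 dimers
  cen <- census(make_cluster_set(c(rep(1, 53), rep(2, 4))))
  expect_equal(unname(cen$percent[c("monomer", "dimer")]), c(86.9, 13.1))
})

test_that("census conserves molecules and sums to 100 within rounding", {
  set.seed(17)
  for (rep in 1:30) {
    sizes <- sample(1:5, sample(3:12, 1), replace = TRUE)
    cen <- census(make_cluster_set(sizes))
    expect_identical(sum(as.integer(names(cen$counts)) * cen$counts),
                     as.integer(sum(sizes)))
    expect_lte(abs(sum(cen$percent) - 100), 0.2)  # four rounded terms
  }
  bad <- make_cluster_set(c(2, 2))
  bad$n_molecules <- 5L
  expect_error(census(bad), "sum to 4")
})

test_that("time series over a stationary trajectory is constant", {
  spec <- plant_spec(24, clusters = planted_dimers(3), seed = 4)
  traj <- build_equilibrium_trajectory(spec, n_frames = 6, exchange_rate = 2)
  ser <- census_timeseries(traj, 0:5, crit)
  expect_equal(nrow(ser), 6)
  expect_true(all(ser$monomer == 75.0))
  expect_true(all(ser$dimer == 25.0))
  expect_error(census_timeseries(traj, c(0, 99), crit), "outside trajectory span")
})

test_that("a staged trajectory shows a monotone dimer percentage", {
  # frames built with 0, 1, 2, 3 planted dimers out of 12 molecules
  frames <- list()
  topo <- NULL
  for (k in 0:3) {
    spec <- plant_spec(12, clusters = planted_dimers(k), seed = 30 + k)
    tr <- build_conformation(spec)
    topo <- tr$topology
    frames[[k + 1]] <- traj_frame(k, spec$box, tr$frames[[1]]$coords)
  }
  staged <- trajectory(topo, frames)
  ser <- census_timeseries(staged, 0:3, crit)
  expect_true(all(diff(ser$dimer) > 0))
})

test_that("pair distance traces report below-cutoff fractions", {
  spec <- plant_spec(10, clusters = planted_dimers(1), seed = 6)
  traj <- build_equilibrium_trajectory(spec, n_frames = 5, exchange_rate = 0)
  bound <- attr(traj, "membership")[[1]][[1]]  # the planted dimer's members
  tr <- pair_distance_trace(traj, bound[1], bound[2], crit)
  expect_equal(nrow(tr), 5)
  expect_true(all(tr$distance < 3.8))
  expect_equal(attr(tr, "below_cutoff")[["f2f"]], 1)
  # two scattered monomers never bind
  mono <- setdiff(sprintf("mol%d", 1:10), bound)[1:2]
  tr2 <- pair_distance_trace(traj, mono[1], mono[2], crit)
  expect_equal(attr(tr2, "below_cutoff")[["e2f"]], 0)
  expect_error(pair_distance_trace(traj, "mol1", "mol1"), "must differ")
  expect_error(pair_distance_trace(traj, "mol1", "nope"), "unknown molecule")
})

test_that("equilibrium detection finds the earliest stable checkpoint", {
  constant <- data.frame(monomer = rep(75, 6), dimer = rep(25, 6),
                         trimer = 0, polymer = 0)
  expect_identical(detect_equilibrium(constant), 1L)
  growing <- data.frame(monomer = seq(100, 50, by = -10),
                        dimer = seq(0, 50, by = 10), trimer = 0, polymer = 0)
  expect_identical(detect_equilibrium(growing), NA_integer_)
  # one excursion at the second checkpoint, then back: stable from the third
  excursion <- data.frame(monomer = c(50.0, 55.9, 50.0, 50.0, 50.0, 50.0),
                          dimer = c(41.2, 35.3, 41.2, 41.2, 41.2, 41.2),
                          trimer = c(8.8, 8.8, 8.8, 8.8, 8.8, 8.8), polymer = 0)
  expect_identical(detect_equilibrium(excursion, window = 2, tol = 5.0), 3L)
  expect_error(detect_equilibrium(constant, window = 10), "exceeds series length")
  expect_error(detect_equilibrium(constant, window = 1), ">= 2")
})

test_that("hydrogen bonds require both distance and angle", {
  # linear O-H...O with donor-acceptor separation 2.8 A
  coords <- rbind(c(0, 0, 0),      # donor O
                  c(0.96, 0, 0),   # H
                  c(2.8, 0, 0))    # acceptor O
  f <- traj_frame(0, 30, coords)
  donors <- matrix(c(1L, 2L), 1, 2)
  expect_identical(count_hbonds(f, donors, acceptors = 3L), 1L)
  far <- traj_frame(0, 30, rbind(c(0, 0, 0), c(0.96, 0, 0), c(5, 0, 0)))
  expect_identical(count_hbonds(far, donors, acceptors = 3L), 0L)
  # bent geometry below the angle cutoff does not count
  bent <- traj_frame(0, 30, rbind(c(0, 0, 0), c(0.96, 0, 0), c(0.96, 2.0, 0)))
  expect_identical(count_hbonds(bent, donors, acceptors = 3L), 0L)
})

test_that("hydrogen-bond counts match a brute-force oracle on random frames", {
  set.seed(23)
  for (rep in 1:10) {
    n_d <- 4; n_a <- 6
    box <- 15
    dpos <- matrix(stats::runif(n_d * 3, 0, box), n_d, 3)
    hpos <- dpos + t(replicate(n_d, { v <- stats::rnorm(3); 0.96 * v / sqrt(sum(v^2)) }))
    apos <- matrix(stats::runif(n_a * 3, 0, box), n_a, 3)
    coords <- rbind(dpos, hpos, apos)
    f <- traj_frame(0, box, coords)
    donors <- cbind(1:n_d, n_d + 1:n_d)
    acceptors <- 2 * n_d + 1:n_a
    # oracle: explicit triple loop over 27 images for the H...A distance
    expected <- 0L
    for (k in 1:n_d) for (a in acceptors) {
      h <- coords[n_d + k, ]; d <- coords[k, ]
      r <- brute_min_image(h, coords[a, ], rep(box, 3))
      if (r <= 3.5) {
        ha <- coords[a, ] - h
        ha <- ha - box * floor(ha / box + 0.5)
        hd <- d - h
        hd <- hd - box * floor(hd / box + 0.5)
        ang <- acos(sum(ha * hd) / sqrt(sum(ha^2) * sum(hd^2))) * 180 / pi
        if (ang >= 130) expected <- expected + 1L
      }
    }
    expect_identical(count_hbonds(f, donors, acceptors), expected)
  }
})
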