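crit <- stacking_criteria()

test_that("criteria validation enforces ordering and ranges", {
  expect_error(stacking_criteria(cutoff_f2f = 4.0, cutoff_offset = 3.9), "f2f <= offset")
  expect_error(stacking_criteria(cutoff_e2f = -1), "positive|f2f <= offset")
  expect_error(stacking_criteria(parallel_angle_max = 95), "\\(0, 90\\)")
})

test_that("conformer classification follows distance, angle and slip", {
  # eclipsed parallel sandwich at 3.5 A -> face-to-face
  sys <- hex_system(rbind(c(10, 10, 10), c(10, 10, 13.5)))
  ct <- classify_pair(sys$frame, sys$topology$molecules[[1]],
                      sys$topology$molecules[[2]], crit)
  expect_equal(ct$conformer, "face-to-face")
  expect_equal(ct$distance, 3.5, tolerance = 1e-9)
  expect_lt(ct$angle, 1e-6)

  # parallel at 4.5 A exceeds both parallel cutoffs -> no contact
  sys <- hex_system(rbind(c(10, 10, 10), c(10, 10, 14.5)))
  expect_null(classify_pair(sys$frame, sys$topology$molecules[[1]],
                            sys$topology$molecules[[2]], crit))

  # perpendicular planes at 4.5 A -> edge-to-face (cutoff 5.0)
  sys <- hex_system(rbind(c(10, 10, 10), c(10, 10, 14.5)),
                    normals = rbind(c(0, 0, 1), c(0, 1, 0)))
  ct <- classify_pair(sys$frame, sys$topology$molecules[[1]],
                      sys$topology$molecules[[2]], crit)
  expect_equal(ct$conformer, "edge-to-face")
  expect_equal(ct$angle, 90, tolerance = 1e-6)

  # parallel with a 1.5 A lateral slip -> offset face-to-face
  sys <- hex_system(rbind(c(10, 10, 10), c(10, 11.5, 13.4)))
  ct <- classify_pair(sys$frame, sys$topology$molecules[[1]],
                      sys$topology$molecules[[2]], crit)
  expect_equal(ct$conformer, "offset-face-to-face")
  expect_equal(ct$offset, 1.5, tolerance = 1e-9)
})

test_that("classification is symmetric in the pair order", {
  set.seed(21)
  for (i in 1:25) {
    c1 <- c(10, 10, 10)
    c2 <- c1 + stats::rnorm(3, sd = 2)
    n1 <- stats::rnorm(3); n2 <- stats::rnorm(3)
    sys <- hex_system(rbind(c1, c2), normals = rbind(n1 / sqrt(sum(n1^2)),
                                                     n2 / sqrt(sum(n2^2))))
    a <- classify_pair(sys$frame, sys$topology$molecules[[1]],
                       sys$topology$molecules[[2]], crit)
    b <- classify_pair(sys$frame, sys$topology$molecules[[2]],
                       sys$topology$molecules[[1]], crit)
    expect_identical(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_identical(a$conformer, b$conformer)
      expect_equal(a$distance, b$distance, tolerance = 1e-9)
    }
  }
})

test_that("enlarging any cutoff never decreases the number of contacts", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 12
    cents <- matrix(stats::runif(n * 3, 0, 24), n, 3)
    normals <- t(replicate(n, { v <- stats::rnorm(3); v / sqrt(sum(v^2)) }))
    sys <- hex_system(cents, normals = normals, box = 24)
    count_contacts <- function(cr) {
      length(cluster_frame(sys$frame, sys$topology, cr)$contacts)
    }
    base <- count_contacts(crit)
    wider <- stacking_criteria(cutoff_f2f = 3.9, cutoff_offset = 4.4, cutoff_e2f = 6.0)
    expect_gte(count_contacts(wider), base)
  }
})

test_that("clusters are connected components: chain of contacts is a trimer", {
  sys <- hex_system(rbind(c(10, 10, 10), c(10, 10, 13.5), c(10, 10, 17)))
  cs <- cluster_frame(sys$frame, sys$topology, crit)
  expect_length(cs$clusters, 1)
  expect_setequal(cs$clusters[[1]], c("mol1", "mol2", "mol3"))
  cen <- census(cs)
  expect_equal(cen$percent[["trimer"]], 100)
})

test_that("a contact-free frame is all monomers", {
  sys <- hex_system(rbind(c(5, 5, 5), c(20, 5, 5), c(35, 5, 5)), box = 45)
  cs <- cluster_frame(sys$frame, sys$topology, crit)
  expect_length(cs$clusters, 3)
  expect_true(all(lengths(cs$clusters) == 1))
})

test_that("cluster partitions equal the brute-force union-find oracle", {
  set.seed(8)
  for (rep in 1:15) {
    n <- 14
    cents <- matrix(stats::runif(n * 3, 0, 22), n, 3)
    normals <- t(replicate(n, { v <- stats::rnorm(3); v / sqrt(sum(v^2)) }))
    sys <- hex_system(cents, normals = normals, box = 22)
    cs <- cluster_frame(sys$frame, sys$topology, crit)
    # oracle: classify all pairs independently, then hand-rolled union-find
    edges <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (!is.null(classify_pair(sys$frame, sys$topology$molecules[[i]],
                                 sys$topology$molecules[[j]], crit)))
        edges <- rbind(edges, c(i, j))
    }
    oracle <- canon_partition(union_find_partition(n, edges))
    got <- canon_partition(lapply(cs$clusters, function(cl)
      as.integer(sub("mol", "", cl))))
    expect_identical(got, oracle)
  }
})

test_that("lattice translations leave the census unchanged", {
  spec <- plant_spec(20, clusters = c(planted_dimers(3),
                                      list(list(size = 3, conformer = "edge-to-face",
                                                distance = 4.5))),
                     seed = 13)
  traj <- build_conformation(spec)
  f <- traj$frames[[1]]
  base <- census(cluster_frame(f, traj$topology, crit))
  set.seed(99)
  for (rep in 1:5) {
    shift <- sample(-2:2, 3, replace = TRUE) * spec$box
    f2 <- traj_frame(f$time, f$box, sweep(f$coords, 2, shift, `+`))
    moved <- census(cluster_frame(f2, traj$topology, crit))
    expect_identical(moved$percent, base$percent)
    expect_identical(moved$counts, base$counts)
  }
})

test_that("ring-pair mode requires rings and agrees on single-ring molecules", {
  sys <- hex_system(rbind(c(10, 10, 10), c(10, 10, 13.5)))
  rp <- stacking_criteria(mode = "ring-pair")
  ct <- classify_pair(sys$frame, sys$topology$molecules[[1]],
                      sys$topology$molecules[[2]], rp)
  expect_equal(ct$conformer, "face-to-face")
  noring <- sys$topology$molecules[[1]]
  noring$rings <- list()
  expect_error(classify_pair(sys$frame, noring, sys$topology$molecules[[2]], rp),
               "ring definitions")
})
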