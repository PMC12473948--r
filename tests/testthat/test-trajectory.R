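test_that("minimum-image distance handles wrapping and identities", {
  expect_equal(minimum_image_distance(c(1, 0, 0), c(9.5, 0, 0), c(10, 10, 10)), 1.5)
  expect_equal(minimum_image_distance(c(3, 4, 5), c(3, 4, 5), c(10, 10, 10)), 0)
})

test_that("minimum-image distance matches the 27-image brute-force oracle", {
  set.seed(11)
  for (i in 1:100) {
    box <- stats::runif(3, 5, 30)
    p <- stats::runif(3, -20, 50)  # points may lie outside the primary cell
    q <- stats::runif(3, -20, 50)
    pw <- p - box * floor(p / box)
    qw <- q - box * floor(q / box)
    expect_equal(minimum_image_distance(pw, qw, box),
                 brute_min_image(pw, qw, box), tolerance = 1e-9)
    # symmetry and the half-diagonal bound
    expect_equal(minimum_image_distance(pw, qw, box),
                 minimum_image_distance(qw, pw, box))
    expect_lte(minimum_image_distance(pw, qw, box), sqrt(3) / 2 * max(box))
  }
})

test_that("trajectory construction enforces its invariants", {
  sys <- hex_system(matrix(c(5, 5, 5), 1, 3))
  f1 <- sys$frame
  f2 <- traj_frame(1, f1$box, f1$coords)
  expect_error(trajectory(sys$topology, list(f2, f1)), "strictly increasing")
  expect_error(trajectory(sys$topology, list()), "at least one frame")
  expect_error(traj_frame(0, c(10, -1, 10), f1$coords), "positive")
  short <- traj_frame(0, 50, f1$coords[1:3, ])
  expect_error(trajectory(sys$topology, list(short)), "coordinate rows")
})

test_that("XYZ round-trip preserves counts, times and coordinates", {
  sys <- hex_system(rbind(c(5, 5, 5), c(15, 5, 5), c(25, 5, 5)), box = 30)
  f2 <- traj_frame(2.5, sys$frame$box, sys$frame$coords + 0.25)
  traj <- trajectory(sys$topology, list(sys$frame, f2))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, f, "xyz")
  back <- read_trajectory(f, "xyz",
                          list(mode = "block", atoms_per_molecule = 6,
                               rings = list(1:6)))
  expect_length(back$frames, 2)
  expect_length(back$topology$molecules, 3)
  expect_equal(vapply(back$frames, `[[`, numeric(1), "time"), c(0, 2.5))
  expect_lt(max(abs(back$frames[[2]]$coords - f2$coords)), 1e-3)
})

test_that("GRO round-trip converts nm and keeps 0.01 A precision", {
  sys <- hex_system(rbind(c(3, 4, 5), c(12, 4, 5)), box = 20)
  traj <- trajectory(sys$topology, list(sys$frame))
  f <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj, f, "gro")
  back <- read_trajectory(f, "gro", list(mode = "residue", rings = list(1:6)))
  expect_equal(back$frames[[1]]$box, c(20, 20, 20))
  expect_lte(max(abs(back$frames[[1]]$coords - sys$frame$coords)), 0.01)
  expect_length(back$topology$molecules, 2)
})

test_that("a 1.0 nm GRO box reads as 10 A", {
  lines <- c("t= 0.0", "1",
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MOL", "C", 1L, 0.5, 0.5, 0.5),
             sprintf("%10.5f%10.5f%10.5f", 1.0, 1.0, 1.0))
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines, f)
  tr <- read_trajectory(f, "gro", list(mode = "explicit",
                                       molecules = list(list(id = "m1", atoms = 1))))
  expect_equal(tr$frames[[1]]$box, c(10, 10, 10))
  expect_equal(tr$frames[[1]]$coords[1, ], c(5, 5, 5))
})

test_that("triclinic GRO boxes are rejected", {
  lines <- c("t= 0.0", "1",
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "MOL", "C", 1L, 0.5, 0.5, 0.5),
             "   1.00000   1.00000   1.00000   0.00000   0.00000   0.30000   0.00000   0.00000   0.00000")
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines, f)
  expect_error(read_trajectory(f, "gro", list(mode = "explicit",
                                              molecules = list(list(id = "m1", atoms = 1)))),
               "triclinic")
})

test_that("PDB round-trip keeps boxes, times and molecule count", {
  sys <- hex_system(rbind(c(5, 5, 5), c(15, 15, 15)), box = 25)
  f2 <- traj_frame(1, sys$frame$box, sys$frame$coords + 0.5)
  traj <- trajectory(sys$topology, list(sys$frame, f2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f, "pdb")
  back <- read_trajectory(f, "pdb", list(mode = "residue", rings = list(1:6)))
  expect_length(back$frames, 2)
  expect_length(back$topology$molecules, 2)
  expect_equal(back$frames[[1]]$box, c(25, 25, 25))
  expect_equal(vapply(back$frames, `[[`, numeric(1), "time"), c(0, 1))
  expect_lt(max(abs(back$frames[[2]]$coords - f2$coords)), 1e-2)
})

test_that("a 61-molecule planted box survives an XYZ round trip", {
  spec <- plant_spec(61, clusters = planted_dimers(4), seed = 9)
  traj <- build_conformation(spec)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, f, "xyz")
  back <- read_trajectory(f, "xyz", list(mode = "block", atoms_per_molecule = 6,
                                         rings = list(1:6)))
  expect_length(back$topology$molecules, 61)
  cen <- census(cluster_frame(back$frames[[1]], back$topology))
  expect_equal(unname(cen$percent[c("monomer", "dimer")]), c(86.9, 13.1))
})

test_that("grouping validation rejects out-of-range atoms and malformed files", {
  sys <- hex_system(matrix(c(5, 5, 5), 1, 3))
  traj <- trajectory(sys$topology, list(sys$frame))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, f, "xyz")
  expect_error(read_trajectory(f, "xyz",
                               list(mode = "explicit",
                                    molecules = list(list(id = "m", atoms = 1:12)))),
               "outside 1..6")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "time=0 box=10,10,10", "C 0 0 0", "C nope 0 0"), bad)
  expect_error(read_trajectory(bad, "xyz", list(mode = "block", atoms_per_molecule = 1)),
               "malformed|non-numeric")
})
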