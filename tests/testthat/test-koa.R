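test_that("log K_OA follows the solvation free energy relation", {
  expect_equal(logkoa_from_dg(0), 0)
  # -40 kJ/mol at 298 K: 40000 / (2.303 * 8.314 * 298)
  expect_equal(logkoa_from_dg(-40, 298), 7.01, tolerance = 1e-3)
  # monotone: more negative dg -> larger log K_OA
  dgs <- seq(-60, 0, by = 5)
  expect_true(all(diff(logkoa_from_dg(dgs)) < 0))
  expect_error(logkoa_from_dg(-40, 0), "positive")
})

test_that("dg -> logK -> dg round-trips to 1e-9", {
  set.seed(2)
  dg <- stats::runif(20, -80, -5)
  expect_equal(dg_from_logkoa(logkoa_from_dg(dg, 298), 298), dg, tolerance = 1e-9)
})

test_that("apparent log K_OA degenerates correctly without aggregation", {
  th <- list(species_thermo("monomer", -41))
  est <- apparent_logkoa(c(monomer = 100), th)
  expect_equal(est$apparent_log_koa, logkoa_from_dg(-41))
  expect_equal(unname(est$by_mode["monomer-fraction"]), logkoa_from_dg(-41))
})

test_that("equal per-molecule free energies collapse the weighted mode", {
  th <- list(species_thermo("monomer", -41), species_thermo("dimer", -82))
  est <- apparent_logkoa(c(monomer = 50, dimer = 50), th)
  expect_equal(est$apparent_log_koa, logkoa_from_dg(-41), tolerance = 1e-12)
})

test_that("the weighted estimator matches hand arithmetic and its bounds", {
  th <- list(species_thermo("monomer", -41.0), species_thermo("dimer", -90.0))
  f <- c(monomer = 86.9, dimer = 13.1)
  est <- apparent_logkoa(f, th, temperature = 298)
  hand <- 0.869 * logkoa_from_dg(-41, 298) + 0.131 * logkoa_from_dg(-45, 298)
  expect_equal(est$apparent_log_koa, hand, tolerance = 1e-9)
  lo <- min(est$per_species_logkoa); hi <- max(est$per_species_logkoa)
  expect_gte(est$apparent_log_koa, lo)
  expect_lte(est$apparent_log_koa, hi)
  # per_molecule flag suppresses the division by size
  th2 <- list(species_thermo("monomer", -41.0),
              species_thermo("dimer", -45.0, per_molecule = TRUE))
  expect_equal(apparent_logkoa(f, th2, temperature = 298)$apparent_log_koa,
               hand, tolerance = 1e-12)
})

test_that("fractions must be complete, named and normalized", {
  th <- list(species_thermo("monomer", -41))
  expect_error(apparent_logkoa(c(monomer = 80, dimer = 20), th),
               "no solvation free energy.*dimer")
  expect_error(apparent_logkoa(c(monomer = 80), th), "sum to 100")
  expect_error(apparent_logkoa(c(80, 20), th), "named")
})

test_that("a more favorable dimer makes both modes increase with dimer fraction", {
  th <- list(species_thermo("monomer", -41), species_thermo("dimer", -100))
  fr <- seq(0, 40, by = 5)
  vals_w <- vapply(fr, function(fd)
    apparent_logkoa(c(monomer = 100 - fd, dimer = fd), th)$apparent_log_koa,
    numeric(1))
  vals_m <- vapply(fr[-1], function(fd)
    apparent_logkoa(c(monomer = 100 - fd, dimer = fd), th,
                    mode = "monomer-fraction")$apparent_log_koa, numeric(1))
  expect_true(all(diff(vals_w) > 0))
  expect_true(all(diff(vals_m) > 0))
})

test_that("concentration profiles flag monotonicity and handle degeneracies", {
  th <- list(species_thermo("monomer", -41), species_thermo("dimer", -100))
  tab <- data.frame(concentration = c(0.15, 0.075, 0.0375),
                    monomer = c(70, 85, 100), dimer = c(30, 15, 0))
  prof <- concentration_profile(tab, th)
  expect_true(all(diff(prof$apparent_log_koa) < 0))
  expect_false(isTRUE(attr(prof, "trend_violation")))
  # all-monomer rows: constant profile
  flat <- data.frame(concentration = c(0.1, 0.05), monomer = c(100, 100), dimer = 0)
  pf <- concentration_profile(flat, th)
  expect_equal(diff(pf$apparent_log_koa), 0)
  # single row: one estimate, no trend flag
  one <- concentration_profile(tab[1, ], th)
  expect_equal(nrow(one), 1)
  expect_true(is.na(attr(one, "trend_violation")))
  expect_error(concentration_profile(tab[0, ], th), "empty")
  # inverted ordering (rising apparent value on dilution) is flagged
  bad <- data.frame(concentration = c(0.15, 0.075),
                    monomer = c(100, 70), dimer = c(0, 30))
  expect_warning(pb <- concentration_profile(bad, th), "increases on dilution")
  expect_true(attr(pb, "trend_violation"))
})
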