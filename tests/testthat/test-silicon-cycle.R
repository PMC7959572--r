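test_that("utilization inverts the open-system model at its endpoints", {
  u <- compute_utilization(c(1.71, 0.10, 1.388))
  expect_equal(u$utilization_pct, c(100, 0, 80), tolerance = 1e-10)
  expect_equal(u$fraction_remaining, c(0, 1, 0.2), tolerance = 1e-10)
  expect_equal(u$qc_flag, rep("ok", 3))
})

test_that("utilization is affine in d30si with slope 100/|epsilon|", {
  k <- isotope_constants()
  grid <- seq(-1, 3, by = 0.05)
  u <- compute_utilization(grid, k)$utilization_pct
  slopes <- diff(u) / diff(grid)
  expect_equal(slopes, rep(100 / abs(k$epsilon), length(slopes)),
               tolerance = 1e-9)
  expect_true(all(diff(u) > 0))
})

test_that("out-of-range utilization is flagged, never clamped", {
  u <- compute_utilization(c(1.9, -0.5))
  expect_equal(u$qc_flag, c("out_of_range", "out_of_range"))
  expect_gt(u$utilization_pct[1], 100)
  expect_lt(u$utilization_pct[2], 0)
})

test_that("non-finite isotope values are rejected naming the sample", {
  expect_error(compute_utilization(c(1.5, NA), sample_id = c("s1", "s2")),
               "s2")
  expect_error(isotope_constants(epsilon = 0.5), "negative")
})

test_that("BSi MAR is the product of concentration, density and rate", {
  expect_identical(compute_bsi_mar(0, 0.7, 0.1), 0)
  expect_equal(compute_bsi_mar(20, 0.5, 0.05), 0.005)
  expect_equal(compute_bsi_mar(20, 0.5, 0.10),
               2 * compute_bsi_mar(20, 0.5, 0.05))
  expect_error(compute_bsi_mar(-1, 0.5, 0.05), "non-negative")
})

test_that("alignment interpolates MAR onto isotope ages without extrapolation", {
  iso <- data.frame(sample_id = c("x", "y"), age_ce = c(1950, 1975),
                    d30si = c(1.4, 1.5), d30si_2sigma = c(0.1, 0.1))
  bsi <- data.frame(age_ce = c(1950, 2000), bsi_pct = c(20, 40),
                    dbd_g_cm3 = c(0.5, 0.5), sar_cm_yr = c(0.02, 0.02))
  paired <- align_series(iso, bsi)
  # exact age match passes through; midpoint of MAR 0.002 and 0.004 is 0.003
  expect_equal(paired$mar, c(0.002, 0.003))
  iso_out <- iso; iso_out$age_ce <- c(1950, 2019)
  expect_error(align_series(iso_out, bsi), "extrapolation")
  expect_error(align_series(iso[, -3], bsi), "d30si")
})

test_that("supply is 100 at the reference and scales with MAR and utilization", {
  paired <- tiny_paired()
  s <- compute_supply(paired)
  expect_identical(s$supply_pct[s$is_reference], 100)
  expect_equal(s$age_ce[s$is_reference], 2005)
  # MAR at 1900/1950 is half the reference, utilization equal -> 50%
  expect_equal(s$supply_pct[1:2], c(50, 50), tolerance = 1e-6)

  # halved utilization at equal MAR doubles supply
  p2 <- paired
  p2$d30si[1] <- 1.71 + (-1.61) * 0.6       # U = 40 vs U_ref = 80
  p2$mar[1] <- paired$mar[4]
  s2 <- compute_supply(p2)
  expect_equal(s2$supply_pct[1], 200, tolerance = 1e-6)
})

test_that("supply is invariant to a common rescaling of all MAR values", {
  paired <- tiny_paired()
  s1 <- compute_supply(paired)
  p3 <- paired; p3$mar <- p3$mar * 7.3
  s3 <- compute_supply(p3)
  expect_equal(s1$supply_pct, s3$supply_pct, tolerance = 1e-12)
})

test_that("reference matching honours tolerance and breaks ties young", {
  paired <- tiny_paired()
  expect_error(compute_supply(paired, reference_age = 1920, tolerance = 2),
               "no paired sample")
  # equidistant candidates at 2000 and 2010: the younger (2010) wins
  p <- paired
  p$age_ce <- c(1900, 1950, 2000, 2010)
  s <- compute_supply(p, reference_age = 2005, tolerance = 5)
  expect_equal(s$age_ce[s$is_reference], 2010)
})

test_that("Monte Carlo is degenerate at zero noise and reproducible", {
  paired <- tiny_paired()
  paired$d30si_2sigma <- 0
  r <- propagate_uncertainty(paired, n_reps = 200, seed = 1,
                             sigma = list(bsi_pct = 0, dbd = 0, sar = 0))
  expect_equal(r$utilization_mc_median, r$utilization_pct, tolerance = 1e-12)
  expect_equal(r$supply_mc_median, r$supply_pct, tolerance = 1e-12)
  expect_equal(r$utilization_mc_sigma, rep(0, 4))
  expect_equal(r$supply_mc_sigma, rep(0, 4))

  paired2 <- tiny_paired()
  a <- propagate_uncertainty(paired2, n_reps = 500, seed = 42)
  b <- propagate_uncertainty(paired2, n_reps = 500, seed = 42)
  expect_identical(a, b)
  expect_error(propagate_uncertainty(paired2, n_reps = 1), "n_reps")
})

test_that("MC medians track deterministic values and sigma scales linearly", {
  core <- make_core(core_config(), seed = 8)
  paired <- align_series(core$isotopes, core$bsi)
  n_reps <- 4000
  r <- propagate_uncertainty(paired, n_reps = n_reps, seed = 2,
                             sigma = list(bsi_pct = 0, dbd = 0, sar = 0))
  se <- r$utilization_mc_sigma / sqrt(n_reps)
  expect_true(all(abs(r$utilization_mc_median - r$utilization_pct) <=
                    3 * pmax(se, 1e-12) + 0.02))

  # doubling the isotope noise doubles the utilization MC sigma (+-5%)
  p2 <- paired; p2$d30si_2sigma <- paired$d30si_2sigma * 2
  r2 <- propagate_uncertainty(p2, n_reps = n_reps, seed = 2,
                              sigma = list(bsi_pct = 0, dbd = 0, sar = 0))
  ratio <- r2$utilization_mc_sigma / r$utilization_mc_sigma
  expect_true(all(abs(ratio - 2) < 0.1))
})

test_that("the reference sample carries nonzero supply MC sigma", {
  r <- propagate_uncertainty(tiny_paired(), n_reps = 1000, seed = 5)
  ref <- which(r$is_reference)
  expect_identical(r$supply_pct[ref], 100)
  expect_gt(r$supply_mc_sigma[ref], 0)
  expect_equal(r$supply_mc_median[ref], 100, tolerance = 2)
})
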