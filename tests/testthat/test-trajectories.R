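test_that("simple paths are counted according to the entry/exit rules", {
  geom <- pore_geometry(z_entry = -1.4, z_exit = 1.7, z_div = 0)
  # monotone path straight through: one traversal, one halfway
  z_through <- seq(-2, 2, by = 0.05)
  expect_equal(count_permeations(z_through, geom)[["total"]], 1)
  expect_equal(count_halfway(z_through, geom)[["total"]], 1)
  expect_equal(count_permeations(z_through, geom)[["up"]], 1)
  expect_equal(count_permeations(z_through, geom)[["down"]], 0)

  # enters, reaches z = -0.5 (short of z_div), retreats: nothing counted
  z_retreat <- c(-2, -1, -0.5, -1, -2)
  expect_equal(count_permeations(z_retreat, geom)[["total"]], 0)
  expect_equal(count_halfway(z_retreat, geom)[["total"]], 0)

  # enters, crosses z_div, retreats: halfway but no traversal
  z_recross <- c(-2, -1, 0.5, -1, -2)
  expect_equal(count_permeations(z_recross, geom)[["total"]], 0)
  expect_equal(count_halfway(z_recross, geom)[["total"]], 1)

  # downhill direction is symmetric
  z_down <- rev(z_through)
  expect_equal(count_permeations(z_down, geom)[["down"]], 1)
  expect_equal(count_halfway(z_down, geom)[["total"]], 1)

  # empty or trivial trajectories count nothing
  expect_equal(count_permeations(numeric(0), geom)[["total"]], 0)
  expect_equal(count_permeations(c(-2, -2), geom)[["total"]], 0)
})

test_that("streaming event counts equal a brute-force replay on 1000 random walks", {
  geom <- pore_geometry(z_entry = -1.4, z_exit = 1.7, z_div = 0.1)
  set.seed(12)
  for (i in 1:1000) {
    z <- cumsum(c(runif(1, -3, 3), rnorm(250, 0, 0.6)))
    expect_identical(
      unname(count_permeations(z, geom)[["total"]]),
      unname(brute_force_counts(z, geom)[["through"]]))
    expect_identical(
      unname(count_halfway(z, geom)[["total"]]),
      unname(brute_force_counts(z, geom)[["halfway"]]))
  }
})

test_that("completion requires reaching the dividing surface: N_through <= N_halfway", {
  geom <- pore_geometry()
  set.seed(3)
  for (i in 1:50) {
    z <- cumsum(c(-2, rnorm(500, 0.02, 0.5)))
    expect_lte(count_permeations(z, geom)[["total"]],
               count_halfway(z, geom)[["total"]])
  }
})

test_that("ballistic trajectories give kappa = 1 exactly; degenerate sets signal errors", {
  geom <- pore_geometry()
  ballistic <- lapply(seq(-3, -2, length.out = 20), function(z0)
    seq(z0, z0 + 6, by = 0.02))
  k <- transmission_coefficient(ballistic, geom)
  expect_identical(k$kappa, 1)
  expect_equal(k$N_through, k$N_halfway)
  # strict-ratio mode returns the literal inverse ratio
  ks <- transmission_coefficient(ballistic, geom, strict_ratio = TRUE)
  expect_identical(ks$kappa, 1)

  # walkers reflected before the dividing surface: no halfway reaches
  bounce <- replicate(10, c(-2, seq(-1.3, -0.6, by = 0.1),
                            seq(-0.7, -2, by = -0.1)), simplify = FALSE)
  expect_error(transmission_coefficient(bounce, geom), "dividing surface")

  # walkers that reach z_div but always recross: undefined estimate
  recross <- replicate(10, c(-2, -1, 0.05, -1, -2), simplify = FALSE)
  expect_error(transmission_coefficient(recross, geom), "undefined")
})

test_that("kappa of unbiased walkers matches an independent first-passage simulation", {
  geom <- pore_geometry(z_entry = -1.4, z_exit = 1.7, z_div = 0)
  trajs <- generate_walk_trajectories(NULL, geom, n_particles = 300,
                                      n_steps = 3000, step_sd = 0.1,
                                      seed = 8)
  k <- transmission_coefficient(trajs, geom)

  # independent oracle: free random walk released just inside the entry,
  # absorbed at either boundary; kappa = P(exit far side | reached z_div)
  set.seed(99)
  n_rel <- 4000
  reached <- 0L; crossed <- 0L
  for (i in seq_len(n_rel)) {
    z <- geom$z_entry + abs(rnorm(1, 0, 0.1))  # entry overshoot
    hit_div <- FALSE
    while (z >= geom$z_entry && z <= geom$z_exit) {
      if (z >= geom$z_div) hit_div <- TRUE
      z <- z + rnorm(1, 0, 0.1)
    }
    if (hit_div) reached <- reached + 1L
    if (z > geom$z_exit) crossed <- crossed + 1L
  }
  kappa_oracle <- crossed / reached
  se <- sqrt(kappa_oracle * (1 - kappa_oracle)) *
    sqrt(1 / reached + 1 / k$N_halfway)
  expect_lt(abs(k$kappa - kappa_oracle), 3 * se)
})

test_that("kappa is stable under dividing-surface shifts for flat-potential walkers", {
  trajs <- generate_walk_trajectories(NULL, pore_geometry(),
                                      n_particles = 300, n_steps = 3000,
                                      step_sd = 0.1, seed = 8)
  ks <- vapply(c(-0.2, -0.1, 0, 0.1, 0.2), function(zd)
    transmission_coefficient(trajs, pore_geometry(z_div = zd))$kappa, 0)
  k0 <- transmission_coefficient(trajs, pore_geometry())
  expect_lt(max(ks) - min(ks), 6 * k0$sd + 0.05)
  expect_true(all(ks > 0 & ks <= 1))
})

test_that("the flat-potential free-energy profile is flat within the sampling bound", {
  geom <- pore_geometry()
  set.seed(10)
  z <- runif(2e5, geom$z_entry, geom$z_exit)
  prof <- free_energy_profile(z, geom, temperature = 296)
  RT <- aquaflux_constants$R * 296
  dev <- prof$dG - mean(prof$dG, na.rm = TRUE)
  per_bin <- 2e5 / nrow(prof)
  expect_lt(max(abs(dev), na.rm = TRUE), 3 * RT / sqrt(per_bin))
})

test_that("a harmonic well is recovered by Boltzmann inversion", {
  geom <- pore_geometry(z_entry = -1.4, z_exit = 1.7, bin_width = 0.05)
  RT <- aquaflux_constants$R * 296
  kspring <- 4 * RT                      # U = (k/2) z^2, J/mol per nm^2
  sd_z <- sqrt(RT / kspring)
  set.seed(20)
  z <- rnorm(1e6, 0, sd_z)               # exact Boltzmann sampler
  z <- z[z >= geom$z_entry & z <= geom$z_exit]
  prof <- free_energy_profile(z, geom, temperature = 296)
  ok <- prof$count > 200                  # exclude starved tail bins
  expected <- kspring / 2 * prof$z[ok]^2
  shift <- mean(prof$dG[ok] - expected)
  rms <- sqrt(mean((prof$dG[ok] - expected - shift)^2))
  expect_lt(rms, 0.05 * RT)

  # scale invariance: doubling all counts leaves the profile unchanged
  prof2 <- free_energy_profile(c(z, z), geom, temperature = 296)
  expect_equal(prof2$dG[ok], prof$dG[ok], tolerance = 1e-12)
})

test_that("walker generation is seeded, Boltzmann-distributed, and supports drift", {
  geom <- pore_geometry()
  # deterministic drift with no noise traverses ballistically
  tr <- generate_walk_trajectories(NULL, geom, n_particles = 5,
                                   n_steps = 400, step_sd = 0,
                                   drift = 0.05,
                                   z0 = rep(geom$z_entry - 0.9, 5))
  expect_equal(count_permeations(tr, geom)[["up"]], 5)
  expect_identical(transmission_coefficient(tr, geom)$kappa, 1)

  # same seed, same trajectories
  t1 <- generate_walk_trajectories(NULL, geom, n_particles = 10,
                                   n_steps = 100, seed = 5)
  t2 <- generate_walk_trajectories(NULL, geom, n_particles = 10,
                                   n_steps = 100, seed = 5)
  expect_identical(t1$z, t2$z)

  # equilibrium occupancy in a quadratic well matches Boltzmann weights
  RT <- aquaflux_constants$R * 296
  U <- function(z) 2 * RT * z^2
  tr <- generate_walk_trajectories(U, geom, n_particles = 1500,
                                   n_steps = 1500, step_sd = 0.08,
                                   temperature = 296, seed = 33)
  zf <- vapply(tr$z, function(zz) zz[length(zz)], 0)  # final positions
  breaks <- seq(-2.4, 2.7, by = 0.6)
  obs <- table(cut(zf, breaks))
  mids <- breaks[-length(breaks)] + 0.3
  # expected Boltzmann mass per bin (domain is [-2.4, 2.7])
  w <- vapply(seq_along(mids), function(i)
    integrate(function(x) exp(-U(x) / RT), breaks[i], breaks[i + 1])$value,
    0)
  p <- w / sum(w)
  keep <- p * length(zf) >= 5
  chi2 <- sum((as.numeric(obs[keep]) - length(zf) * p[keep])^2 /
                (length(zf) * p[keep]))
  crit <- qchisq(0.99, df = sum(keep) - 1)
  expect_lt(chi2, crit)
})

test_that("trajectories round-trip through the tabular text format", {
  tr <- generate_walk_trajectories(NULL, pore_geometry(), n_particles = 4,
                                   n_steps = 50, seed = 2)
  path <- tempfile(fileext = ".txt")
  write_trajectories(tr, path)
  back <- read_trajectories(path)
  expect_length(back, 4)
  for (j in 1:4) expect_equal(back[[j]], tr$z[[j]], tolerance = 1e-6)
})
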