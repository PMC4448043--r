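test_that("track deposition splits segments exactly at voxel boundaries", {
  g <- fluence_grid(r_edges = c(0, 0.1), z_edges = c(0, 0.05, 0.1))
  g1 <- deposit_track(g, c(0, 0, 0.01), c(0, 0, 0.03), 1)
  expect_equal(g1$values[1, 1], 0.02, tolerance = 1e-14)
  expect_equal(g1$values[1, 2], 0)

  g2 <- deposit_track(g, c(0, 0, 0.04), c(0, 0, 0.06), 1)
  expect_equal(g2$values[1, 1], 0.01, tolerance = 1e-14)
  expect_equal(g2$values[1, 2], 0.01, tolerance = 1e-14)

  # zero-length segment is a no-op
  g3 <- deposit_track(g, c(0, 0, 0.01), c(0, 0, 0.01), 1)
  expect_identical(g3$values, g$values)
})

test_that("deposition conserves weight x length over random segments", {
  g <- fluence_grid(r_edges = seq(0, 0.5, by = 0.05),
                    z_edges = seq(-0.1, 0.5, by = 0.05))
  u <- matrix(rng_substream(17, 1, 0, 7 * 1e4), ncol = 7)
  total_in <- 0
  for (i in seq_len(nrow(u))) {
    p0 <- c((u[i, 1] - 0.5), (u[i, 2] - 0.5), u[i, 3] - 0.3)
    p1 <- p0 + 0.2 * c(u[i, 4] - 0.5, u[i, 5] - 0.5, u[i, 6] - 0.5)
    w <- u[i, 7]
    total_in <- total_in + w * sqrt(sum((p1 - p0)^2))
    g <- deposit_track(g, p0, p1, w)
  }
  total_out <- sum(g$values) + g$outside_track
  expect_lt(abs(total_out - total_in) / total_in, 1e-10)
})

test_that("fluence normalization implements the track-length estimator", {
  g <- fluence_grid(r_edges = c(0, 0.1), z_edges = c(0, 0.1),
                    n_photons = 50)
  expect_true(all(fluence_map(g, power = 2)$values == 0))

  vol <- pi * 0.1^2 * 0.1
  g$values[1, 1] <- vol * 50 / 2          # -> fluence exactly 1 at P = 2
  m <- fluence_map(g, power = 2)
  expect_equal(m$values[1, 1], 1, tolerance = 1e-12)

  expect_error(fluence_map(fluence_grid(c(0, 1), c(0, 1)), power = 1),
               "n_photons")
  g$source_power <- NA_real_
  expect_error(fluence_map(g), "power")
})

test_that("a pencil beam in a pure absorber reproduces Beer-Lambert decay", {
  absorber <- optical_medium("absorber", 1.36, mu_a = 0.07, mu_s = 0)
  geo <- layered_geometry(
    list(list(z_min = 0, z_max = 3, medium = "absorber")),
    media = list(absorber = absorber), tissue_medium = "absorber")
  cfg <- run_config(geo, pencil_source(), n_photons = 1e5, seed = 1,
                    grid = grid_spec(dr = 0.05, dz = 0.01, r_max = 0.1,
                                     z_min = 0, z_max = 2))
  m <- fluence_map(run_simulation(cfg)$grid, power = 1)
  iz0 <- 1
  iz1 <- which.min(abs(m$z_centers - 1))
  ratio <- m$values[1, iz1] / m$values[1, iz0]
  expect_within(ratio, exp(-0.07 * (m$z_centers[iz1] - m$z_centers[iz0])),
                0.01)
})

test_that("activation volume and penetration depth count tissue voxels", {
  # voxel volume pi r1^2 dz = 0.001 mm^3 by construction
  r1 <- sqrt(0.001 / (pi * 0.1))
  g <- fluence_grid(r_edges = c(0, r1), z_edges = seq(0, 1, by = 0.1),
                    n_photons = 1)
  g$values[1, 1:7] <- 10                  # 7 voxels above any threshold <= 10
  m <- fluence_map(g, power = pi * r1^2 * 0.1)  # fluence 10 in those voxels
  expect_equal(activation_volume(m, 1), 0.007, tolerance = 1e-9)
  expect_equal(activation_volume(m, 100), 0)
  expect_equal(penetration_depth(m, 1), 0.65, tolerance = 1e-12)
  expect_identical(penetration_depth(m, 100), -Inf)

  # fixture with the documented 0.495 mm last-bin centre
  g2 <- fluence_grid(r_edges = c(0, 0.1), z_edges = seq(0, 1, by = 0.01),
                     n_photons = 1)
  g2$values[1, 1:50] <- 1                 # z in [0, 0.5)
  m2 <- fluence_map(g2, power = 1)
  th <- min(m2$values[1, 1:50] / 2)
  expect_equal(penetration_depth(m2, th), 0.495, tolerance = 1e-12)
})

test_that("threshold sweeps are monotone non-increasing", {
  g <- fluence_grid(r_edges = seq(0, 0.5, by = 0.05),
                    z_edges = seq(0, 0.5, by = 0.05), n_photons = 10)
  set.seed(1)
  g$values[] <- runif(length(g$values))
  m <- fluence_map(g, power = 5)
  th <- seq(min(m$values[m$values > 0]), max(m$values), length.out = 10)
  rep <- activation_report(m, th)
  expect_true(all(diff(rep$volume_mm3) <= 0))
  expect_true(all(diff(rep$max_depth_mm[is.finite(rep$max_depth_mm)]) <= 0))
})

test_that("interface profile reports the half-max diameter", {
  re <- seq(0, 0.5, by = 0.05)
  g <- fluence_grid(r_edges = re, z_edges = c(0, 0.1), n_photons = 1)
  vol <- pi * diff(re^2) * 0.1
  g$values[, 1] <- vol                        # uniform fluence of 1
  m <- fluence_map(g, power = 1)
  prof <- interface_profile(m)
  expect_equal(prof$half_max_diameter, 1)     # uniform row: full grid width

  g$values[, 1] <- c(8, 8, 2, 1, rep(0, 6)) * vol
  m <- fluence_map(g, power = 1)              # half max 4 between bins 2 and 3
  prof <- interface_profile(m)
  r_half <- 0.075 + (8 - 4) / (8 - 2) * 0.05
  expect_equal(prof$half_max_diameter, 2 * r_half, tolerance = 1e-12)
})
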