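test_that("Beer-Lambert oracle passes and is exact in the lossless limit", {
  lossless <- beer_lambert_oracle(mu_a = 0, depths = 1, n_photons = 5000)
  expect_true(all(lossless$pass))
  expect_equal(lossless$computed, 1, tolerance = 1e-9)

  res <- beer_lambert_oracle(mu_a = 0.07, depths = c(1, 3),
                             n_photons = 5e4, seed = 2)
  expect_true(all(res$pass))
  expect_equal(res$reference[1], exp(-0.07), tolerance = 0.01)
  expect_equal(res$reference[2], exp(-0.21), tolerance = 0.01)
})

test_that("energy balance holds on completed runs and trivially at n = 0", {
  empty <- run_simulation(mled_config(0))
  expect_true(energy_balance_oracle(empty$tallies)$pass)
  expect_identical(energy_residual(empty$tallies), 0)

  # pure absorber with no scattering: everything must be absorbed
  absorber <- optical_medium("absorber", 1.36, mu_a = 1, mu_s = 0)
  geo <- layered_geometry(
    list(list(z_min = 0, z_max = 50, medium = "absorber")),
    media = list(absorber = absorber), domain_radius = 20,
    tissue_medium = "absorber")
  cfg <- run_config(geo, pencil_source(), n_photons = 5000, seed = 1,
                    grid = grid_spec(dr = 0.1, dz = 0.1, r_max = 0.5,
                                     z_min = 0, z_max = 2))
  res <- run_simulation(cfg)
  expect_true(energy_balance_oracle(res$tallies)$pass)
  expect_equal(unname(res$tallies$absorbed["absorber"]), 5000,
               tolerance = 1e-9)
})

test_that("the scalar reference engine reproduces the compiled engine exactly", {
  for (maker in list(mled_config, fiber_config)) {
    cfg <- maker(100, seed = 6)
    res <- reference_engine_equivalence(cfg, n = 60)
    expect_true(res$pass)
    expect_identical(res$computed, 0)
  }
})

test_that("the equivalence comparison detects a perturbed deviate", {
  cfg <- mled_config(5, seed = 8)
  scene <- optomc:::scene_pack(cfg)
  clean <- propagate_photon(scene, 2, photon_stream(8, 2))

  # negative control: flip the 6th deviate of the photon's substream
  tampered_stream <- local({
    inner <- photon_stream(8, 2)
    n_drawn <- 0
    list(unif = function() {
      n_drawn <<- n_drawn + 1
      u <- inner$unif()
      if (n_drawn == 6) 1 - u else u
    },
    position = inner$position, reset = inner$reset)
  })
  tampered <- propagate_photon(scene, 2, tampered_stream)
  expect_false(isTRUE(all.equal(clean$events, tampered$events)))
})

test_that("the diffusion-limit decay rate is near the theoretical value", {
  res <- diffusion_check(n_photons = 5e4, seed = 3)
  expect_false(res$gating)
  expect_lt(abs(res$computed - res$reference) / res$reference, 0.25)
})
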