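# Shared scenario builders and a cache for the expensive full-scale runs
# used by several acceptance checks.

mled_config <- function(n_photons, seed = 1, ...) {
  run_config(mled_probe_geometry(), led_disc_source(),
             n_photons = n_photons, seed = seed, ...)
}

fiber_config <- function(n_photons, seed = 1, ...) {
  run_config(fiber_standoff_geometry(), fiber_source(),
             n_photons = n_photons, seed = seed, ...)
}

# infinite-tissue scenario (source far from every boundary)
deep_tissue_config <- function(n_photons, seed = 1, ...) {
  tis <- default_media()$tissue
  geo <- layered_geometry(
    list(list(z_min = 0, z_max = 40, medium = "tissue")),
    media = list(tissue = tis), domain_radius = 20)
  run_config(geo, pencil_source(z_launch = 20), n_photons = n_photons,
             seed = seed,
             grid = grid_spec(dr = 0.1, dz = 0.1, r_max = 0.5,
                              z_min = 19, z_max = 21), ...)
}

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- maker()
  .run_cache[[key]]
}

# full-scale runs shared between acceptance checks
mled_full_run <- function() {
  cached_run("mled_1e6", function() run_simulation(mled_config(1e6)))
}

fiber_full_run <- function() {
  cached_run("fiber_1e6", function() run_simulation(fiber_config(1e6)))
}

expect_within <- function(object, center, halfwidth) {
  expect_true(abs(object - center) <= halfwidth,
              label = sprintf("%g within %g +/- %g", object, center,
                              halfwidth))
}
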