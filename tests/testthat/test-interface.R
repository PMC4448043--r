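test_that("current-to-irradiance calibration interpolates the anchors", {
  expect_identical(current_to_interface_irradiance(0.1), 0.5)
  expect_identical(current_to_interface_irradiance(4), 40)
  expect_identical(current_to_interface_irradiance(6), 52)
  # between printed anchors: linear
  expect_equal(current_to_interface_irradiance(5), (40 + 52) / 2,
               tolerance = 1e-12)
  expect_equal(current_to_interface_irradiance(0.25),
               0.5 + (0.25 - 0.1) / (4 - 0.1) * (40 - 0.5),
               tolerance = 1e-12)
  expect_error(current_to_interface_irradiance(0.05), "out of calibrated")
  expect_error(current_to_interface_irradiance(7), "out of calibrated")
  expect_error(calibration_table(c(1, 1), c(1, 2)), "strictly increasing")
  expect_error(calibration_table(c(1, 2), c(2, 1)), "strictly increasing")
})

test_that("config loading validates every field and names offenders", {
  cfg <- load_config(system.file("extdata", "mled.yaml", package = "optomc"),
                     overrides = list(run = list(n_photons = 100)))
  expect_s3_class(cfg, "run_config")
  expect_identical(cfg$n_photons, 100)
  expect_identical(cfg$source$type, "led_disc")

  raw <- yaml::read_yaml(system.file("extdata", "mled.yaml",
                                     package = "optomc"))
  raw$media$tissue$mu_a <- NULL
  err <- tryCatch(as_run_config(raw), error = conditionMessage)
  expect_match(err, "mu_a")
  expect_match(err, "tissue")

  raw2 <- yaml::read_yaml(system.file("extdata", "mled.yaml",
                                      package = "optomc"))
  raw2$run$n_photons <- NULL
  raw2$source$type <- "laser"
  err2 <- tryCatch(as_run_config(raw2), error = conditionMessage)
  expect_match(err2, "n_photons")
  expect_match(err2, "source.type")
})

test_that("the config hash is whitespace-insensitive but value-sensitive", {
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  f3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("run:", "  n_photons: 10", "  seed: 1"), f1)
  writeLines(c("run:", "",
               "    n_photons:    10", "    seed:   1"), f2)
  writeLines(c("run:", "  n_photons: 11", "  seed: 1"), f3)
  expect_identical(config_hash(f1), config_hash(f2))
  expect_false(identical(config_hash(f1), config_hash(f3)))
  # key order is canonicalized away
  expect_identical(config_hash(list(a = 1, b = 2)),
                   config_hash(list(b = 2, a = 1)))
})

test_that("grid files round-trip bit-exactly with full metadata", {
  cfg <- mled_config(300, seed = 11)
  res <- run_simulation(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_grid(res$grid, f)
  back <- read_grid(f)
  expect_identical(back$values, res$grid$values)
  expect_identical(back$r_edges, res$grid$r_edges)
  expect_identical(back$z_edges, res$grid$z_edges)
  expect_identical(back$n_photons, res$grid$n_photons)
  expect_identical(back$seed, res$grid$seed)
  expect_identical(back$outside_track, res$grid$outside_track)
  expect_identical(back$geometry$tissue_medium, "tissue")
  expect_equal(back$geometry$media$tissue$mu_s, 11.7)

  # a second identical run writes byte-identical files
  f2 <- withr::local_tempfile(fileext = ".json")
  write_grid(run_simulation(cfg)$grid, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  f3 <- withr::local_tempfile()
  expect_error(suppressWarnings(read_grid(f3)), "malformed|cannot")
  writeLines("{\"format\": \"something-else\"}", f3)
  expect_error(read_grid(f3), "not an optomc grid")
})

test_that("reports and TSV exports are written and readable", {
  cfg <- mled_config(300)
  m <- fluence_map(run_simulation(cfg)$grid, power = 1)
  rep <- activation_report(m, c(0.5, 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$threshold, c(0.5, 1))

  ft <- withr::local_tempfile(fileext = ".tsv")
  export_map_tsv(m, ft)
  tab <- read.delim(ft)
  expect_identical(nrow(tab), length(m$r_centers) * length(m$z_centers))
  expect_identical(names(tab), c("r_mm", "z_mm", "fluence_mW_mm2"))
})
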