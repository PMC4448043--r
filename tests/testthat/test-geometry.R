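test_that("layered geometries validate tiling and media references", {
  media <- default_media()
  expect_error(
    layered_geometry(list(list(z_min = 0, z_max = 1, medium = "nope")),
                     media),
    "unknown medium")
  expect_error(
    layered_geometry(list(list(z_min = 0, z_max = 1, medium = "tissue"),
                          list(z_min = 2, z_max = 3, medium = "tissue")),
                     media),
    "tile")
  geo <- mled_probe_geometry()
  expect_s3_class(geo, "layered_geometry")
  expect_identical(region_at(geo, 0, -0.05), "sapphire")
  expect_identical(region_at(geo, 0.1, -0.05), "tissue")  # beside the probe
  expect_identical(region_at(geo, 0, 0.5), "tissue")
  expect_true(is.na(region_at(geo, 0, -0.2)))             # above the contact
  expect_true(is.na(region_at(geo, 6, 1)))                # outside the domain
})

test_that("distance_to_boundary finds the nearest surface exactly", {
  geo <- mled_probe_geometry()
  hit <- distance_to_boundary(c(0, 0, -0.05), c(0, 0, 1), geo)
  expect_equal(hit$distance, 0.05, tolerance = 1e-12)
  expect_identical(hit$surface, "z_down")

  hit2 <- distance_to_boundary(c(0, 0, 1), c(0, 0, 1), geo)
  expect_equal(hit2$distance, 4, tolerance = 1e-12)  # tissue extends to 5 mm

  hit3 <- distance_to_boundary(c(0, 0, -0.05), c(1, 0, 0), geo)
  expect_equal(hit3$distance, 0.075, tolerance = 1e-12)
  expect_identical(hit3$surface, "lateral")

  expect_error(distance_to_boundary(c(0, 0, -1), c(0, 0, 1), geo),
               "outside")
})

test_that("reported hit points lie on the reported surface", {
  geo <- mled_probe_geometry()
  scene <- optomc:::scene_pack_geometry(geo)
  u <- matrix(rng_substream(13, 1, 0, 5 * 2000), ncol = 5)
  for (i in seq_len(nrow(u))) {
    # random point in the sapphire inner zone, random direction
    pos <- c((u[i, 1] - 0.5) * 0.1, (u[i, 2] - 0.5) * 0.1,
             -0.1 + 0.1 * u[i, 3])
    if (sqrt(sum(pos[1:2]^2)) >= 0.075) next
    d <- c(u[i, 4] - 0.5, u[i, 5] - 0.5, u[i, 1] - 0.5)
    nd <- sqrt(sum(d^2))
    if (nd < 1e-3) next
    d <- d / nd
    hit <- distance_to_boundary(pos, d, geo)
    p <- pos + hit$distance * d
    err <- switch(hit$surface,
      z_up = abs(p[3] - (-0.1)),
      z_down = abs(p[3] - 0),
      lateral = abs(sqrt(sum(p[1:2]^2)) - 0.075),
      edge = abs(sqrt(sum(p[1:2]^2)) - 5))
    expect_lt(err, 1e-9)
  }
})
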