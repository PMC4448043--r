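test_that("disc positions are uniform over the emitting area", {
  expect_equal(sample_disc_position(0.030, 0, 0.3), c(0, 0))
  expect_equal(sample_disc_position(0.030, 1, 0), c(0.015, 0),
               tolerance = 1e-12)

  u <- matrix(rng_substream(2, 1, 0, 2e5), ncol = 2)
  r <- 0.015 * sqrt(u[, 1])
  frac <- mean(r < 0.0075)
  se <- sqrt(0.25 * 0.75 / nrow(u))
  expect_within(frac, 0.25, 3 * se)    # area ratio (1/2)^2
  expect_true(all(r <= 0.015))
})

test_that("Lambertian directions are cosine weighted about the axis", {
  expect_equal(sample_lambertian_direction(c(0, 0, 1), 0, 0.7), c(0, 0, 1),
               tolerance = 1e-12)

  u <- matrix(rng_substream(4, 1, 0, 2e5), ncol = 2)
  dirs <- t(apply(u, 1, function(ui) {
    sample_lambertian_direction(c(0, 0, 1), ui[1], ui[2])
  }))
  ct <- dirs[, 3]
  expect_true(all(ct >= 0))
  n <- nrow(dirs)
  expect_within(mean(ct), 2 / 3, 3 * sd(ct) / sqrt(n))
  frac60 <- mean(ct > cos(60 * pi / 180))
  expect_within(frac60, 0.75, 3 * sqrt(0.75 * 0.25 / n))
  # azimuthal symmetry: transverse first moments vanish
  expect_within(mean(dirs[, 1]), 0, 3 * sd(dirs[, 1]) / sqrt(n))
  expect_within(mean(dirs[, 2]), 0, 3 * sd(dirs[, 2]) / sqrt(n))
})

test_that("fiber launches stay inside the core and the NA cone", {
  spec <- fiber_source()
  n <- 2e4
  rad <- numeric(n)
  ct <- numeric(n)
  for (i in seq_len(n)) {
    s <- photon_stream(9, i)
    out <- sample_fiber_launch(spec, s, n_launch = 1.34)
    rad[i] <- sqrt(sum(out$position[1:2]^2))
    ct[i] <- out$direction[3]
  }
  expect_true(all(rad <= 0.0525 + 1e-12))
  theta_max <- asin(0.22 / 1.34)
  expect_true(all(acos(ct) <= theta_max + 1e-9))

  # truncated 2-D Gaussian radial CDF at one sigma, against a
  # brute-force numeric integral of r exp(-r^2 / (2 sigma^2))
  sigma <- spec$sigma
  core_r <- spec$core_diameter / 2
  dens <- function(r) r * exp(-r^2 / (2 * sigma^2))
  frac_expected <- integrate(dens, 0, sigma)$value /
    integrate(dens, 0, core_r)$value
  frac <- mean(rad < sigma)
  se <- sqrt(frac_expected * (1 - frac_expected) / n)
  expect_within(frac, frac_expected, 3 * se)
})

test_that("source constructors validate their specifications", {
  expect_error(fiber_source(sigma = 0), "sigma")
  expect_error(fiber_source(na = 0), "na")
  expect_error(led_disc_source(diameter = -1), "diameter")
  # NA cone wider than the launch medium allows is impossible
  expect_error(sample_fiber_launch(fiber_source(na = 0.9), photon_stream(1, 1),
                                   n_launch = 0.5))
})
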