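test_that("free-path sampling inverts the Beer-Lambert law", {
  expect_identical(sample_free_path(11.77, 1), 0)
  expect_equal(sample_free_path(11.77, exp(-1)), 1 / 11.77,
               tolerance = 1e-12)
  expect_identical(sample_free_path(0, 0.5), Inf)
  expect_error(sample_free_path(11.77, 0), "invalid deviate")
  expect_error(sample_free_path(11.77, 1.5), "invalid deviate")

  u <- rng_substream(7, 1, 0, 1e5)
  s <- sample_free_path(11.77, u)
  se <- sd(s) / sqrt(length(s))
  expect_within(mean(s), 1 / 11.77, 3 * se)
  # draws reproduce the exponential law: KS statistic below the 1%
  # critical value D = 1.63 / sqrt(n)
  D <- suppressWarnings(
    ks.test(s, pexp, rate = 11.77)$statistic)
  expect_lt(D, 1.63 / sqrt(length(s)))
})

test_that("attenuation splits weight by the albedo and conserves it", {
  pure_scatter <- optical_medium("m", 1.36, mu_a = 0, mu_s = 5)
  expect_equal(attenuate(1, pure_scatter),
               list(new_weight = 1, absorbed = 0))
  pure_absorber <- optical_medium("m", 1.36, mu_a = 5, mu_s = 0)
  expect_equal(attenuate(1, pure_absorber),
               list(new_weight = 0, absorbed = 1))
  tissue <- optical_medium("tissue", 1.36, mu_a = 0.07, mu_s = 11.7,
                           g = 0.88)
  out <- attenuate(1, tissue)
  expect_equal(out$new_weight, 11.7 / 11.77, tolerance = 1e-12)
  expect_equal(out$absorbed, 0.07 / 11.77, tolerance = 1e-12)

  # exact conservation, bit for bit, across random weights
  w <- rng_substream(3, 1, 0, 200)
  for (wi in w) {
    o <- attenuate(wi, tissue)
    expect_identical(o$new_weight + o$absorbed, wi)
  }
  transparent <- optical_medium("t", 1.5)
  expect_error(attenuate(1, transparent), "transparent")
})

test_that("Henyey-Greenstein sampling matches its closed form and moments", {
  expect_identical(sample_hg_cos(0, 0.5), 0)
  expect_equal(sample_hg_cos(0.88, 0), -1, tolerance = 1e-12)
  expect_equal(sample_hg_cos(0.88, 1), 1, tolerance = 1e-12)
  expect_equal(sample_hg_cos(0.88, 0.5), 0.97927, tolerance = 1e-4)
  expect_error(sample_hg_cos(1, 0.5), "anisotropy")

  u <- rng_substream(11, 1, 0, 1e6)
  ct <- sample_hg_cos(0.88, u)
  expect_true(all(ct >= -1 & ct <= 1))
  se <- sd(ct) / sqrt(length(ct))
  expect_within(mean(ct), 0.88, 3 * se)

  # g = 0 is isotropic: cosine uniform on [-1, 1]
  ct0 <- sample_hg_cos(0, u[1:1e5])
  D <- suppressWarnings(ks.test(ct0, punif, -1, 1)$statistic)
  expect_lt(D, 1.63 / sqrt(1e5))
})

test_that("direction rotation preserves the deflection cosine and unit norm", {
  expect_equal(rotate_direction(c(0, 0, 1), 1, 1.3), c(0, 0, 1),
               tolerance = 1e-12)
  expect_equal(rotate_direction(c(0, 0, 1), 0, 0), c(1, 0, 0),
               tolerance = 1e-12)

  u <- matrix(rng_substream(5, 1, 0, 5e4), ncol = 5)
  for (i in seq_len(nrow(u))) {
    d <- c(u[i, 1] - 0.5, u[i, 2] - 0.5, u[i, 3] - 0.5)
    d <- d / sqrt(sum(d^2))
    ct <- 2 * u[i, 4] - 1
    out <- rotate_direction(d, ct, 2 * pi * u[i, 5])
    expect_lt(abs(sum(out^2) - 1), 1e-12)
    expect_lt(abs(sum(out * d) - ct), 1e-9)
  }

  # near-pole inputs stay finite and exact
  near_pole <- c(1e-10, 0, sqrt(1 - 1e-20))
  out <- rotate_direction(near_pole, 0.3, 2)
  expect_lt(abs(sum(out^2) - 1), 1e-12)
  expect_lt(abs(sum(out * near_pole) - 0.3), 1e-9)
})

test_that("unpolarized Fresnel reflectance has its closed-form anchors", {
  expect_identical(fresnel_unpolarized(1.36, 1.36, 0.7), 0)
  expect_equal(fresnel_unpolarized(1.77, 1.36, 1),
               ((1.77 - 1.36) / (1.77 + 1.36))^2, tolerance = 1e-12)
  # critical angle sapphire -> tissue is asin(1.36/1.77) = 50.2 deg
  crit <- asin(1.36 / 1.77)
  expect_identical(fresnel_unpolarized(1.77, 1.36, cos(55 * pi / 180)), 1)
  expect_identical(fresnel_unpolarized(1.77, 1.36, cos(crit + 1e-9)), 1)
  # continuous rise to 1 approaching the critical angle from below
  expect_gt(fresnel_unpolarized(1.77, 1.36, cos(crit - 1e-9)), 0.99)
  angles <- seq(0.1, crit - 1e-4, length.out = 50)
  R <- fresnel_unpolarized(1.77, 1.36, cos(angles))
  expect_true(all(R >= 0 & R <= 1))
  expect_true(all(diff(R) >= 0))
  expect_error(fresnel_unpolarized(1.77, 1.36, 0), "invalid geometry")
})

test_that("refraction obeys Snell's law and flags TIR", {
  out <- refract_direction(c(0, 0, 1), c(0, 0, -1), 1.77, 1.36)
  expect_false(out$tir)
  expect_equal(out$direction, c(0, 0, 1), tolerance = 1e-12)

  # 30 degrees sapphire -> tissue bends to asin(1.77 sin30 / 1.36)
  th <- 30 * pi / 180
  d <- c(sin(th), 0, cos(th))
  out <- refract_direction(d, c(0, 0, -1), 1.77, 1.36)
  expect_false(out$tir)
  sin_t <- sqrt(out$direction[1]^2 + out$direction[2]^2)
  expect_lt(abs(1.77 * sin(th) - 1.36 * sin_t), 1e-9)
  # transmitted ray stays in the plane of incidence (y = 0 here)
  expect_lt(abs(out$direction[2]), 1e-12)
  expect_lt(abs(sum(out$direction^2) - 1), 1e-12)

  th2 <- 60 * pi / 180
  out2 <- refract_direction(c(sin(th2), 0, cos(th2)), c(0, 0, -1),
                            1.77, 1.36)
  expect_true(out2$tir)
  expect_error(refract_direction(c(0, 0, 2), c(0, 0, -1), 1, 1),
               "invalid vector")
})
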