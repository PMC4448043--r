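#' Sample a photon free path by inversion of the Beer-Lambert law
#'
#' The path length between interaction sites in a turbid medium is
#' exponentially distributed with rate `mu_t`; inverting the CDF gives
#' `s = -log(u) / mu_t` for a uniform deviate `u`.  In a transparent
#' medium (`mu_t = 0`) the free path is unbounded and `Inf` is returned,
#' signalling that the photon reaches the next boundary without
#' interacting.
#'
#' @param mu_t total interaction coefficient, mm^-1, `>= 0`.
#' @param u uniform deviate(s) in (0, 1].
#' @return Path length(s) in mm.
#' @examples
#' sample_free_path(11.77, exp(-1))  # the mean free path, 1/11.77 mm
#' @export
sample_free_path <- function(mu_t, u) {
  if (!is.numeric(mu_t) || length(mu_t) != 1L || mu_t < 0) {
    stop("'mu_t' must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(u) || any(u <= 0) || any(u > 1)) {
    stop("invalid deviate: 'u' must lie in (0, 1]", call. = FALSE)
  }
  if (mu_t == 0) {
    return(rep(Inf, length(u)))
  }
  -log(u) / mu_t
}

#' Split photon weight into absorbed and surviving parts at an interaction
#'
#' At each interaction site the fraction `mu_a / mu_t` of the current
#' weight is deposited locally and the rest continues as the scattered
#' photon.  The split conserves weight exactly: the absorbed part is
#' computed as `weight - new_weight` so the two parts always sum to the
#' input bit-for-bit.
#'
#' @param weight current photon weight in (0, 1].
#' @param medium an [optical_medium()] with `mu_t > 0`.
#' @return List with components `new_weight` and `absorbed`.
#' @examples
#' tissue <- optical_medium("tissue", 1.36, mu_a = 0.07, mu_s = 11.7, g = 0.88)
#' attenuate(1, tissue)
#' @export
attenuate <- function(weight, medium) {
  stopifnot(inherits(medium, "optical_medium"))
  mt <- medium$mu_a + medium$mu_s
  if (mt <= 0) {
    stop("no interaction possible: medium is transparent (mu_t = 0)",
         call. = FALSE)
  }
  new_weight <- weight * (medium$mu_s / mt)
  list(new_weight = new_weight, absorbed = weight - new_weight)
}

#' Sample the cosine of the Henyey-Greenstein deflection angle
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function, the
#' standard one-parameter model of anisotropic single scattering in
#' tissue optics.  Its first moment equals the anisotropy `g`; `g = 0`
#' reduces to isotropic scattering, for which the cosine is uniform on
#' \[-1, 1\].
#'
#' @param g anisotropy, strictly inside (-1, 1).
#' @param u uniform deviate(s) in \[0, 1\].
#' @return Deflection cosine(s) in \[-1, 1\].
#' @examples
#' sample_hg_cos(0.88, 0.5)
#' mean(sample_hg_cos(0.88, runif(1e5)))  # close to g
#' @export
sample_hg_cos <- function(g, u) {
  if (!is.numeric(g) || length(g) != 1L || abs(g) >= 1) {
    stop("invalid anisotropy: |g| must be < 1", call. = FALSE)
  }
  if (!is.numeric(u) || any(u < 0) || any(u > 1)) {
    stop("'u' must lie in [0, 1]", call. = FALSE)
  }
  if (g == 0) {
    return(2 * u - 1)
  }
  tmp <- (1 - g * g) / (1 - g + 2 * g * u)
  ct <- (1 + g * g - tmp * tmp) / (2 * g)
  pmin(1, pmax(-1, ct))
}

#' Rotate a direction by a polar deflection and azimuth in its local frame
#'
#' Applies the conventional local-frame rotation used in photon transport:
#' the new direction makes angle `acos(cos_theta)` with the input and its
#' azimuth about the input axis is `phi`.  A numerically stable branch is
#' taken when the input is within 1e-9 of the z pole, where the general
#' formula suffers catastrophic cancellation.
#'
#' @param direction unit 3-vector.
#' @param cos_theta deflection cosine in \[-1, 1\].
#' @param phi azimuth in radians.
#' @return Unit 3-vector.
#' @examples
#' rotate_direction(c(0, 0, 1), cos_theta = 0, phi = 0)  # +x
#' @export
rotate_direction <- function(direction, cos_theta, phi) {
  stopifnot(is.numeric(direction), length(direction) == 3L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("'direction' must be a unit vector", call. = FALSE)
  }
  if (cos_theta < -1 || cos_theta > 1) {
    stop("'cos_theta' must lie in [-1, 1]", call. = FALSE)
  }
  ux <- direction[1]; uy <- direction[2]; uz <- direction[3]
  ct <- cos_theta
  st2 <- 1 - ct * ct
  st <- sqrt(max(0, st2))
  cp <- cos(phi); sp <- sin(phi)
  if (abs(uz) > 1 - 1e-9) {
    sgn <- if (uz >= 0) 1 else -1
    nx <- st * cp
    ny <- sgn * st * sp
    nz <- sgn * ct
  } else {
    tmp <- sqrt(1 - uz * uz)
    nx <- st * (ux * uz * cp - uy * sp) / tmp + ux * ct
    ny <- st * (uy * uz * cp + ux * sp) / tmp + uy * ct
    nz <- -st * cp * tmp + uz * ct
  }
  nrm <- sqrt(nx * nx + ny * ny + nz * nz)
  c(nx, ny, nz) / nrm
}

#' Unpolarized Fresnel reflectance at a planar dielectric interface
#'
#' Average of the s- and p-polarized Fresnel reflectances.  Beyond the
#' critical angle (going from dense to rare, `sin(theta_i) > n2/n1`) the
#' reflectance is exactly 1: total internal reflection.
#'
#' @param n1 refractive index on the incident side.
#' @param n2 refractive index on the far side.
#' @param cos_incident cosine(s) of the incidence angle, in (0, 1].
#' @return Reflectance(s) in \[0, 1\].
#' @examples
#' fresnel_unpolarized(1.77, 1.36, 1)           # sapphire -> tissue, normal
#' fresnel_unpolarized(1.77, 1.36, cos(55 * pi / 180))  # beyond critical: 1
#' @export
fresnel_unpolarized <- function(n1, n2, cos_incident) {
  if (!is.numeric(n1) || n1 < 1 || !is.numeric(n2) || n2 < 1) {
    stop("refractive indices must be >= 1", call. = FALSE)
  }
  if (any(cos_incident <= 0) || any(cos_incident > 1)) {
    stop("invalid geometry: 'cos_incident' must lie in (0, 1]", call. = FALSE)
  }
  vapply(cos_incident, function(ci) {
    if (n1 == n2) return(0)
    sini2 <- max(0, 1 - ci * ci)
    sint <- n1 * sqrt(sini2) / n2
    if (sint >= 1) return(1)
    cost <- sqrt(1 - sint * sint)
    rs <- (n1 * ci - n2 * cost) / (n1 * ci + n2 * cost)
    rp <- (n1 * cost - n2 * ci) / (n1 * cost + n2 * ci)
    0.5 * (rs * rs + rp * rp)
  }, numeric(1))
}

#' Refract a direction across a planar interface (Snell's law)
#'
#' The transmitted direction lies in the plane of incidence and satisfies
#' `n1 sin(theta_i) = n2 sin(theta_t)`.  When the incidence angle exceeds
#' the critical angle no transmitted ray exists and the total-internal-
#' reflection flag is returned instead.
#'
#' @param direction unit 3-vector pointing into the surface.
#' @param normal outward unit normal (so `sum(direction * normal) < 0`).
#' @param n1 refractive index on the incident side.
#' @param n2 refractive index on the far side.
#' @return List with `direction` (unit 3-vector, or `NULL` under TIR) and
#'   logical `tir`.
#' @examples
#' refract_direction(c(0, 0, 1), c(0, 0, -1), 1.77, 1.36)  # normal incidence
#' @export
refract_direction <- function(direction, normal, n1, n2) {
  stopifnot(is.numeric(direction), length(direction) == 3L,
            is.numeric(normal), length(normal) == 3L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(normal^2)) - 1) > 1e-9) {
    stop("invalid vector: 'direction' and 'normal' must be unit vectors",
         call. = FALSE)
  }
  ddn <- sum(direction * normal)
  if (ddn >= 0) {
    stop("'direction' must point into the surface (direction . normal < 0)",
         call. = FALSE)
  }
  cosi <- -ddn
  eta <- n1 / n2
  sint2 <- eta * eta * (1 - cosi * cosi)
  if (sint2 > 1) {
    return(list(direction = NULL, tir = TRUE))
  }
  cost <- sqrt(max(0, 1 - sint2))
  t <- eta * direction + (eta * cosi - cost) * normal
  list(direction = t / sqrt(sum(t^2)), tir = FALSE)
}
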