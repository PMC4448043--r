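#' Lambertian micro-LED disc source
#'
#' Photons start from uniformly random positions on a disc of the given
#' diameter (the 30 um emitting pixel) in the plane `z = z_launch`, moving
#' into the hemisphere about +z with a cosine-weighted (Lambertian)
#' angular distribution.  The launch plane is the GaN/sapphire interface:
#' light enters the sapphire substrate directly (the few-um GaN epilayers
#' are not modelled as a distinct medium).
#'
#' @param diameter emitting disc diameter, mm.
#' @param z_launch launch plane, mm (top of the sapphire slab).
#' @param collimated if `TRUE` all photons launch along +z (a pencil/flat
#'   beam control, not the physical device).
#' @return Object of class `mc_source`.
#' @examples
#' led_disc_source()
#' @export
led_disc_source <- function(diameter = 0.030, z_launch = -0.1,
                            collimated = FALSE) {
  if (diameter < 0) stop("'diameter' must be >= 0", call. = FALSE)
  structure(
    list(type = "led_disc", diameter = diameter, z_launch = z_launch,
         collimated = isTRUE(collimated), power = NA_real_),
    class = "mc_source")
}

#' Multimode fiber source
#'
#' Photons start from the fiber aperture at `z_launch` with radial
#' positions drawn from a centred two-dimensional Gaussian of standard
#' deviation `sigma`, rejection-truncated at the core rim, and directions
#' uniform in solid angle inside the numerical-aperture cone.  The cone
#' half-angle is `asin(NA / n)` with `n` the index of the launch medium
#' (saline) when `na_reference = "medium"`, or `asin(NA)` when
#' `na_reference = "air"`.
#'
#' @param core_diameter fiber core diameter, mm.
#' @param na numerical aperture.
#' @param sigma radial standard deviation of the launch-position
#'   weighting, mm; defaults to half the core radius, which puts about
#'   86\% of the untruncated mass inside the core (a typical multimode
#'   near field).
#' @param power total output power at the tip, mW.
#' @param z_launch tip plane, mm (top of the saline standoff).
#' @param na_reference whether the NA bound is evaluated in the launch
#'   medium or in air.
#' @return Object of class `mc_source`.
#' @examples
#' fiber_source()
#' @export
fiber_source <- function(core_diameter = 0.105, na = 0.22,
                         sigma = core_diameter / 4, power = 1.1,
                         z_launch = -0.3,
                         na_reference = c("medium", "air")) {
  na_reference <- match.arg(na_reference)
  if (core_diameter <= 0) stop("'core_diameter' must be > 0", call. = FALSE)
  if (na <= 0) stop("'na' must be > 0", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("invalid source: 'sigma' must be > 0", call. = FALSE)
  }
  structure(
    list(type = "fiber", core_diameter = core_diameter, na = na,
         sigma = sigma, power = power, z_launch = z_launch,
         na_reference = na_reference),
    class = "mc_source")
}

#' Collimated pencil beam (validation source)
#'
#' Launches every photon from the axis at `z_launch` along +z.  Used by
#' the Beer-Lambert and diffusion oracles, not a physical device.
#'
#' @param z_launch launch plane, mm.
#' @return Object of class `mc_source`.
#' @export
pencil_source <- function(z_launch = 0) {
  structure(
    list(type = "pencil", z_launch = z_launch, power = NA_real_),
    class = "mc_source")
}

#' @export
print.mc_source <- function(x, ...) {
  desc <- switch(x$type,
    led_disc = sprintf("Lambertian disc, diameter %g mm at z = %g mm%s",
                       x$diameter, x$z_launch,
                       if (x$collimated) " (collimated)" else ""),
    fiber = sprintf(
      "fiber, core %g mm, NA %g (%s), sigma %g mm, %g mW at z = %g mm",
      x$core_diameter, x$na, x$na_reference, x$sigma, x$power, x$z_launch),
    pencil = sprintf("pencil beam at z = %g mm", x$z_launch))
  cat(sprintf("<mc_source> %s\n", desc))
  invisible(x)
}

#' Sample a uniform position on a disc
#'
#' Inverse-CDF sampling with uniform areal density: radius
#' `(diameter/2) * sqrt(u1)`, azimuth `2 pi u2`.
#'
#' @param diameter disc diameter, mm.
#' @param u1,u2 uniform deviates.
#' @return 2-vector (x, y) in the disc plane, mm.
#' @export
sample_disc_position <- function(diameter, u1, u2) {
  stopifnot(diameter >= 0)
  r <- (diameter / 2) * sqrt(u1)
  ph <- 2 * pi * u2
  c(r * cos(ph), r * sin(ph))
}

#' Sample a cosine-weighted (Lambertian) direction about an axis
#'
#' Polar angle with `cos(theta) = sqrt(1 - u1)` (density proportional to
#' `cos(theta)` on the hemisphere), azimuth `2 pi u2`.
#'
#' @param axis unit 3-vector the hemisphere is centred on.
#' @param u1,u2 uniform deviates.
#' @return Unit 3-vector.
#' @export
sample_lambertian_direction <- function(axis = c(0, 0, 1), u1, u2) {
  ct <- sqrt(1 - u1)
  if (all(axis == c(0, 0, 1))) {
    st <- sqrt(u1)
    ph <- 2 * pi * u2
    return(c(st * cos(ph), st * sin(ph), ct))
  }
  rotate_direction(axis, ct, 2 * pi * u2)
}

#' Sample a fiber launch position and direction
#'
#' Radial position from the truncated Gaussian (redrawing deviates until
#' the radius falls inside the core), direction uniform in solid angle
#' within the NA cone.
#'
#' @param spec a [fiber_source()].
#' @param stream a [photon_stream()] supplying the deviates.
#' @param n_launch refractive index of the launch medium (used when
#'   `na_reference = "medium"`).
#' @return List with `position` (3-vector, mm) and `direction` (unit
#'   3-vector).
#' @export
sample_fiber_launch <- function(spec, stream, n_launch = 1.34) {
  stopifnot(inherits(spec, "mc_source"), spec$type == "fiber")
  cos_max <- fiber_cos_max(spec, n_launch)
  core_r <- spec$core_diameter / 2
  repeat {
    u <- stream$unif()
    rad <- spec$sigma * sqrt(-2 * log(u))
    if (rad <= core_r) break
  }
  ph <- 2 * pi * stream$unif()
  pos <- c(rad * cos(ph), rad * sin(ph), spec$z_launch)
  ct <- 1 - stream$unif() * (1 - cos_max)
  st <- sqrt(1 - ct * ct)
  ph2 <- 2 * pi * stream$unif()
  list(position = pos,
       direction = c(st * cos(ph2), st * sin(ph2), ct))
}

fiber_cos_max <- function(spec, n_launch) {
  sin_max <- if (spec$na_reference == "medium") spec$na / n_launch else spec$na
  if (sin_max >= 1) {
    stop("numerical aperture exceeds the launch-medium index", call. = FALSE)
  }
  cos(asin(sin_max))
}

# numeric source block of the packed scene:
# c(type, z_launch, radius, sigma, cos_max, collimated)
scene_pack_source <- function(source, geometry) {
  code <- switch(source$type, led_disc = 0, fiber = 1, pencil = 2)
  radius <- switch(source$type,
                   led_disc = source$diameter / 2,
                   fiber = source$core_diameter / 2,
                   pencil = 0)
  cos_max <- 1
  sigma <- 0
  if (source$type == "fiber") {
    n_launch <- launch_index(source, geometry)
    cos_max <- fiber_cos_max(source, n_launch)
    sigma <- source$sigma
  }
  collim <- if (source$type == "led_disc") as.numeric(source$collimated) else 0
  c(code, source$z_launch, radius, sigma, cos_max, collim)
}

launch_index <- function(source, geometry) {
  m <- region_at(geometry, 0, source$z_launch)
  if (is.na(m)) {
    stop("source plane lies outside the layered geometry", call. = FALSE)
  }
  geometry$media[[m]]$refractive_index
}
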