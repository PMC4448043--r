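#' Cylindrical scoring grid specification
#'
#' Track-length tallies are accumulated on a uniform cylindrical (r, z)
#' grid with half-open bins `[lo, hi)`.  The default resolves the 30 um
#' LED with 3 radial bins while keeping well under 1e6 voxels, and spans
#' the sapphire/saline layers (z < 0) as well as 2 mm of tissue.
#'
#' @param dr radial bin width, mm.
#' @param dz axial bin width, mm.
#' @param r_max outer radius of the grid, mm (multiple of `dr`).
#' @param z_min,z_max axial extent, mm (multiples of `dz` apart).
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(dr = 0.01, dz = 0.01, r_max = 1.5,
                      z_min = -0.4, z_max = 2.0) {
  if (dr <= 0 || dz <= 0) stop("bin widths must be > 0", call. = FALSE)
  if (r_max <= 0 || z_max <= z_min) {
    stop("invalid grid extent", call. = FALSE)
  }
  nr <- round(r_max / dr)
  nz <- round((z_max - z_min) / dz)
  if (abs(nr * dr - r_max) > 1e-9 || abs(z_min + nz * dz - z_max) > 1e-9) {
    stop("grid extents must be integer multiples of the bin widths",
         call. = FALSE)
  }
  structure(list(dr = dr, dz = dz, r_max = r_max, z_min = z_min,
                 z_max = z_max, nr = as.integer(nr), nz = as.integer(nz)),
            class = "grid_spec")
}

#' Assemble a validated simulation run configuration
#'
#' @param geometry a [layered_geometry()].
#' @param source an `mc_source` ([led_disc_source()], [fiber_source()] or
#'   [pencil_source()]).
#' @param n_photons number of photons to launch, `>= 0`.
#' @param seed run seed (integer-valued); every photon derives its own
#'   reproducible random substream from it.
#' @param grid a [grid_spec()].
#' @param roulette_threshold weight below which Russian roulette is
#'   played.
#' @param roulette_survival survival probability of the roulette (the
#'   survivor's weight is boosted by its reciprocal, keeping termination
#'   unbiased).
#' @param strict_termination if `TRUE`, photons below the threshold are
#'   simply terminated and their weight tallied, reproducing plain
#'   threshold termination instead of roulette.
#' @param step_cap maximum steps per photon; capped photons are tallied,
#'   never silently dropped.
#' @param thresholds fluence-rate thresholds (mW/mm^2) used by the
#'   analysis helpers.
#' @param calibration a [calibration_table()] mapping drive current to
#'   interface irradiance.
#' @return Object of class `run_config`.
#' @examples
#' cfg <- run_config(mled_probe_geometry(), led_disc_source(),
#'                   n_photons = 1000, seed = 1)
#' @export
run_config <- function(geometry, source, n_photons, seed = 1L,
                       grid = grid_spec(),
                       roulette_threshold = 1e-4,
                       roulette_survival = 0.1,
                       strict_termination = FALSE,
                       step_cap = 1e5,
                       thresholds = 1,
                       calibration = default_calibration()) {
  problems <- character(0)
  if (!inherits(geometry, "layered_geometry")) {
    problems <- c(problems, "'geometry' must be a layered_geometry")
  }
  if (!inherits(source, "mc_source")) {
    problems <- c(problems, "'source' must be an mc_source")
  }
  if (!is.numeric(n_photons) || length(n_photons) != 1L || n_photons < 0 ||
      n_photons != floor(n_photons)) {
    problems <- c(problems, "'n_photons' must be a non-negative integer")
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed)) {
    problems <- c(problems, "'seed' must be an integer")
  }
  if (!inherits(grid, "grid_spec")) {
    problems <- c(problems, "'grid' must be a grid_spec")
  }
  if (!is.numeric(roulette_threshold) || roulette_threshold <= 0 ||
      roulette_threshold >= 1) {
    problems <- c(problems, "'roulette_threshold' must lie in (0, 1)")
  }
  if (!is.numeric(roulette_survival) || roulette_survival <= 0 ||
      roulette_survival >= 1) {
    problems <- c(problems, "'roulette_survival' must lie in (0, 1)")
  }
  if (!is.numeric(step_cap) || step_cap < 1) {
    problems <- c(problems, "'step_cap' must be >= 1")
  }
  if (!is.numeric(thresholds) || any(thresholds <= 0)) {
    problems <- c(problems, "'thresholds' must all be > 0")
  }
  if (!inherits(calibration, "calibration_table")) {
    problems <- c(problems, "'calibration' must be a calibration_table")
  }
  if (length(problems)) {
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  if (inherits(geometry, "layered_geometry") &&
      inherits(source, "mc_source")) {
    if (is.na(region_at(geometry, 0, source$z_launch))) {
      stop("invalid run configuration:\n  - source plane (z_launch) lies ",
           "outside the layered geometry", call. = FALSE)
    }
  }
  structure(
    list(geometry = geometry, source = source,
         n_photons = as.double(n_photons), seed = as.double(seed),
         grid = grid, roulette_threshold = roulette_threshold,
         roulette_survival = roulette_survival,
         strict_termination = isTRUE(strict_termination),
         step_cap = as.double(step_cap), thresholds = thresholds,
         calibration = calibration),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  photons: %g   seed: %g\n", x$n_photons, x$seed))
  print(x$source)
  print(x$geometry)
  cat(sprintf("  grid: dr = dz = %g mm, r <= %g mm, z in [%g, %g] mm\n",
              x$grid$dr, x$grid$r_max, x$grid$z_min, x$grid$z_max))
  invisible(x)
}

# full packed scene consumed by both engines
scene_pack <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- scene_pack_geometry(config$geometry)
  sc$source <- scene_pack_source(config$source, config$geometry)
  g <- config$grid
  sc$grid <- c(g$z_min, g$dz, g$nz, g$dr, g$nr)
  sc$run <- list(n_photons = config$n_photons, seed = config$seed,
                 roulette_threshold = config$roulette_threshold,
                 roulette_survival = config$roulette_survival,
                 strict_termination = config$strict_termination,
                 step_cap = config$step_cap)
  sc
}

#' Run the Monte Carlo simulation
#'
#' Launches `n_photons` photons from the configured source, each on its
#' own reproducible random substream, propagates them through the layered
#' geometry and accumulates track-length tallies on the cylindrical grid.
#' The result is invariant to the order in which photons are executed.
#'
#' @param config a [run_config()].
#' @param record_events if `TRUE`, every traversed segment is returned as
#'   a row of an event matrix (intended for small photon counts).
#' @param verbose print a one-line run summary.
#' @return Object of class `mc_result`: a list with `grid` (a
#'   `fluence_grid`), `tallies` (an `mc_tallies`), the `config`, `elapsed`
#'   seconds and, if requested, `events`.
#' @examples
#' cfg <- run_config(mled_probe_geometry(), led_disc_source(),
#'                   n_photons = 200, seed = 1)
#' res <- run_simulation(cfg)
#' res$tallies
#' @export
run_simulation <- function(config, record_events = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  scene <- scene_pack(config)
  t0 <- proc.time()[["elapsed"]]
  out <- .mc_run_cpp(scene, record_events)
  elapsed <- proc.time()[["elapsed"]] - t0
  tl <- out$tallies
  names(tl$absorbed) <- scene$media_names
  tallies <- structure(tl, class = "mc_tallies")
  g <- config$grid
  grid <- fluence_grid(
    r_edges = (0:g$nr) * g$dr,
    z_edges = g$z_min + (0:g$nz) * g$dz,
    values = out$values,
    n_photons = config$n_photons,
    seed = config$seed,
    source_power = config$source$power,
    geometry = config$geometry)
  grid$outside_track <- tl$outside_grid_track
  res <- structure(
    list(grid = grid, tallies = tallies, config = config,
         elapsed = elapsed),
    class = "mc_result")
  if (record_events) res$events <- out$events
  if (verbose) print(res)
  res
}

#' @export
print.mc_result <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(
    "<mc_result> %g photons in %.1f s | absorbed %.4f, escaped %.4f, back-plane %.4f, edge %.4f, roulette %.2e, capped %g | energy residual %.2e\n",
    t$launched, x$elapsed, sum(t$absorbed), t$escaped_domain,
    t$back_plane_loss, t$edge_loss, t$roulette_net, t$n_capped,
    energy_residual(t)))
  invisible(x)
}

#' @export
print.mc_tallies <- function(x, ...) {
  cat("<mc_tallies>\n")
  cat(sprintf("  launched:        %g\n", x$launched))
  for (m in names(x$absorbed)) {
    cat(sprintf("  absorbed[%s]: %g\n", m, x$absorbed[[m]]))
  }
  cat(sprintf("  escaped_domain:  %g\n", x$escaped_domain))
  cat(sprintf("  back_plane_loss: %g\n", x$back_plane_loss))
  cat(sprintf("  edge_loss:       %g\n", x$edge_loss))
  cat(sprintf("  roulette_net:    %g\n", x$roulette_net))
  cat(sprintf("  capped:          %g (n = %g)\n", x$capped, x$n_capped))
  cat(sprintf("  energy residual: %.3e\n", energy_residual(x)))
  invisible(x)
}

#' Energy-balance residual of a run
#'
#' `launched - (sum(absorbed) + escaped + back-plane + edge + capped)
#' - roulette_net`; every weight change in the engine is tallied, so the
#' residual is zero up to floating-point rounding.
#'
#' @param tallies an `mc_tallies`.
#' @return Signed residual in launched-weight units.
#' @export
energy_residual <- function(tallies) {
  tallies$launched -
    (sum(tallies$absorbed) + tallies$escaped_domain +
       tallies$back_plane_loss + tallies$edge_loss + tallies$capped) -
    tallies$roulette_net
}

#' Russian roulette for low-weight photons
#'
#' Below the threshold, a photon survives with probability `survival_p`
#' and its weight is boosted by `1/survival_p`, otherwise it is
#' terminated; the expected returned weight equals the input, so the
#' termination is unbiased (unlike plain threshold termination, which
#' destroys weight).
#'
#' @param weight photon weight(s).
#' @param threshold weight below which the roulette is played.
#' @param survival_p survival probability, in (0, 1).
#' @param u uniform deviate(s).
#' @return Updated weight(s); 0 means terminated.
#' @examples
#' roulette(0.5, 1e-4, 0.1, 0.99)   # above threshold: unchanged
#' roulette(5e-5, 1e-4, 0.1, 0.05)  # survivor: boosted to 5e-4
#' @export
roulette <- function(weight, threshold, survival_p, u) {
  if (survival_p <= 0 || survival_p >= 1) {
    stop("'survival_p' must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- max(length(weight), length(u))
  weight <- rep_len(weight, n)
  u <- rep_len(u, n)
  out <- weight
  play <- weight < threshold
  out[play & u < survival_p] <- weight[play & u < survival_p] / survival_p
  out[play & u >= survival_p] <- 0
  out
}

# ------------------------------------------------- scalar reference engine

#' Construct a photon state
#'
#' @param position 3-vector, mm.
#' @param direction unit 3-vector.
#' @param weight statistical weight in (0, 1].
#' @param medium medium name the photon is in.
#' @param alive logical flag.
#' @return Object of class `photon_state`.
#' @export
photon_state <- function(position, direction, weight = 1,
                         medium = NA_character_, alive = TRUE) {
  stopifnot(length(position) == 3L, length(direction) == 3L)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("'direction' must be a unit vector", call. = FALSE)
  }
  if (weight <= 0 || weight > 1) {
    stop("'weight' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(position = position, direction = direction,
                 weight = weight, medium = medium, alive = alive),
            class = "photon_state")
}

# rotation used by the reference engine: same arithmetic as the compiled
# kernel, with the transcendental primitives taken from the C library so
# the two engines agree bit-for-bit
ref_rotate <- function(dx, dy, dz, ct, phi) {
  st2 <- 1 - ct * ct
  if (st2 < 0) st2 <- 0
  st <- sqrt(st2)
  cs <- .libm_sincos(phi)
  cp <- cs[1]; sp <- cs[2]
  if (abs(dz) > 1 - 1e-9) {
    sgn <- if (dz >= 0) 1 else -1
    nx <- st * cp
    ny <- sgn * st * sp
    nz <- sgn * ct
  } else {
    tmp <- sqrt(1 - dz * dz)
    nx <- st * (dx * dz * cp - dy * sp) / tmp + dx * ct
    ny <- st * (dy * dz * cp + dx * sp) / tmp + dy * ct
    nz <- -st * cp * tmp + dz * ct
  }
  nrm <- sqrt(nx * nx + ny * ny + nz * nz)
  c(nx / nrm, ny / nrm, nz / nrm)
}

# internal scalar state used by the reference engine
ref_launch <- function(scene, stream, photon_index) {
  src <- scene$source
  type <- src[1]
  z <- src[2]
  if (type == 0) {                        # Lambertian / collimated disc
    u1 <- stream$unif(); u2 <- stream$unif()
    rr <- src[3] * sqrt(u1)
    ph <- 2 * pi * u2
    cs <- .libm_sincos(ph)
    x <- rr * cs[1]; y <- rr * cs[2]
    if (src[6] != 0) {
      dx <- 0; dy <- 0; dz <- 1
    } else {
      u3 <- stream$unif(); u4 <- stream$unif()
      ct <- sqrt(1 - u3)
      st <- sqrt(u3)
      ph2 <- 2 * pi * u4
      cs2 <- .libm_sincos(ph2)
      dx <- st * cs2[1]; dy <- st * cs2[2]; dz <- ct
    }
  } else if (type == 1) {                 # fiber
    repeat {
      u <- stream$unif()
      rad <- src[4] * sqrt(-2 * .libm_log(u))
      if (rad <= src[3]) break
    }
    u2 <- stream$unif()
    ph <- 2 * pi * u2
    cs <- .libm_sincos(ph)
    x <- rad * cs[1]; y <- rad * cs[2]
    u3 <- stream$unif(); u4 <- stream$unif()
    ct <- 1 - u3 * (1 - src[5])
    st <- sqrt(1 - ct * ct)
    ph2 <- 2 * pi * u4
    cs2 <- .libm_sincos(ph2)
    dx <- st * cs2[1]; dy <- st * cs2[2]; dz <- ct
  } else {                                # pencil
    x <- 0; y <- 0; dx <- 0; dy <- 0; dz <- 1
  }
  lay <- scene$layers
  li <- NA_integer_
  for (i in seq_len(nrow(lay))) {
    if (z >= lay[i, 1] && z < lay[i, 2]) { li <- i; break }
  }
  if (is.na(li)) stop("source plane lies outside the layered geometry")
  inner <- sqrt(x * x + y * y) < lay[li, 4]
  mi <- if (inner) lay[li, 3] else lay[li, 5]
  list(x = x, y = y, z = z, dx = dx, dy = dy, dz = dz, w = 1,
       li = li, inner = inner, mi = as.integer(mi),
       alive = TRUE, steps = 0L, fate = NA_character_,
       photon = photon_index)
}

# one hop of the reference engine; returns state + event row + tally deltas
ref_step <- function(st, scene, stream) {
  med <- scene$media
  lay <- scene$layers
  run <- scene$run
  deltas <- list()
  event <- NULL

  st$steps <- st$steps + 1L
  if (st$steps > run$step_cap) {
    st$alive <- FALSE; st$fate <- "capped"
    deltas <- c(deltas, list(list(kind = "capped", amount = st$w)))
    return(list(state = st, event = event, deltas = deltas))
  }
  mua <- med[st$mi, 2]; mus <- med[st$mi, 3]
  mut <- mua + mus
  s <- if (mut > 0) -.libm_log(stream$unif()) / mut else Inf

  bd <- scene_dist_boundary(scene, st$li, st$inner,
                            c(st$x, st$y, st$z), c(st$dx, st$dy, st$dz))

  if (s < bd$distance) {
    nx <- st$x + s * st$dx; ny <- st$y + s * st$dy; nz <- st$z + s * st$dz
    event <- c(st$photon, st$x, st$y, st$z, nx, ny, nz, st$w, st$mi)
    st$x <- nx; st$y <- ny; st$z <- nz
    neww <- st$w * (mus / mut)
    deltas <- c(deltas, list(list(kind = "absorbed", medium = st$mi,
                                  amount = st$w - neww)))
    st$w <- neww
    if (st$w <= 0) {
      st$alive <- FALSE; st$fate <- "absorbed"
      return(list(state = st, event = event, deltas = deltas))
    }
    ct <- sample_hg_cos(med[st$mi, 4], stream$unif())
    d <- ref_rotate(st$dx, st$dy, st$dz, ct, 2 * pi * stream$unif())
    st$dx <- d[1]; st$dy <- d[2]; st$dz <- d[3]
    if (st$w < run$roulette_threshold) {
      if (run$strict_termination) {
        deltas <- c(deltas, list(list(kind = "roulette", amount = st$w)))
        st$alive <- FALSE; st$fate <- "roulette"
      } else {
        ur <- stream$unif()
        if (ur < run$roulette_survival) {
          nw <- st$w / run$roulette_survival
          deltas <- c(deltas, list(list(kind = "roulette",
                                        amount = st$w - nw)))
          st$w <- nw
        } else {
          deltas <- c(deltas, list(list(kind = "roulette", amount = st$w)))
          st$alive <- FALSE; st$fate <- "roulette"
        }
      }
    }
    return(list(state = st, event = event, deltas = deltas))
  }

  # ---- boundary hop
  t <- bd$distance
  nx <- st$x + t * st$dx; ny <- st$y + t * st$dy; nz <- st$z + t * st$dz
  event <- c(st$photon, st$x, st$y, st$z, nx, ny, nz, st$w, st$mi)
  st$x <- nx; st$y <- ny; st$z <- nz

  if (bd$surface == "edge") {
    deltas <- c(deltas, list(list(kind = "edge_loss", amount = st$w)))
    st$alive <- FALSE; st$fate <- "edge_loss"
  } else if (bd$surface %in% c("z_up", "z_down")) {
    zp <- if (bd$surface == "z_up") lay[st$li, 1] else lay[st$li, 2]
    st$z <- zp
    lj <- if (bd$surface == "z_up") st$li - 1L else st$li + 1L
    if (lj < 1L) {
      deltas <- c(deltas, list(list(kind = "back_plane", amount = st$w)))
      st$alive <- FALSE; st$fate <- "back_plane_loss"
    } else if (lj > nrow(lay)) {
      deltas <- c(deltas, list(list(kind = "escaped", amount = st$w)))
      st$alive <- FALSE; st$fate <- "escaped_domain"
    } else {
      r_hit <- sqrt(st$x * st$x + st$y * st$y)
      blk <- if (bd$surface == "z_up") {
        lay[st$li, 6] != 0 && st$inner
      } else {
        lay[lj, 6] != 0 && r_hit < lay[lj, 4]
      }
      if (blk) {
        refl <- scene$backplane_reflectivity
        dead <- TRUE
        if (refl > 0) {
          u <- stream$unif()
          if (u < refl) {
            st$dz <- -st$dz
            dead <- FALSE
          }
        }
        if (dead) {
          deltas <- c(deltas, list(list(kind = "back_plane", amount = st$w)))
          st$alive <- FALSE; st$fate <- "back_plane_loss"
        }
      } else {
        inner_j <- r_hit < lay[lj, 4]
        mj <- as.integer(if (inner_j) lay[lj, 3] else lay[lj, 5])
        n1 <- med[st$mi, 1]; n2 <- med[mj, 1]
        cosi <- abs(st$dz)
        R <- fresnel_unpolarized(n1, n2, cosi)
        u <- stream$unif()
        if (u < R) {
          st$dz <- -st$dz
        } else {
          nzn <- if (st$dz > 0) -1 else 1
          eta <- n1 / n2
          sint2 <- eta * eta * (1 - cosi * cosi)
          cost <- sqrt(max(0, 1 - sint2))
          tx <- eta * st$dx
          ty <- eta * st$dy
          tz <- eta * st$dz + (eta * cosi - cost) * nzn
          nrm <- sqrt(tx * tx + ty * ty + tz * tz)
          st$dx <- tx / nrm; st$dy <- ty / nrm; st$dz <- tz / nrm
          st$li <- lj; st$inner <- inner_j; st$mi <- mj
        }
      }
    }
  } else {                                # lateral cylinder
    Rc <- lay[st$li, 4]
    r_hit <- sqrt(st$x * st$x + st$y * st$y)
    if (r_hit > 0) {
      f <- Rc / r_hit
      st$x <- st$x * f; st$y <- st$y * f
    }
    rx <- st$x / Rc; ry <- st$y / Rc
    mj <- as.integer(if (st$inner) lay[st$li, 5] else lay[st$li, 3])
    n1 <- med[st$mi, 1]; n2 <- med[mj, 1]
    ddotn <- st$dx * rx + st$dy * ry
    cosi <- abs(ddotn)
    R <- fresnel_unpolarized(n1, n2, cosi)
    u <- stream$unif()
    if (u < R) {
      st$dx <- st$dx - 2 * ddotn * rx
      st$dy <- st$dy - 2 * ddotn * ry
    } else {
      sgn <- if (ddotn > 0) -1 else 1
      nxn <- sgn * rx; nyn <- sgn * ry
      eta <- n1 / n2
      sint2 <- eta * eta * (1 - cosi * cosi)
      cost <- sqrt(max(0, 1 - sint2))
      fac <- eta * cosi - cost
      tx <- eta * st$dx + fac * nxn
      ty <- eta * st$dy + fac * nyn
      tz <- eta * st$dz
      nrm <- sqrt(tx * tx + ty * ty + tz * tz)
      st$dx <- tx / nrm; st$dy <- ty / nrm; st$dz <- tz / nrm
      st$inner <- !st$inner; st$mi <- mj
    }
  }
  list(state = st, event = event, deltas = deltas)
}

#' Launch one photon of the scalar reference engine
#'
#' @param config a [run_config()].
#' @param photon_index 1-based photon index (selects the random
#'   substream).
#' @param stream optionally, an already-positioned [photon_stream()].
#' @return List with the internal scalar state and the stream.
#' @export
launch_photon <- function(config, photon_index = 1, stream = NULL) {
  scene <- if (inherits(config, "run_config")) scene_pack(config) else config
  if (is.null(stream)) {
    stream <- photon_stream(scene$run$seed, photon_index)
  }
  list(state = ref_launch(scene, stream, photon_index), stream = stream,
       scene = scene)
}

#' Advance a reference-engine photon by one hop
#'
#' One hop either moves the photon to its sampled interaction site
#' (absorb + scatter + possibly roulette) or to the nearest boundary of
#' its region (resolved with one deviate against the Fresnel
#' reflectance).
#'
#' @param photon the list returned by [launch_photon()] or a previous
#'   `step_photon()` call.
#' @return The same structure with updated `state`, plus `event` (the
#'   traversed segment) and `deltas` (tally contributions).
#' @export
step_photon <- function(photon) {
  out <- ref_step(photon$state, photon$scene, photon$stream)
  list(state = out$state, stream = photon$stream, scene = photon$scene,
       event = out$event, deltas = out$deltas)
}

#' Propagate one photon of the scalar reference engine to termination
#'
#' @inheritParams launch_photon
#' @return List with `events` (matrix of traversed segments), `fate`, and
#'   `tallies` (named contributions).
#' @export
propagate_photon <- function(config, photon_index = 1, stream = NULL) {
  ph <- launch_photon(config, photon_index, stream)
  scene <- ph$scene
  st <- ph$state
  events <- vector("list", 64L)
  nev <- 0L
  tall <- list(absorbed = numeric(nrow(scene$media)),
               escaped_domain = 0, back_plane_loss = 0, edge_loss = 0,
               roulette_net = 0, capped = 0, n_capped = 0)
  while (st$alive) {
    out <- ref_step(st, scene, ph$stream)
    st <- out$state
    if (!is.null(out$event)) {
      nev <- nev + 1L
      if (nev > length(events)) events <- c(events, vector("list", nev))
      events[[nev]] <- out$event
    }
    for (d in out$deltas) {
      kind <- d[["kind"]]
      amount <- as.numeric(d[["amount"]])
      if (kind == "absorbed") {
        mi <- as.integer(d[["medium"]])
        tall$absorbed[mi] <- tall$absorbed[mi] + amount
      } else if (kind == "escaped") {
        tall$escaped_domain <- tall$escaped_domain + amount
      } else if (kind == "back_plane") {
        tall$back_plane_loss <- tall$back_plane_loss + amount
      } else if (kind == "edge_loss") {
        tall$edge_loss <- tall$edge_loss + amount
      } else if (kind == "roulette") {
        tall$roulette_net <- tall$roulette_net + amount
      } else if (kind == "capped") {
        tall$capped <- tall$capped + amount
        tall$n_capped <- tall$n_capped + 1
      }
    }
  }
  ev <- if (nev > 0) {
    m <- do.call(rbind, events[seq_len(nev)])
    colnames(m) <- c("photon", "x0", "y0", "z0", "x1", "y1", "z1",
                     "weight", "medium")
    m
  } else {
    matrix(numeric(0), 0, 9,
           dimnames = list(NULL, c("photon", "x0", "y0", "z0", "x1", "y1",
                                   "z1", "weight", "medium")))
  }
  list(events = ev, fate = st$fate, tallies = tall)
}

#' Run the scalar reference engine
#'
#' A deliberately naive, one-photon-at-a-time R implementation of the
#' transport loop.  Given the same configuration and seed it consumes
#' exactly the same random deviates as the compiled engine and must
#' reproduce its event stream and tallies bit-for-bit; the equivalence is
#' checked by [reference_engine_equivalence()].
#'
#' @param config a [run_config()].
#' @param n_photons number of photons (defaults to the config's; keep
#'   small, this engine is slow by design).
#' @return List with `tallies` (same layout as the compiled engine's) and
#'   `events`.
#' @export
run_simulation_reference <- function(config, n_photons = NULL) {
  stopifnot(inherits(config, "run_config"))
  scene <- scene_pack(config)
  n <- n_photons %||% config$n_photons
  tall <- list(launched = as.double(n),
               absorbed = numeric(nrow(scene$media)),
               escaped_domain = 0, back_plane_loss = 0, edge_loss = 0,
               roulette_net = 0, capped = 0, n_capped = 0)
  ev_list <- vector("list", n)
  for (p in seq_len(n)) {
    one <- propagate_photon(scene, photon_index = p,
                            stream = photon_stream(scene$run$seed, p))
    ev_list[[p]] <- one$events
    tall$absorbed <- tall$absorbed + one$tallies$absorbed
    tall$escaped_domain <- tall$escaped_domain + one$tallies$escaped_domain
    tall$back_plane_loss <- tall$back_plane_loss +
      one$tallies$back_plane_loss
    tall$edge_loss <- tall$edge_loss + one$tallies$edge_loss
    tall$roulette_net <- tall$roulette_net + one$tallies$roulette_net
    tall$capped <- tall$capped + one$tallies$capped
    tall$n_capped <- tall$n_capped + one$tallies$n_capped
  }
  names(tall$absorbed) <- scene$media_names
  events <- do.call(rbind, ev_list)
  list(tallies = structure(tall, class = "mc_tallies"), events = events)
}
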