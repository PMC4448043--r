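#' Cylindrical track-length tally grid
#'
#' Holds raw track-length sums (mm times launched-weight units) on a
#' uniform cylindrical (r, z) grid.  The fluence rate in a voxel is
#' `values / (voxel volume * n_photons) * source_power` (mW/mm^2), with
#' voxel volume `pi (r_hi^2 - r_lo^2) dz`: the track-length estimator of
#' fluence.
#'
#' @param r_edges strictly increasing radial bin edges starting at 0, mm;
#'   must be uniformly spaced.
#' @param z_edges strictly increasing axial bin edges, mm; uniform.
#' @param values matrix of raw tallies (`length(r_edges) - 1` rows,
#'   `length(z_edges) - 1` columns); defaults to zeros.
#' @param n_photons photons launched into the tallies.
#' @param seed run seed recorded in the metadata.
#' @param source_power total source power, mW (`NA` when the power is set
#'   later by calibration).
#' @param geometry the [layered_geometry()] the tallies were accumulated
#'   in (used to identify tissue voxels); may be `NULL` for synthetic
#'   grids, in which case every voxel counts as tissue.
#' @return Object of class `fluence_grid`.
#' @export
fluence_grid <- function(r_edges, z_edges, values = NULL, n_photons = 0,
                         seed = NA_real_, source_power = NA_real_,
                         geometry = NULL) {
  stopifnot(is.numeric(r_edges), is.numeric(z_edges),
            length(r_edges) >= 2L, length(z_edges) >= 2L)
  if (r_edges[1] != 0 || any(diff(r_edges) <= 0) || any(diff(z_edges) <= 0)) {
    stop("edges must be strictly increasing and r_edges must start at 0",
         call. = FALSE)
  }
  dr <- diff(r_edges); dz <- diff(z_edges)
  if (max(abs(dr - dr[1])) > 1e-9 * dr[1] ||
      max(abs(dz - dz[1])) > 1e-9 * dz[1]) {
    stop("grid bins must be uniform", call. = FALSE)
  }
  nr <- length(r_edges) - 1L
  nz <- length(z_edges) - 1L
  if (is.null(values)) values <- matrix(0, nr, nz)
  stopifnot(is.matrix(values), nrow(values) == nr, ncol(values) == nz)
  if (any(values < 0)) stop("tally values must be >= 0", call. = FALSE)
  structure(
    list(r_edges = r_edges, z_edges = z_edges, values = values,
         n_photons = n_photons, seed = seed, source_power = source_power,
         geometry = geometry, outside_track = 0),
    class = "fluence_grid")
}

#' @export
print.fluence_grid <- function(x, ...) {
  cat(sprintf(
    "<fluence_grid> %d x %d (r x z) voxels, r <= %g mm, z in [%g, %g] mm, %g photons\n",
    nrow(x$values), ncol(x$values), max(x$r_edges), min(x$z_edges),
    max(x$z_edges), x$n_photons))
  invisible(x)
}

voxel_volumes <- function(grid_or_map) {
  vr <- pi * diff(grid_or_map$r_edges^2)
  vz <- diff(grid_or_map$z_edges)
  outer(vr, vz)
}

#' Deposit one track segment into a fluence grid
#'
#' The segment is split exactly at every voxel boundary it crosses (z
#' planes and radial shells); each voxel receives the photon weight times
#' the sub-segment length, so the total deposited equals weight times the
#' in-grid length to rounding.  Portions outside the grid are added to
#' the grid's `outside_track` tally.  A zero-length segment is a no-op.
#'
#' @param grid a [fluence_grid()].
#' @param start,end segment endpoints, 3-vectors (x, y, z) in mm.
#' @param weight photon weight carried along the segment.
#' @return The updated grid.
#' @examples
#' g <- fluence_grid(r_edges = c(0, 0.1), z_edges = c(0, 0.02, 0.04))
#' g <- deposit_track(g, c(0, 0, 0.0), c(0, 0, 0.02), 1)
#' g$values
#' @export
deposit_track <- function(grid, start, end, weight) {
  stopifnot(inherits(grid, "fluence_grid"),
            length(start) == 3L, length(end) == 3L)
  dd <- end - start
  L <- sqrt(sum(dd^2))
  if (L <= 0 || weight <= 0) return(grid)

  re <- grid$r_edges; ze <- grid$z_edges
  dr <- re[2] - re[1]; dz <- ze[2] - ze[1]
  nr <- length(re) - 1L; nz <- length(ze) - 1L
  z0g <- ze[1]
  x0 <- start[1]; y0 <- start[2]; z0 <- start[3]
  ddx <- dd[1]; ddy <- dd[2]; ddz <- dd[3]

  ta <- 0; tb <- 1
  zhi <- z0g + nz * dz
  if (ddz != 0) {
    tl <- (z0g - z0) / ddz; th <- (zhi - z0) / ddz
    ta <- max(ta, min(tl, th)); tb <- min(tb, max(tl, th))
  } else if (z0 < z0g || z0 >= zhi) {
    grid$outside_track <- grid$outside_track + weight * L
    return(grid)
  }
  a <- ddx * ddx + ddy * ddy
  b <- 2 * (x0 * ddx + y0 * ddy)
  cc <- x0 * x0 + y0 * y0
  Rg <- nr * dr
  if (a > 0) {
    disc <- b * b - 4 * a * (cc - Rg * Rg)
    if (disc <= 0) {
      if (cc >= Rg * Rg) {
        grid$outside_track <- grid$outside_track + weight * L
        return(grid)
      }
    } else {
      s <- sqrt(disc)
      ta <- max(ta, (-b - s) / (2 * a))
      tb <- min(tb, (-b + s) / (2 * a))
    }
  } else if (cc >= Rg * Rg) {
    grid$outside_track <- grid$outside_track + weight * L
    return(grid)
  }
  if (ta >= tb) {
    grid$outside_track <- grid$outside_track + weight * L
    return(grid)
  }
  grid$outside_track <- grid$outside_track + weight * L * (1 - (tb - ta))

  ts <- c(ta, tb)
  if (ddz != 0) {
    za <- z0 + ta * ddz; zb <- z0 + tb * ddz
    zmn <- min(za, zb); zmx <- max(za, zb)
    jlo <- max(0L, floor((zmn - z0g) / dz) + 1)
    jhi <- min(nz, floor((zmx - z0g) / dz))
    if (jhi >= jlo) {
      planes <- z0g + (jlo:jhi) * dz
      planes <- planes[planes > zmn & planes < zmx]
      ts <- c(ts, (planes - z0) / ddz)
    }
  }
  if (a > 0) {
    r2_at <- function(t) a * t * t + b * t + cc
    shells <- function(p, q, increasing) {
      rp <- sqrt(max(0, r2_at(p))); rq <- sqrt(max(0, r2_at(q)))
      rlo <- min(rp, rq); rhi <- max(rp, rq)
      klo <- max(1L, floor(rlo / dr) + 1)
      khi <- floor(rhi / dr)
      out <- numeric(0)
      if (khi >= klo) {
        for (k in klo:khi) {
          redge <- k * dr
          d2 <- b * b - 4 * a * (cc - redge * redge)
          if (d2 <= 0) next
          s <- sqrt(d2)
          t <- if (increasing) (-b + s) / (2 * a) else (-b - s) / (2 * a)
          if (t > p && t < q) out <- c(out, t)
        }
      }
      out
    }
    tstar <- -b / (2 * a)
    ts <- c(ts,
            if (tstar > ta && tstar < tb) {
              c(shells(ta, tstar, FALSE), shells(tstar, tb, TRUE))
            } else if (tstar <= ta) {
              shells(ta, tb, TRUE)
            } else {
              shells(ta, tb, FALSE)
            })
  }
  ts <- sort(ts)
  for (i in seq_len(length(ts) - 1L)) {
    t0 <- ts[i]; t1 <- ts[i + 1L]
    dt <- t1 - t0
    if (dt <= 0) next
    tm <- 0.5 * (t0 + t1)
    xm <- x0 + tm * ddx; ym <- y0 + tm * ddy; zm <- z0 + tm * ddz
    rm <- sqrt(xm * xm + ym * ym)
    ir <- floor(rm / dr) + 1
    iz <- floor((zm - z0g) / dz) + 1
    if (ir >= 1 && ir <= nr && iz >= 1 && iz <= nz) {
      grid$values[ir, iz] <- grid$values[ir, iz] + weight * dt * L
    } else {
      grid$outside_track <- grid$outside_track + weight * dt * L
    }
  }
  grid
}

#' Convert raw tallies to a fluence-rate map
#'
#' Applies the track-length estimator normalization: fluence rate per
#' voxel equals the raw track-length sum divided by voxel volume and
#' photon count, scaled by the total source power.
#'
#' @param grid a [fluence_grid()] with `n_photons > 0`.
#' @param power total source power, mW; defaults to the power recorded in
#'   the grid (e.g. the fiber's 1.1 mW).  For micro-LED runs the power is
#'   usually derived from the drive current via
#'   [scale_power_to_interface()].
#' @return Object of class `fluence_map` with per-voxel fluence rate in
#'   mW/mm^2.
#' @export
fluence_map <- function(grid, power = NULL) {
  stopifnot(inherits(grid, "fluence_grid"))
  if (grid$n_photons <= 0) {
    stop("fluence requires n_photons > 0", call. = FALSE)
  }
  power <- power %||% grid$source_power
  if (is.null(power) || is.na(power)) {
    stop("source power is not set; pass 'power' or use ",
         "scale_power_to_interface()", call. = FALSE)
  }
  vol <- voxel_volumes(grid)
  vals <- grid$values / (vol * grid$n_photons) * power
  structure(
    list(values = vals, r_edges = grid$r_edges, z_edges = grid$z_edges,
         r_centers = (grid$r_edges[-1] + grid$r_edges[-length(grid$r_edges)]) / 2,
         z_centers = (grid$z_edges[-1] + grid$z_edges[-length(grid$z_edges)]) / 2,
         power = power, n_photons = grid$n_photons,
         geometry = grid$geometry),
    class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf(
    "<fluence_map> %d x %d voxels, source power %g mW, peak %.3g mW/mm^2\n",
    nrow(x$values), ncol(x$values), x$power, max(x$values)))
  invisible(x)
}

# logical matrix marking voxels whose centre lies in tissue
tissue_voxels <- function(map) {
  if (is.null(map$geometry)) {
    return(matrix(TRUE, nrow(map$values), ncol(map$values)))
  }
  geo <- map$geometry
  med <- vapply(map$z_centers, function(z) {
    region_at(geo, map$r_centers, rep(z, length(map$r_centers)))
  }, character(length(map$r_centers)))
  med == geo$tissue_medium & !is.na(med)
}

#' Source power that reproduces a target interface irradiance
#'
#' Micro-LED drive currents are specified through the irradiance they
#' produce at the probe/tissue interface.  This returns the total source
#' power (mW) that makes the peak fluence rate in the first tissue z-bin
#' equal the target irradiance, so a map can be scaled to a given drive
#' current via the calibration table.
#'
#' @param grid a [fluence_grid()] from a run.
#' @param irradiance target peak interface irradiance, mW/mm^2.
#' @return Power in mW.
#' @export
scale_power_to_interface <- function(grid, irradiance) {
  stopifnot(inherits(grid, "fluence_grid"), irradiance > 0)
  raw <- fluence_map(grid, power = 1)
  iz <- which(raw$z_centers > 0)[1]
  if (is.na(iz)) stop("grid has no tissue-side (z > 0) bins", call. = FALSE)
  peak <- max(raw$values[, iz])
  if (peak <= 0) stop("no fluence reached the first tissue bin", call. = FALSE)
  irradiance / peak
}

#' Tissue volume illuminated above a fluence threshold
#'
#' Sums the volumes of tissue voxels (voxel centre in tissue) whose
#' fluence rate is at or above the threshold; the usual threshold is the
#' nominal ChR2 activation fluence of 1 mW/mm^2.
#'
#' @param map a [fluence_map()].
#' @param threshold fluence threshold, mW/mm^2, `> 0`.
#' @return Volume in mm^3.
#' @export
activation_volume <- function(map, threshold) {
  stopifnot(inherits(map, "fluence_map"), threshold > 0)
  vol <- voxel_volumes(map)
  sum(vol[tissue_voxels(map) & map$values >= threshold])
}

#' Maximum illuminated tissue depth
#'
#' The largest z bin centre among tissue voxels whose fluence rate
#' reaches the threshold; `-Inf` if no voxel does.
#'
#' @inheritParams activation_volume
#' @return Depth in mm (z coordinate of the deepest above-threshold
#'   voxel centre).
#' @export
penetration_depth <- function(map, threshold) {
  stopifnot(inherits(map, "fluence_map"), threshold > 0)
  hit <- tissue_voxels(map) & map$values >= threshold
  if (!any(hit)) return(-Inf)
  max(map$z_centers[col(hit)[hit]])
}

#' Radial irradiance profile at the tissue interface
#'
#' Returns the fluence-rate row of the first tissue z-bin together with
#' its half-maximum diameter (the outermost radius at which the profile
#' falls to half its peak, linearly interpolated between bin centres,
#' doubled).  Because the micro-LED emits through 100 um of sapphire, the
#' half-max diameter of its illumination site exceeds the 30 um physical
#' pixel.
#'
#' @param map a [fluence_map()] whose grid includes z > 0 bins.
#' @return List with `r` (bin centres, mm), `fluence` (mW/mm^2) and
#'   `half_max_diameter` (mm).
#' @export
interface_profile <- function(map) {
  stopifnot(inherits(map, "fluence_map"))
  iz <- which(map$z_centers > 0)[1]
  if (is.na(iz)) stop("grid has no tissue-side (z > 0) bins", call. = FALSE)
  row <- map$values[, iz]
  r <- map$r_centers
  pk <- max(row)
  hm <- pk / 2
  above <- which(row >= hm)
  i <- max(above)
  r_half <- if (i == length(row)) {
    max(map$r_edges)
  } else {
    r[i] + (row[i] - hm) / (row[i] - row[i + 1]) * (r[i + 1] - r[i])
  }
  list(r = r, fluence = row, half_max_diameter = 2 * r_half)
}

#' Threshold sweep of activation volume and penetration depth
#'
#' @param map a [fluence_map()].
#' @param thresholds fluence thresholds, mW/mm^2.
#' @return Object of class `activation_report`: a data frame with one
#'   row per threshold (`threshold`, `volume_mm3`, `max_depth_mm`,
#'   `n_voxels`).
#' @export
activation_report <- function(map, thresholds = c(0.5, 1, 2)) {
  stopifnot(inherits(map, "fluence_map"), all(thresholds > 0))
  tis <- tissue_voxels(map)
  vol <- voxel_volumes(map)
  rows <- lapply(thresholds, function(th) {
    hit <- tis & map$values >= th
    data.frame(threshold = th,
               volume_mm3 = sum(vol[hit]),
               max_depth_mm = if (any(hit)) {
                 max(map$z_centers[col(hit)[hit]])
               } else {
                 -Inf
               },
               n_voxels = sum(hit))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("activation_report", "data.frame")
  out
}

#' Plot a fluence-rate map
#'
#' log10 pseudo-colour image of the (r, z) fluence map, z downward (into
#' tissue), mirroring r about the axis.
#'
#' @param x a [fluence_map()].
#' @param floor smallest fluence (mW/mm^2) shown.
#' @param ... passed to [graphics::image()].
#' @return The map, invisibly.
#' @export
plot.fluence_map <- function(x, floor = 1e-3, ...) {
  v <- log10(pmax(x$values, floor))
  full <- rbind(v[rev(seq_len(nrow(v))), , drop = FALSE], v)
  xs <- c(-rev(x$r_centers), x$r_centers)
  graphics::image(xs, x$z_centers, full, ylim = rev(range(x$z_centers)),
                  xlab = "r (mm)", ylab = "z (mm)",
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}
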