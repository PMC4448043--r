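#' Build a layered slab geometry with lateral cylindrical bounds
#'
#' The simulation domain is a cylinder of radius `domain_radius` aligned
#' with the emission axis (z).  It is tiled along z by layers; each layer
#' has an inner medium inside `lateral_radius` and, optionally, a
#' different outer medium between `lateral_radius` and the domain edge
#' (used for the sapphire probe shank embedded in tissue).  All interfaces
#' are resolved with unpolarized Fresnel optics; a layer flagged
#' `top_blocked` carries an opaque contact over its inner zone's top plane
#' (the reflecting p-contact behind a micro-LED), absorbing by default or
#' specularly reflecting with probability `backplane_reflectivity`.
#'
#' Photons crossing the top of the first layer are tallied as back-plane
#' loss, those crossing the bottom of the last layer as escaped, and those
#' reaching the domain edge as edge loss.
#'
#' Coordinates: z increases along the emission axis, z = 0 at the
#' probe/tissue (or saline/tissue) interface, tissue at z > 0, lengths in
#' mm.
#'
#' @param layers list of layer specs; each a list with `z_min`, `z_max`,
#'   `medium`, and optionally `lateral_radius` (default: the domain
#'   radius), `outer_medium` (default: same as `medium`) and `top_blocked`
#'   (default `FALSE`).
#' @param media named list of [optical_medium()] objects.
#' @param domain_radius radius (mm) beyond which photons are tallied as
#'   edge loss.
#' @param backplane_reflectivity specular reflectivity of blocked
#'   contacts, in \[0, 1\]; 0 means purely absorbing.
#' @param tissue_medium name of the medium that counts as neural tissue
#'   for activation volume and penetration depth analyses.
#' @return Object of class `layered_geometry`.
#' @examples
#' geo <- mled_probe_geometry()
#' geo
#' @export
layered_geometry <- function(layers, media, domain_radius = 5,
                             backplane_reflectivity = 0,
                             tissue_medium = "tissue") {
  stopifnot(is.list(layers), length(layers) >= 1L, is.list(media))
  if (!all(vapply(media, inherits, logical(1), "optical_medium"))) {
    stop("'media' must be a named list of optical_medium objects",
         call. = FALSE)
  }
  if (domain_radius <= 0) stop("'domain_radius' must be > 0", call. = FALSE)
  if (backplane_reflectivity < 0 || backplane_reflectivity > 1) {
    stop("'backplane_reflectivity' must lie in [0, 1]", call. = FALSE)
  }
  lay <- lapply(layers, function(L) {
    list(z_min = L$z_min, z_max = L$z_max, medium = L$medium,
         lateral_radius = min(L$lateral_radius %||% domain_radius,
                              domain_radius),
         outer_medium = L$outer_medium %||% L$medium,
         top_blocked = isTRUE(L$top_blocked))
  })
  for (L in lay) {
    if (!is.numeric(L$z_min) || !is.numeric(L$z_max) || L$z_min >= L$z_max) {
      stop("each layer needs z_min < z_max", call. = FALSE)
    }
    for (m in c(L$medium, L$outer_medium)) {
      if (!m %in% names(media)) {
        stop(sprintf("layer references unknown medium '%s'", m),
             call. = FALSE)
      }
    }
    if (L$lateral_radius <= 0) {
      stop("'lateral_radius' must be > 0", call. = FALSE)
    }
  }
  if (length(lay) > 1L) {
    for (i in seq_len(length(lay) - 1L)) {
      if (lay[[i]]$z_max != lay[[i + 1L]]$z_min) {
        stop("layers must tile the z-axis without gaps or overlap",
             call. = FALSE)
      }
    }
  }
  if (!tissue_medium %in% names(media)) {
    stop(sprintf("tissue medium '%s' not found in media", tissue_medium),
         call. = FALSE)
  }
  structure(
    list(layers = lay, media = media, domain_radius = domain_radius,
         backplane_reflectivity = backplane_reflectivity,
         tissue_medium = tissue_medium),
    class = "layered_geometry")
}

#' @export
print.layered_geometry <- function(x, ...) {
  cat(sprintf("<layered_geometry> %d layer(s), domain radius %g mm\n",
              length(x$layers), x$domain_radius))
  for (L in x$layers) {
    extra <- if (L$outer_medium != L$medium) {
      sprintf(" (r < %g mm; %s outside)", L$lateral_radius, L$outer_medium)
    } else ""
    blk <- if (L$top_blocked) " [blocked top]" else ""
    cat(sprintf("  z in [%g, %g) mm: %s%s%s\n",
                L$z_min, L$z_max, L$medium, extra, blk))
  }
  invisible(x)
}

#' Geometry of the sapphire micro-LED probe embedded in cortex
#'
#' A 100 um sapphire slab laterally bounded at the 150 um probe width
#' (half-width 75 um), with the micro-LED's reflecting contact on its top
#' face, above semi-infinite brain tissue.  Tissue also surrounds the
#' probe laterally, so light trapped in the sapphire by total internal
#' reflection eventually leaves through the lateral faces into tissue.
#' `tissue_above > 0` adds a tissue layer on top of the probe plane,
#' modelling a probe inserted to depth: the shallow cortex then sits above
#' the emitter and the domain top is the cortical surface.
#'
#' With `sapphire_thickness = 0` the slab is omitted entirely and sources
#' launch directly at the tissue surface (the no-spread control).
#'
#' @param media named list of [optical_medium()]; needs `sapphire` (unless
#'   thickness is 0) and the tissue medium.
#' @param sapphire_thickness slab thickness, mm.
#' @param probe_half_width lateral half-width of the probe, mm.
#' @param tissue_above thickness of tissue above the probe plane, mm.
#' @param domain_depth extent of tissue below the interface, mm.
#' @inheritParams layered_geometry
#' @return `layered_geometry`.
#' @export
mled_probe_geometry <- function(media = default_media(),
                                sapphire_thickness = 0.1,
                                probe_half_width = 0.075,
                                tissue_above = 0,
                                domain_depth = 5,
                                domain_radius = 5,
                                backplane_reflectivity = 0,
                                tissue_medium = "tissue") {
  layers <- list()
  if (tissue_above > 0) {
    layers <- c(layers, list(list(
      z_min = -sapphire_thickness - tissue_above,
      z_max = -sapphire_thickness,
      medium = tissue_medium)))
  }
  if (sapphire_thickness > 0) {
    layers <- c(layers, list(list(
      z_min = -sapphire_thickness, z_max = 0, medium = "sapphire",
      lateral_radius = probe_half_width, outer_medium = tissue_medium,
      top_blocked = TRUE)))
  }
  layers <- c(layers, list(list(
    z_min = 0, z_max = domain_depth, medium = tissue_medium)))
  layered_geometry(layers, media, domain_radius = domain_radius,
                   backplane_reflectivity = backplane_reflectivity,
                   tissue_medium = tissue_medium)
}

#' Geometry of a fiber above the cortical surface
#'
#' The fiber tip sits in a saline standoff layer above semi-infinite brain
#' tissue; light must cross the standoff before entering tissue.
#'
#' @param media named list of [optical_medium()]; needs `saline` and the
#'   tissue medium.
#' @param standoff saline thickness between fiber tip and tissue, mm.
#' @inheritParams mled_probe_geometry
#' @return `layered_geometry`.
#' @export
fiber_standoff_geometry <- function(media = default_media(),
                                    standoff = 0.3,
                                    domain_depth = 5,
                                    domain_radius = 5,
                                    tissue_medium = "tissue") {
  layers <- list(
    list(z_min = -standoff, z_max = 0, medium = "saline"),
    list(z_min = 0, z_max = domain_depth, medium = tissue_medium))
  layered_geometry(layers, media, domain_radius = domain_radius,
                   tissue_medium = tissue_medium)
}

#' Medium at a point of the geometry
#'
#' @param geometry a [layered_geometry()].
#' @param r radial coordinate(s), mm.
#' @param z axial coordinate(s), mm.
#' @return Character vector of medium names (`NA` outside the domain).
#' @export
region_at <- function(geometry, r, z) {
  stopifnot(inherits(geometry, "layered_geometry"))
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (r[i] >= geometry$domain_radius) next
    for (L in geometry$layers) {
      if (z[i] >= L$z_min && z[i] < L$z_max) {
        out[i] <- if (r[i] < L$lateral_radius) L$medium else L$outer_medium
        break
      }
    }
  }
  out
}

# --- internal numeric scene representation shared by both engines ---------

# layer/zone indices for a position strictly inside the domain
locate_zone <- function(scene, position) {
  z <- position[3]
  r <- sqrt(position[1]^2 + position[2]^2)
  lay <- scene$layers
  for (i in seq_len(nrow(lay))) {
    if (z >= lay[i, 1] && z < lay[i, 2]) {
      return(list(layer = i, inner = r < lay[i, 4]))
    }
  }
  stop("position lies outside all regions of the geometry", call. = FALSE)
}

# mirror of the compiled engine's boundary search (identical arithmetic)
scene_dist_boundary <- function(scene, li, inner, pos, dir) {
  eps <- 1e-12
  lay <- scene$layers
  x <- pos[1]; y <- pos[2]; z <- pos[3]
  dx <- dir[1]; dy <- dir[2]; dz <- dir[3]
  best <- 1e30
  type <- NA_character_
  if (dz > 0) {
    t <- (lay[li, 2] - z) / dz
    if (t > eps && t < best) { best <- t; type <- "z_down" }
  } else if (dz < 0) {
    t <- (lay[li, 1] - z) / dz
    if (t > eps && t < best) { best <- t; type <- "z_up" }
  }
  a <- dx * dx + dy * dy
  if (a > 0) {
    b <- 2 * (x * dx + y * dy)
    cc <- x * x + y * y
    rlat <- lay[li, 4]
    Rdom <- scene$domain_radius
    if (inner) {
      spans <- rlat >= Rdom
      Rc <- if (spans) Rdom else rlat
      disc <- b * b - 4 * a * (cc - Rc * Rc)
      if (disc > 0) {
        t <- (-b + sqrt(disc)) / (2 * a)
        if (t > eps && t < best) {
          best <- t
          type <- if (spans) "edge" else "lateral"
        }
      }
    } else {
      disc <- b * b - 4 * a * (cc - rlat * rlat)
      if (disc > 0) {
        t1 <- (-b - sqrt(disc)) / (2 * a)
        if (t1 > eps && t1 < best) { best <- t1; type <- "lateral" }
      }
      disc2 <- b * b - 4 * a * (cc - Rdom * Rdom)
      if (disc2 > 0) {
        t2 <- (-b + sqrt(disc2)) / (2 * a)
        if (t2 > eps && t2 < best) { best <- t2; type <- "edge" }
      }
    }
  }
  list(distance = unname(best), surface = type)
}

#' Distance to the nearest bounding surface of the current region
#'
#' @param position 3-vector (mm), strictly inside a region.
#' @param direction unit 3-vector.
#' @param geometry a [layered_geometry()] or a compiled scene.
#' @return List with `distance` (mm) and `surface` (one of `"z_up"`,
#'   `"z_down"`, `"lateral"`, `"edge"`).
#' @examples
#' geo <- mled_probe_geometry()
#' distance_to_boundary(c(0, 0, -0.05), c(0, 0, 1), geo)
#' @export
distance_to_boundary <- function(position, direction, geometry) {
  scene <- if (inherits(geometry, "layered_geometry")) {
    scene_pack_geometry(geometry)
  } else {
    geometry
  }
  zone <- locate_zone(scene, position)
  scene_dist_boundary(scene, zone$layer, zone$inner, position, direction)
}

# numeric geometry block of the packed scene
scene_pack_geometry <- function(geometry) {
  media <- geometry$media
  mnames <- names(media)
  med <- do.call(rbind, lapply(media, function(m) {
    c(m$refractive_index, m$mu_a, m$mu_s, m$g)
  }))
  dimnames(med) <- NULL   # bare numerics: scalar subsets must stay nameless
  lay <- do.call(rbind, lapply(geometry$layers, function(L) {
    c(L$z_min, L$z_max, match(L$medium, mnames), L$lateral_radius,
      match(L$outer_medium, mnames), as.numeric(L$top_blocked))
  }))
  dimnames(lay) <- NULL
  list(media = med, media_names = mnames, layers = lay,
       domain_radius = geometry$domain_radius,
       backplane_reflectivity = geometry$backplane_reflectivity,
       tissue_medium = geometry$tissue_medium)
}
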