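#' Drive-current to interface-irradiance calibration table
#'
#' The micro-LED's optical output is specified by bench-measured anchor
#' points mapping drive current (mA) to the irradiance delivered at the
#' probe/tissue interface (mW/mm^2).  Interface irradiance is stored
#' directly and never derived from surface-irradiance values, whose
#' attenuation factor is not constant across the operating range.
#'
#' @param current_mA anchor currents, strictly increasing, mA.
#' @param irradiance_mW_mm2 interface irradiances at the anchors,
#'   strictly increasing, mW/mm^2.
#' @return Object of class `calibration_table`.
#' @examples
#' default_calibration()
#' @export
calibration_table <- function(current_mA, irradiance_mW_mm2) {
  stopifnot(is.numeric(current_mA), is.numeric(irradiance_mW_mm2),
            length(current_mA) == length(irradiance_mW_mm2),
            length(current_mA) >= 2L)
  if (any(diff(current_mA) <= 0)) {
    stop("anchor currents must be strictly increasing", call. = FALSE)
  }
  if (any(diff(irradiance_mW_mm2) <= 0)) {
    stop("anchor irradiances must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(current_mA = current_mA,
               irradiance_mW_mm2 = irradiance_mW_mm2),
    class = c("calibration_table", "data.frame"))
}

#' Default micro-LED calibration anchors
#'
#' 0.1 mA gives 0.5 mW/mm^2 at the probe/tissue interface, 4 mA gives
#' 40 mW/mm^2 and 6 mA gives 52 mW/mm^2.
#'
#' @return A [calibration_table()].
#' @export
default_calibration <- function() {
  calibration_table(current_mA = c(0.1, 4, 6),
                    irradiance_mW_mm2 = c(0.5, 40, 52))
}

#' Interpolate interface irradiance for a drive current
#'
#' Piecewise-linear interpolation through the calibration anchors; exact
#' at the anchors, no extrapolation outside the calibrated range.
#'
#' @param current drive current(s), mA.
#' @param table a [calibration_table()].
#' @return Interface irradiance(s), mW/mm^2.
#' @examples
#' current_to_interface_irradiance(4)    # 40
#' current_to_interface_irradiance(5)    # midway between 40 and 52
#' @export
current_to_interface_irradiance <- function(current,
                                            table = default_calibration()) {
  stopifnot(inherits(table, "calibration_table"))
  if (any(current < min(table$current_mA)) ||
      any(current > max(table$current_mA))) {
    stop(sprintf(
      "current out of calibrated range [%g, %g] mA; no extrapolation",
      min(table$current_mA), max(table$current_mA)), call. = FALSE)
  }
  approx(table$current_mA, table$irradiance_mW_mm2, xout = current,
         method = "linear", ties = "ordered")$y
}

# ------------------------------------------------------------ config IO --

#' Load and validate a run configuration file
#'
#' Reads a YAML run description (media table, geometry, source, run
#' parameters, grid, analysis thresholds, calibration anchors), validates
#' every field and reports all violations at once.  Shipped
#' configurations live under `system.file("extdata", package = "optomc")`:
#' `mled.yaml` (the micro-LED probe) and `fiber.yaml` (the fiber above
#' the cortical surface).
#'
#' @param path YAML file path.
#' @param overrides named list merged over the file contents before
#'   validation (e.g. `list(run = list(n_photons = 1e5, seed = 7))`).
#' @return A [run_config()].
#' @examples
#' cfg <- load_config(system.file("extdata", "mled.yaml", package = "optomc"),
#'                    overrides = list(run = list(n_photons = 100)))
#' @export
load_config <- function(path, overrides = NULL) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("malformed config '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(overrides)) raw <- modifyList(raw, overrides)
  as_run_config(raw)
}

#' Build a run configuration from a plain list
#'
#' The list form mirrors the YAML schema; see the shipped config files.
#' All validation failures are collected and reported together, naming
#' the offending fields.
#'
#' @param raw nested named list.
#' @return A [run_config()].
#' @export
as_run_config <- function(raw) {
  problems <- character(0)
  need <- function(block, field, check = is.numeric) {
    v <- raw[[block]][[field]]
    if (is.null(v)) {
      problems <<- c(problems, sprintf("missing %s.%s", block, field))
      return(NULL)
    }
    if (!check(v)) {
      problems <<- c(problems, sprintf("invalid %s.%s", block, field))
      return(NULL)
    }
    v
  }

  if (is.null(raw$media) || !is.list(raw$media) || !length(raw$media)) {
    problems <- c(problems, "missing media table")
  } else {
    for (nm in names(raw$media)) {
      m <- raw$media[[nm]]
      for (f in c("refractive_index", "mu_a", "mu_s", "g")) {
        if (is.null(m[[f]]) || !is.numeric(m[[f]])) {
          problems <- c(problems, sprintf("media.%s: missing or invalid %s",
                                          nm, f))
        }
      }
    }
  }

  n_photons <- need("run", "n_photons")
  seed <- need("run", "seed")
  step_cap <- raw$run$step_cap %||% 1e5
  rr <- raw$roulette %||% list()
  threshold <- rr$threshold %||% 1e-4
  survival <- rr$survival %||% 0.1
  strict <- isTRUE(rr$strict_termination)

  gtype <- raw$geometry$type
  if (is.null(gtype) ||
      !gtype %in% c("mled_probe", "fiber_standoff", "layers")) {
    problems <- c(problems,
                  "geometry.type must be one of mled_probe, fiber_standoff, layers")
  }
  stype <- raw$source$type
  if (is.null(stype) || !stype %in% c("led_disc", "fiber", "pencil")) {
    problems <- c(problems,
                  "source.type must be one of led_disc, fiber, pencil")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  media <- media_from_list(raw$media)
  geo <- raw$geometry
  geometry <- switch(gtype,
    mled_probe = mled_probe_geometry(
      media = media,
      sapphire_thickness = geo$sapphire_thickness %||% 0.1,
      probe_half_width = geo$probe_half_width %||% 0.075,
      tissue_above = geo$tissue_above %||% 0,
      domain_depth = geo$domain_depth %||% 5,
      domain_radius = geo$domain_radius %||% 5,
      backplane_reflectivity = geo$backplane_reflectivity %||% 0,
      tissue_medium = geo$tissue_medium %||% "tissue"),
    fiber_standoff = fiber_standoff_geometry(
      media = media,
      standoff = geo$standoff %||% 0.3,
      domain_depth = geo$domain_depth %||% 5,
      domain_radius = geo$domain_radius %||% 5,
      tissue_medium = geo$tissue_medium %||% "tissue"),
    layers = layered_geometry(
      geo$layers, media,
      domain_radius = geo$domain_radius %||% 5,
      backplane_reflectivity = geo$backplane_reflectivity %||% 0,
      tissue_medium = geo$tissue_medium %||% "tissue"))

  src <- raw$source
  source <- switch(stype,
    led_disc = led_disc_source(
      diameter = src$diameter %||% 0.030,
      z_launch = src$z_launch %||%
        -(geo$sapphire_thickness %||% 0.1),
      collimated = isTRUE(src$collimated)),
    fiber = fiber_source(
      core_diameter = src$core_diameter %||% 0.105,
      na = src$na %||% 0.22,
      sigma = src$sigma %||% (src$core_diameter %||% 0.105) / 4,
      power = src$power %||% 1.1,
      z_launch = src$z_launch %||% -(geo$standoff %||% 0.3),
      na_reference = src$na_reference %||% "medium"),
    pencil = pencil_source(z_launch = src$z_launch %||% 0))

  gr <- raw$grid %||% list()
  grid <- grid_spec(dr = gr$dr %||% 0.01, dz = gr$dz %||% 0.01,
                    r_max = gr$r_max %||% 1.5,
                    z_min = gr$z_min %||% -0.4,
                    z_max = gr$z_max %||% 2.0)

  cal <- raw$calibration
  calibration <- if (is.null(cal)) {
    default_calibration()
  } else {
    calibration_table(cal$current_mA, cal$interface_mW_mm2)
  }

  run_config(geometry = geometry, source = source,
             n_photons = n_photons, seed = seed, grid = grid,
             roulette_threshold = threshold, roulette_survival = survival,
             strict_termination = strict, step_cap = step_cap,
             thresholds = unlist(raw$analysis$thresholds %||% 1),
             calibration = calibration)
}

#' Semantic hash of a configuration
#'
#' MD5 of the canonicalized (recursively name-sorted, full-precision
#' JSON) parsed configuration; whitespace and key order in the YAML file
#' do not affect it, any semantic field change does.
#'
#' @param raw parsed config list, or a path to a YAML file.
#' @return 32-character hash string.
#' @export
config_hash <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) raw <- yaml::read_yaml(raw)
  canon <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      if (!is.null(nm) && any(nzchar(nm))) x <- x[order(nm)]
      lapply(x, canon)
    } else {
      x
    }
  }
  js <- jsonlite::toJSON(canon(raw), digits = NA, auto_unbox = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

# ----------------------------------------------------------- grid files --

#' Write a fluence grid to a self-describing JSON container
#'
#' Stores edges, raw values (column major) and full metadata (photon
#' count, seed, source power, media table, geometry layers) with
#' full double precision, so `read_grid(write_grid(g))` reproduces the
#' grid bit-exactly and identical config + seed yields byte-identical
#' files.
#'
#' @param grid a [fluence_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "fluence_grid"))
  geo <- grid$geometry
  doc <- list(
    format = "optomc-grid",
    version = 1L,
    r_edges = grid$r_edges,
    z_edges = grid$z_edges,
    values = as.vector(grid$values),
    metadata = list(
      n_photons = grid$n_photons,
      seed = grid$seed,
      source_power = grid$source_power,
      outside_track = grid$outside_track,
      media = if (!is.null(geo)) {
        lapply(geo$media, function(m) {
          list(refractive_index = m$refractive_index, mu_a = m$mu_a,
               mu_s = m$mu_s, g = m$g)
        })
      },
      tissue_medium = if (!is.null(geo)) geo$tissue_medium,
      domain_radius = if (!is.null(geo)) geo$domain_radius,
      backplane_reflectivity = if (!is.null(geo)) {
        geo$backplane_reflectivity
      },
      layers = if (!is.null(geo)) geo$layers))
  writeLines(json_emit(doc), path)
  invisible(path)
}

# minimal JSON emitter writing doubles with "%.17g" so that numeric
# payloads survive a write/read cycle bit-exactly (jsonlite caps numeric
# output below round-trip precision)
json_emit <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      body <- vapply(seq_along(x), function(i) {
        sprintf("\"%s\":%s", nm[i], json_emit(x[[i]]))
      }, character(1))
      return(paste0("{", paste(body, collapse = ","), "}"))
    }
    return(paste0("[", paste(vapply(x, json_emit, character(1)),
                             collapse = ","), "]"))
  }
  if (is.character(x)) {
    enc <- paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  } else if (is.logical(x)) {
    enc <- ifelse(is.na(x), "null", ifelse(x, "true", "false"))
  } else if (is.numeric(x)) {
    enc <- ifelse(is.na(x), "null", sprintf("%.17g", x))
  } else {
    stop("cannot encode object of class ", class(x)[1], call. = FALSE)
  }
  if (length(enc) == 1L) enc else {
    paste0("[", paste(enc, collapse = ","), "]")
  }
}

#' Read a fluence grid written by [write_grid()]
#'
#' @param path file path.
#' @return A [fluence_grid()].
#' @export
read_grid <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("malformed grid file '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (!identical(doc$format, "optomc-grid")) {
    stop(sprintf("'%s' is not an optomc grid container (field 'format')",
                 path), call. = FALSE)
  }
  md <- doc$metadata
  geometry <- NULL
  if (!is.null(md$media) && length(md$media)) {
    media <- lapply(names(md$media), function(nm) {
      m <- md$media[[nm]]
      optical_medium(nm, m$refractive_index, m$mu_a, m$mu_s, m$g)
    })
    names(media) <- names(md$media)
    layers <- lapply(seq_len(nrow(md$layers)), function(i) {
      as.list(md$layers[i, ])
    })
    geometry <- layered_geometry(
      layers, media, domain_radius = md$domain_radius,
      backplane_reflectivity = md$backplane_reflectivity,
      tissue_medium = md$tissue_medium)
  }
  nr <- length(doc$r_edges) - 1L
  nz <- length(doc$z_edges) - 1L
  g <- fluence_grid(r_edges = as.double(doc$r_edges),
                    z_edges = as.double(doc$z_edges),
                    values = matrix(as.double(doc$values), nr, nz),
                    n_photons = as.double(md$n_photons %||% 0),
                    seed = as.double(md$seed %||% NA_real_),
                    source_power = as.double(md$source_power %||% NA_real_),
                    geometry = geometry)
  g$outside_track <- as.double(md$outside_track %||% 0)
  g
}

#' Export a fluence map as delimited text
#'
#' Plain (r, z, fluence) TSV for interoperability with other tools.
#'
#' @param map a [fluence_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "fluence_map"))
  df <- data.frame(
    r_mm = rep(map$r_centers, times = length(map$z_centers)),
    z_mm = rep(map$z_centers, each = length(map$r_centers)),
    fluence_mW_mm2 = as.vector(map$values))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param report an [activation_report()] or any list/data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
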