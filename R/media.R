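#' Define an optical medium
#'
#' A medium is characterised by its refractive index and, for turbid media,
#' by the absorption coefficient `mu_a`, scattering coefficient `mu_s`
#' (both per mm) and the scattering anisotropy `g` (the mean cosine of the
#' single-scattering deflection angle).  Transparent media such as sapphire
#' or saline have `mu_a = mu_s = 0`; free paths in them are unbounded and
#' photons only interact with boundaries.
#'
#' @param name label used to reference the medium from a geometry.
#' @param refractive_index dimensionless, `>= 1`.
#' @param mu_a absorption coefficient, mm^-1, `>= 0`.
#' @param mu_s scattering coefficient, mm^-1, `>= 0`.
#' @param g scattering anisotropy, strictly inside (-1, 1).
#'
#' @return An object of class `optical_medium`.
#' @examples
#' brain <- optical_medium("tissue", 1.36, mu_a = 0.07, mu_s = 11.7, g = 0.88)
#' brain
#' @export
optical_medium <- function(name, refractive_index, mu_a = 0, mu_s = 0, g = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(refractive_index) || length(refractive_index) != 1L ||
      refractive_index < 1) {
    stop("'refractive_index' must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(mu_a) || length(mu_a) != 1L || mu_a < 0) {
    stop("'mu_a' must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(mu_s) || length(mu_s) != 1L || mu_s < 0) {
    stop("'mu_s' must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(g) || length(g) != 1L || abs(g) >= 1) {
    stop("'g' must be a single number strictly inside (-1, 1)", call. = FALSE)
  }
  structure(
    list(name = name, refractive_index = refractive_index,
         mu_a = mu_a, mu_s = mu_s, g = g),
    class = "optical_medium")
}

#' Total interaction coefficient of a medium
#'
#' @param medium an [optical_medium()].
#' @return `mu_a + mu_s` in mm^-1.
#' @export
mu_t <- function(medium) {
  stopifnot(inherits(medium, "optical_medium"))
  medium$mu_a + medium$mu_s
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf("<optical_medium> %s: n = %g, mu_a = %g /mm, mu_s = %g /mm, g = %g\n",
              x$name, x$refractive_index, x$mu_a, x$mu_s, x$g))
  invisible(x)
}

#' Standard media for micro-LED probe and fiber simulations
#'
#' Reads the shipped default configuration and returns its media table:
#' sapphire (n = 1.77, transparent), physiological saline (n = 1.34,
#' transparent) and grey-matter brain tissue at 450 nm (n = 1.36,
#' mu_a = 0.07 /mm, mu_s = 11.7 /mm, g = 0.88).  All values are plain
#' config-file entries, not constants baked into the code, so they can be
#' overridden per run.
#'
#' @return Named list of [optical_medium()] objects.
#' @export
default_media <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "mled.yaml",
                                     package = "optomc", mustWork = TRUE))
  media_from_list(cfg$media)
}

media_from_list <- function(lst) {
  out <- lapply(names(lst), function(nm) {
    m <- lst[[nm]]
    optical_medium(nm, m$refractive_index,
                   mu_a = m$mu_a %||% 0,
                   mu_s = m$mu_s %||% 0,
                   g = m$g %||% 0)
  })
  names(out) <- names(lst)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
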