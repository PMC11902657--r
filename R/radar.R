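#' Radar sweep configuration
#'
#' Describes a stepped/linear frequency sweep for a monostatic planar-aperture
#' near-field imager. The sampling plane sits at `z = -R0`; the scene origin is
#' the coordinate origin, with `z` pointing down-range (away from the aperture).
#'
#' @param f_min,f_max Sweep band edges in Hz. Defaults are the Ka-band
#'   32--37 GHz sweep used throughout the package.
#' @param n_freq Number of frequency samples (uniform in frequency, hence in
#'   wavenumber).
#' @param c Propagation speed in m/s.
#' @param R0 Distance from the aperture plane to the scene origin, in metres.
#'
#' @return An object of class `radar_config`.
#' @examples
#' cfg <- radar_config()
#' range(wavenumber_axis(cfg))
#' @export
radar_config <- function(f_min = 32e9, f_max = 37e9, n_freq = 64,
                         c = 299792458, R0 = 0.5) {
  if (!is.numeric(c) || length(c) != 1 || c <= 0) {
    stop("invalid radar config: propagation speed `c` must be positive")
  }
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min >= f_max) {
    stop("invalid radar config: need f_min < f_max")
  }
  if (n_freq < 2) stop("invalid radar config: n_freq must be >= 2")
  if (R0 <= 0) stop("invalid radar config: R0 must be positive")
  structure(
    list(f_min = f_min, f_max = f_max, n_freq = as.integer(n_freq),
         c = c, R0 = R0),
    class = "radar_config"
  )
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf("<radar_config> %.3g-%.3g GHz, %d freqs, R0 = %.3g m\n",
              x$f_min / 1e9, x$f_max / 1e9, x$n_freq, x$R0))
  invisible(x)
}

#' Wavenumber axis of a sweep
#'
#' Converts the frequency sweep to wavenumbers `k = 2*pi*f/c`, uniformly
#' spaced because the sweep is uniform in frequency.
#'
#' @param cfg A [radar_config()].
#' @return Numeric vector of `n_freq` wavenumbers in rad/m, strictly
#'   increasing.
#' @export
wavenumber_axis <- function(cfg) {
  stopifnot(inherits(cfg, "radar_config"))
  2 * pi * seq(cfg$f_min, cfg$f_max, length.out = cfg$n_freq) / cfg$c
}

#' Planar aperture sampling grid
#'
#' Uniformly spaced ideal sample positions `(x', y', -R0)` of the scanned
#' aperture. Default spacings are the prototype's 4 mm horizontal and 5 mm
#' vertical sampling intervals.
#'
#' @param nx,ny Number of samples along x (horizontal) and y (vertical).
#' @param dx,dy Sample spacing in metres.
#' @param center Logical; centre the aperture on the origin (default `TRUE`).
#' @return An object of class `aperture_grid` with `x` and `y` position
#'   vectors in metres.
#' @export
aperture_grid <- function(nx = 64, ny = 64, dx = 0.004, dy = 0.005,
                          center = TRUE) {
  stopifnot(nx >= 1, ny >= 1, dx > 0, dy > 0)
  x <- (seq_len(nx) - 1) * dx
  y <- (seq_len(ny) - 1) * dy
  if (center) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  structure(list(x = x, y = y, dx = dx, dy = dy), class = "aperture_grid")
}

#' @export
print.aperture_grid <- function(x, ...) {
  cat(sprintf("<aperture_grid> %d x %d samples, %.1f x %.1f mm pitch\n",
              length(x$x), length(x$y), 1000 * x$dx, 1000 * x$dy))
  invisible(x)
}

check_uniform <- function(v, label, tol = 1e-9) {
  if (length(v) > 2) {
    d <- diff(v)
    if (max(abs(d - d[1])) > tol * max(abs(d[1]), 1e-300)) {
      stop(sprintf("%s axis must be uniformly spaced", label))
    }
  }
  invisible(TRUE)
}

#' Point-scatterer scene
#'
#' A scene is a set of ideal point scatterers, each with a position in metres
#' and a complex reflectivity. Positions use the image-centred frame: origin
#' at the scene centre, `z` down-range, aperture at `z = -R0`.
#'
#' @param x,y,z Numeric vectors of scatterer coordinates in metres.
#' @param reflectivity Complex (or numeric) vector of scattering amplitudes,
#'   recycled to the number of scatterers.
#' @param extent Optional bounding box, a list with `x`, `y`, `z` ranges.
#'   Computed from the scatterers (with a small margin) when omitted.
#' @return An object of class `sar_scene`.
#' @examples
#' sc <- sar_scene(x = 0, y = 0, z = 0)
#' @export
sar_scene <- function(x = numeric(), y = numeric(), z = numeric(),
                      reflectivity = 1 + 0i, extent = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n > 0 && any(!is.finite(x) | !is.finite(y) | !is.finite(z))) {
    stop("scatterer coordinates must be finite")
  }
  amp <- rep_len(as.complex(reflectivity), n)
  if (is.null(extent)) {
    pad <- 0.01
    extent <- if (n == 0) {
      list(x = c(-pad, pad), y = c(-pad, pad), z = c(-pad, pad))
    } else {
      list(x = range(x) + c(-pad, pad), y = range(y) + c(-pad, pad),
           z = range(z) + c(-pad, pad))
    }
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 reflectivity = amp, extent = extent),
            class = "sar_scene")
}

#' @export
print.sar_scene <- function(x, ...) {
  cat(sprintf("<sar_scene> %d scatterers\n", length(x$x)))
  invisible(x)
}

#' @rdname sar_scene
#' @param scene A `sar_scene`.
#' @export
n_scatterers <- function(scene) length(scene$x)

#' Read / write scenes as JSON
#'
#' Scenes serialize to a JSON array of `{x, y, z, amp_re, amp_im}` records.
#'
#' @param scene A [sar_scene()].
#' @param path File path.
#' @return `write_scene_json()` returns `path` invisibly; `read_scene_json()`
#'   returns a `sar_scene`.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "sar_scene"))
  df <- data.frame(x = scene$x, y = scene$y, z = scene$z,
                   amp_re = Re(scene$reflectivity),
                   amp_im = Im(scene$reflectivity))
  jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0 || NROW(df) == 0) return(sar_scene())
  sar_scene(x = df$x, y = df$y, z = df$z,
            reflectivity = complex(real = df$amp_re, imaginary = df$amp_im))
}
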