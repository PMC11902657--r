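#' Slant range from an aperture sample to a scatterer
#'
#' Euclidean distance between the aperture sample `(x', y', -R0)` and a
#' scatterer at `(x, y, z)`:
#' `R = sqrt((x'-x)^2 + (y'-y)^2 + (R0+z)^2)`.
#'
#' @param xp,yp Aperture sample coordinates in metres (vectorized).
#' @param x,y,z Scatterer coordinates in metres.
#' @param R0 Aperture-to-origin distance in metres; must satisfy `R0 + z > 0`
#'   (target in front of the aperture).
#' @return Slant range(s) in metres.
#' @export
slant_range <- function(xp, yp, x, y, z, R0) {
  if (any(R0 + z <= 0)) stop("scatterer lies behind the aperture (R0 + z <= 0)")
  sqrt((xp - x)^2 + (yp - y)^2 + (R0 + z)^2)
}

#' Simulate the baseband echo of a point-scatterer scene
#'
#' Evaluates the monostatic planar-aperture echo
#' `s(x', y', k) = sum_n sigma_n * exp(-2i * k * R_n(x', y'))`
#' on the full aperture-by-wavenumber grid. The continuous scattering
#' integral is replaced by a discrete sum over ideal point scatterers; no
#' antenna pattern weighting is applied.
#'
#' @param scene A [sar_scene()]. An empty scene yields an all-zero cube with
#'   a warning.
#' @param grid An [aperture_grid()].
#' @param cfg A [radar_config()].
#' @return An `echo_cube`: a list with complex array `data` of shape
#'   `(nx, ny, n_freq)`, axis vectors `x_axis`, `y_axis` (m) and `k_axis`
#'   (rad/m), and the generating `cfg`.
#' @export
simulate_echo <- function(scene, grid, cfg) {
  stopifnot(inherits(scene, "sar_scene"), inherits(grid, "aperture_grid"),
            inherits(cfg, "radar_config"))
  k <- wavenumber_axis(cfg)
  nx <- length(grid$x); ny <- length(grid$y); nk <- length(k)
  data <- array(0 + 0i, dim = c(nx, ny, nk))
  if (n_scatterers(scene) == 0) {
    warning("empty scene: returning all-zero echo cube")
  } else {
    xp <- matrix(grid$x, nx, ny)
    yp <- matrix(grid$y, nx, ny, byrow = TRUE)
    for (i in seq_len(n_scatterers(scene))) {
      R <- slant_range(xp, yp, scene$x[i], scene$y[i], scene$z[i], cfg$R0)
      # outer product of aperture ranges with the wavenumber axis
      phase <- outer(as.vector(R), k)
      data <- data + scene$reflectivity[i] *
        array(exp(-2i * phase), dim = c(nx, ny, nk))
    }
  }
  new_echo_cube(data, grid$x, grid$y, k, cfg)
}

new_echo_cube <- function(data, x_axis, y_axis, k_axis, cfg) {
  structure(list(data = data, x_axis = x_axis, y_axis = y_axis,
                 k_axis = k_axis, cfg = cfg),
            class = "echo_cube")
}

#' @export
print.echo_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_cube> %d x %d aperture samples x %d wavenumbers\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Add circularly symmetric complex Gaussian receiver noise
#'
#' Noise power is scaled so that mean signal power / noise power equals
#' `10^(snr_db/10)`. `snr_db = Inf` is a no-noise passthrough. Reproducible
#' for a given `seed`; the global RNG state is left untouched.
#'
#' @param echo An `echo_cube` from [simulate_echo()].
#' @param snr_db Signal-to-noise ratio in dB (finite, or `Inf` for none).
#' @param seed Integer seed.
#' @return A new `echo_cube` with noise added.
#' @export
add_receiver_noise <- function(echo, snr_db, seed = 1L) {
  stopifnot(inherits(echo, "echo_cube"))
  if (is.infinite(snr_db) && snr_db > 0) return(echo)
  if (!is.finite(snr_db)) stop("snr_db must be finite or +Inf")
  sig_pow <- mean(Mod(echo$data)^2)
  if (sig_pow == 0) return(echo)
  noise_pow <- sig_pow / 10^(snr_db / 10)
  n <- length(echo$data)
  noise <- with_local_seed(seed, {
    complex(real = stats::rnorm(n, sd = sqrt(noise_pow / 2)),
            imaginary = stats::rnorm(n, sd = sqrt(noise_pow / 2)))
  })
  echo$data <- echo$data + array(noise, dim = dim(echo$data))
  echo
}

# Run `expr` under a temporary RNG seed, restoring any prior global state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
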