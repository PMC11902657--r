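#' @section Wavenumber-domain reconstruction:
#' The imaging chain follows the classical range-migration (omega-k)
#' algorithm for a monostatic planar aperture: a 2D Fourier transform over
#' the aperture, multiplication by the free-space reference function
#' `exp(+i*sqrt(4k^2 - kx^2 - ky^2)*R0)`, Stolt interpolation from the
#' nonuniform `kz(k) = sqrt(4k^2 - kx^2 - ky^2)` samples onto a uniform
#' `kz` grid, and a 3D inverse Fourier transform. All transforms are
#' unitary so energy is conserved step by step.
#' @name rma
NULL

unitary_fft2_slices <- function(data, inverse = FALSE) {
  d <- dim(data)
  scale <- sqrt(d[1] * d[2])
  for (ik in seq_len(d[3])) {
    data[, , ik] <- stats::fft(data[, , ik], inverse = inverse) / scale
  }
  data
}

# FFT-dual wavenumber axis for n samples at pitch d, in wrapped (DFT) order.
fft_wavenumbers <- function(n, d) {
  m <- seq_len(n) - 1
  m[m >= ceiling(n / 2)] <- m[m >= ceiling(n / 2)] - n
  2 * pi * m / (n * d)
}

new_spectrum <- function(data, kx_axis, ky_axis, zkind, k_axis = NULL,
                         kz_axis = NULL, cfg, x0, y0, dx, dy,
                         compensated = FALSE) {
  structure(list(data = data, kx_axis = kx_axis, ky_axis = ky_axis,
                 z_axis_kind = zkind, k_axis = k_axis, kz_axis = kz_axis,
                 cfg = cfg, x0 = x0, y0 = y0, dx = dx, dy = dy,
                 compensated = compensated),
            class = "sar_spectrum")
}

#' @export
print.sar_spectrum <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sar_spectrum> %d x %d x %d (%s axis)%s\n", d[1], d[2], d[3],
              x$z_axis_kind,
              if (isTRUE(x$compensated)) ", phase-compensated" else ""))
  invisible(x)
}

#' 2D aperture Fourier transform of an echo cube
#'
#' Transforms `s(x', y', k)` to `s(kx, ky, k)` with a unitary FFT per
#' wavenumber slice. The aperture may be zero-padded (`pad` > 1) to reduce
#' wrap-around in the reconstructed image. Phases are referenced to absolute
#' aperture coordinates so that scatterer positions come out in the scene
#' frame.
#'
#' @param echo An `echo_cube`.
#' @param pad Zero-padding factor (>= 1) applied to both aperture axes.
#' @return A `sar_spectrum` with `z_axis_kind = "k"`.
#' @export
forward_2d_transform <- function(echo, pad = 1) {
  stopifnot(inherits(echo, "echo_cube"), pad >= 1)
  check_uniform(echo$x_axis, "x'")
  check_uniform(echo$y_axis, "y'")
  check_uniform(echo$k_axis, "k")
  d <- dim(echo$data)
  nx <- d[1]; ny <- d[2]; nk <- d[3]
  dx <- if (nx > 1) echo$x_axis[2] - echo$x_axis[1] else 1
  dy <- if (ny > 1) echo$y_axis[2] - echo$y_axis[1] else 1
  nxp <- round(nx * pad); nyp <- round(ny * pad)
  data <- array(0 + 0i, dim = c(nxp, nyp, nk))
  data[seq_len(nx), seq_len(ny), ] <- echo$data
  data <- unitary_fft2_slices(data)
  kx <- fft_wavenumbers(nxp, dx)
  ky <- fft_wavenumbers(nyp, dy)
  x0 <- echo$x_axis[1]; y0 <- echo$y_axis[1]
  # reference the DFT phases to the absolute first-sample position
  ramp <- exp(-1i * (outer(kx * x0, ky * y0, "+")))
  for (ik in seq_len(nk)) data[, , ik] <- data[, , ik] * ramp
  new_spectrum(data, kx, ky, "k", k_axis = echo$k_axis, cfg = echo$cfg,
               x0 = x0, y0 = y0, dx = dx, dy = dy)
}

#' Matched-filter phase compensation
#'
#' Multiplies the aperture spectrum by the reference function
#' `exp(+i * kz * R0)` with `kz = sqrt(4k^2 - kx^2 - ky^2)`, compensating
#' the propagation phase from the aperture plane to the scene origin.
#' Evanescent samples (`4k^2 < kx^2 + ky^2`) carry no propagating energy and
#' are set to zero.
#'
#' @param spec A `sar_spectrum` with `z_axis_kind = "k"`.
#' @param R0 Reference distance in metres (defaults to the config's `R0`).
#' @return The compensated `sar_spectrum`.
#' @export
matched_filter_phase <- function(spec, R0 = spec$cfg$R0) {
  stopifnot(inherits(spec, "sar_spectrum"))
  if (spec$z_axis_kind != "k") {
    stop("matched_filter_phase() expects a signal-wavenumber (k) spectrum")
  }
  kr2 <- outer(spec$kx_axis^2, spec$ky_axis^2, "+")
  for (ik in seq_along(spec$k_axis)) {
    kz2 <- 4 * spec$k_axis[ik]^2 - kr2
    prop <- kz2 > 0
    mult <- matrix(0 + 0i, nrow(kr2), ncol(kr2))
    mult[prop] <- exp(1i * sqrt(kz2[prop]) * R0)
    spec$data[, , ik] <- spec$data[, , ik] * mult
  }
  spec$compensated <- TRUE
  spec
}

#' Stolt interpolation onto a uniform kz grid
#'
#' For each `(kx, ky)` column, the spectrum samples sit at the nonuniform
#' `kz(k) = sqrt(4k^2 - kx^2 - ky^2)`. This resamples them onto a uniform
#' `kz` grid spanning `[2*k_min, 2*k_max]` (the broadside support) by 1D
#' interpolation in `k`: a target `kz` needs `k = sqrt(kz^2+kx^2+ky^2)/2`,
#' which lies on the uniform sweep axis where ordinary interpolation
#' applies. Targets outside the sweep band are set to zero.
#'
#' @param spec A phase-compensated `sar_spectrum` (`z_axis_kind = "k"`).
#' @param n_kz Number of uniform kz samples (>= 2); defaults to the number
#'   of sweep samples.
#' @param method Interpolation rule: `"linear"` (default) or `"spline"`
#'   (natural cubic, per column; slower).
#' @return A `sar_spectrum` with `z_axis_kind = "kz"`.
#' @export
stolt_resample <- function(spec, n_kz = length(spec$k_axis),
                           method = c("linear", "spline")) {
  stopifnot(inherits(spec, "sar_spectrum"))
  method <- match.arg(method)
  if (spec$z_axis_kind != "k") stop("spectrum already resampled")
  if (n_kz < 2) stop("n_kz must be >= 2")
  k <- spec$k_axis
  nk <- length(k)
  dk <- k[2] - k[1]
  kz_axis <- seq(2 * k[1], 2 * k[nk], length.out = n_kz)
  d <- dim(spec$data)
  nxy <- d[1] * d[2]
  kr2 <- as.vector(outer(spec$kx_axis^2, spec$ky_axis^2, "+"))
  M <- matrix(spec$data, nrow = nxy, ncol = nk)
  out <- matrix(0 + 0i, nrow = nxy, ncol = n_kz)
  if (method == "linear") {
    tol <- 1e-9
    for (iz in seq_len(n_kz)) {
      k_req <- sqrt(kz_axis[iz]^2 + kr2) / 2
      t <- (k_req - k[1]) / dk
      valid <- t >= -tol & t <= nk - 1 + tol
      if (!any(valid)) next
      tv <- pmin(pmax(t[valid], 0), nk - 1)
      i0 <- pmin(floor(tv), nk - 2)
      frac <- tv - i0
      rows <- which(valid)
      out[rows, iz] <- M[cbind(rows, i0 + 1)] * (1 - frac) +
        M[cbind(rows, i0 + 2)] * frac
    }
  } else {
    for (r in seq_len(nxy)) {
      k_req <- sqrt(kz_axis^2 + kr2[r]) / 2
      valid <- k_req >= k[1] & k_req <= k[nk]
      if (!any(valid)) next
      sre <- stats::spline(k, Re(M[r, ]), xout = k_req[valid])$y
      sim <- stats::spline(k, Im(M[r, ]), xout = k_req[valid])$y
      out[r, valid] <- complex(real = sre, imaginary = sim)
    }
  }
  new_spectrum(array(out, dim = c(d[1], d[2], n_kz)),
               spec$kx_axis, spec$ky_axis, "kz", kz_axis = kz_axis,
               cfg = spec$cfg, x0 = spec$x0, y0 = spec$y0,
               dx = spec$dx, dy = spec$dy, compensated = spec$compensated)
}

new_image_volume <- function(data, x_axis, y_axis, z_axis) {
  structure(list(data = data, x_axis = x_axis, y_axis = y_axis,
                 z_axis = z_axis),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  invisible(x)
}

#' 3D inverse transform of a Stolt-resampled spectrum
#'
#' Unitary 3D inverse FFT from `(kx, ky, kz)` to `(x, y, z)`. The spatial
#' axes follow from the wavenumber spacings (`dx = 2*pi/(N*dkx)` etc.) and
#' are centred on the scene origin; since `kz = 2k` the two-way propagation
#' scaling is already built into the kz axis.
#'
#' @param spec A `sar_spectrum` with `z_axis_kind = "kz"`.
#' @return An `image_volume` with complex voxel data and metre axes.
#' @export
inverse_3d_transform <- function(spec) {
  stopifnot(inherits(spec, "sar_spectrum"))
  if (spec$z_axis_kind != "kz") {
    stop("inverse_3d_transform() expects a resampled (kz) spectrum")
  }
  check_uniform(spec$kz_axis, "kz")
  d <- dim(spec$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  dkz <- spec$kz_axis[2] - spec$kz_axis[1]
  dz <- 2 * pi / (nz * dkz)
  x_axis <- (seq_len(nx) - 1) * spec$dx
  x_axis <- x_axis - mean(x_axis)
  y_axis <- (seq_len(ny) - 1) * spec$dy
  y_axis <- y_axis - mean(y_axis)
  z_axis <- (seq_len(nz) - 1) * dz
  z_axis <- z_axis - mean(z_axis)
  # phase-reference the DFT so index 1 maps to the first axis coordinate
  ramp_xy <- exp(1i * (outer(spec$kx_axis * x_axis[1],
                             spec$ky_axis * y_axis[1], "+")))
  data <- spec$data
  for (iz in seq_len(nz)) {
    data[, , iz] <- data[, , iz] * ramp_xy * exp(1i * spec$kz_axis[iz] * z_axis[1])
  }
  vol <- stats::fft(data, inverse = TRUE) / sqrt(nx * ny * nz)
  # residual carrier from the non-wrapped kz origin (phase only)
  carrier <- exp(1i * spec$kz_axis[1] * (z_axis - z_axis[1]))
  for (iz in seq_len(nz)) vol[, , iz] <- vol[, , iz] * carrier[iz]
  new_image_volume(vol, x_axis, y_axis, z_axis)
}

#' Range-migration reconstruction
#'
#' Full wavenumber-domain image formation: 2D aperture FFT, matched-filter
#' phase compensation, Stolt interpolation, 3D inverse FFT, then cropping to
#' the requested imaging window.
#'
#' @param echo An `echo_cube`.
#' @param cfg A `radar_config` (defaults to the echo's own).
#' @param pad Aperture zero-padding factor (default 2).
#' @param n_kz Uniform kz sample count (default: number of sweep samples).
#' @param z_window Length-2 range window in metres about the scene origin
#'   (default +/- 10 cm); use `NULL` to keep the full ambiguous window.
#' @param crop_xy Keep only the cross-range region covered by the physical
#'   aperture (default `TRUE`; padding enlarges the grid otherwise).
#' @param method Stolt interpolation rule, see [stolt_resample()].
#' @return An `image_volume`.
#' @examples
#' cfg <- radar_config(n_freq = 16)
#' grid <- aperture_grid(nx = 16, ny = 16)
#' echo <- simulate_echo(sar_scene(0, 0, 0), grid, cfg)
#' vol <- reconstruct(echo, pad = 2)
#' peak_voxel(vol)$coords
#' @export
reconstruct <- function(echo, cfg = echo$cfg, pad = 2,
                        n_kz = length(echo$k_axis),
                        z_window = c(-0.1, 0.1), crop_xy = TRUE,
                        method = "linear") {
  stopifnot(inherits(echo, "echo_cube"))
  spec <- forward_2d_transform(echo, pad = pad)
  spec <- matched_filter_phase(spec, R0 = cfg$R0)
  spec <- stolt_resample(spec, n_kz = n_kz, method = method)
  vol <- inverse_3d_transform(spec)
  if (crop_xy) {
    keep_x <- vol$x_axis >= min(echo$x_axis) - spec$dx / 2 &
      vol$x_axis <= max(echo$x_axis) + spec$dx / 2
    keep_y <- vol$y_axis >= min(echo$y_axis) - spec$dy / 2 &
      vol$y_axis <= max(echo$y_axis) + spec$dy / 2
    vol$data <- vol$data[keep_x, keep_y, , drop = FALSE]
    vol$x_axis <- vol$x_axis[keep_x]
    vol$y_axis <- vol$y_axis[keep_y]
  }
  if (!is.null(z_window)) {
    keep_z <- vol$z_axis >= z_window[1] & vol$z_axis <= z_window[2]
    if (!any(keep_z)) stop("z_window excludes every reconstructed slice")
    vol$data <- vol$data[, , keep_z, drop = FALSE]
    vol$z_axis <- vol$z_axis[keep_z]
  }
  vol
}

#' Brute-force back-projection (reference imager)
#'
#' Direct evaluation of `sigma(v) = sum_{x',y',k} s(x',y',k) *
#' exp(+2i*k*R(v))` on an arbitrary voxel grid. Exact (no interpolation or
#' far-field approximations) but O(N_aperture * N_freq * N_voxel); intended
#' as an independent cross-check of [reconstruct()] on small grids.
#'
#' @param echo An `echo_cube`.
#' @param x,y,z Voxel-centre axes in metres.
#' @param cfg A `radar_config` (defaults to the echo's own).
#' @return An `image_volume`.
#' @export
backproject <- function(echo, x, y, z, cfg = echo$cfg) {
  stopifnot(inherits(echo, "echo_cube"))
  k <- echo$k_axis
  nk <- length(k)
  dk <- if (nk > 1) k[2] - k[1] else 0
  vox <- expand.grid(x = x, y = y, z = z)
  nv <- nrow(vox)
  acc <- complex(nv)
  rz2 <- (cfg$R0 + vox$z)
  for (ix in seq_along(echo$x_axis)) {
    dx2 <- (echo$x_axis[ix] - vox$x)^2
    for (iy in seq_along(echo$y_axis)) {
      R <- sqrt(dx2 + (echo$y_axis[iy] - vox$y)^2 + rz2^2)
      ph <- exp(2i * k[1] * R)
      step <- exp(2i * dk * R)
      s <- echo$data[ix, iy, ]
      col <- s[1] * ph
      for (ik in seq_len(nk)[-1]) {
        ph <- ph * step
        col <- col + s[ik] * ph
      }
      acc <- acc + col
    }
  }
  new_image_volume(array(acc, dim = c(length(x), length(y), length(z))),
                   x, y, z)
}

#' Locate the strongest voxel
#'
#' @param vol An `image_volume`.
#' @return List with `index` (ix, iy, iz) and `coords` (x, y, z in metres).
#' @export
peak_voxel <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  idx <- arrayInd(which.max(Mod(vol$data)), dim(vol$data))
  list(index = as.integer(idx),
       coords = c(x = vol$x_axis[idx[1]], y = vol$y_axis[idx[2]],
                  z = vol$z_axis[idx[3]]))
}

new_detection_image <- function(pixels, pitch, note = "") {
  structure(list(pixels = pixels, pitch = pitch, note = note),
            class = "detection_image")
}

#' @export
print.detection_image <- function(x, ...) {
  cat(sprintf("<detection_image> %d x %d px, pitch %.2f x %.2f mm%s\n",
              nrow(x$pixels), ncol(x$pixels),
              1000 * x$pitch[1], 1000 * x$pitch[2],
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Project a volume to a 2D detection image
#'
#' Magnitude projection along the range (z) axis, followed by min-max
#' normalization to `[0, 1]`. Rows of the result run along y (vertical),
#' columns along x, i.e. standard image layout.
#'
#' @param vol An `image_volume`.
#' @param mode `"max"` (default) or `"sum"` projection.
#' @param normalize Rescale so the brightest pixel is 1 (an all-zero
#'   projection stays zero). Set `FALSE` to keep raw magnitudes.
#' @return A `detection_image`.
#' @export
project_to_image <- function(vol, mode = c("max", "sum"), normalize = TRUE) {
  stopifnot(inherits(vol, "image_volume"))
  mode <- match.arg(mode)
  mag <- Mod(vol$data)
  proj <- if (mode == "max") apply(mag, c(1, 2), max) else
    apply(mag, c(1, 2), sum)
  img <- t(proj)   # rows = y, cols = x
  if (normalize) {
    mx <- max(img)
    if (mx > 0) img <- img / mx
  }
  py <- if (length(vol$y_axis) > 1) abs(diff(vol$y_axis[1:2])) else 1
  px <- if (length(vol$x_axis) > 1) abs(diff(vol$x_axis[1:2])) else 1
  new_detection_image(img, pitch = c(py, px),
                      note = paste0(mode, "-projection"))
}
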