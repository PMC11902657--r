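# Shared fixtures: small configurations that keep unit tests fast.

# Ka-band sweep with the round propagation speed used for hand-derived
# wavenumber values.
ka_cfg <- function(n_freq = 16, R0 = 0.3, c = 3e8) {
  radar_config(f_min = 32e9, f_max = 37e9, n_freq = n_freq, c = c, R0 = R0)
}

small_grid <- function(n = 16, d = 0.004) {
  aperture_grid(nx = n, ny = n, dx = d, dy = d)
}

random_feature_map <- function(h = 8, w = 8, c = 4, seed = 1) {
  withr::with_seed(seed, array(rnorm(h * w * c), dim = c(h, w, c)))
}

# energy of a complex array
energy <- function(x) sum(Mod(x)^2)

# echo cube filled with a constant value
echo_of_constant <- function(grid, cfg, value) {
  suppressWarnings(echo <- simulate_echo(sar_scene(), grid, cfg))
  echo$data[] <- value
  echo
}

# small empty image volume with metre axes
new_test_volume <- function(nx = 8, ny = 6, nz = 3) {
  orchardsar:::new_image_volume(
    array(0 + 0i, dim = c(nx, ny, nz)),
    x_axis = seq_len(nx) * 0.004, y_axis = seq_len(ny) * 0.004,
    z_axis = seq_len(nz) * 0.03)
}

# tiny fast-mode dataset for detector tests (images 64 px so the head map
# is 8x8)
tiny_dataset <- function(n = 6, seed = 42) {
  op <- orchard_params(n_images = n, image_size = 64, seed = seed)
  render_orchard_dataset(op, mode = "fast")
}

# detector sized for 64 px test images (C5 is 2x2, so a two-level pyramid)
tiny_detector_config <- function(...) {
  detector_config(dspp_grids = c(1, 2), ...)
}
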