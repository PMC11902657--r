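test_that("2D aperture transform is unitary and localizes DC / impulses", {
  cfg <- ka_cfg(n_freq = 4)
  grid <- small_grid(8)
  withr::with_seed(3, {
    echo <- simulate_echo(sar_scene(0.01, 0, 0.02), grid, cfg)
    spec <- forward_2d_transform(echo)
    expect_equal(energy(spec$data), energy(echo$data), tolerance = 1e-9)
    specp <- forward_2d_transform(echo, pad = 2)
    expect_equal(energy(specp$data), energy(echo$data), tolerance = 1e-9)
  })
  # constant echo concentrates at kx = ky = 0 (the first DFT bin)
  dc <- echo_of_constant(grid, cfg, 1 + 0i)
  sdc <- forward_2d_transform(dc)
  mag <- Mod(sdc$data[, , 1])
  expect_equal(mag[1, 1], sqrt(64), tolerance = 1e-9)
  expect_equal(sum(mag) - mag[1, 1], 0, tolerance = 1e-9)
  # an aperture impulse spreads flat over (kx, ky)
  imp <- dc
  imp$data[] <- 0
  imp$data[3, 5, ] <- 1
  simp <- forward_2d_transform(imp)
  expect_equal(Mod(simp$data[, , 1]), matrix(1 / 8, 8, 8), tolerance = 1e-9)
})

test_that("matched filter applies exp(i kz R0) and zeroes evanescence", {
  cfg <- ka_cfg(n_freq = 2, R0 = 0.3)
  # coarse 2 mm sampling so |kx| extends past 2k and evanescence exists
  grid <- aperture_grid(nx = 16, ny = 16, dx = 0.002, dy = 0.002)
  echo <- echo_of_constant(grid, cfg, 1 + 0i)
  spec <- forward_2d_transform(echo)
  spec$data[] <- 1 + 0i
  out <- matched_filter_phase(spec)
  k <- spec$k_axis
  # broadside bin: phase advance 2 k R0, magnitude untouched
  expect_equal(Arg(out$data[1, 1, 1]), Arg(exp(2i * k[1] * 0.3)),
               tolerance = 1e-9)
  expect_equal(Mod(out$data[1, 1, 1]), 1, tolerance = 1e-12)
  kr2 <- outer(spec$kx_axis^2, spec$ky_axis^2, "+")
  for (ik in seq_along(k)) {
    ev <- kr2 >= 4 * k[ik]^2
    expect_true(any(ev))          # fixture really has an evanescent region
    expect_true(all(out$data[, , ik][ev] == 0))
    expect_equal(Mod(out$data[, , ik][!ev]),
                 rep(1, sum(!ev)), tolerance = 1e-12)
  }
})

test_that("Stolt resampling follows the dispersion relation exactly for
           linear spectra", {
  cfg <- ka_cfg(n_freq = 16, R0 = 0.3)
  grid <- small_grid(8)
  echo <- simulate_echo(sar_scene(0, 0, 0), grid, cfg)
  spec <- forward_2d_transform(echo)
  k <- spec$k_axis
  # overwrite with a spectrum linear in k: exact under linear interpolation
  lin <- function(kk) 2 * kk - k[1]
  for (ik in seq_along(k)) spec$data[, , ik] <- lin(k[ik]) + 0i
  spec$compensated <- TRUE
  out <- stolt_resample(spec, n_kz = 24)
  expect_identical(out$z_axis_kind, "kz")
  expect_equal(range(out$kz_axis), c(2 * k[1], 2 * k[16]), tolerance = 1e-12)
  kr2 <- outer(out$kx_axis^2, out$ky_axis^2, "+")
  for (iz in c(1, 9, 24)) {
    k_req <- sqrt(out$kz_axis[iz]^2 + kr2) / 2
    inside <- k_req >= k[1] & k_req <= k[16]
    got <- Re(out$data[, , iz])
    expect_equal(got[inside], lin(k_req[inside]), tolerance = 1e-9)
    expect_true(all(got[!inside] == 0))
  }
  expect_error(stolt_resample(spec, n_kz = 1), "n_kz")
})

test_that("3D inverse transform conserves energy and maps zero to zero", {
  cfg <- ka_cfg(n_freq = 8)
  grid <- small_grid(8)
  echo <- simulate_echo(sar_scene(0.005, -0.005, 0.01), grid, cfg)
  spec <- stolt_resample(matched_filter_phase(forward_2d_transform(echo)))
  vol <- inverse_3d_transform(spec)
  expect_equal(energy(vol$data), energy(spec$data), tolerance = 1e-9)
  zspec <- spec
  zspec$data[] <- 0
  expect_true(all(inverse_3d_transform(zspec)$data == 0))
})

test_that("reconstruction focuses point targets within one voxel", {
  cfg <- radar_config(n_freq = 32, R0 = 0.5)
  grid <- aperture_grid(nx = 32, ny = 32)
  withr::with_seed(11, {
    for (trial in 1:8) {
      pos <- c(runif(1, -0.05, 0.05), runif(1, -0.06, 0.06),
               runif(1, -0.04, 0.04))
      echo <- simulate_echo(sar_scene(pos[1], pos[2], pos[3]), grid, cfg)
      vol <- reconstruct(echo, pad = 2)
      pk <- peak_voxel(vol)$coords
      expect_lt(abs(pk["x"] - pos[1]), diff(vol$x_axis[1:2]))
      expect_lt(abs(pk["y"] - pos[2]), diff(vol$y_axis[1:2]))
      expect_lt(abs(pk["z"] - pos[3]), diff(vol$z_axis[1:2]))
    }
  })
})

test_that("reconstruction is shift-equivariant in x", {
  cfg <- radar_config(n_freq = 16, R0 = 0.5)
  grid <- aperture_grid(nx = 32, ny = 32)
  e1 <- simulate_echo(sar_scene(0, 0.01, 0.02), grid, cfg)
  e2 <- simulate_echo(sar_scene(0.02, 0.01, 0.02), grid, cfg)
  p1 <- peak_voxel(reconstruct(e1, pad = 2))$coords
  p2 <- peak_voxel(reconstruct(e2, pad = 2))$coords
  expect_equal(p2["x"] - p1["x"], c(x = 0.02), tolerance = 1e-9)
  expect_equal(p2["y"], p1["y"], tolerance = 1e-9)
})

test_that("evanescent spectrum samples never influence the image", {
  cfg <- ka_cfg(n_freq = 8, R0 = 0.3)
  grid <- aperture_grid(nx = 12, ny = 12, dx = 0.002, dy = 0.002)
  echo <- simulate_echo(sar_scene(0.004, -0.002, 0.01), grid, cfg)
  spec <- forward_2d_transform(echo)
  spec2 <- spec
  kr2 <- outer(spec$kx_axis^2, spec$ky_axis^2, "+")
  withr::with_seed(5, {
    for (ik in seq_along(spec$k_axis)) {
      ev <- kr2 >= 4 * spec$k_axis[ik]^2
      slab <- spec2$data[, , ik]
      slab[ev] <- complex(real = rnorm(sum(ev)), imaginary = rnorm(sum(ev)))
      spec2$data[, , ik] <- slab
    }
  })
  v1 <- inverse_3d_transform(stolt_resample(matched_filter_phase(spec)))
  v2 <- inverse_3d_transform(stolt_resample(matched_filter_phase(spec2)))
  expect_identical(v1$data, v2$data)
})

test_that("back-projection agrees with the wavenumber-domain image", {
  cfg <- radar_config(n_freq = 16, R0 = 0.5)
  grid <- aperture_grid(nx = 32, ny = 32)
  # keep the target off voxel-boundary midpoints so the argmax is unambiguous
  sc <- sar_scene(0.01, -0.012, 0.02)
  echo <- simulate_echo(sc, grid, cfg)
  vol <- reconstruct(echo, pad = 2)
  bp <- backproject(echo, vol$x_axis, vol$y_axis, vol$z_axis)
  a <- Mod(vol$data); b <- Mod(bp$data)
  corr <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gte(corr, 0.9)
  expect_equal(peak_voxel(vol)$index, peak_voxel(bp)$index)
  zecho <- echo
  zecho$data[] <- 0
  expect_true(all(backproject(zecho, vol$x_axis, vol$y_axis,
                              vol$z_axis)$data == 0))
})

test_that("projection to a detection image normalizes and orients", {
  vol <- new_test_volume()
  vol$data[5, 3, 2] <- 10 + 0i
  img <- project_to_image(vol, "max")
  expect_equal(max(img$pixels), 1)
  # rows run along y, columns along x
  expect_equal(which(img$pixels == 1, arr.ind = TRUE)[1, ], c(row = 3, col = 5))
  raw_max <- project_to_image(vol, "max", normalize = FALSE)$pixels
  raw_sum <- project_to_image(vol, "sum", normalize = FALSE)$pixels
  expect_true(all(raw_max <= raw_sum + 1e-12))
  zvol <- new_test_volume()
  expect_true(all(project_to_image(zvol, "max")$pixels == 0))
})
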