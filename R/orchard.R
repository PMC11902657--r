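#' Synthetic orchard scene recipe
#'
#' Parameters of the statistical scene model used to generate labelled
#' SAR-like orchard imagery: apples are compact clusters of a few weak
#' quasi-point scatterers; branches are chains of strong colinear
#' scatterers; leaves are a diffuse background of weak Rayleigh-amplitude
#' scatterers; a stated fraction of apples is embedded in locally densified
#' foliage (occlusion). The apple amplitude band must sit strictly below
#' the branch band, enforcing the weak-scatterer regime.
#'
#' @param n_images Number of images to render.
#' @param image_size Image side length in pixels.
#' @param pixel_pitch Metres per pixel (default 4 mm, the horizontal
#'   sampling interval of the imaging prototype).
#' @param apples_per_image Inclusive integer range.
#' @param apple_radius Apple radius range in metres.
#' @param apple_amplitude Apple reflectivity band (relative amplitude).
#' @param branch_segments Inclusive integer range of branch chains.
#' @param branch_amplitude Branch reflectivity band; must exceed the apple
#'   band.
#' @param leaf_density Leaf scatterers per square metre.
#' @param leaf_scale Rayleigh scale of leaf amplitudes.
#' @param speckle_looks Effective number of incoherent looks for the
#'   multiplicative speckle model.
#' @param occlusion_fraction Fraction of apples placed inside a dense leaf
#'   pocket.
#' @param noise_floor Additive amplitude noise level after speckle.
#' @param z_extent Depth range of the scene in metres.
#' @param seed Integer seed; every derived randomness is reproducible.
#' @return An `orchard_params` list.
#' @export
orchard_params <- function(n_images = 20, image_size = 128,
                           pixel_pitch = 0.004,
                           apples_per_image = c(2, 5),
                           apple_radius = c(0.025, 0.045),
                           apple_amplitude = c(0.25, 0.5),
                           branch_segments = c(2, 4),
                           branch_amplitude = c(0.9, 1.6),
                           leaf_density = 600,
                           leaf_scale = 0.08,
                           speckle_looks = 4,
                           occlusion_fraction = 0.3,
                           noise_floor = 0.02,
                           z_extent = c(-0.05, 0.05),
                           seed = 1L) {
  stopifnot(apples_per_image[1] <= apples_per_image[2],
            apple_amplitude[1] < apple_amplitude[2],
            branch_amplitude[1] < branch_amplitude[2],
            occlusion_fraction >= 0, occlusion_fraction <= 1,
            speckle_looks >= 1)
  if (apple_amplitude[2] >= branch_amplitude[1]) {
    stop("apple amplitude band must lie strictly below the branch band")
  }
  structure(as.list(environment()), class = "orchard_params")
}

scene_halfwidth <- function(params) params$image_size * params$pixel_pitch / 2

#' Draw one random orchard scene
#'
#' @param params An [orchard_params()].
#' @param seed Integer seed for this scene.
#' @return A list: `scene` (a [sar_scene()]), and `apples`, a data frame of
#'   cluster records (centre, radius, scatterer count, spatial extent in
#'   metres).
#' @export
sample_orchard_scene <- function(params, seed = params$seed) {
  hw <- scene_halfwidth(params)
  with_local_seed(seed, {
    xs <- ys <- zs <- amp <- numeric(0)
    # --- apples: compact clusters of 1-5 weak point scatterers ----------
    n_app <- sample(params$apples_per_image[1]:params$apples_per_image[2], 1)
    centers <- matrix(numeric(0), ncol = 3)
    radii <- numeric(0)
    placed <- 0
    tries <- 0
    while (placed < n_app && tries < 50 * n_app) {
      tries <- tries + 1
      r <- stats::runif(1, params$apple_radius[1], params$apple_radius[2])
      cx <- stats::runif(1, -hw + r + 0.02, hw - r - 0.02)
      cy <- stats::runif(1, -hw + r + 0.02, hw - r - 0.02)
      cz <- stats::runif(1, params$z_extent[1], params$z_extent[2])
      if (placed > 0) {
        dmin <- min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2))
        if (dmin < r + max(radii) + 0.02) next
      }
      centers <- rbind(centers, c(cx, cy, cz))
      radii <- c(radii, r)
      placed <- placed + 1
    }
    if (placed < n_app) {
      message(sprintf("orchard scene: placed %d of %d apples after retries",
                      placed, n_app))
    }
    apples <- NULL
    for (i in seq_len(placed)) {
      m <- sample(1:5, 1)
      # points inside the apple sphere (rejection-free: scaled ball draw)
      u <- matrix(stats::rnorm(3 * m), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      rr <- radii[i] * stats::runif(m)^(1 / 3)
      pts <- sweep(u * rr, 2, centers[i, ], "+")
      a <- stats::runif(m, params$apple_amplitude[1],
                        params$apple_amplitude[2])
      xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2]); zs <- c(zs, pts[, 3])
      amp <- c(amp, a)
      apples <- rbind(apples, data.frame(
        cx = centers[i, 1], cy = centers[i, 2], cz = centers[i, 3],
        radius = radii[i], n_points = m,
        x_min = centers[i, 1] - radii[i], x_max = centers[i, 1] + radii[i],
        y_min = centers[i, 2] - radii[i], y_max = centers[i, 2] + radii[i]))
    }
    # --- branches: colinear chains of strong scatterers -----------------
    n_br <- sample(params$branch_segments[1]:params$branch_segments[2], 1)
    for (b in seq_len(n_br)) {
      len <- stats::runif(1, 0.15, 0.4)
      ang <- stats::runif(1, 0, pi)
      x0 <- stats::runif(1, -hw, hw); y0 <- stats::runif(1, -hw, hw)
      z0 <- stats::runif(1, params$z_extent[1], params$z_extent[2])
      npt <- max(2, round(len / 0.01))
      tt <- seq(0, len, length.out = npt)
      bx <- x0 + tt * cos(ang); by <- y0 + tt * sin(ang)
      inside <- abs(bx) < hw & abs(by) < hw
      if (!any(inside)) next
      a <- stats::runif(sum(inside), params$branch_amplitude[1],
                        params$branch_amplitude[2])
      xs <- c(xs, bx[inside]); ys <- c(ys, by[inside])
      zs <- c(zs, rep(z0, sum(inside)))
      amp <- c(amp, a)
    }
    # --- leaves: diffuse weak Rayleigh clutter --------------------------
    n_leaf <- stats::rpois(1, params$leaf_density * (2 * hw)^2)
    if (n_leaf > 0) {
      lx <- stats::runif(n_leaf, -hw, hw)
      ly <- stats::runif(n_leaf, -hw, hw)
      lz <- stats::runif(n_leaf, params$z_extent[1], params$z_extent[2])
      la <- params$leaf_scale * sqrt(-2 * log(stats::runif(n_leaf)))
      xs <- c(xs, lx); ys <- c(ys, ly); zs <- c(zs, lz); amp <- c(amp, la)
    }
    # --- occlusion: densified foliage pockets around some apples --------
    if (!is.null(apples) && params$occlusion_fraction > 0) {
      n_occ <- round(params$occlusion_fraction * nrow(apples))
      if (n_occ > 0) {
        for (i in sample(seq_len(nrow(apples)), n_occ)) {
          m <- 25
          ox <- stats::rnorm(m, apples$cx[i], 1.5 * apples$radius[i])
          oy <- stats::rnorm(m, apples$cy[i], 1.5 * apples$radius[i])
          oz <- stats::runif(m, params$z_extent[1], params$z_extent[2])
          oa <- params$leaf_scale * sqrt(-2 * log(stats::runif(m)))
          xs <- c(xs, ox); ys <- c(ys, oy); zs <- c(zs, oz)
          amp <- c(amp, oa)
        }
      }
    }
    ext <- list(x = c(-hw, hw), y = c(-hw, hw), z = params$z_extent)
    list(scene = sar_scene(xs, ys, zs, reflectivity = amp, extent = ext),
         apples = if (is.null(apples)) {
           data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      radius = numeric(0), n_points = integer(0),
                      x_min = numeric(0), x_max = numeric(0),
                      y_min = numeric(0), y_max = numeric(0))
         } else apples)
  })
}

.orchard_env <- new.env(parent = emptyenv())

#' Measured point-spread function
#'
#' Runs the physics chain (echo simulation + range-migration
#' reconstruction) for a unit point scatterer at the origin on a small
#' aperture matched to the requested pixel pitch, and returns the
#' peak-normalized 2D magnitude patch together with its half-power radius
#' in pixels. Cached per pitch.
#'
#' @param pixel_pitch Metres per pixel.
#' @param patch Patch side length (odd).
#' @param cfg Radar configuration used for the measurement.
#' @return List: `psf` (patch x patch magnitude, peak 1), `halfwidth_px`.
#' @export
measure_psf <- function(pixel_pitch = 0.004, patch = 15,
                        cfg = radar_config(n_freq = 32)) {
  key <- sprintf("psf_%g_%d", pixel_pitch, patch)
  hit <- .orchard_env[[key]]
  if (!is.null(hit)) return(hit)
  n_ap <- 32
  grid <- aperture_grid(nx = n_ap, ny = n_ap, dx = pixel_pitch,
                        dy = pixel_pitch)
  echo <- simulate_echo(sar_scene(0, 0, 0), grid, cfg)
  vol <- reconstruct(echo, pad = 2)
  img <- project_to_image(vol, "max")$pixels
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  half <- (patch - 1) / 2
  rows <- pk[1] + (-half:half); cols <- pk[2] + (-half:half)
  ok_r <- rows >= 1 & rows <= nrow(img)
  ok_c <- cols >= 1 & cols <= ncol(img)
  psf <- matrix(0, patch, patch)
  psf[which(ok_r), which(ok_c)] <- img[rows[ok_r], cols[ok_c]]
  psf <- psf / max(psf)
  hw_px <- max(1, sum(psf[half + 1, ] >= 0.5) / 2)
  out <- list(psf = psf, halfwidth_px = hw_px)
  .orchard_env[[key]] <- out
  out
}

#' Unit-mean multiplicative speckle field
#'
#' Multi-look intensity speckle: per-pixel Gamma(shape = looks,
#' rate = looks) draws, mean exactly 1.
#'
#' @param h,w Field size in pixels.
#' @param looks Number of looks (1 = fully developed single-look speckle).
#' @param seed Integer seed.
#' @return `h x w` matrix of positive multipliers with unit mean.
#' @export
speckle_field <- function(h, w, looks = 4, seed = 1L) {
  with_local_seed(seed, {
    matrix(stats::rgamma(h * w, shape = looks, rate = looks), h, w)
  })
}

scene_to_boxes <- function(apples, params, pad_px) {
  hw <- scene_halfwidth(params)
  n <- params$image_size
  to_px <- function(v) (v + hw) / params$pixel_pitch
  if (nrow(apples) == 0) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  }
  b <- data.frame(
    x1 = pmax(0, to_px(apples$x_min) - pad_px),
    y1 = pmax(0, to_px(apples$y_min) - pad_px),
    x2 = pmin(n, to_px(apples$x_max) + pad_px),
    y2 = pmin(n, to_px(apples$y_max) + pad_px))
  b[b$x2 > b$x1 & b$y2 > b$y1, , drop = FALSE]
}

render_fast <- function(scn, params, seed) {
  n <- params$image_size
  hw <- scene_halfwidth(params)
  psf <- measure_psf(params$pixel_pitch)
  patch <- nrow(psf$psf)
  half <- (patch - 1) / 2
  amp_img <- matrix(0, n, n)
  sc <- scn$scene
  for (i in seq_along(sc$x)) {
    c0 <- round((sc$x[i] + hw) / params$pixel_pitch + 0.5)
    r0 <- round((sc$y[i] + hw) / params$pixel_pitch + 0.5)
    rows <- (r0 - half):(r0 + half)
    cols <- (c0 - half):(c0 + half)
    ok_r <- rows >= 1 & rows <= n
    ok_c <- cols >= 1 & cols <= n
    if (!any(ok_r) || !any(ok_c)) next
    amp_img[rows[ok_r], cols[ok_c]] <- amp_img[rows[ok_r], cols[ok_c]] +
      Mod(sc$reflectivity[i]) * psf$psf[which(ok_r), which(ok_c)]
  }
  spk <- speckle_field(n, n, params$speckle_looks, seed = seed + 7L)
  noise <- with_local_seed(seed + 13L,
                           matrix(abs(stats::rnorm(n * n,
                                                   sd = params$noise_floor)),
                                  n, n))
  img <- sqrt(amp_img^2 * spk) + noise
  mx <- max(img)
  if (mx > 0) img <- img / mx
  new_detection_image(img, pitch = rep(params$pixel_pitch, 2),
                      note = "fast-mode render")
}

render_physics <- function(scn, params, cfg = radar_config(n_freq = 32)) {
  n <- params$image_size
  grid <- aperture_grid(nx = n, ny = n, dx = params$pixel_pitch,
                        dy = params$pixel_pitch)
  echo <- simulate_echo(scn$scene, grid, cfg)
  vol <- reconstruct(echo, pad = 2, z_window = params$z_extent * 2)
  img <- project_to_image(vol, "max")
  img$note <- "physics-mode render"
  img
}

#' Render a labelled synthetic dataset
#'
#' `"physics"` mode chains echo simulation, range-migration reconstruction
#' and range projection for every image (slow; meant for small fixture
#' sets). `"fast"` mode stamps the measured PSF at every scatterer
#' position and applies unit-mean multiplicative speckle (training-scale
#' data). Ground-truth boxes are the projected apple-cluster extents
#' padded by one PSF half-width.
#'
#' @param params An [orchard_params()].
#' @param mode `"fast"` (default) or `"physics"`.
#' @return List of annotated samples -- each a list with `image`
#'   (`detection_image`), `boxes` (corner-form pixel data frame), `scene`
#'   -- plus a `manifest` attribute recording seed, mode and parameters.
#' @export
render_orchard_dataset <- function(params, mode = c("fast", "physics")) {
  mode <- match.arg(mode)
  psf <- measure_psf(params$pixel_pitch)
  samples <- vector("list", params$n_images)
  for (i in seq_len(params$n_images)) {
    sd_i <- params$seed + 1000L * i
    scn <- sample_orchard_scene(params, seed = sd_i)
    image <- if (mode == "fast") render_fast(scn, params, seed = sd_i)
    else render_physics(scn, params)
    boxes <- scene_to_boxes(scn$apples, params, pad_px = psf$halfwidth_px)
    samples[[i]] <- list(image = image, boxes = boxes, scene = scn$scene,
                         id = i)
  }
  attr(samples, "manifest") <- list(
    seed = params$seed, mode = mode, n_images = params$n_images,
    image_size = params$image_size, pixel_pitch = params$pixel_pitch,
    psf_halfwidth_px = psf$halfwidth_px)
  samples
}

#' Deterministic train/test split
#'
#' Shuffles with the given seed and splits at `ratio` (train fraction,
#' default 0.7, i.e. the usual 7:3 protocol: 150 samples give 105/45).
#'
#' @param samples A list of samples.
#' @param ratio Train fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` sample lists.
#' @export
split_dataset <- function(samples, ratio = 0.7, seed = 1L) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples to split")
  stopifnot(ratio > 0, ratio < 1)
  ord <- with_local_seed(seed, sample.int(n))
  n_train <- round(ratio * n)
  n_train <- min(max(n_train, 1), n - 1)
  list(train = samples[ord[seq_len(n_train)]],
       test = samples[ord[(n_train + 1):n]])
}

#' Augment an annotated sample
#'
#' Horizontal flip, integer-pixel translation (zero padded) and additive
#' Gaussian noise (re-clipped to `[0, 1]`), with boxes transformed
#' consistently.
#'
#' @param sample An annotated sample (list with `image`, `boxes`).
#' @param hflip Mirror horizontally.
#' @param translate Length-2 integer pixel shift `(dx, dy)`.
#' @param noise_sd Additive Gaussian noise standard deviation (0 = none).
#' @param seed Seed for the noise draw.
#' @return The augmented sample.
#' @export
augment_sample <- function(sample, hflip = FALSE, translate = c(0, 0),
                           noise_sd = 0, seed = 1L) {
  img <- sample$image$pixels
  boxes <- sample$boxes
  h <- nrow(img); w <- ncol(img)
  if (isTRUE(hflip)) {
    img <- img[, rev(seq_len(w)), drop = FALSE]
    if (nrow(boxes) > 0) {
      boxes <- data.frame(x1 = w - boxes$x2, y1 = boxes$y1,
                          x2 = w - boxes$x1, y2 = boxes$y2)
    }
  }
  dx <- as.integer(translate[1]); dy <- as.integer(translate[2])
  if (dx != 0 || dy != 0) {
    out <- matrix(0, h, w)
    src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
    ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
    out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
    img <- out
    if (nrow(boxes) > 0) {
      boxes <- data.frame(x1 = pmax(0, boxes$x1 + dx),
                          y1 = pmax(0, boxes$y1 + dy),
                          x2 = pmin(w, boxes$x2 + dx),
                          y2 = pmin(h, boxes$y2 + dy))
      boxes <- boxes[boxes$x2 > boxes$x1 & boxes$y2 > boxes$y1, ,
                     drop = FALSE]
    }
  }
  if (noise_sd > 0) {
    img <- img + with_local_seed(seed,
                                 matrix(stats::rnorm(h * w, sd = noise_sd),
                                        h, w))
    img <- pmin(pmax(img, 0), 1)
  }
  sample$image$pixels <- img
  sample$boxes <- boxes
  sample
}
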