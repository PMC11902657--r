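test_that("scene sampling is reproducible and structured", {
  op <- orchard_params(seed = 3)
  s1 <- sample_orchard_scene(op, seed = 21)
  s2 <- sample_orchard_scene(op, seed = 21)
  expect_identical(s1, s2)
  s3 <- sample_orchard_scene(op, seed = 22)
  expect_false(identical(s1$scene$x, s3$scene$x))
  expect_gte(nrow(s1$apples), op$apples_per_image[1])
  # scatterers stay inside the stated extent
  hw <- op$image_size * op$pixel_pitch / 2
  expect_true(all(abs(s1$scene$x) <= hw + 3 * 1.5 * max(op$apple_radius)))
})

test_that("apple reflectivity sits below branch reflectivity by design", {
  expect_error(orchard_params(apple_amplitude = c(0.5, 1.0),
                              branch_amplitude = c(0.9, 1.6)),
               "strictly below")
  # sampled bands respect the configured ordering on average
  op <- orchard_params(seed = 1)
  apple_means <- branch_means <- numeric(0)
  for (i in 1:100) {
    scn <- sample_orchard_scene(op, seed = 100 + i)
    amp <- Mod(scn$scene$reflectivity)
    apple_idx <- seq_len(sum(scn$apples$n_points))
    apple_means <- c(apple_means, mean(amp[apple_idx]))
    strong <- amp >= op$branch_amplitude[1]
    if (any(strong)) branch_means <- c(branch_means, mean(amp[strong]))
  }
  expect_lt(mean(apple_means), mean(branch_means))
})

test_that("a clutter-only recipe yields no boxes", {
  op <- orchard_params(n_images = 2, image_size = 64,
                       apples_per_image = c(0, 0), seed = 5)
  ds <- render_orchard_dataset(op, "fast")
  expect_length(ds, 2)
  for (s in ds) expect_equal(nrow(s$boxes), 0)
})

test_that("speckle is multiplicative with unit mean", {
  s <- speckle_field(256, 256, looks = 4, seed = 9)
  expect_true(all(s > 0))
  expect_equal(mean(s), 1, tolerance = 0.02)
  expect_identical(s, speckle_field(256, 256, looks = 4, seed = 9))
  # single-look speckle is exponential: variance ~ 1
  s1 <- speckle_field(256, 256, looks = 1, seed = 10)
  expect_equal(stats::var(as.vector(s1)), 1, tolerance = 0.05)
})

test_that("fast rendering produces labelled images in [0,1]", {
  op <- orchard_params(n_images = 4, image_size = 64, seed = 8)
  ds <- render_orchard_dataset(op, "fast")
  expect_length(ds, 4)
  for (s in ds) {
    expect_true(all(s$image$pixels >= 0 & s$image$pixels <= 1))
    expect_equal(dim(s$image$pixels), c(64, 64))
    expect_true(nrow(s$boxes) >= 0)
    expect_true(all(s$boxes$x2 <= 64 & s$boxes$y2 <= 64))
  }
  manifest <- attr(ds, "manifest")
  expect_equal(manifest$n_images, 4)
})

test_that("physics rendering focuses an isolated apple inside its box", {
  op <- orchard_params(n_images = 1, image_size = 64,
                       apples_per_image = c(1, 1),
                       branch_segments = c(0, 0), leaf_density = 0,
                       occlusion_fraction = 0, seed = 31)
  ds <- render_orchard_dataset(op, "physics")
  s <- ds[[1]]
  expect_equal(nrow(s$boxes), 1)
  pk <- which(s$image$pixels == max(s$image$pixels), arr.ind = TRUE)[1, ]
  # pixel (r, c) covers x in [c-1, c), y in [r-1, r)
  expect_gte(pk["col"], s$boxes$x1)
  expect_lte(pk["col"], s$boxes$x2 + 1)
  expect_gte(pk["row"], s$boxes$y1)
  expect_lte(pk["row"], s$boxes$y2 + 1)
})

test_that("denser foliage never darkens the clutter background", {
  mk <- function(density) {
    op <- orchard_params(n_images = 1, image_size = 64,
                         apples_per_image = c(0, 0),
                         branch_segments = c(0, 0),
                         leaf_density = density, seed = 12)
    render_orchard_dataset(op, "fast")[[1]]$image
  }
  # compare un-normalized content via the mean of the rendered field
  lo <- mk(150)
  hi <- mk(900)
  expect_gte(sum(hi$pixels > 0.1), sum(lo$pixels > 0.1))
})

test_that("the 7:3 split is deterministic and sized correctly", {
  fake <- lapply(1:150, function(i) list(id = i))
  sp <- split_dataset(fake, ratio = 0.7, seed = 2)
  expect_length(sp$train, 105)
  expect_length(sp$test, 45)
  sp2 <- split_dataset(fake, ratio = 0.7, seed = 2)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(fake, ratio = 0.7, seed = 3)))
  # no sample appears twice
  ids <- c(vapply(sp$train, `[[`, integer(1), "id"),
           vapply(sp$test, `[[`, integer(1), "id"))
  expect_equal(sort(ids), 1:150)
  sp3 <- split_dataset(fake[1:10], ratio = 0.5, seed = 1)
  expect_length(sp3$train, 5)
  expect_error(split_dataset(fake[1], 0.7), "at least 2")
})

test_that("augmentations transform pixels and boxes consistently", {
  img <- matrix(0, 100, 100)
  img[25:35, 15:25] <- 1   # bright blob at rows 25-35, cols 15-25
  sample <- list(image = orchardsar:::new_detection_image(img, c(1, 1)),
                 boxes = data.frame(x1 = 10, y1 = 20, x2 = 30, y2 = 40))
  # mirror: x -> W - x
  flipped <- augment_sample(sample, hflip = TRUE)
  expect_equal(as.numeric(flipped$boxes),
               c(70, 20, 90, 40))
  # flipping twice restores everything
  back <- augment_sample(flipped, hflip = TRUE)
  expect_equal(back$image$pixels, sample$image$pixels)
  expect_equal(as.numeric(back$boxes), as.numeric(sample$boxes))
  # blob stays inside the transformed box after a flip
  blob <- which(flipped$image$pixels == 1, arr.ind = TRUE)
  expect_true(all(blob[, "col"] - 1 >= flipped$boxes$x1 &
                    blob[, "col"] <= flipped$boxes$x2 + 1))
  # null translation is the identity
  same <- augment_sample(sample, translate = c(0, 0))
  expect_identical(same$image$pixels, sample$image$pixels)
  # translation moves pixels and boxes together
  tr <- augment_sample(sample, translate = c(5, -3))
  expect_equal(as.numeric(tr$boxes), c(15, 17, 35, 37))
  blob2 <- which(tr$image$pixels == 1, arr.ind = TRUE)
  expect_equal(range(blob2[, "col"]), c(20, 30))
  expect_equal(range(blob2[, "row"]), c(22, 32))
  # noise stays clipped and is reproducible per seed
  nz1 <- augment_sample(sample, noise_sd = 0.1, seed = 4)
  nz2 <- augment_sample(sample, noise_sd = 0.1, seed = 4)
  expect_identical(nz1$image$pixels, nz2$image$pixels)
  expect_true(all(nz1$image$pixels >= 0 & nz1$image$pixels <= 1))
})
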