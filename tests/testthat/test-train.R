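test_that("a short training run completes, logs and checkpoints", {
  ds <- tiny_dataset(n = 6)
  cfg <- tiny_detector_config()
  m <- fit_detector(ds, cfg, epochs = 1, batch_size = 3, warmup = 5,
                    augment = FALSE, seed = 4)
  expect_s3_class(m, "apple_detector")
  expect_equal(nrow(m$history), 1)
  expect_true(is.finite(m$history$loss[1]))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_detector(m, path)
  back <- load_detector(path)
  expect_equal(back$params, m$params)
  # restored model runs inference
  d <- detect_apples(back, ds[[1]]$image$pixels)
  expect_true(all(c("x1", "score") %in% names(d)))
})

test_that("training is reproducible for a fixed seed", {
  ds <- tiny_dataset(n = 4)
  cfg <- tiny_detector_config()
  m1 <- fit_detector(ds, cfg, epochs = 1, batch_size = 2, warmup = 2,
                     seed = 11)
  m2 <- fit_detector(ds, cfg, epochs = 1, batch_size = 2, warmup = 2,
                     seed = 11)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_equal(m1$params, m2$params)
  m3 <- fit_detector(ds, cfg, epochs = 1, batch_size = 2, warmup = 2,
                     seed = 12)
  expect_false(identical(m1$history$loss, m3$history$loss))
})

test_that("optimizing longer reduces the training loss", {
  ds <- tiny_dataset(n = 4)
  cfg <- tiny_detector_config()
  m <- fit_detector(ds, cfg, epochs = 10, batch_size = 4, warmup = 5,
                    lr = 2e-3, augment = FALSE, seed = 21)
  expect_lt(m$history$loss[10], m$history$loss[1])
})

test_that("momentum SGD is available as an optimizer and also learns", {
  ds <- tiny_dataset(n = 4)
  cfg <- tiny_detector_config()
  m <- fit_detector(ds, cfg, epochs = 4, batch_size = 4, warmup = 2,
                    lr = 5e-3, optimizer = "sgd", augment = FALSE,
                    seed = 31)
  expect_true(all(is.finite(m$history$loss)))
  expect_lt(m$history$loss[4], m$history$loss[1])
})

test_that("the learning-rate schedule warms up and decays", {
  lrs <- vapply(1:200, lr_at_step, numeric(1), total = 200,
                base_lr = 1e-3, warmup = 50)
  expect_equal(lrs[25], 0.5e-3, tolerance = 1e-12)
  expect_equal(lrs[50], 1e-3, tolerance = 1e-12)
  expect_lt(lrs[200], 1e-4)
  expect_true(all(diff(lrs[1:50]) > 0))
  expect_true(all(diff(lrs[51:200]) < 0))
  step <- vapply(1:200, lr_at_step, numeric(1), total = 200,
                 base_lr = 1e-3, warmup = 10, schedule = "step")
  expect_equal(unique(step[11:136]), 1e-3)
  expect_equal(unique(step[138:200]), 1e-4)
})

test_that("perfect and empty detections bound the evaluation", {
  ds <- tiny_dataset(n = 3)
  gts <- do.call(rbind, lapply(ds, function(s)
    if (nrow(s$boxes)) cbind(image_id = s$id, s$boxes)))
  perfect <- cbind(gts, score = 0.9)
  expect_equal(evaluate_detections(perfect, gts)$ap, 100)
  r <- evaluate_detections(perfect[0, ], gts)
  expect_equal(r$ap, 0)
  expect_equal(r$recall, 0)
})

test_that("the pipeline commands chain into a working end-to-end run", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "ds")
  gen <- cmd_gendata(list(orchard = list(n_images = 6, image_size = 64),
                          out_dir = data_dir), seed = 5)
  expect_equal(gen$n_train, 4)
  expect_equal(gen$n_test, 2)
  expect_true(file.exists(file.path(data_dir, "manifest.yaml")))
  # identical seeds give byte-identical datasets
  data_dir2 <- file.path(dir, "ds2")
  cmd_gendata(list(orchard = list(n_images = 6, image_size = 64),
                   out_dir = data_dir2), seed = 5)
  m1 <- yaml::read_yaml(file.path(data_dir, "manifest.yaml"))$images
  m2 <- yaml::read_yaml(file.path(data_dir2, "manifest.yaml"))$images
  expect_identical(m1, m2)
  expect_error(cmd_gendata(list(orchard = list(n_images = 1,
                                               image_size = 64),
                                out_dir = file.path(dir, "bad")),
                           seed = 1),
               "at least 2")
  model <- cmd_train(list(data_dir = data_dir,
                          detector = list(dspp_grids = c(1, 2)),
                          epochs = 1, batch_size = 2, warmup = 2,
                          out_dir = dir),
                     seed = 6)
  expect_true(file.exists(file.path(dir, "detector.ckpt")))
  expect_true(file.exists(file.path(dir, "train_log.json")))
  rep <- cmd_eval(list(data_dir = data_dir, out_dir = dir,
                       checkpoint = file.path(dir, "detector.ckpt")),
                  seed = 7)
  metrics <- jsonlite::fromJSON(file.path(dir, "metrics.json"))
  expect_true(is.finite(metrics$ap))
  if (metrics$precision + metrics$recall > 0) {
    expect_equal(metrics$f1,
                 2 * metrics$precision * metrics$recall /
                   (metrics$precision + metrics$recall),
                 tolerance = 1e-6)
  }
})

test_that("the simulate command reports the focused peak of a scene file", {
  dir <- withr::local_tempdir()
  scene_path <- file.path(dir, "scene.json")
  write_scene_json(sar_scene(0.012, -0.01, 0.02), scene_path)
  rep <- cmd_simulate(list(scene = scene_path, out_dir = dir,
                           radar = list(n_freq = 16),
                           aperture = list(nx = 24, ny = 24,
                                           dx = 0.004, dy = 0.004)),
                      seed = 3)
  expect_true(file.exists(file.path(dir, "echo.osar")))
  expect_true(file.exists(file.path(dir, "volume.osar")))
  expect_lt(abs(rep$peak_coords$x - 0.012), 0.01)
  expect_lt(abs(rep$peak_coords$y + 0.01), 0.01)
  # empty scene: all-zero volume, no error
  write_scene_json(sar_scene(), scene_path)
  expect_warning(
    rep0 <- cmd_simulate(list(scene = scene_path, out_dir = dir,
                              radar = list(n_freq = 8),
                              aperture = list(nx = 8, ny = 8)),
                         seed = 3),
    "empty scene")
  expect_equal(rep0$peak_magnitude, 0)
  # missing files error out
  expect_error(cmd_simulate(list(scene = file.path(dir, "nope.json")),
                            seed = 1), "existing")
  expect_error(cmd_eval(list(data_dir = dir), seed = 1,
                        checkpoint = file.path(dir, "nope.ckpt")),
               "not found")
})
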