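#' @section Parameter trees:
#' Detector parameters live in a nested named list whose leaves are double
#' arrays. The helpers below walk the tree to wrap leaves as differentiable
#' nodes, harvest gradients and apply optimizer updates; integer leaves
#' (structural markers) are left untouched.
#' @name param-tree
NULL

walk_params <- function(params, fn, path = "") {
  if (is.list(params)) {
    for (nm in names(params)) {
      params[[nm]] <- walk_params(params[[nm]], fn,
                                  paste0(path, "/", nm))
    }
    params
  } else if (is.double(params)) {
    fn(params, path)
  } else {
    params
  }
}

wrap_params <- function(params) walk_params(params, function(x, p) ag_param(x))

collect_grads <- function(wrapped) {
  grads <- list()
  walk <- function(node, path) {
    if (is_ag(node)) {
      g <- node$grad
      if (is.null(g)) g <- node$value * 0
      # normalize to the leaf's own shape (vjps may attach or drop dims)
      if (is.null(dim(node$value))) {
        g <- as.vector(g)
      } else {
        dim(g) <- dim(node$value)
      }
      grads[[path]] <<- g
    } else if (is.list(node)) {
      for (nm in names(node)) walk(node[[nm]], paste0(path, "/", nm))
    }
  }
  walk(wrapped, "")
  grads
}

flatten_leaves <- function(params) {
  leaves <- list()
  walk_params(params, function(x, p) {
    leaves[[p]] <<- x
    x
  })
  leaves
}

set_leaves <- function(params, leaves) {
  walk_params(params, function(x, p) leaves[[p]])
}

#' Learning-rate schedule
#'
#' Linear warm-up to the base rate over `warmup` steps, then either a flat
#' rate (`"step"` decays by 10x at 2/3 of training) or cosine annealing to
#' (nearly) zero at `total` steps.
#'
#' @param step Current 1-based optimizer step.
#' @param total Total planned steps.
#' @param base_lr Peak learning rate.
#' @param warmup Warm-up step count.
#' @param schedule `"cosine"` (default) or `"step"`.
#' @return The learning rate for this step.
#' @export
lr_at_step <- function(step, total, base_lr = 1e-3, warmup = 100,
                       schedule = c("cosine", "step")) {
  schedule <- match.arg(schedule)
  if (warmup > 0 && step <= warmup) return(base_lr * step / warmup)
  if (schedule == "cosine") {
    prog <- (step - warmup) / max(1, total - warmup)
    base_lr * 0.5 * (1 + cos(pi * min(1, prog)))
  } else {
    if (step > warmup + 2 / 3 * (total - warmup)) base_lr / 10 else base_lr
  }
}

#' Train the apple detector
#'
#' End-to-end joint optimization of backbone, DSPP, RFN, CAFE and head
#' with Adam, focal + smooth-L1 losses, mini-batch gradient averaging and
#' warm-up/decay learning-rate scheduling. Optional on-the-fly
#' augmentation (random horizontal flip, translation, noise). Aborts with
#' a diagnostic if the loss turns non-finite.
#'
#' @param samples Training samples from [render_orchard_dataset()].
#' @param cfg A [detector_config()].
#' @param epochs Training epochs.
#' @param batch_size Images per optimizer step.
#' @param lr Peak learning rate.
#' @param warmup Warm-up steps.
#' @param schedule `"cosine"` or `"step"`.
#' @param optimizer `"adam"` (default) or `"sgd"` (momentum 0.9).
#' @param augment Apply random flip/translate/noise augmentation.
#' @param val_samples Optional held-out samples; when supplied, AP@0.5 is
#'   computed each epoch and the best-AP parameters are kept.
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation.
#' @param verbose Print per-epoch progress.
#' @return An `apple_detector`: parameters, config, training history.
#' @export
fit_detector <- function(samples, cfg = detector_config(), epochs = 8,
                         batch_size = 8, lr = 1e-3, warmup = 100,
                         schedule = "cosine", optimizer = c("adam", "sgd"),
                         augment = TRUE,
                         val_samples = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(length(samples) >= 1)
  optimizer <- match.arg(optimizer)
  params <- detector_init(cfg, seed = seed)
  imgs <- lapply(samples, function(s) s$image$pixels)
  gts <- lapply(samples, function(s) as.matrix(s$boxes))
  d <- dim(imgs[[1]])
  map_hw <- d / cfg$stride
  anchors <- detector_anchors(map_hw[1], map_hw[2], cfg)
  base_assign <- lapply(gts, function(g) assign_anchors(anchors, g, cfg))
  n <- length(samples)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- steps_per_epoch * epochs
  opt_m <- opt_v <- NULL
  step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_ap = numeric(0))
  best <- list(ap = -Inf, params = params)
  rng_stream <- with_local_seed(seed + 17L,
                                sample.int(.Machine$integer.max %/% 2,
                                           epochs))
  for (ep in seq_len(epochs)) {
    ord <- with_local_seed(rng_stream[ep], sample.int(n))
    ep_loss <- 0
    for (bs in seq_len(steps_per_epoch)) {
      idx <- ord[((bs - 1) * batch_size + 1):min(bs * batch_size, n)]
      step <- step + 1L
      wp <- wrap_params(params)
      loss <- NULL
      for (ii in idx) {
        if (augment) {
          aug_seed <- rng_stream[ep] + 31L * ii
          draw <- with_local_seed(aug_seed, list(
            flip = stats::runif(1) < 0.5,
            shift = sample(-8:8, 2, replace = TRUE),
            noise = stats::runif(1, 0, 0.02)))
          s <- augment_sample(list(image = list(pixels = imgs[[ii]]),
                                   boxes = as.data.frame(gts[[ii]])),
                              hflip = draw$flip, translate = draw$shift,
                              noise_sd = draw$noise, seed = aug_seed)
          img_i <- s$image$pixels
          assign_i <- assign_anchors(anchors, as.matrix(s$boxes), cfg)
        } else {
          img_i <- imgs[[ii]]
          assign_i <- base_assign[[ii]]
        }
        out <- detector_forward(wp, img_i, cfg)
        li <- detector_loss(out, assign_i, cfg)
        loss <- if (is.null(loss)) li else ag_add(loss, li)
      }
      loss <- ag_scale(loss, 1 / length(idx))
      lv <- ag_value(loss)
      if (!is.finite(lv)) {
        stop(sprintf("training diverged at epoch %d step %d (loss %g)",
                     ep, bs, lv))
      }
      ep_loss <- ep_loss + lv
      ag_backward(loss)
      grads <- collect_grads(wp)
      leaves <- flatten_leaves(params)
      if (is.null(opt_m)) {
        opt_m <- lapply(grads, function(g) g * 0)
        opt_v <- opt_m
      }
      lr_t <- lr_at_step(step, total_steps, lr, warmup, schedule)
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (key in names(leaves)) {
        g <- grads[[key]]
        if (optimizer == "adam") {
          opt_m[[key]] <- b1 * opt_m[[key]] + (1 - b1) * g
          opt_v[[key]] <- b2 * opt_v[[key]] + (1 - b2) * g^2
          mhat <- opt_m[[key]] / (1 - b1^step)
          vhat <- opt_v[[key]] / (1 - b2^step)
          leaves[[key]] <- leaves[[key]] - lr_t * mhat / (sqrt(vhat) + eps)
        } else {
          opt_m[[key]] <- b1 * opt_m[[key]] + g
          leaves[[key]] <- leaves[[key]] - lr_t * opt_m[[key]]
        }
      }
      params <- set_leaves(params, leaves)
    }
    ep_loss <- ep_loss / steps_per_epoch
    val_ap <- NA_real_
    if (!is.null(val_samples)) {
      tmp <- structure(list(params = params, cfg = cfg),
                       class = "apple_detector")
      val_ap <- evaluate_model(tmp, val_samples)$ap
      if (val_ap > best$ap) best <- list(ap = val_ap, params = params)
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss, val_ap = val_ap))
    if (verbose) {
      cat(sprintf("epoch %d/%d  loss %.4f%s\n", ep, epochs, ep_loss,
                  if (is.na(val_ap)) "" else sprintf("  val AP %.1f%%",
                                                     val_ap)))
    }
  }
  final_params <- if (is.finite(best$ap)) best$params else params
  structure(list(params = final_params, cfg = cfg, history = history,
                 seed = seed, epochs = epochs),
            class = "apple_detector")
}

#' @export
print.apple_detector <- function(x, ...) {
  cat(sprintf("<apple_detector> %d epochs trained; final loss %.4f\n",
              nrow(x$history), utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Evaluate a detector on annotated samples
#'
#' Runs inference on every sample and scores the pooled detections with
#' [evaluate_detections()] (AP/Recall/F1 at IoU 0.5).
#'
#' @param model An `apple_detector`.
#' @param samples Annotated samples.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, samples) {
  dets <- NULL
  gts <- NULL
  for (s in samples) {
    d <- detect_apples(model, s$image$pixels)
    if (nrow(d) > 0) dets <- rbind(dets, cbind(image_id = s$id, d))
    if (nrow(s$boxes) > 0) gts <- rbind(gts, cbind(image_id = s$id, s$boxes))
  }
  evaluate_detections(dets, gts)
}

#' Save / load detector checkpoints
#'
#' A checkpoint is a single serialized file holding the parameters, the
#' configuration snapshot and the training history.
#'
#' @param model An `apple_detector`.
#' @param path Checkpoint file path.
#' @return `save_detector()` returns `path` invisibly; `load_detector()`
#'   the restored `apple_detector`.
#' @export
save_detector <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  structure(readRDS(path), class = "apple_detector")
}
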