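#' Detector configuration
#'
#' A compact, CPU-trainable detector with the architecture: convolutional
#' backbone producing four feature scales (C2..C5, strides 4/8/16/32),
#' dynamic spatial pyramid pooling on C5, recursive fusion of all four
#' scales at the C3 resolution, non-local context enhancement, and a
#' RetinaNet-style anchor head (3 scales x 3 aspect ratios per position)
#' with focal classification loss and smooth-L1 box regression.
#'
#' @param channels Backbone channel widths: stem then C2..C5.
#' @param fusion_width Channel width of the fused map.
#' @param rfn_iterations Recursive fusion passes `T`.
#' @param dspp_grids DSPP pyramid grid sizes (must fit the C5 map).
#' @param anchor_sizes,anchor_ratios Anchor box generators (pixels /
#'   height-to-width ratios).
#' @param use_dspp,use_rfn,use_cafe Module switches; turning all three off
#'   yields the plain base detector used as the ablation reference (single
#'   pass resize-project-sum fusion, raw C5).
#' @param focal_alpha,focal_gamma,smooth_l1_beta Loss constants.
#' @param pos_iou,neg_iou Anchor assignment thresholds (in between:
#'   ignored).
#' @param score_min,nms_iou Inference-time score floor and NMS threshold.
#' @return A `detector_config` list.
#' @export
detector_config <- function(channels = c(8, 16, 24, 32, 40),
                            fusion_width = 32,
                            rfn_iterations = 2,
                            dspp_grids = c(1, 2, 4),
                            anchor_sizes = c(16, 22, 28),
                            anchor_ratios = c(0.75, 1, 4 / 3),
                            use_dspp = TRUE, use_rfn = TRUE,
                            use_cafe = TRUE,
                            focal_alpha = 0.25, focal_gamma = 2,
                            smooth_l1_beta = 1 / 9,
                            pos_iou = 0.5, neg_iou = 0.4,
                            score_min = 0.05, nms_iou = 0.5) {
  stopifnot(length(channels) == 5)
  structure(list(
    channels = channels, fusion_width = fusion_width,
    rfn_iterations = rfn_iterations, dspp_grids = dspp_grids,
    anchor_sizes = anchor_sizes, anchor_ratios = anchor_ratios,
    use_dspp = use_dspp, use_rfn = use_rfn, use_cafe = use_cafe,
    focal_alpha = focal_alpha, focal_gamma = focal_gamma,
    smooth_l1_beta = smooth_l1_beta,
    pos_iou = pos_iou, neg_iou = neg_iou,
    score_min = score_min, nms_iou = nms_iou,
    stride = 8), class = "detector_config")
}

conv_init <- function(kh, kw, c_in, c_out, gain = 2) {
  matrix(stats::rnorm(kh * kw * c_in * c_out,
                      sd = sqrt(gain / (kh * kw * c_in))),
         kh * kw * c_in, c_out)
}

#' Initialize detector parameters
#'
#' He-initialized convolutions; the classification head bias starts at the
#' usual rare-foreground prior (`-log((1-pi)/pi)`, `pi = 0.01`) and the
#' CAFE output projection at zero (identity residual block).
#'
#' @param cfg A [detector_config()].
#' @param seed Integer seed.
#' @return Nested named list of parameter arrays.
#' @export
detector_init <- function(cfg = detector_config(), seed = 1L) {
  ch <- cfg$channels
  na <- length(cfg$anchor_sizes) * length(cfg$anchor_ratios)
  with_local_seed(seed, {
    block <- function(c_in, c_out) {
      list(w1 = conv_init(3, 3, c_in, c_out), b1 = numeric(c_out),
           w2 = conv_init(3, 3, c_out, c_out), b2 = numeric(c_out))
    }
    params <- list(
      stem = block(1, ch[1]),
      c2 = block(ch[1], ch[2]),
      c3 = block(ch[2], ch[3]),
      c4 = block(ch[3], ch[4]),
      c5 = block(ch[4], ch[5]),
      dspp = dspp_init(ch[5],
                       pyramid_config(cfg$dspp_grids, pool_kind = "average"),
                       seed = seed + 1L),
      rfn = rfn_init(ch[2:5],
                     rfn_config(width = cfg$fusion_width, ref_level = 2,
                                iterations = cfg$rfn_iterations),
                     seed = seed + 2L),
      cafe = cafe_init(cfg$fusion_width, seed = seed + 3L),
      head = list(
        w1 = conv_init(3, 3, cfg$fusion_width, cfg$fusion_width),
        b1 = numeric(cfg$fusion_width),
        w2 = conv_init(3, 3, cfg$fusion_width, cfg$fusion_width),
        b2 = numeric(cfg$fusion_width),
        cls_w = conv_init(3, 3, cfg$fusion_width, na, gain = 0.01),
        cls_b = rep(-log((1 - 0.01) / 0.01), na),
        reg_w = conv_init(3, 3, cfg$fusion_width, 4 * na, gain = 0.01),
        reg_b = numeric(4 * na)
      ))
    params
  })
}

conv_block <- function(x, p, stride) {
  x <- ag_relu(ag_conv2d(x, p$w1, p$b1, stride = stride, pad = 1))
  ag_relu(ag_conv2d(x, p$w2, p$b2, stride = 1, pad = 1))
}

#' Detector forward pass
#'
#' Runs the backbone and the enabled modules, returning per-anchor
#' classification logits and box-regression offsets. Works on plain arrays
#' (inference) or `ag_tensor` parameters (training).
#'
#' @param params Parameters from [detector_init()] (possibly wrapped as
#'   `ag_tensor`s).
#' @param image `H x W` numeric matrix in `[0, 1]` (H, W multiples of 32).
#' @param cfg The [detector_config()].
#' @return List: `cls` (`N x 1` logits), `reg` (`N x 4` offsets), `fmap`
#'   (the head input map), and `map_dim` (its `H' x W'`).
#' @export
detector_forward <- function(params, image, cfg = detector_config()) {
  d <- dim(image)
  x <- array(image, dim = c(d[1], d[2], 1))
  stem <- conv_block(x, params$stem, stride = 2)
  c2 <- conv_block(stem, params$c2, stride = 2)
  c3 <- conv_block(c2, params$c3, stride = 2)
  c4 <- conv_block(c3, params$c4, stride = 2)
  c5 <- conv_block(c4, params$c5, stride = 2)
  if (cfg$use_dspp) {
    dcfg <- pyramid_config(cfg$dspp_grids, pool_kind = "average")
    c5 <- dspp_forward(c5, params$dspp, dcfg)$enhanced_map
  }
  rcfg <- rfn_config(width = cfg$fusion_width, ref_level = 2,
                     iterations = cfg$rfn_iterations)
  fused <- if (cfg$use_rfn) {
    recursive_refine(list(c2, c3, c4, c5), params$rfn, rcfg)
  } else {
    rfn_base_fuse(list(c2, c3, c4, c5), params$rfn, rcfg)
  }
  if (cfg$use_cafe) fused <- cafe_forward(fused, params$cafe)
  c(head_forward(fused, params$head), list(fmap = fused))
}

#' Anchor head on a feature map
#'
#' Two shared 3x3 conv+ReLU layers followed by sibling 3x3 convolutions
#' producing one classification logit and four box offsets per anchor per
#' position. Output rows are ordered feature-row fastest, then column,
#' then anchor shape (matching [detector_anchors()]).
#'
#' @param fmap Feature map `H' x W' x C` (array or `ag_tensor`).
#' @param head Head parameter list (see [detector_init()]).
#' @return List: `cls` (`N x 1`), `reg` (`N x 4`), `map_dim`.
#' @export
head_forward <- function(fmap, head) {
  h <- ag_relu(ag_conv2d(fmap, head$w1, head$b1, pad = 1))
  h <- ag_relu(ag_conv2d(h, head$w2, head$b2, pad = 1))
  cls <- ag_conv2d(h, head$cls_w, head$cls_b, pad = 1)
  reg <- ag_conv2d(h, head$reg_w, head$reg_b, pad = 1)
  md <- dim(ag_value(cls))
  n <- md[1] * md[2] * md[3]
  list(cls = ag_reshape(cls, c(n, 1)),
       reg = reg_to_rows(reg, md),
       map_dim = md[1:2])
}

# [H, W, 4*na] offsets -> (H*W*na) x 4 rows matching the anchor
# enumeration (position fastest, then anchor shape). Offset o of anchor a
# lives in channel (o-1)*na + a, so each offset block reshapes directly.
reg_to_rows <- function(reg, md) {
  na <- md[3]
  hw <- md[1] * md[2]
  v <- ag_reshape(reg, c(hw, 4 * na))
  cols <- lapply(1:4, function(o) {
    idx <- (o - 1) * na + seq_len(na)
    sel <- matrix(0, 4 * na, na)
    sel[cbind(idx, seq_len(na))] <- 1
    ag_reshape(ag_matmul(v, sel), c(hw * na, 1))
  })
  out <- cols[[1]]
  for (o in 2:4) out <- ag_concat_cols(out, cols[[o]])
  out
}

#' Anchor grid for a feature map
#'
#' Anchor enumeration matches the flattening order of the head outputs:
#' feature row (y) fastest, then column (x), then the anchor shape index
#' (size within ratio).
#'
#' @param h,w Feature map size.
#' @param cfg The [detector_config()] (stride, sizes, ratios).
#' @return `n x 4` matrix of corner-form anchor boxes in image pixels.
#' @export
detector_anchors <- function(h, w, cfg = detector_config()) {
  shapes <- expand.grid(size = cfg$anchor_sizes, ratio = cfg$anchor_ratios)
  grid <- expand.grid(i = seq_len(h), j = seq_len(w))
  out <- matrix(0, nrow = nrow(grid) * nrow(shapes), ncol = 4)
  row <- 1L
  for (s in seq_len(nrow(shapes))) {
    bh <- shapes$size[s] * sqrt(shapes$ratio[s])
    bw <- shapes$size[s] / sqrt(shapes$ratio[s])
    cy <- (grid$i - 0.5) * cfg$stride
    cx <- (grid$j - 0.5) * cfg$stride
    idx <- row:(row + nrow(grid) - 1L)
    out[idx, ] <- cbind(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
    row <- row + nrow(grid)
  }
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

#' Assign anchors to ground-truth boxes
#'
#' IoU >= `pos_iou` makes an anchor positive, < `neg_iou` negative,
#' in-between ignored; additionally each ground-truth box claims its
#' highest-IoU anchor so no target goes unassigned.
#'
#' @param anchors `n x 4` anchor matrix.
#' @param gt `m x 4` matrix of ground-truth boxes (may have zero rows).
#' @param cfg The [detector_config()].
#' @return List: `labels` (1 positive / 0 negative / -1 ignore) and
#'   `targets` (`n x 4` regression offsets, nonzero only for positives).
#' @export
assign_anchors <- function(anchors, gt, cfg = detector_config()) {
  n <- nrow(anchors)
  labels <- numeric(n)
  targets <- matrix(0, n, 4)
  if (is.null(gt) || nrow(gt) == 0) {
    return(list(labels = labels, targets = targets))
  }
  ious <- iou_matrix(anchors, gt)
  best_gt <- max.col(ious, ties.method = "first")
  best_iou <- ious[cbind(seq_len(n), best_gt)]
  labels[best_iou >= cfg$pos_iou] <- 1
  labels[best_iou >= cfg$neg_iou & best_iou < cfg$pos_iou] <- -1
  # force-match: every gt claims its best anchor
  for (g in seq_len(nrow(gt))) {
    a <- which.max(ious[, g])
    labels[a] <- 1
    best_gt[a] <- g
  }
  pos <- which(labels == 1)
  targets[pos, ] <- encode_boxes(anchors[pos, , drop = FALSE],
                                 gt[best_gt[pos], , drop = FALSE])
  list(labels = labels, targets = targets)
}

# center/size offset encoding used by the regression head
encode_boxes <- function(anchors, boxes) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  ax <- anchors[, 1] + aw / 2; ay <- anchors[, 2] + ah / 2
  bw <- boxes[, 3] - boxes[, 1]; bh <- boxes[, 4] - boxes[, 2]
  bx <- boxes[, 1] + bw / 2; by <- boxes[, 2] + bh / 2
  cbind((bx - ax) / aw, (by - ay) / ah, log(bw / aw), log(bh / ah))
}

#' @rdname assign_anchors
#' @param offsets `n x 4` predicted offsets.
#' @export
decode_boxes <- function(anchors, offsets) {
  aw <- anchors[, 3] - anchors[, 1]; ah <- anchors[, 4] - anchors[, 2]
  ax <- anchors[, 1] + aw / 2; ay <- anchors[, 2] + ah / 2
  bx <- ax + offsets[, 1] * aw; by <- ay + offsets[, 2] * ah
  bw <- aw * exp(offsets[, 3]); bh <- ah * exp(offsets[, 4])
  cbind(bx - bw / 2, by - bh / 2, bx + bw / 2, by + bh / 2)
}

#' Training loss graph for one image
#'
#' Focal classification loss over non-ignored anchors plus smooth-L1
#' regression over positives, both normalized by the positive count.
#'
#' @param out Output of [detector_forward()].
#' @param assignment Output of [assign_anchors()] for the same image.
#' @param cfg The [detector_config()].
#' @return Scalar loss (`ag_tensor` when the forward pass was recorded).
#' @export
detector_loss <- function(out, assignment, cfg = detector_config()) {
  labels <- assignment$labels
  use <- which(labels >= 0)
  y <- labels[use]
  npos <- max(1, sum(labels == 1))
  x <- ag_rows(out$cls, use)
  logp <- ag_scale(ag_softplus(ag_scale(x, -1)), -1)    # log p
  log1mp <- ag_scale(ag_softplus(x), -1)                # log (1-p)
  ym <- matrix(y, ncol = 1)
  pt_log <- ag_add(ag_mul(logp, ym), ag_mul(log1mp, 1 - ym))
  pt <- ag_exp(pt_log)
  at <- matrix(ifelse(y == 1, cfg$focal_alpha, 1 - cfg$focal_alpha),
               ncol = 1)
  modulator <- ag_pow(ag_add(1, ag_scale(pt, -1)), cfg$focal_gamma)
  cls_loss <- ag_scale(
    ag_sum(ag_mul(at, ag_mul(modulator, pt_log))), -1 / npos)
  pos <- which(labels == 1)
  if (length(pos) == 0) return(cls_loss)
  diff <- ag_sub(ag_rows(out$reg, pos),
                 assignment$targets[pos, , drop = FALSE])
  reg_loss <- ag_scale(ag_sum(ag_smooth_l1(diff, cfg$smooth_l1_beta)),
                       1 / npos)
  ag_add(cls_loss, reg_loss)
}

#' Run inference on one image
#'
#' Forward pass, sigmoid scoring, box decoding, score floor, then greedy
#' NMS.
#'
#' @param model An `apple_detector` from [fit_detector()], or a list with
#'   `params` and `cfg`.
#' @param image `H x W` matrix in `[0, 1]`.
#' @return Data frame of detections: `x1, y1, x2, y2, score`.
#' @export
detect_apples <- function(model, image) {
  cfg <- model$cfg
  out <- detector_forward(model$params, image, cfg)
  anchors <- detector_anchors(out$map_dim[1], out$map_dim[2], cfg)
  scores <- as.vector(1 / (1 + exp(-ag_value(out$cls))))
  keep <- which(scores >= cfg$score_min)
  if (length(keep) == 0) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), score = numeric(0)))
  }
  boxes <- decode_boxes(anchors[keep, , drop = FALSE],
                        ag_value(out$reg)[keep, , drop = FALSE])
  d <- dim(image)
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), d[2])
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), d[1])
  ok <- boxes[, 3] > boxes[, 1] & boxes[, 4] > boxes[, 2]
  boxes <- boxes[ok, , drop = FALSE]
  sc <- scores[keep][ok]
  sel <- nms(boxes, sc, cfg$nms_iou)
  data.frame(x1 = boxes[sel, 1], y1 = boxes[sel, 2],
             x2 = boxes[sel, 3], y2 = boxes[sel, 4], score = sc[sel])
}
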