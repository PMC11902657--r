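#' Focal loss for binary classification
#'
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for positives and
#' `1 - p` for negatives, and the usual class balance `alpha_t = alpha` for
#' positives, `1 - alpha` for negatives. The per-anchor losses are summed
#' and normalized by the number of positive anchors (at least 1).
#'
#' @param p Predicted probabilities in (0, 1); values outside are clamped
#'   to `[eps, 1-eps]` with a warning.
#' @param y Binary labels (0/1), recycled against `p`.
#' @param alpha Positive-class balance weight (default 0.25).
#' @param gamma Focusing exponent (default 2; `gamma = 0` recovers
#'   class-balanced cross-entropy).
#' @param eps Clamping tolerance.
#' @return A single loss value.
#' @examples
#' focal_loss(0.5, 1, alpha = 1, gamma = 0)  # -log(0.5)
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2, eps = 1e-7) {
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities outside (0,1) clamped")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  y <- rep_len(y, length(p))
  pt <- ifelse(y == 1, p, 1 - p)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  npos <- max(1, sum(y == 1))
  sum(-at * (1 - pt)^gamma * log(pt)) / npos
}

#' Smooth L1 (Huber) regression loss
#'
#' `0.5 d^2 / beta` for `|d| < beta`, else `|d| - beta/2`; offsets are
#' summed per box and averaged over boxes.
#'
#' @param pred,target Numeric vectors or `n x 4` matrices of box offsets.
#' @param beta Transition point (> 0, default 1/9).
#' @return A single loss value.
#' @export
smooth_l1 <- function(pred, target, beta = 1 / 9) {
  stopifnot(beta > 0)
  d <- as.matrix(pred) - as.matrix(target)
  v <- ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
  mean(rowSums(v))
}

#' Intersection over union of axis-aligned boxes
#'
#' Boxes are `(x1, y1, x2, y2)` corner form with `x2 > x1`, `y2 > y1`.
#'
#' @param a,b Length-4 vectors, or `n x 4` / `m x 4` matrices for
#'   [iou_matrix()].
#' @return `iou()` returns a scalar in `[0, 1]`; `iou_matrix()` an
#'   `n x m` matrix.
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

#' @rdname iou
#' @export
iou_matrix <- function(a, b) {
  a <- matrix(as.matrix(a), ncol = 4)
  b <- matrix(as.matrix(b), ncol = 4)
  n <- nrow(a); m <- nrow(b)
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(area_a, area_b, "+") - inter)
}

#' Greedy non-maximum suppression
#'
#' Detections are visited in descending score order (ties broken by the
#' earlier index); each survivor suppresses all later boxes overlapping it
#' with IoU above the threshold.
#'
#' @param boxes `n x 4` matrix of corner-form boxes.
#' @param scores Length-`n` finite scores.
#' @param iou_thresh Suppression threshold (default 0.5).
#' @return Integer indices of the surviving detections, in descending
#'   score order.
#' @export
nms <- function(boxes, scores, iou_thresh = 0.5) {
  stopifnot(all(is.finite(scores)))
  boxes <- matrix(as.matrix(boxes), ncol = 4)
  ord <- order(-scores)   # stable: ties keep original order
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) > 0) {
      ious <- iou_matrix(boxes[i, , drop = FALSE],
                         boxes[ord, , drop = FALSE])[1, ]
      ord <- ord[ious <= iou_thresh]
    }
  }
  keep
}

#' Detection metrics at IoU 0.5
#'
#' Score-ranked greedy matching: detections are visited in descending
#' score order and matched to the unmatched ground-truth box of the same
#' image with the highest IoU, provided it reaches the threshold; every
#' further detection of an already-matched box counts as a false positive.
#' AP uses all-point interpolation (area under the precision envelope).
#' Recall, precision and F1 are reported at the score cut-off that
#' maximizes F1.
#'
#' @param detections Data frame with columns `image_id`, `x1`, `y1`, `x2`,
#'   `y2`, `score`.
#' @param ground_truth Data frame with columns `image_id`, `x1`, `y1`,
#'   `x2`, `y2`. Must be non-empty (AP is undefined without ground truth;
#'   an error is signalled).
#' @param iou_thresh Matching threshold (default 0.5).
#' @return A `metrics_report`: `ap`, `recall`, `precision`, `f1` (all in
#'   percent), TP/FP/FN counts at the F1-optimal cut-off, and the ranked
#'   precision-recall table.
#' @examples
#' gt <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
#' det <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10,
#'                   score = 0.9)
#' evaluate_detections(det, gt)$ap
#' @export
evaluate_detections <- function(detections, ground_truth, iou_thresh = 0.5) {
  if (is.null(ground_truth) || nrow(ground_truth) == 0) {
    stop("AP is undefined: no ground-truth boxes supplied")
  }
  n_gt <- nrow(ground_truth)
  if (is.null(detections) || nrow(detections) == 0) {
    return(structure(list(ap = 0, recall = 0, precision = 0, f1 = 0,
                          tp = 0L, fp = 0L, fn = n_gt, n_gt = n_gt,
                          score_cutoff = NA_real_,
                          pr = data.frame(score = numeric(0),
                                          precision = numeric(0),
                                          recall = numeric(0))),
                     class = "metrics_report"))
  }
  ord <- order(-detections$score)
  det <- detections[ord, , drop = FALSE]
  matched <- logical(n_gt)
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    sel <- which(ground_truth$image_id == det$image_id[i] & !matched)
    if (length(sel) == 0) next
    ious <- iou_matrix(
      as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
      as.matrix(ground_truth[sel, c("x1", "y1", "x2", "y2")]))[1, ]
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      matched[sel[j]] <- TRUE
      tp[i] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / n_gt
  # all-point interpolated AP: integrate the precision envelope over recall
  env <- rev(cummax(rev(prec)))
  ap <- sum(diff(c(0, rec)) * env)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  best <- which.max(f1)
  structure(list(
    ap = 100 * ap,
    recall = 100 * rec[best],
    precision = 100 * prec[best],
    f1 = 100 * f1[best],
    tp = as.integer(cum_tp[best]),
    fp = as.integer(cum_fp[best]),
    fn = as.integer(n_gt - cum_tp[best]),
    n_gt = n_gt,
    score_cutoff = det$score[best],
    pr = data.frame(score = det$score, precision = prec, recall = rec)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> AP@0.5 %.1f%%  Recall %.1f%%  F1 %.1f%%  (TP %d / FP %d / FN %d)\n",
    x$ap, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}
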