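# Independent brute-force references used by both unit and acceptance tests.

# NMS by repeated argmax + pairwise IoU elimination
nms_oracle <- function(boxes, scores, thresh) {
  alive <- rep(TRUE, nrow(boxes))
  keep <- integer(0)
  repeat {
    cand <- which(alive)
    if (length(cand) == 0) break
    best <- cand[which.max(scores[cand])]
    keep <- c(keep, best)
    alive[best] <- FALSE
    for (j in which(alive)) {
      if (iou(boxes[best, ], boxes[j, ]) > thresh) alive[j] <- FALSE
    }
  }
  keep
}

# PR-curve enumeration with explicit loops; all-point AP by rectangle sums
evaluate_oracle <- function(det, gt, thresh = 0.5) {
  det <- det[order(det$score, decreasing = TRUE), , drop = FALSE]
  used <- rep(FALSE, nrow(gt))
  is_tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    best_j <- 0; best_iou <- -1
    for (j in seq_len(nrow(gt))) {
      if (used[j] || gt$image_id[j] != det$image_id[i]) next
      v <- iou(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
               as.numeric(gt[j, c("x1", "y1", "x2", "y2")]))
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0 && best_iou >= thresh) {
      used[best_j] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  tp <- 0; fp <- 0
  prec <- rec <- numeric(nrow(det))
  for (i in seq_along(is_tp)) {
    if (is_tp[i]) tp <- tp + 1 else fp <- fp + 1
    prec[i] <- tp / (tp + fp)
    rec[i] <- tp / nrow(gt)
  }
  ap <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    if (rec[i] > prev_r) {
      ap <- ap + (rec[i] - prev_r) * max(prec[i:length(prec)])
      prev_r <- rec[i]
    }
  }
  100 * ap
}

# random detection/ground-truth pair generator for metric cross-checks
random_detection_case <- function() {
  n_img <- sample(1:3, 1)
  gt <- do.call(rbind, lapply(seq_len(n_img), function(im) {
    k <- sample(1:4, 1)
    x <- runif(k, 0, 80); y <- runif(k, 0, 80)
    data.frame(image_id = im, x1 = x, y1 = y, x2 = x + 15, y2 = y + 15)
  }))
  nd <- sample(1:8, 1)
  src <- gt[sample(nrow(gt), nd, replace = TRUE), ]
  jit <- matrix(runif(nd * 2, -10, 10), nd, 2)
  det <- data.frame(image_id = src$image_id,
                    x1 = src$x1 + jit[, 1], y1 = src$y1 + jit[, 2],
                    x2 = src$x2 + jit[, 1], y2 = src$y2 + jit[, 2],
                    score = round(runif(nd), 3))
  list(det = det, gt = gt)
}
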