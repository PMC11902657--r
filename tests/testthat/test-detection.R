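test_that("focal loss reduces to cross-entropy at gamma 0", {
  expect_equal(focal_loss(0.5, 1, alpha = 1, gamma = 0), -log(0.5))
  expect_equal(focal_loss(0.5, 1, alpha = 1, gamma = 0), 0.6931,
               tolerance = 1e-4)
  expect_equal(focal_loss(0.5, 1, alpha = 1, gamma = 2), 0.1733,
               tolerance = 1e-4)
  expect_equal(focal_loss(0.5, 1, alpha = 1, gamma = 2),
               0.25 * 0.6931472, tolerance = 1e-6)
  # confident correct predictions drive the loss to zero monotonically
  p <- seq(0.5, 0.999, by = 0.01)
  l <- vapply(p, function(pp) focal_loss(pp, 1), numeric(1))
  expect_true(all(diff(l) < 0))
  expect_lt(l[length(l)], 1e-3)
  expect_warning(focal_loss(1.5, 1), "clamped")
})

test_that("focal loss normalizes by the positive count", {
  p <- c(0.9, 0.2, 0.3)
  y <- c(1, 0, 0)
  each <- c(-0.25 * (1 - 0.9)^2 * log(0.9),
            -0.75 * 0.2^2 * log(0.8),
            -0.75 * 0.3^2 * log(0.7))
  expect_equal(focal_loss(p, y), sum(each) / 1, tolerance = 1e-12)
})

test_that("smooth L1 has the right branches and continuity point", {
  expect_equal(smooth_l1(0, 0, beta = 1), 0)
  expect_equal(smooth_l1(2, 0, beta = 1), 1.5)
  # both branches agree at |d| = beta
  b <- 1 / 9
  eps <- 1e-9
  expect_equal(smooth_l1(b - eps, 0, beta = b),
               smooth_l1(b + eps, 0, beta = b), tolerance = 1e-7)
  expect_equal(smooth_l1(b, 0, beta = b), 0.5 * b, tolerance = 1e-12)
  # summed over offsets, averaged over boxes
  pred <- rbind(c(2, 0, 0, 0), c(0, 2, 2, 0))
  expect_equal(smooth_l1(pred, pred * 0, beta = 1), (1.5 + 3) / 2)
})

test_that("IoU matches hand-computed overlaps", {
  a <- c(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(5, 5, 6, 6)), 0)
  expect_equal(iou(a, c(1, 1, 3, 3)), 1 / 7)
  m <- iou_matrix(rbind(a, c(1, 1, 3, 3)), rbind(a))
  expect_equal(as.vector(m), c(1, 1 / 7))
})

test_that("greedy NMS agrees with a brute-force reference", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(nms(b, c(0.9, 0.8)), 1L)
  expect_equal(nms(b, c(0.8, 0.9)), 2L)
  disj <- rbind(c(0, 0, 5, 5), c(10, 10, 15, 15), c(20, 0, 25, 5))
  expect_equal(sort(nms(disj, c(0.5, 0.9, 0.7))), 1:3)
  withr::with_seed(21, {
    for (trial in 1:100) {
      n <- sample(3:10, 1)
      x <- runif(n, 0, 50); y <- runif(n, 0, 50)
      w <- runif(n, 5, 25); h <- runif(n, 5, 25)
      boxes <- cbind(x, y, x + w, y + h)
      scores <- round(runif(n), 3)   # occasional exact ties
      expect_equal(nms(boxes, scores, 0.4),
                   nms_oracle(boxes, scores, 0.4))
    }
  })
})

test_that("evaluation reproduces hand-worked AP cases", {
  gt1 <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  det1 <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 14,
                     score = 0.8)  # IoU 10/14 = 0.71
  r1 <- evaluate_detections(det1, gt1)
  expect_equal(r1$ap, 100)
  expect_equal(r1$recall, 100)
  # ranked TP, FP, TP on two ground truths: AP = (1 + 2/3) / 2
  gt2 <- data.frame(image_id = c(1, 1),
                    x1 = c(0, 100), y1 = c(0, 100),
                    x2 = c(10, 110), y2 = c(10, 110))
  det2 <- data.frame(image_id = 1,
                     x1 = c(0, 50, 100), y1 = c(0, 50, 100),
                     x2 = c(10, 60, 110), y2 = c(10, 60, 110),
                     score = c(0.9, 0.8, 0.7))
  r2 <- evaluate_detections(det2, gt2)
  expect_equal(r2$ap, 100 * (1 + 2 / 3) / 2, tolerance = 1e-9)
  expect_equal(r2$ap, 83.33, tolerance = 1e-2)
  # duplicate hits on one ground truth: the second is a false positive
  det3 <- data.frame(image_id = 1,
                     x1 = c(0, 1), y1 = c(0, 0),
                     x2 = c(10, 11), y2 = c(10, 10),
                     score = c(0.9, 0.8))
  r3 <- evaluate_detections(det3, gt1)
  expect_equal(r3$tp + r3$fp + r3$fn >= 1, TRUE)
  expect_equal(max(r3$pr$recall), 1)
  expect_equal(r3$pr$precision[2], 0.5)
  # degenerate inputs
  expect_error(evaluate_detections(det1, gt1[0, ]), "undefined")
  r0 <- evaluate_detections(det1[0, ], gt1)
  expect_equal(r0$ap, 0)
  expect_equal(r0$recall, 0)
})

test_that("AP is invariant to monotone score rescaling and never raised by
           trailing false positives", {
  gt <- data.frame(image_id = c(1, 1, 2),
                   x1 = c(0, 30, 0), y1 = c(0, 30, 0),
                   x2 = c(10, 40, 10), y2 = c(10, 40, 10))
  det <- data.frame(image_id = c(1, 1, 2, 2),
                    x1 = c(0, 60, 1, 80), y1 = c(0, 60, 0, 80),
                    x2 = c(10, 70, 11, 90), y2 = c(10, 70, 10, 90),
                    score = c(0.9, 0.6, 0.5, 0.3))
  base <- evaluate_detections(det, gt)
  resc <- det
  resc$score <- plogis(5 * det$score - 2)   # strictly monotone
  expect_equal(evaluate_detections(resc, gt)$ap, base$ap, tolerance = 1e-9)
  worse <- rbind(det, data.frame(image_id = 1, x1 = 200, y1 = 200,
                                 x2 = 210, y2 = 210, score = 0.01))
  expect_lte(evaluate_detections(worse, gt)$ap, base$ap + 1e-12)
})

test_that("AP agrees with an independent enumeration on random cases", {
  withr::with_seed(31, {
    for (trial in 1:100) {
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
      expect_equal(evaluate_detections(det, gt)$ap,
                   evaluate_oracle(det, gt), tolerance = 1e-9)
    }
  })
})

test_that("reported F1 is consistent with precision and recall", {
  withr::with_seed(41, {
    gt <- data.frame(image_id = rep(1:3, each = 3),
                     x1 = runif(9, 0, 80), y1 = runif(9, 0, 80))
    gt$x2 <- gt$x1 + 12; gt$y2 <- gt$y1 + 12
    det <- gt[sample(9, 12, replace = TRUE), ]
    det$x1 <- det$x1 + runif(12, -6, 6); det$x2 <- det$x1 + 12
    det$score <- runif(12)
    r <- evaluate_detections(det, gt)
    expect_equal(r$f1,
                 2 * r$precision * r$recall / (r$precision + r$recall),
                 tolerance = 1e-6)
    expect_true(all(c(r$ap, r$recall, r$f1) >= 0 &
                      c(r$ap, r$recall, r$f1) <= 100))
  })
})
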