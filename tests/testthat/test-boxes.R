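test_that("iou matches hand-counted and rasterized oracles", {
  b <- box(0, 0, 10, 10)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(box(0, 0, 1, 1), box(5, 5, 6, 6)), 0)
  # overlap of unit cells: inter 1, union 7
  expect_equal(iou(box(0, 0, 2, 2), box(1, 1, 3, 3)), 1 / 7)
  # zero-area convention
  expect_equal(iou(box(1, 1, 1, 1), box(1, 1, 1, 1)), 0)
  # rasterized pixel-counting oracle on integer boxes up to 64x64
  set.seed(1)
  for (k in 1:25) {
    a <- sort(sample(0:64, 2)); b2 <- sort(sample(0:64, 2))
    c1 <- sort(sample(0:64, 2)); c2 <- sort(sample(0:64, 2))
    if (a[1] == a[2] || b2[1] == b2[2] || c1[1] == c1[2] || c2[1] == c2[2])
      next
    ba <- box(a[1], b2[1], a[2], b2[2])
    bb <- box(c1[1], c2[1], c1[2], c2[2])
    expect_close(iou(ba, bb), iou_raster_oracle(ba, bb), tol = 1e-9)
  }
})

test_that("corner and center views are exact round trips", {
  set.seed(2)
  b <- random_boxes(50)
  expect_equal(box_from_cxcywh(box_to_cxcywh(b)), b,
               ignore_attr = TRUE)
  expect_true(all(box_area(b) >= 0))
})

test_that("giou degrades to iou under enclosure and is bounded by iou", {
  a <- box(0, 0, 4, 4); b <- box(1, 1, 3, 3)
  expect_equal(giou(a, b), 0.25)
  expect_equal(giou(a, b), iou(a, b))
  expect_equal(giou(a, a), 1)
  # disjoint: C = (0,0,3,3), |C \ (A u B)| = 9 - 2
  expect_equal(giou(box(0, 0, 1, 1), box(2, 2, 3, 3)), -7 / 9)
  set.seed(3)
  for (k in 1:20) {
    a <- random_boxes(500); b <- random_boxes(500)
    expect_true(all(giou(a, b) <= iou(a, b) + 1e-12))
    expect_close(giou(a, b), giou(b, a), tol = 1e-12)
    expect_close(iou(a, b), iou(b, a), tol = 1e-12)
  }
})

test_that("diou loss penalizes center distance and tends to 2", {
  expect_equal(diou_loss(box(0, 0, 4, 4), box(0, 0, 4, 4)), 0)
  # concentric: rho = 0, loss = 1 - IoU
  expect_equal(diou_loss(box(0, 0, 4, 4), box(1, 1, 3, 3)), 0.75)
  # far-separated equal boxes approach the analytic limit 2
  far <- diou_loss(box(0, 0, 1, 1), box(1e6, 0, 1e6 + 1, 1))
  expect_gt(far, 1.999)
  expect_lt(far, 2)
  # centers coincide => loss = 1 - iou (property)
  set.seed(4)
  for (k in 1:200) {
    c0 <- runif(2, 5, 15); s1 <- runif(2, 1, 8); s2 <- runif(2, 1, 8)
    a <- box_from_cxcywh(matrix(c(c0, s1), 1))
    b <- box_from_cxcywh(matrix(c(c0, s2), 1))
    expect_close(diou_loss(a, b), 1 - iou(a, b), tol = 1e-12)
  }
  expect_error(diou_loss(box(1, 1, 1, 1), box(1, 1, 1, 1)), "diagonal")
})

test_that("ciou loss matches term-by-term oracle and reduces to diou", {
  expect_equal(ciou_loss(box(0, 0, 4, 4), box(0, 0, 4, 4)), 0)
  # same aspect ratio => v = 0 => equals diou loss
  set.seed(5)
  for (k in 1:100) {
    c1 <- runif(2, 0, 10); c2 <- runif(2, 0, 10)
    s <- runif(2, 1, 6); f <- runif(1, 0.3, 3)
    a <- box_from_cxcywh(matrix(c(c1, s), 1))
    b <- box_from_cxcywh(matrix(c(c2, s * f), 1))
    expect_close(ciou_loss(a, b), diou_loss(a, b), tol = 1e-12)
  }
  # independent scalar evaluation of every term:
  # pred (0,0,4,2), gt (0,0,2,2)
  pred <- box(0, 0, 4, 2); gt <- box(0, 0, 2, 2)
  i <- 4 / (8 + 4 - 4)                      # = 0.5
  rho2 <- (2 - 1)^2 + (1 - 1)^2             # centers (2,1), (1,1)
  c2 <- 4^2 + 2^2                           # enclosing box (0,0,4,2)
  v <- (4 / pi^2) * (atan(2 / 2) - atan(4 / 2))^2
  alpha <- v / ((1 - i) + v)
  expect_equal(i, 0.5)
  expect_equal(rho2 / c2, 0.05)
  expect_close(ciou_loss(pred, gt), 1 - i + rho2 / c2 + alpha * v,
               tol = 1e-12)
  expect_error(ciou_loss(box(0, 0, 0, 2), box(0, 0, 2, 2)), "positive")
})

test_that("analytic ciou gradient matches finite differences", {
  set.seed(6)
  fails <- 0
  for (k in 1:100) {
    pc <- c(runif(2, 0, 20), runif(2, 1, 15))
    gt <- box_from_cxcywh(matrix(c(runif(2, 0, 20), runif(2, 1, 15)), 1))
    an <- ardnet:::ciou_loss_grad(box_from_cxcywh(matrix(pc, 1)), gt)
    eps <- 1e-6
    for (q in 1:4) {
      p1 <- pc; p1[q] <- p1[q] + eps
      p2 <- pc; p2[q] <- p2[q] - eps
      fd <- (ciou_loss(box_from_cxcywh(matrix(p1, 1)), gt) -
             ciou_loss(box_from_cxcywh(matrix(p2, 1)), gt)) / (2 * eps)
      if (abs(fd - an[q]) > 1e-4 * max(1, abs(fd))) fails <- fails + 1
    }
  }
  expect_equal(fails, 0)
})

test_that("nms suppresses same-class overlaps and is idempotent", {
  d1 <- data.frame(score = 0.8, class_id = 0, x1 = 0, y1 = 0, x2 = 10,
                   y2 = 10)
  expect_equal(nrow(nms(d1, 0.5, 0.1)), 1)
  # iou 0.8 pair: only the higher score survives
  two <- data.frame(score = c(0.7, 0.9), class_id = 0,
                    x1 = c(0, 0), y1 = c(0, 0), x2 = c(10, 10),
                    y2 = c(10, 9))   # iou = 0.9
  out <- nms(two, 0.5)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)
  # low-overlap pair both kept, sorted by descending score
  apart <- data.frame(score = c(0.6, 0.9), class_id = 0,
                      x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                      y2 = c(10, 30))
  out <- nms(apart, 0.5)
  expect_equal(out$score, c(0.9, 0.6))
  # different classes are never suppressed against each other
  two$class_id <- c(0, 1)
  expect_equal(nrow(nms(two, 0.5)), 2)
  # idempotence on random detection sets
  set.seed(7)
  for (k in 1:20) {
    b <- random_boxes(30, lim = 15)
    d <- data.frame(score = runif(30), class_id = sample(0:1, 30, TRUE),
                    x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4])
    once <- nms(d, 0.45)
    expect_equal(nms(once, 0.45), once)
  }
  expect_equal(nrow(nms(d1[0, ], 0.5)), 0)
})

test_that("average precision integrates the hand-enumerated envelope", {
  gt1 <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  hit <- data.frame(image_id = 1, score = 0.9, x1 = 0, y1 = 0, x2 = 10,
                    y2 = 10)
  expect_equal(average_precision(hit, gt1, 0.5), 1)
  expect_equal(average_precision(hit[0, ], gt1, 0.5), 0)
  expect_error(average_precision(hit, gt1[0, ], 0.5), "undefined")
  # 2 GTs, ranked TP, FP, TP:
  # PR points (1, 0.5), (0.5, 0.5), (2/3, 1); envelope integral = 5/6
  gts <- data.frame(image_id = c(1, 1), x1 = c(0, 20), y1 = c(0, 20),
                    x2 = c(10, 30), y2 = c(10, 30))
  dets <- data.frame(image_id = 1, score = c(0.9, 0.8, 0.7),
                     x1 = c(0, 50, 20), y1 = c(0, 50, 20),
                     x2 = c(10, 60, 30), y2 = c(10, 60, 30))
  expect_equal(average_precision(dets, gts, 0.5), 5 / 6)
  # 11-point mode on the same fixture:
  # recalls 0..0.5 -> max precision 1; 0.6..1.0 -> 2/3
  expect_equal(average_precision(dets, gts, 0.5, "11point"),
               (6 * 1 + 5 * 2 / 3) / 11)
  # invariance to rank-preserving score rescaling
  dets2 <- dets; dets2$score <- dets$score^3 / 2
  expect_equal(average_precision(dets2, gts, 0.5),
               average_precision(dets, gts, 0.5))
})

test_that("detection tables survive a write/read round trip", {
  d <- data.frame(image_id = c("a", "b"), class = c(0L, 1L),
                  score = c(0.5, 0.25), x1 = c(1.5, 2), y1 = c(0, 1),
                  x2 = c(10, 20), y2 = c(12, 22))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_detections(d, p)
  expect_equal(read_detections(p), d)
})
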