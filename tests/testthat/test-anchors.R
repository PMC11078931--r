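test_that("default anchor inventory holds the nine standard sizes", {
  a <- anchor_set()
  expect_equal(nrow(a$sizes), 9)
  expect_equal(a$strides, c(8L, 16L, 32L))
  expect_equal(a$sizes,
               matrix(c(10, 13, 16, 30, 33, 23, 30, 61, 62, 45, 59, 119,
                        116, 90, 156, 198, 373, 326), ncol = 2,
                      byrow = TRUE))
  expect_error(anchor_set(a$sizes[1:6, ]), "9")
})

test_that("zero offsets decode to the anchor centered in its cell", {
  b <- decode_box(c(0, 0, 0, 0), anchor = c(16, 30), cell = c(3, 4))
  cc <- box_to_cxcywh(b)
  expect_equal(as.numeric(cc), c(3.5, 4.5, 16, 30))
  # pixels via stride
  b8 <- decode_box(c(0, 0, 0, 0), anchor = c(16, 30), cell = c(3, 4),
                   stride = 8)
  expect_equal(as.numeric(box_to_cxcywh(b8)[1, 1:2]), c(28, 36))
  expect_equal(as.numeric(box_to_cxcywh(b8)[1, 3:4]), c(16, 30))
})

test_that("decode limits: center spans (c-0.5, c+1.5), size approaches 4x", {
  big <- 40
  up <- box_to_cxcywh(decode_box(c(big, big, big, big), c(10, 20), c(2, 2)))
  lo <- box_to_cxcywh(decode_box(-c(big, big, big, big), c(10, 20), c(2, 2)))
  expect_equal(as.numeric(up[1, 1:2]), c(3.5, 3.5), tolerance = 1e-8)
  expect_equal(as.numeric(lo[1, 1:2]), c(1.5, 1.5), tolerance = 1e-8)
  expect_equal(as.numeric(up[1, 3:4]), c(40, 80), tolerance = 1e-6)
  expect_equal(as.numeric(lo[1, 3]), 0, tolerance = 1e-6)
  # strict open bounds over random offsets
  set.seed(11)
  t <- matrix(rnorm(4e4, sd = 5), ncol = 4)
  cc <- box_to_cxcywh(decode_box(t, anchor = c(7, 9), cell = c(5, 6)))
  expect_true(all(cc[, 1] > 4.5 & cc[, 1] < 6.5))
  expect_true(all(cc[, 2] > 5.5 & cc[, 2] < 7.5))
  expect_true(all(cc[, 3] > 0 & cc[, 3] < 4 * 7))
  expect_true(all(cc[, 4] > 0 & cc[, 4] < 4 * 9))
})

test_that("cross-neighborhood matching adds the two leaning cells", {
  an <- anchor_set()
  # GT centered at cell fraction (0.3, 0.3) of stride-8 cell (5, 5),
  # sized to match only the first-scale anchors
  gt <- box_from_cxcywh(matrix(c(5.3 * 8, 5.3 * 8, 12, 14), 1))
  m <- match_targets(gt, an, input_size = 128)
  m8 <- m[m$scale == 1, ]
  cells <- unique(m8[, c("cell_x", "cell_y")])
  expect_equal(nrow(cells), 3)
  expect_true(all(apply(cells, 1, paste, collapse = ",") %in%
                    c("5,5", "4,5", "5,4")))
  # center exactly at the cell center: own cell only
  gt2 <- box_from_cxcywh(matrix(c(5.5 * 8, 5.5 * 8, 12, 14), 1))
  m2 <- match_targets(gt2, an, input_size = 128)
  expect_equal(nrow(unique(m2[m2$scale == 1, c("cell_x", "cell_y")])), 1)
  # leaning right/down adds the other neighbors
  gt3 <- box_from_cxcywh(matrix(c(5.7 * 8, 5.7 * 8, 12, 14), 1))
  cells3 <- unique(match_targets(gt3, an, 128)[, c("cell_x", "cell_y")])
  expect_true(all(apply(cells3, 1, paste, collapse = ",") %in%
                    c("5,5", "6,5", "5,6")))
})

test_that("the 4x size-ratio filter rejects unreachable anchors", {
  an <- anchor_set(matrix(rep(c(10, 10), 9), ncol = 2, byrow = TRUE))
  # width ratio 5 against every anchor: no positives anywhere
  gt <- box_from_cxcywh(matrix(c(64, 64, 50, 10), 1))
  expect_equal(nrow(match_targets(gt, an, 128)), 0)
  # ratio just under 4 passes
  gt2 <- box_from_cxcywh(matrix(c(64, 64, 39, 10), 1))
  expect_gt(nrow(match_targets(gt2, an, 128)), 0)
  expect_warning(
    match_targets(box(c(0, 10), c(0, 10), c(0, 20), c(5, 20)),
                  anchor_set(), 128),
    "nonpositive")
})

test_that("neighbor matching never yields fewer positives than single-cell", {
  an <- anchor_set()
  set.seed(12)
  for (k in 1:25) {
    n <- sample(1:4, 1)
    cx <- runif(n, 10, 118); cy <- runif(n, 10, 118)
    w <- runif(n, 5, 60); h <- runif(n, 5, 60)
    gts <- box_from_cxcywh(cbind(cx, cy, pmin(w, 2 * pmin(cx, 128 - cx)),
                                 pmin(h, 2 * pmin(cy, 128 - cy))))
    cross <- match_targets(gts, an, 128)
    single <- match_targets(gts, an, 128, neighbor_cells = FALSE)
    expect_gte(nrow(cross), nrow(single))
    # every positive decodes (at t = 0) to a center within 1.5 cells of
    # the GT center
    if (nrow(cross) > 0) {
      strides <- an$strides[cross$scale]
      gc <- box_to_cxcywh(gts)[cross$gt, , drop = FALSE]
      dx <- abs((cross$cell_x + 0.5) - gc[, 1] / strides)
      dy <- abs((cross$cell_y + 0.5) - gc[, 2] / strides)
      expect_true(all(dx <= 1.5 & dy <= 1.5))
    }
  }
})

test_that("prediction decoding scores, thresholds and suppresses", {
  an <- scale_anchor_set(anchor_set(), 64)
  d <- 5 + 1
  grids <- list(array(-20, c(8, 8, 3 * d)), array(-20, c(4, 4, 3 * d)),
                array(-20, c(2, 2, 3 * d)))
  # all objectness at -inf-ish: nothing survives
  expect_equal(nrow(decode_predictions(grids, an, 1, 0.1, 0.45)), 0)
  # one confident cell: score = sigmoid(obj) * sigmoid(cls)
  g <- grids
  lobj <- log(0.8 / 0.2); lcls <- log(0.9 / 0.1)
  g[[1]][3, 4, 5] <- lobj   # anchor 1 obj at cell (x=3, y=2) zero-based
  g[[1]][3, 4, 6] <- lcls
  out <- decode_predictions(g, an, 1, 0.1, 0.45)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.8 * 0.9, tolerance = 1e-12)
  # two anchors decoding to near-identical boxes: one survives NMS
  a1 <- anchors_at_scale(an, 1)
  tw <- function(r) log(r / (1 - r))
  g[[1]][3, 4, 1:4] <- 0          # anchor 1 at its t = 0 box
  g[[1]][3, 4, d + 1:2] <- 0      # anchor 2 centered in the same cell
  g[[1]][3, 4, d + 5] <- lobj
  g[[1]][3, 4, d + 6] <- lcls
  # pick anchor-2 offsets so its box matches anchor 1's t = 0 box
  g[[1]][3, 4, d + 3] <- tw(sqrt(a1[1, 1] / a1[2, 1]) / 2)
  g[[1]][3, 4, d + 4] <- tw(sqrt(a1[1, 2] / a1[2, 2]) / 2)
  out2 <- decode_predictions(g, an, 1, 0.1, 0.45)
  expect_equal(nrow(out2), 1)
  # scoring is monotone in the objectness logit
  g2 <- g
  g2[[1]][3, 4, 5] <- lobj + 1
  s1 <- decode_predictions(g, an, 1, 0.01, 1)$score
  s2 <- decode_predictions(g2, an, 1, 0.01, 1)$score
  expect_true(max(s2) > max(s1))
  expect_error(decode_predictions(g[1:2], an, 1), "three scales")
  bad <- g; bad[[2]] <- array(0, c(4, 4, 7))
  expect_error(decode_predictions(bad, an, 1), "depth")
})
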