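make_preds <- function(cfg, fill = 0, batch = 1) {
  d <- 5 + cfg$n_classes
  s <- cfg$input_size
  list(array(fill, c(s / 8, s / 8, 3 * d, batch)),
       array(fill, c(s / 16, s / 16, 3 * d, batch)),
       array(fill, c(s / 32, s / 32, 3 * d, batch)))
}

# write one positive's raw values into a grid list
poke <- function(preds, cfg, row, vals) {
  d <- 5 + cfg$n_classes
  for (f in seq_along(vals))
    preds[[row$scale]][row$cell_y + 1, row$cell_x + 1,
                       (row$anchor - 1) * d + f, row$image] <- vals[f]
  preds
}

test_that("classification loss hits its closed forms", {
  cfg <- tiny_cfg(input_size = 64)
  gt <- list(boxes = box_from_cxcywh(matrix(c(32, 32, 12, 14), 1)),
             classes = 0L)
  lc <- loss_config(reduction = "sum", lambda_class = 1)
  asg <- match_targets(gt$boxes, cfg$anchors, 64)
  preds <- make_preds(cfg)
  # p = 0.5 on every positive: sum BCE = n_pos * ln 2
  expect_equal(classification_loss(preds, list(gt), cfg, lc),
               nrow(asg) * log(2), tolerance = 1e-10)
  # perfect one-hot predictions drive the loss to ~0
  big <- make_preds(cfg, fill = 0)
  for (q in seq_len(nrow(asg)))
    big <- poke(big, cfg, cbind(asg[q, ], image = 1), c(0, 0, 0, 0, 0, 40))
  expect_lt(classification_loss(big, list(gt), cfg, lc), 1e-10)
  # additive over disjoint positive sets (two images vs separate calls)
  gt2 <- list(boxes = box_from_cxcywh(matrix(c(16, 48, 10, 10), 1)),
              classes = 0L)
  p2 <- make_preds(cfg, batch = 2)
  both <- classification_loss(p2, list(gt, gt2), cfg, lc)
  expect_equal(both,
               classification_loss(make_preds(cfg), list(gt), cfg, lc) +
                 classification_loss(make_preds(cfg), list(gt2), cfg, lc),
               tolerance = 1e-10)
})

test_that("confidence loss weights negatives by the no-object factor", {
  cfg <- tiny_cfg(input_size = 64)
  none <- list(boxes = NULL, classes = integer())
  # no positives, confident background: loss ~ 0
  p <- make_preds(cfg, fill = 0)
  for (s in 1:3) {
    d <- 5 + cfg$n_classes
    p[[s]][, , c(5, d + 5, 2 * d + 5), ] <- -40
  }
  lc0 <- loss_config(reduction = "sum", lambda_conf = 1, balance = c(1, 1, 1))
  expect_lt(confidence_loss(p, list(none), cfg, lc0), 1e-10)
  # all logits 0 (p = 0.5): loss = noobj * n_anchors * ln 2
  p0 <- make_preds(cfg, fill = 0)
  n_anchor <- (8 * 8 + 4 * 4 + 2 * 2) * 3
  l1 <- confidence_loss(p0, list(none), cfg,
                        loss_config(noobj_weight = 0.3, reduction = "sum",
                                    balance = c(1, 1, 1)))
  expect_equal(l1, 0.3 * n_anchor * log(2), tolerance = 1e-8)
  # doubling the no-object weight exactly doubles the background term
  l2 <- confidence_loss(p0, list(none), cfg,
                        loss_config(noobj_weight = 0.6, reduction = "sum",
                                    balance = c(1, 1, 1)))
  expect_equal(l2, 2 * l1, tolerance = 1e-10)
})

test_that("localization loss matches the box-metric oracle and decreases
           along interpolation toward the target", {
  cfg <- tiny_cfg(input_size = 64)
  gt <- list(boxes = box_from_cxcywh(matrix(c(32.5, 32.5, 16, 16), 1)),
             classes = 0L)
  lc <- loss_config(reduction = "sum", lambda_loc = 1)
  # decoded boxes identical to the GT would give 0; verify via offsets
  # that reproduce the GT exactly from its own cell at scale 2
  # (cell center 32.5 within cell (4, 4), stride 16 -> t = 0 on x/y when
  # fractional offset is 0.5... use the numeric route instead:
  p <- make_preds(cfg)
  ls <- compute_loss(p, list(gt), cfg, lc)
  asg <- match_targets(gt$boxes, cfg$anchors, 64)
  # oracle: decode each positive at t = 0 and sum ciou losses
  oracle <- 0
  for (q in seq_len(nrow(asg))) {
    st <- cfg$anchors$strides[asg$scale[q]]
    an <- anchors_at_scale(cfg$anchors, asg$scale[q])[asg$anchor[q], ]
    b <- decode_box(c(0, 0, 0, 0), an, c(asg$cell_x[q], asg$cell_y[q]), st)
    oracle <- oracle + ciou_loss(b, gt$boxes)
  }
  expect_equal(ls$loc, oracle, tolerance = 1e-10)
  # straight-line interpolation of a box toward its GT: loss decreases
  target <- gt$boxes
  start <- box_from_cxcywh(matrix(c(20, 20, 6, 30), 1))
  prev <- Inf
  for (t in seq(0, 1, by = 0.2)) {
    bt <- (1 - t) * start + t * target
    l <- ciou_loss(bt, target)
    expect_lte(l, prev + 1e-12)
    prev <- l
  }
})

test_that("total loss is the sum of its terms and reproducible", {
  cfg <- tiny_cfg(input_size = 64)
  set.seed(55)
  gt <- list(boxes = box_from_cxcywh(matrix(c(30, 30, 14, 10), 1)),
             classes = 0L)
  p <- make_preds(cfg)
  for (s in 1:3) p[[s]][] <- rnorm(length(p[[s]]), sd = 0.5)
  r <- compute_loss(p, list(gt), cfg, loss_config())
  expect_equal(r$total, r$class + r$conf + r$loc, tolerance = 1e-12)
  expect_gte(r$total, 0)
  r2 <- compute_loss(p, list(gt), cfg, loss_config())
  expect_identical(r, r2)
  # all sub-terms zero => 0 (perfect empty-scene background)
  p0 <- make_preds(cfg)
  for (s in 1:3) p0[[s]][, , ardnet:::grid_channel_slot(1, "obj", 1), ] <- -60
  for (s in 1:3) for (a in 2:3)
    p0[[s]][, , ardnet:::grid_channel_slot(a, "obj", 1), ] <- -60
  r0 <- compute_loss(p0, list(list(boxes = NULL, classes = integer())),
                     cfg, loss_config())
  expect_lt(r0$total, 1e-12)
})

test_that("loss gradients match finite differences (hard labels)", {
  cfg <- tiny_cfg(n_classes = 2, input_size = 64)
  set.seed(56)
  targets <- list(list(boxes = box(c(5, 30), c(8, 20), c(25, 60), c(20, 40)),
                       classes = c(0L, 1L)))
  lc <- loss_config(obj_target = "one")
  p <- make_preds(cfg)
  for (s in 1:3) p[[s]][] <- rnorm(length(p[[s]]))
  r <- compute_loss(p, targets, cfg, lc)
  eps <- 1e-6
  worst <- 0
  for (k in 1:120) {
    s <- sample(3, 1); q <- sample(length(p[[s]]), 1)
    p2 <- p; p2[[s]][q] <- p2[[s]][q] + eps
    l1 <- compute_loss(p2, targets, cfg, lc)$total
    p2[[s]][q] <- p2[[s]][q] - 2 * eps
    l2 <- compute_loss(p2, targets, cfg, lc)$total
    fd <- (l1 - l2) / (2 * eps)
    worst <- max(worst, abs(fd - r$dgrids[[s]][q]) /
                   max(abs(fd), abs(r$dgrids[[s]][q]), 1e-6))
  }
  expect_lt(worst, 1e-3)
})

test_that("network + loss gradients agree with finite differences on a
           sample of parameters across layer kinds", {
  cfg <- tiny_cfg(n_classes = 1, input_size = 64)
  m <- ardnet_model(cfg, seed = 3)
  g <- m$graph
  set.seed(57)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  targets <- list(list(boxes = box(8, 10, 40, 28), classes = 0L))
  lc <- loss_config(obj_target = "one")
  lossfun <- function() {
    compute_loss(ardnet:::nn_forward(g, x, train = TRUE), targets, cfg,
                 lc)
  }
  r <- lossfun()
  ardnet:::nn_zero_grads(g)
  ardnet:::nn_backward(g, r$dgrids)
  kinds <- vapply(g$layers, function(l) l$kind, character(1))
  pick <- c(which(kinds == "conv")[2], which(kinds == "involution")[1],
            which(kinds == "cbam")[1], which(kinds == "bnact")[1])
  eps <- 1e-5
  for (li in pick) {
    l <- g$layers[[li]]
    for (nm in names(l$params)) {
      k <- sample(length(l$params[[nm]]), 1)
      orig <- l$params[[nm]][k]
      l$params[[nm]][k] <- orig + eps; lp <- lossfun()$total
      l$params[[nm]][k] <- orig - eps; lm <- lossfun()$total
      l$params[[nm]][k] <- orig
      fd <- (lp - lm) / (2 * eps)
      an <- l$grads[[nm]][k]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-4), 1e-2,
                label = sprintf("layer %d %s", li, nm))
    }
  }
})
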