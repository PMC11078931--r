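# Shared fixtures: tiny configurations and random-box generators.

tiny_cfg <- function(n_classes = 1, input_size = 64, ...) {
  ardnet_config(n_classes = n_classes, input_size = input_size,
                width_multiple = 0.25, depth_multiple = 1 / 9,
                allow_small_involution = TRUE, ...)
}

random_boxes <- function(n, lim = 20, min_size = 0.1) {
  x1 <- runif(n, 0, lim); y1 <- runif(n, 0, lim)
  box(x1, y1, x1 + runif(n, min_size, lim), y1 + runif(n, min_size, lim))
}

# rasterized unit-cell IoU oracle on the integer grid
iou_raster_oracle <- function(a, b, lim = 64) {
  count <- function(bx) {
    m <- matrix(FALSE, lim, lim)
    xs <- seq_len(lim) - 0.5; ys <- seq_len(lim) - 0.5
    outer(ys, xs, function(y, x)
      x > bx[1] & x < bx[3] & y > bx[2] & y < bx[4])
  }
  ma <- count(a); mb <- count(b)
  inter <- sum(ma & mb); uni <- sum(ma | mb)
  if (uni == 0) 0 else inter / uni
}

expect_close <- function(x, y, tol = 1e-8) {
  expect_true(max(abs(x - y)) < tol,
              label = sprintf("max|diff| = %g", max(abs(x - y))))
}
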