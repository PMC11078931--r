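test_that("focus slices 2x2 neighborhoods losslessly in document order", {
  # 1-channel [[a, b], [c, d]] -> channels (a, c, b, d)
  x <- array(c(1, 3, 2, 4), c(2, 2, 1, 1))  # column-major: a,c,b,d
  f <- focus(x)
  expect_equal(dim(f), c(1, 1, 4, 1))
  expect_equal(as.numeric(f), c(1, 3, 2, 4))
  # 3 x 640-equivalent shape check at small size
  x2 <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  f2 <- focus(x2)
  expect_equal(dim(f2), c(4, 4, 12, 1))
  expect_equal(unfocus(f2), x2)
  expect_error(focus(array(0, c(3, 4, 3, 1))), "even")
})

test_that("spp pools match a naive sliding-window max oracle", {
  set.seed(41)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  for (k in c(5, 9, 13)) {
    y <- ardnet:::.maxpool_forward(x, dim(x), as.integer(k), 1L,
                                   as.integer(k %/% 2))$y
    r <- k %/% 2
    for (c in 1:2) for (j in 1:8) for (i in 1:8) {
      win <- x[max(1, i - r):min(8, i + r), max(1, j - r):min(8, j + r), c, 1]
      expect_equal(y[i, j, c, 1], max(win))
    }
  }
  # constant map: every pooled branch equals the input; spp preserves shape
  cfg <- tiny_cfg()
  g <- ardnet:::nn_graph()
  g$out_idx <- ardnet:::add_spp_block(g, 0, cfg$channels[5], tag = "spp")
  xc <- array(1, c(6, 6, cfg$channels[5], 1))
  y <- ardnet:::nn_forward(g, xc, train = FALSE)
  expect_equal(dim(y[[1]])[1:2], c(6, 6))
  expect_equal(dim(y[[1]])[3], cfg$channels[5])
})

test_that("backbone taps sit at strides 8/16/32 with the channel plan", {
  cfg <- tiny_cfg(input_size = 64)
  bb <- build_backbone(cfg)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  taps <- ardnet:::nn_forward(bb, x, train = FALSE)
  expect_equal(dim(taps[[1]]), c(8, 8, cfg$channels[3], 1))
  expect_equal(dim(taps[[2]]), c(4, 4, cfg$channels[4], 1))
  expect_equal(dim(taps[[3]]), c(2, 2, cfg$channels[5], 1))
  expect_true(all(vapply(taps, function(t) all(is.finite(t)), logical(1))))
  # 640 input via shape inference: 80/40/20 grids
  cfg640 <- ardnet_config(input_size = 640)
  bb640 <- build_backbone(cfg640)
  shapes <- ardnet:::infer_shapes(bb640, c(640, 640, 3))
  expect_equal(shapes[[bb640$out_idx[1]]][1:2], c(80, 80))
  expect_equal(shapes[[bb640$out_idx[2]]][1:2], c(40, 40))
  expect_equal(shapes[[bb640$out_idx[3]]][1:2], c(20, 20))
})

test_that("head emits 3*(5+N)-deep grids and involution preserves shapes", {
  for (nc in c(1, 3)) {
    cfg <- tiny_cfg(n_classes = nc, input_size = 64)
    m <- ardnet_model(cfg, seed = 1)
    x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
    preds <- ardnet_forward(m, x)
    expect_equal(dim(preds[[1]]), c(8, 8, 3 * (5 + nc), 2))
    expect_equal(dim(preds[[2]]), c(4, 4, 3 * (5 + nc), 2))
    expect_equal(dim(preds[[3]]), c(2, 2, 3 * (5 + nc), 2))
  }
  # swapping head cores changes parameters but not output shapes
  cfg_conv <- tiny_cfg(input_size = 64, inv20 = FALSE, inv23 = FALSE)
  m2 <- ardnet_model(cfg_conv, seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  p1 <- ardnet_forward(ardnet_model(tiny_cfg(input_size = 64), seed = 1), x)
  p2 <- ardnet_forward(m2, x)
  expect_equal(lapply(p1, dim), lapply(p2, dim))
})

test_that("forward is deterministic and finite with frozen weights", {
  cfg <- tiny_cfg(input_size = 64)
  m <- ardnet_model(cfg, seed = 9)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  p1 <- ardnet_forward(m, x)
  p2 <- ardnet_forward(m, x)
  expect_identical(p1, p2)
  expect_true(all(vapply(p1, function(p) all(is.finite(p)), logical(1))))
})

test_that("involution gate refuses small stages unless overridden", {
  expect_warning(build_backbone(ardnet_config(width_multiple = 0.25,
                                              depth_multiple = 1 / 9,
                                              input_size = 64)),
                 NA)  # nominal 1024 >= 512: no warning even at width 0.25
  cfg_small <- ardnet_config(input_size = 64)
  cfg_small$plan <- c(8, 16, 32, 64, 128)   # nominal plan below the gate
  cfg_small$channels <- cfg_small$plan
  expect_warning(build_backbone(cfg_small), "involution refused")
})

test_that("parameter accounting is invariant to weights and partitions", {
  cfg <- tiny_cfg()
  m1 <- ardnet_model(cfg, seed = 1)
  m2 <- ardnet_model(cfg, seed = 2)
  expect_equal(count_parameters(m1), count_parameters(m2))
  # partition additivity over stages
  stage_of <- unique(sub("\\..*$", "", m1$graph$tags))
  parts <- vapply(stage_of, function(s)
    as.numeric(count_parameters(m1, paste0(s, "."))), numeric(1))
  expect_equal(sum(parts), as.numeric(count_parameters(m1)))
})

test_that("the involution core is strictly lighter than its conv twin", {
  cfg <- ardnet_config()
  inv <- count_parameters(build_final_stage(cfg, "involution"))
  cv <- count_parameters(build_final_stage(cfg, "conv"))
  expect_lt(inv, cv)
  # ablation ladder: each involution substitution strictly reduces counts
  base <- count_parameters(ardnet_model(ardnet_config(
    inv20 = FALSE, inv23 = FALSE, cbam10 = FALSE)))
  h23 <- count_parameters(ardnet_model(ardnet_config(
    inv20 = FALSE, inv23 = TRUE, cbam10 = FALSE)))
  h2320 <- count_parameters(ardnet_model(ardnet_config(
    inv20 = TRUE, inv23 = TRUE, cbam10 = FALSE)))
  full <- count_parameters(ardnet_model(ardnet_config()))
  expect_lt(h23, base)
  expect_lt(h2320, h23)
  expect_gt(full, h2320)        # CBAM adds a small count
  expect_lt(full - h2320, 1e5)
})

test_that("state dict round trips and checkpoints restore the forward", {
  cfg <- tiny_cfg(input_size = 64)
  m <- ardnet_model(cfg, seed = 3)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  p <- ardnet_forward(m, x)
  ck <- withr::local_tempfile(fileext = ".rds")
  ardnet_save(m, ck)
  m2 <- ardnet_load(ck)
  expect_equal(ardnet_forward(m2, x), p, tolerance = 1e-12)
  # yaml config round trip
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, yml)
  cfg2 <- read_model_config(yml)
  expect_equal(cfg2$channels, cfg$channels)
  expect_equal(cfg2$anchors$sizes, cfg$anchors$sizes)
})
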