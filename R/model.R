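#' Focus slicing (space-to-depth)
#'
#' Losslessly rearranges each 2x2 pixel neighborhood into channels: a
#' `(H, W, C)` map becomes `(H/2, W/2, 4C)` (an RGB image becomes 12
#' channels at a quarter of the area). Channel order is offset-major:
#' top-left block first, then bottom-left, top-right, bottom-right, each
#' block carrying all input channels, so a one-channel `[[a, b], [c, d]]`
#' tile maps to channels `(a, c, b, d)`.
#'
#' @param x array `(H, W, C[, N])` with even H and W.
#' @return the sliced array; `unfocus()` inverts it exactly.
#' @export
focus <- function(x) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    stop("focus: spatial dimensions must be even")
  odd_h <- seq(1, d[1], 2); ev_h <- seq(2, d[1], 2)
  odd_w <- seq(1, d[2], 2); ev_w <- seq(2, d[2], 2)
  out <- array(0, c(d[1] / 2, d[2] / 2, 4 * d[3], d[4]))
  cs <- seq_len(d[3])
  out[, , cs, ] <- x[odd_h, odd_w, , , drop = FALSE]
  out[, , d[3] + cs, ] <- x[ev_h, odd_w, , , drop = FALSE]
  out[, , 2 * d[3] + cs, ] <- x[odd_h, ev_w, , , drop = FALSE]
  out[, , 3 * d[3] + cs, ] <- x[ev_h, ev_w, , , drop = FALSE]
  out
}

#' @rdname focus
#' @export
unfocus <- function(x) {
  x <- as_feature_map(x)
  d <- dim(x)
  c_in <- d[3] / 4
  out <- array(0, c(d[1] * 2, d[2] * 2, c_in, d[4]))
  odd_h <- seq(1, d[1] * 2, 2); ev_h <- seq(2, d[1] * 2, 2)
  odd_w <- seq(1, d[2] * 2, 2); ev_w <- seq(2, d[2] * 2, 2)
  cs <- seq_len(c_in)
  out[odd_h, odd_w, , ] <- x[, , cs, , drop = FALSE]
  out[ev_h, odd_w, , ] <- x[, , c_in + cs, , drop = FALSE]
  out[odd_h, ev_w, , ] <- x[, , 2 * c_in + cs, , drop = FALSE]
  out[ev_h, ev_w, , ] <- x[, , 3 * c_in + cs, , drop = FALSE]
  out
}

make_divisible <- function(x, by = 8) max(by, round(x / by) * by)

#' Detector configuration
#'
#' The layer plan follows the CSP lineage: Focus slicing + 3x3 conv, four
#' stride-2 conv + cross-stage-partial (BCSP1) stages with nominal
#' channel plan 64/128/256/512/1024 (multiplied by `width_multiple` and
#' rounded to a multiple of 8), spatial pyramid pooling before the final
#' stage, and an involution-core final stage. `depth_multiple` scales the
#' nominal per-stage bottleneck repeats `c(3, 9, 21, 6)`; the defaults
#' (width 0.75, depth 1/3, involution K = 7, r = 4, G = C/16) are the
#' configuration pinned by `scripts/calibrate.R`, which jointly matches
#' the published final-stage parameter counts (4.1 M convolution core vs
#' 1.8 M involution core) and the 10.1 M backbone total.
#'
#' Involution cores are only accepted at stages whose nominal channel
#' count is at least 512 (performance collapses below that; the gate can
#' be lifted per call with `allow_small_involution` for ablations).
#'
#' @param n_classes number of object classes N.
#' @param input_size square input resolution in pixels (even multiple
#'   of 32).
#' @param width_multiple channel scaling factor.
#' @param depth_multiple bottleneck-repeat scaling factor.
#' @param base_depths nominal repeats of the four backbone CSP stages.
#' @param head_depth nominal repeats of head CSP blocks (scaled too).
#' @param backbone_involution use involution in the final backbone stage.
#' @param inv20,inv23 involution cores in the two deep head blocks (the
#'   network's layers 20 and 23).
#' @param cbam10 dual-channel attention block on the deepest backbone
#'   tap (the network's layer 10).
#' @param anchors an [anchor_set()]; defaults to the standard nine sizes
#'   rescaled from 640 to `input_size`.
#' @param allow_small_involution lift the 512-channel involution gate.
#' @param inv_K,inv_r involution kernel size and reduction.
#' @return an object of class `ardnet_config`.
#' @export
ardnet_config <- function(n_classes = 1, input_size = 640,
                          width_multiple = 0.75, depth_multiple = 1 / 3,
                          base_depths = c(3, 9, 21, 6), head_depth = 3,
                          backbone_involution = TRUE,
                          inv20 = TRUE, inv23 = TRUE, cbam10 = TRUE,
                          anchors = NULL, allow_small_involution = FALSE,
                          inv_K = 7, inv_r = 4) {
  if (input_size %% 32 != 0)
    stop("ardnet_config: input_size must be a multiple of 32")
  if (is.null(anchors))
    anchors <- scale_anchor_set(anchor_set(), input_size)
  plan <- c(64, 128, 256, 512, 1024)
  structure(list(
    n_classes = as.integer(n_classes), input_size = as.integer(input_size),
    width_multiple = width_multiple, depth_multiple = depth_multiple,
    plan = plan,
    channels = vapply(plan, function(c) make_divisible(c * width_multiple),
                      numeric(1)),
    depths = pmax(1, round(base_depths * depth_multiple)),
    head_depth = max(1, round(head_depth * depth_multiple)),
    backbone_involution = backbone_involution,
    inv20 = inv20, inv23 = inv23, cbam10 = cbam10,
    anchors = anchors, allow_small_involution = allow_small_involution,
    inv_K = as.integer(inv_K), inv_r = as.integer(inv_r)),
    class = "ardnet_config")
}

#' @rdname ardnet_config
#' @export
ardnet_tiny_config <- function(n_classes = 1, input_size = 96, ...) {
  ardnet_config(n_classes = n_classes, input_size = input_size,
                width_multiple = 0.25, depth_multiple = 1 / 9, ...)
}

inv_spec_for <- function(cfg, c) {
  involution_spec(c, K = cfg$inv_K, G = max(1, c %/% 16), r = cfg$inv_r)
}

check_involution_gate <- function(cfg, nominal_channels, where) {
  if (nominal_channels >= 512 || cfg$allow_small_involution) return(TRUE)
  warning(sprintf(
    "involution refused at %s: nominal channels %d < 512 (performance gate); using convolution core",
    where, nominal_channels))
  FALSE
}

# Cross-stage-partial block: split into a processed path (cv1 + n
# bottlenecks) and a shortcut path (cv2), concatenated and fused by cv3.
# core = "involution" replaces each bottleneck's 3x3 conv with an
# involution operator followed by BN + SiLU.
add_c3_block <- function(g, from, cin, cout, n, shortcut = TRUE,
                         core = "conv", cfg = NULL, tag = "c3") {
  h <- cout %/% 2
  i_cv1 <- graph_add(g, conv_layer(cin, h, k = 1), from, paste0(tag, ".cv1"))
  i_cv2 <- graph_add(g, conv_layer(cin, h, k = 1), from, paste0(tag, ".cv2"))
  cur <- i_cv1
  for (b in seq_len(n)) {
    btag <- sprintf("%s.m%d", tag, b)
    i_b1 <- graph_add(g, conv_layer(h, h, k = 1), cur, paste0(btag, ".cv1"))
    if (core == "involution") {
      spec <- inv_spec_for(cfg, h)
      i_core <- graph_add(g, involution_layer(spec), i_b1,
                          paste0(btag, ".inv"))
      i_core <- graph_add(g, bnact_layer(h), i_core, paste0(btag, ".invbn"))
    } else {
      i_core <- graph_add(g, conv_layer(h, h, k = 3), i_b1,
                          paste0(btag, ".cv2"))
    }
    if (shortcut) {
      cur <- graph_add(g, add_layer(), c(cur, i_core), paste0(btag, ".add"))
    } else cur <- i_core
  }
  i_cat <- graph_add(g, concat_layer(), c(cur, i_cv2), paste0(tag, ".cat"))
  graph_add(g, conv_layer(2 * h, cout, k = 1), i_cat, paste0(tag, ".cv3"))
}

add_spp_block <- function(g, from, c, tag = "spp") {
  h <- c %/% 2
  i1 <- graph_add(g, conv_layer(c, h, k = 1), from, paste0(tag, ".cv1"))
  p5 <- graph_add(g, maxpool_layer(5), i1, paste0(tag, ".p5"))
  p9 <- graph_add(g, maxpool_layer(9), i1, paste0(tag, ".p9"))
  p13 <- graph_add(g, maxpool_layer(13), i1, paste0(tag, ".p13"))
  i_cat <- graph_add(g, concat_layer(), c(i1, p5, p9, p13),
                     paste0(tag, ".cat"))
  graph_add(g, conv_layer(4 * h, c, k = 1), i_cat, paste0(tag, ".cv2"))
}

#' Build the feature-extraction backbone
#'
#' Focus slicing, four downsampling CSP stages, spatial pyramid pooling
#' and a final CSP stage whose core filter is the involution operator
#' (`backbone_involution = FALSE` builds the convolution-core twin). The
#' graph exposes three pyramid taps at strides 8, 16 and 32.
#'
#' @param cfg an [ardnet_config()].
#' @param graph optionally, an existing graph to append to.
#' @return an `nn_graph` whose `out_idx` are the three taps.
#' @export
build_backbone <- function(cfg, graph = NULL) {
  ch <- cfg$channels; nd <- cfg$depths
  g <- graph %||% nn_graph()
  i <- graph_add(g, focus_layer(), 0, "b0.focus")
  i <- graph_add(g, conv_layer(12, ch[1], k = 3), i, "b0.conv")
  i <- graph_add(g, conv_layer(ch[1], ch[2], k = 3, stride = 2), i, "b1.conv")
  i <- add_c3_block(g, i, ch[2], ch[2], nd[1], cfg = cfg, tag = "b2")
  i <- graph_add(g, conv_layer(ch[2], ch[3], k = 3, stride = 2), i, "b3.conv")
  p3 <- add_c3_block(g, i, ch[3], ch[3], nd[2], cfg = cfg, tag = "b4")
  i <- graph_add(g, conv_layer(ch[3], ch[4], k = 3, stride = 2), p3, "b5.conv")
  p4 <- add_c3_block(g, i, ch[4], ch[4], nd[3], cfg = cfg, tag = "b6")
  i <- graph_add(g, conv_layer(ch[4], ch[5], k = 3, stride = 2), p4, "b7.conv")
  i <- add_spp_block(g, i, ch[5], tag = "b8.spp")
  core <- "conv"
  if (cfg$backbone_involution && check_involution_gate(cfg, cfg$plan[5], "b9"))
    core <- "involution"
  p5 <- add_c3_block(g, i, ch[5], ch[5], nd[4], core = core, cfg = cfg,
                     tag = "b9")
  g$out_idx <- c(p3, p4, p5)
  g
}

#' Build the multi-scale detection head
#'
#' PANet-style fusion over the three backbone taps: a dual-channel
#' attention block on the deepest tap (the network's layer 10), top-down
#' upsample + concat refinement, then bottom-up stride-2 fusion. The two
#' deep fusion blocks (the network's layers 20 and 23, nominal 512 and
#' 1024 channels) use involution cores when `inv20`/`inv23` are set; the
#' final per-scale 1x1 prediction convolutions stay plain convolutions.
#' Prediction grids have depth `3 * (5 + N)`.
#'
#' @param cfg an [ardnet_config()].
#' @param graph the backbone graph (its `out_idx` must be the taps).
#' @return the graph, with `out_idx` set to the three prediction grids
#'   (strides 8, 16, 32).
#' @export
build_head <- function(cfg, graph) {
  g <- graph
  taps <- g$out_idx
  ch <- cfg$channels
  c3h <- ch[3]; c4h <- ch[4]; c5h <- ch[5]
  nh <- cfg$head_depth
  p5 <- taps[3]
  if (cfg$cbam10)
    p5 <- graph_add(g, cbam_layer(cbam_spec(c5h)), p5, "h10.cbam")
  i11 <- graph_add(g, conv_layer(c5h, c4h, k = 1), p5, "h11.conv")
  iu <- graph_add(g, upsample_layer(), i11, "h12.up")
  ic <- graph_add(g, concat_layer(), c(iu, taps[2]), "h13.cat")
  i14 <- add_c3_block(g, ic, 2 * c4h, c4h, nh, shortcut = FALSE, cfg = cfg,
                      tag = "h14")
  i15 <- graph_add(g, conv_layer(c4h, c3h, k = 1), i14, "h15.conv")
  iu <- graph_add(g, upsample_layer(), i15, "h16.up")
  ic <- graph_add(g, concat_layer(), c(iu, taps[1]), "h17.cat")
  out_s8 <- add_c3_block(g, ic, 2 * c3h, c3h, nh, shortcut = FALSE,
                         cfg = cfg, tag = "h18")
  i19 <- graph_add(g, conv_layer(c3h, c3h, k = 3, stride = 2), out_s8,
                   "h19.conv")
  ic <- graph_add(g, concat_layer(), c(i19, i15), "h19.cat")
  core20 <- if (cfg$inv20 && check_involution_gate(cfg, cfg$plan[4], "h20"))
    "involution" else "conv"
  out_s16 <- add_c3_block(g, ic, 2 * c3h, c4h, nh, shortcut = FALSE,
                          core = core20, cfg = cfg, tag = "h20")
  i22 <- graph_add(g, conv_layer(c4h, c4h, k = 3, stride = 2), out_s16,
                   "h22.conv")
  ic <- graph_add(g, concat_layer(), c(i22, i11), "h22.cat")
  core23 <- if (cfg$inv23 && check_involution_gate(cfg, cfg$plan[5], "h23"))
    "involution" else "conv"
  out_s32 <- add_c3_block(g, ic, 2 * c4h, c5h, nh, shortcut = FALSE,
                          core = core23, cfg = cfg, tag = "h23")
  d_out <- 3 * (5 + cfg$n_classes)
  detect_conv <- function(cin) {
    l <- conv_layer(cin, d_out, k = 1, bias = TRUE, bn = FALSE,
                    act = "linear")
    # low-prior objectness bias: start with ~1% predicted objectness so
    # the background sea is quiet from the first step
    obj_ch <- (0:2) * (5 + cfg$n_classes) + 5
    l$params$b[obj_ch] <- log(0.01 / 0.99)
    l
  }
  o1 <- graph_add(g, detect_conv(c3h), out_s8, "detect.s8")
  o2 <- graph_add(g, detect_conv(c4h), out_s16, "detect.s16")
  o3 <- graph_add(g, detect_conv(c5h), out_s32, "detect.s32")
  g$out_idx <- c(o1, o2, o3)
  g
}

#' Assemble the full detector
#'
#' @param cfg an [ardnet_config()].
#' @param seed optional seed for weight initialization.
#' @return an object of class `ardnet_model` wrapping the layer graph and
#'   its configuration.
#' @export
ardnet_model <- function(cfg = ardnet_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- build_head(cfg, build_backbone(cfg))
  structure(list(graph = g, cfg = cfg), class = "ardnet_model")
}

#' @export
print.ardnet_model <- function(x, ...) {
  cat(sprintf(
    "ardnet_model: %d classes, input %d, width %.2f, %s parameters\n",
    x$cfg$n_classes, x$cfg$input_size, x$cfg$width_multiple,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Run the detector forward
#'
#' @param model an [ardnet_model()].
#' @param x image array `(H, W, 3[, N])`, values in \[0, 1\].
#' @param train logical; training mode uses batch statistics and caches
#'   activations for the backward pass.
#' @return list of three raw prediction grids `(H_s, W_s, 3*(5+N), N)`.
#' @export
ardnet_forward <- function(model, x, train = FALSE) {
  nn_forward(model$graph, x, train = train)
}

#' Build only the final backbone stage
#'
#' Instantiates the final (nominal 1024-channel) CSP stage standalone
#' with either core, for parameter accounting and ablation.
#'
#' @param cfg an [ardnet_config()].
#' @param core `"involution"` or `"conv"`.
#' @return an `nn_graph` holding just that stage.
#' @export
build_final_stage <- function(cfg = ardnet_config(),
                              core = c("involution", "conv")) {
  core <- match.arg(core)
  g <- nn_graph()
  c5 <- cfg$channels[5]
  g$out_idx <- add_c3_block(g, 0, c5, c5, cfg$depths[4], core = core,
                            cfg = cfg, tag = "b9")
  g
}

#' Serialize model weights
#'
#' Weights travel as a flat named list of arrays (keyed by layer index
#' and parameter name), written as an RDS-free plain list so checkpoints
#' can be saved with any container the caller prefers.
#'
#' @param model an `ardnet_model`.
#' @param state a state list from `ardnet_state`.
#' @return `ardnet_state` returns the named list; `ardnet_load_state`
#'   returns the model, invisibly.
#' @export
ardnet_state <- function(model) graph_state_dict(model$graph)

#' @rdname ardnet_state
#' @export
ardnet_load_state <- function(model, state) {
  graph_load_state_dict(model$graph, state)
  invisible(model)
}

#' Write and read a model config as YAML
#'
#' @param cfg an [ardnet_config()].
#' @param path file path.
#' @export
write_model_config <- function(cfg, path) {
  lst <- cfg[c("n_classes", "input_size", "width_multiple", "depth_multiple",
               "backbone_involution", "inv20", "inv23", "cbam10",
               "allow_small_involution", "inv_K", "inv_r")]
  lst$anchor_sizes <- as.vector(t(cfg$anchors$sizes))
  lst$strides <- cfg$anchors$strides
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lst <- yaml::read_yaml(path)
  anchors <- anchor_set(matrix(unlist(lst$anchor_sizes), ncol = 2,
                               byrow = TRUE),
                        unlist(lst$strides))
  ardnet_config(n_classes = lst$n_classes, input_size = lst$input_size,
                width_multiple = lst$width_multiple,
                depth_multiple = lst$depth_multiple,
                backbone_involution = lst$backbone_involution,
                inv20 = lst$inv20, inv23 = lst$inv23, cbam10 = lst$cbam10,
                anchors = anchors,
                allow_small_involution = lst$allow_small_involution,
                inv_K = lst$inv_K, inv_r = lst$inv_r)
}
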