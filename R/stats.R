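#' Count trainable parameters
#'
#' Sums the sizes of all trainable weights (convolution and involution
#' matrices, biases, normalization scale/shift; running statistics are
#' not trainable). `stages` filters layers by tag prefix, e.g. `"b9"`
#' selects the final backbone stage, so the whole-model count is the sum
#' of the per-stage counts.
#'
#' @param model an `ardnet_model` or `nn_graph`.
#' @param stages optional character vector of tag prefixes to include.
#' @return integer parameter count.
#' @export
count_parameters <- function(model, stages = NULL) {
  g <- if (inherits(model, "ardnet_model")) model$graph else model
  total <- 0
  for (i in seq_along(g$layers)) {
    if (!is.null(stages) &&
        !any(startsWith(g$tags[i], stages))) next
    total <- total + sum(vapply(g$layers[[i]]$params, length, numeric(1)))
  }
  as.integer(total)
}

infer_shapes <- function(g, input_dim) {
  # input_dim = c(H, W, C); returns list of c(H, W, C) per node
  shapes <- vector("list", length(g$layers))
  shp <- function(j) if (j == 0) input_dim else shapes[[j]]
  for (i in seq_along(g$layers)) {
    l <- g$layers[[i]]
    s <- shp(g$from[[i]][1])
    shapes[[i]] <- switch(l$kind,
      conv = {
        cfg <- l$cfg
        c(floor((s[1] + 2 * cfg$pad - cfg$k) / cfg$stride) + 1,
          floor((s[2] + 2 * cfg$pad - cfg$k) / cfg$stride) + 1, cfg$cout)
      },
      focus = c(s[1] / 2, s[2] / 2, 4 * s[3]),
      upsample = c(s[1] * 2, s[2] * 2, s[3]),
      concat = {
        cs <- sum(vapply(g$from[[i]], function(j) shp(j)[3], numeric(1)))
        c(s[1], s[2], cs)
      },
      involution = {
        st <- l$cfg$spec$stride
        c((s[1] - 1) %/% st + 1, (s[2] - 1) %/% st + 1, s[3])
      },
      s)  # add, maxpool, bnact, cbam keep the shape
  }
  shapes
}

#' Count multiply-accumulate operations
#'
#' Per-layer MAC tally under a fixed convention: convolutions count
#' `Cin * Cout * K^2 * Hout * Wout`, an involution layer counts
#' `H * W * (C*C/r + C/r*K^2*G + K^2*C)` (kernel generation plus
#' application), the attention block counts its MLP and spatial
#' convolution; pooling, normalization and activations are ignored.
#' 1 MAC = 2 FLOPs if a FLOP figure is wanted.
#'
#' @param model an `ardnet_model` or `nn_graph`.
#' @param input_size square input size in pixels (taken from the config
#'   for an `ardnet_model`).
#' @param stages optional tag-prefix filter as in [count_parameters()].
#' @return total MAC count (numeric, may exceed integer range).
#' @export
count_flops <- function(model, input_size = NULL, stages = NULL) {
  if (inherits(model, "ardnet_model")) {
    input_size <- input_size %||% model$cfg$input_size
    g <- model$graph
  } else {
    g <- model
    if (is.null(input_size)) stop("count_flops: input_size required")
  }
  shapes <- infer_shapes(g, c(input_size, input_size, 3))
  shp <- function(i, j) if (j == 0) c(input_size, input_size, 3)
    else shapes[[j]]
  total <- 0
  for (i in seq_along(g$layers)) {
    if (!is.null(stages) && !any(startsWith(g$tags[i], stages))) next
    l <- g$layers[[i]]
    s_in <- shp(i, g$from[[i]][1])
    s_out <- shapes[[i]]
    total <- total + switch(l$kind,
      conv = l$cfg$cin * l$cfg$cout * l$cfg$k^2 * s_out[1] * s_out[2],
      involution = {
        spec <- l$cfg$spec
        cr <- spec$C / spec$r
        s_out[1] * s_out[2] *
          (spec$C * cr + cr * spec$K^2 * spec$G + spec$K^2 * spec$C)
      },
      cbam = {
        spec <- l$cfg$spec
        cr <- spec$C / spec$reduction
        2 * 2 * spec$C * cr +                       # two pooled MLP passes
          s_in[1] * s_in[2] * 2 * spec$spatial_kernel^2  # spatial conv
      },
      0)
  }
  total
}

#' Per-stage parameter and MAC table
#'
#' Mirrors the accounting columns of the detector's ablation tables: one
#' row per architectural stage with its parameter count and MACs.
#'
#' @param model an `ardnet_model`.
#' @param input_size square input size (defaults to the config's).
#' @return data.frame with columns `stage`, `params`, `macs`.
#' @export
model_stats_table <- function(model, input_size = NULL) {
  g <- model$graph
  stage_of <- sub("\\..*$", "", g$tags)
  stages <- unique(stage_of)
  data.frame(
    stage = stages,
    params = vapply(stages, function(s)
      as.numeric(count_parameters(model, paste0(s, "."))), numeric(1)),
    macs = vapply(stages, function(s)
      count_flops(model, input_size, paste0(s, ".")), numeric(1)),
    row.names = NULL)
}
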