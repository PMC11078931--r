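#' Dual-channel attention (CBAM) specification
#'
#' Sequential channel-then-spatial attention. The channel sub-module
#' squeezes the map with global average and max pooling, pushes both
#' descriptors through one shared bias-free bottleneck MLP
#' (`C -> C/reduction -> C`, ReLU inside), sums them and squashes with the
#' sigmoid; the spatial sub-module stacks the channel-wise mean and max
#' maps, convolves them with a single `k x k` filter and squashes again.
#' Both weight maps are in (0, 1), so the block is a pointwise
#' contraction of the input.
#'
#' @param C number of channels (divisible by `reduction`).
#' @param reduction bottleneck reduction ratio (default 16, canonical).
#' @param spatial_kernel odd spatial kernel size (default 7, canonical).
#' @return an object of class `cbam_spec`.
#' @export
cbam_spec <- function(C, reduction = 16, spatial_kernel = 7) {
  if (C %% reduction != 0)
    stop("cbam_spec: C must be divisible by reduction")
  if (spatial_kernel %% 2 != 1)
    stop("cbam_spec: spatial kernel must be odd")
  structure(list(C = as.integer(C), reduction = as.integer(reduction),
                 spatial_kernel = as.integer(spatial_kernel)),
            class = "cbam_spec")
}

#' @rdname cbam_spec
#' @param spec a `cbam_spec`.
#' @export
cbam_weights <- function(spec) {
  cr <- spec$C %/% spec$reduction
  list(w1 = he_init(cr, spec$C, spec$C),
       w2 = he_init(spec$C, cr, cr),
       ws = he_init(1, spec$spatial_kernel^2 * 2, spec$spatial_kernel^2 * 2),
       bs = 0)
}

#' Channel attention weights
#'
#' @param x feature map `(H, W, C[, N])`.
#' @param spec a [cbam_spec()].
#' @param weights from [cbam_weights()].
#' @return `C x N` matrix of weights in (0, 1).
#' @export
channel_attention <- function(x, spec, weights) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[3] != spec$C) stop("channel_attention: channel mismatch")
  hw <- d[1] * d[2]
  xm <- matrix(x, nrow = hw)
  avg <- matrix(.colMeans(xm, hw, d[3] * d[4]), d[3], d[4])
  mx <- matrix(apply(xm, 2, max), d[3], d[4])
  mlp <- function(v) weights$w2 %*% pmax(weights$w1 %*% v, 0)
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

#' Spatial attention map
#'
#' @inheritParams channel_attention
#' @return array `(H, W, 1, N)` of weights in (0, 1).
#' @export
spatial_attention <- function(x, spec, weights) {
  x <- as_feature_map(x)
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, nrow = hw)
  smap <- array(0, c(d[1], d[2], 2, d[4]))
  for (n in seq_len(d[4])) {
    block <- xm[, (n - 1) * d[3] + seq_len(d[3]), drop = FALSE]
    smap[, , 1, n] <- .rowMeans(block, hw, d[3])
    smap[, , 2, n] <- apply(block, 1, max)
  }
  z <- .conv2d_forward(smap, dim(smap), weights$ws, weights$bs,
                       spec$spatial_kernel, 1L, spec$spatial_kernel %/% 2)
  1 / (1 + exp(-z))
}

#' CBAM forward pass
#'
#' `y = spatial_weights * (channel_weights * x)`; the spatial map is
#' computed on the channel-refined input, and the output has the shape of
#' the input.
#'
#' @inheritParams channel_attention
#' @return feature map with the same dim as `x`.
#' @export
cbam_forward <- function(x, spec, weights) {
  x <- as_feature_map(x)
  d <- dim(x)
  s <- channel_attention(x, spec, weights)
  xc <- x * bn_expand_batch(s, d)
  m <- spatial_attention(xc, spec, weights)
  xc * array(m[, , rep(1, d[3]), , drop = FALSE], d)
}
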