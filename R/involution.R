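#' Involution operator specification
#'
#' Involution inverts the sharing pattern of convolution: instead of one
#' kernel shared across all pixels and distinct per channel pair, it
#' generates a distinct `K x K` kernel at every pixel from that pixel's
#' own feature vector, and shares kernels across channels within `G`
#' groups. The kernel generation function is a two-matrix bottleneck
#' `W1 . relu(norm(W0 . x))` with `W0` of shape `(C/r) x C` and `W1` of
#' shape `(K*K*G) x (C/r)`; `r` is the channel reduction of the
#' bottleneck. Because the spatial extent `K` enters only through `W1`'s
#' output rows, enlarging the kernel barely changes the parameter count,
#' which is what makes large receptive fields cheap.
#'
#' Defaults: `K = 7` (a wide window is the operator's selling point),
#' `r = 4`, and `G = max(1, C/16)` so roughly 16 channels share a kernel.
#'
#' @param C number of channels (divisible by `G` and `r`).
#' @param K odd kernel size.
#' @param G number of kernel-sharing groups.
#' @param r bottleneck reduction ratio.
#' @param stride output decimation; kernels are generated from the
#'   average-pooled input so the kernel grid matches the output grid.
#' @return an object of class `involution_spec`.
#' @examples
#' involution_param_count(involution_spec(16, K = 3, G = 1, r = 4)) # 108
#' @export
involution_spec <- function(C, K = 7, G = max(1, C %/% 16), r = 4,
                            stride = 1) {
  if (K %% 2 != 1) stop("involution_spec: K must be odd")
  if (C %% G != 0) stop("involution_spec: C must be divisible by G")
  if (C %% r != 0) stop("involution_spec: C must be divisible by r")
  if (stride < 1) stop("involution_spec: stride must be positive")
  structure(list(C = as.integer(C), K = as.integer(K), G = as.integer(G),
                 r = as.integer(r), stride = as.integer(stride)),
            class = "involution_spec")
}

#' Initialize involution weights
#'
#' `w0` and `w1` are bias-free matrices (He init); the bottleneck carries
#' a batch normalization with per-channel `gamma`/`beta`.
#'
#' @param spec an [involution_spec()].
#' @return list with `w0`, `w1`, `gamma`, `beta`, `rm`, `rv` (running
#'   normalization statistics, used when `train = FALSE`).
#' @export
involution_weights <- function(spec) {
  cr <- spec$C %/% spec$r
  list(w0 = he_init(cr, spec$C, spec$C),
       w1 = he_init(spec$K^2 * spec$G, cr, cr),
       gamma = rep(1, cr), beta = numeric(cr),
       rm = numeric(cr), rv = rep(1, cr))
}

avg_pool_stride <- function(x, s) {
  d <- dim(x)
  ho <- (d[1] - 1) %/% s + 1; wo <- (d[2] - 1) %/% s + 1
  out <- array(0, c(ho, wo, d[3], d[4]))
  cnt <- matrix(0, ho, wo)
  for (u in seq_len(s)) {
    hi <- seq(u, d[1], by = s)
    for (v in seq_len(s)) {
      wi <- seq(v, d[2], by = s)
      out[seq_along(hi), seq_along(wi), , ] <-
        out[seq_along(hi), seq_along(wi), , , drop = FALSE] +
        x[hi, wi, , , drop = FALSE]
      cnt[seq_along(hi), seq_along(wi)] <- cnt[seq_along(hi), seq_along(wi)] + 1
    }
  }
  sweep(out, c(1, 2), cnt, "/")
}

#' Generate per-pixel involution kernels
#'
#' Applies the kernel generation function to every pixel: the kernel at
#' `(i, j)` depends only on the feature vector at `(i, j)` (the pointwise
#' special case of the neighborhood formulation). With `stride > 1` the
#' input is average-pooled first so the kernel grid matches the output
#' grid.
#'
#' @param x feature map array `(H, W, C[, N])`.
#' @param spec an [involution_spec()].
#' @param weights from [involution_weights()].
#' @param train logical; `TRUE` normalizes with batch statistics.
#' @return array of dim `(K*K*G, Ho*Wo, N)`; row index is
#'   `(g-1)*K^2 + (v-1)*K + u` for kernel entry (u, v) of group g.
#' @export
involution_generate_kernels <- function(x, spec, weights, train = TRUE) {
  x <- as_feature_map(x)
  if (dim(x)[3] != spec$C)
    stop("involution: input has ", dim(x)[3], " channels, spec has ", spec$C)
  if (nrow(weights$w0) != spec$C %/% spec$r ||
      ncol(weights$w0) != spec$C ||
      nrow(weights$w1) != spec$K^2 * spec$G)
    stop("involution: weight shapes do not match spec")
  if (spec$stride > 1) x <- avg_pool_stride(x, spec$stride)
  d <- dim(x)
  xmat <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])
  z0 <- weights$w0 %*% xmat
  cr <- nrow(z0)
  if (train) {
    mu <- .rowMeans(z0, cr, ncol(z0))
    va <- pmax(.rowMeans(z0 * z0, cr, ncol(z0)) - mu^2, 0)
  } else { mu <- weights$rm; va <- weights$rv }
  h <- pmax(((z0 - mu) / sqrt(va + 1e-5)) * weights$gamma + weights$beta, 0)
  kern <- weights$w1 %*% h
  array(kern, c(nrow(kern), d[1] * d[2], d[4]))
}

#' Involution forward pass
#'
#' Output channel k at output pixel (i, j) is the inner product of the
#' generated kernel of k's group with the `K x K` zero-padded input
#' neighborhood of that channel:
#' `Y[i,j,k] = sum_{u,v} kernel[i,j,u,v,g(k)] * X[i+u, j+v, k]`,
#' with group `g(k) = ceiling(k G / C)`. Spatial size is divided by
#' `stride`.
#'
#' @inheritParams involution_generate_kernels
#' @return feature map of dim `(Ho, Wo, C, N)`.
#' @export
involution_forward <- function(x, spec, weights, train = TRUE) {
  x <- as_feature_map(x)
  kern <- involution_generate_kernels(x, spec, weights, train)
  .involution_apply(x, dim(x), kern, spec$K, spec$G, spec$stride)
}

#' Naive involution oracle
#'
#' Literal quadruple-loop evaluation of the involution sum, used to
#' verify the vectorized implementation. `kern` uses the layout of
#' [involution_generate_kernels()].
#'
#' @param x feature map `(H, W, C[, N])`.
#' @param kern kernel array `(K*K*G, Ho*Wo, N)`.
#' @param K,G,stride operator geometry.
#' @export
involution_apply_naive <- function(x, kern, K, G, stride = 1) {
  x <- as_feature_map(x)
  d <- dim(x)
  ho <- (d[1] - 1) %/% stride + 1; wo <- (d[2] - 1) %/% stride + 1
  cg <- d[3] %/% G
  pad <- K %/% 2
  y <- array(0, c(ho, wo, d[3], d[4]))
  for (n in seq_len(d[4])) for (k in seq_len(d[3])) {
    g <- ceiling(k * G / d[3])
    for (j in seq_len(wo)) for (i in seq_len(ho)) {
      acc <- 0
      for (v in seq_len(K)) for (u in seq_len(K)) {
        hi <- (i - 1) * stride + u - pad  # 1-based input row
        wj <- (j - 1) * stride + v - pad
        if (hi < 1 || hi > d[1] || wj < 1 || wj > d[2]) next
        kv <- kern[(g - 1) * K^2 + (v - 1) * K + u, (j - 1) * ho + i, n]
        acc <- acc + kv * x[hi, wj, k, n]
      }
      y[i, j, k, n] <- acc
    }
  }
  y
}

#' Involution parameter count
#'
#' `C*(C/r) + (C/r)*K^2*G` matrix weights plus `2*(C/r)` normalization
#' parameters; no biases, and no dependence on the feature-map size
#' (kernels are generated, not stored).
#'
#' @param spec an [involution_spec()].
#' @return integer parameter count.
#' @export
involution_param_count <- function(spec) {
  cr <- spec$C %/% spec$r
  as.integer(spec$C * cr + cr * spec$K^2 * spec$G + 2 * cr)
}
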