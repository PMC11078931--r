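# Minimal CPU neural-net engine: feature maps are (H, W, C, N) arrays,
# layers are environments holding params/grads/caches, and a model is a
# DAG of layers with explicit "from" edges (0 = network input). Forward
# caches what backward needs; backward accumulates parameter gradients
# in place and returns gradients for each input edge.

as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 3) dim(x) <- c(d, 1L)
  else if (length(d) != 4) stop("feature map must have dim (H, W, C[, N])")
  x
}

new_layer <- function(kind, params = list(), cfg = list(), state = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- params
  e$grads <- lapply(params, function(p) p * 0)  # preserves vector/matrix shape
  e$cfg <- cfg
  e$state <- state
  e$cache <- NULL
  class(e) <- "nn_layer"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layer_forward <- function(layer, inputs, train = FALSE) {
  fn <- get(paste0("fwd_", layer$kind), mode = "function")
  fn(layer, inputs, train)
}

layer_backward <- function(layer, dy) {
  fn <- get(paste0("bwd_", layer$kind), mode = "function")
  fn(layer, dy)
}

# ---- batch normalization over (H, W, N) per channel ------------------------

bn_stats <- function(x) {
  d <- dim(x); hw <- d[1] * d[2]
  xm <- matrix(x, nrow = hw)
  mcn <- matrix(.colMeans(xm, hw, d[3] * d[4]), d[3], d[4])
  m2 <- matrix(.colMeans(xm * xm, hw, d[3] * d[4]), d[3], d[4])
  mu <- rowMeans(mcn)
  list(mu = mu, var = pmax(rowMeans(m2) - mu^2, 0))
}

bn_expand <- function(v, d) rep(v, each = d[1] * d[2])  # recycles over N

bn_forward <- function(x, gamma, beta, state, train, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(x)
  momentum <- state$momentum %||% momentum
  if (train) {
    st <- bn_stats(x)
    state$rm <- (1 - momentum) * state$rm + momentum * st$mu
    state$rv <- (1 - momentum) * state$rv + momentum * st$var
  } else {
    st <- list(mu = state$rm, var = state$rv)
  }
  inv_std <- 1 / sqrt(st$var + eps)
  xhat <- (x - bn_expand(st$mu, d)) * bn_expand(inv_std, d)
  y <- xhat * bn_expand(gamma, d) + bn_expand(beta, d)
  list(y = y, cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma,
                           m = d[1] * d[2] * d[4], train = train),
       state = state)
}

bn_backward <- function(dy, cache) {
  d <- dim(dy); hw <- d[1] * d[2]
  cn <- d[3] * d[4]
  dym <- matrix(dy, nrow = hw)
  xh <- cache$xhat
  s1 <- rowSums(matrix(.colSums(dym, hw, cn), d[3], d[4]))            # sum dy
  s2 <- rowSums(matrix(.colSums(dym * matrix(xh, nrow = hw), hw, cn),
                       d[3], d[4]))                                   # sum dy*xhat
  dgamma <- s2
  dbeta <- s1
  m <- cache$m
  if (cache$train) {
    dx <- (bn_expand(cache$gamma * cache$inv_std / m, d)) *
      (m * dy - bn_expand(s1, d) - xh * bn_expand(s2, d))
  } else {
    dx <- dy * bn_expand(cache$gamma * cache$inv_std, d)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -----------------------------------------------------------

act_forward <- function(x, act) {
  switch(act,
         silu = { s <- 1 / (1 + exp(-x)); list(y = x * s, cache = s) },
         relu = list(y = pmax(x, 0), cache = NULL),
         linear = list(y = x, cache = NULL))
}

act_backward <- function(dy, x, act, cache) {
  switch(act,
         silu = dy * (cache * (1 + x * (1 - cache))),
         relu = dy * (x > 0),
         linear = dy)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# ---- conv (+BN +activation) layer ------------------------------------------

conv_layer <- function(cin, cout, k = 1, stride = 1, pad = NULL,
                       bias = FALSE, bn = TRUE, act = "silu") {
  pad <- pad %||% (k %/% 2)
  params <- list(w = he_init(cout, k * k * cin, k * k * cin))
  if (bias) params$b <- numeric(cout)
  if (bn) { params$gamma <- rep(1, cout); params$beta <- numeric(cout) }
  new_layer("conv", params,
            cfg = list(cin = cin, cout = cout, k = k, stride = stride,
                       pad = pad, bias = bias, bn = bn, act = act),
            state = list(rm = numeric(cout), rv = rep(1, cout)))
}

fwd_conv <- function(layer, inputs, train) {
  x <- inputs[[1]]
  cfg <- layer$cfg
  z <- .conv2d_forward(x, dim(x), layer$params$w,
                       if (cfg$bias) layer$params$b else numeric(0),
                       cfg$k, cfg$stride, cfg$pad)
  bn_cache <- NULL
  if (cfg$bn) {
    st <- new.env(); st$rm <- layer$state$rm; st$rv <- layer$state$rv
    st$momentum <- layer$state$momentum
    bf <- bn_forward(z, layer$params$gamma, layer$params$beta, st, train)
    layer$state$rm <- st$rm; layer$state$rv <- st$rv
    a <- bf$y; bn_cache <- bf$cache
  } else a <- z
  af <- act_forward(a, cfg$act)
  layer$cache <- list(x = x, a = a, bn = bn_cache, act = af$cache)
  af$y
}

bwd_conv <- function(layer, dy) {
  cfg <- layer$cfg
  cc <- layer$cache
  da <- act_backward(dy, cc$a, cfg$act, cc$act)
  if (cfg$bn) {
    bb <- bn_backward(da, cc$bn)
    layer$grads$gamma <- layer$grads$gamma + bb$dgamma
    layer$grads$beta <- layer$grads$beta + bb$dbeta
    dz <- bb$dx
  } else dz <- da
  g <- .conv2d_backward(cc$x, dim(cc$x), layer$params$w, dz,
                        cfg$k, cfg$stride, cfg$pad, cfg$bias)
  layer$grads$w <- layer$grads$w + g$dw
  if (cfg$bias) layer$grads$b <- layer$grads$b + as.numeric(g$db)
  list(g$dx)
}

# ---- standalone BN + activation (used after involution cores) --------------

bnact_layer <- function(c, act = "silu") {
  new_layer("bnact", list(gamma = rep(1, c), beta = numeric(c)),
            cfg = list(c = c, act = act),
            state = list(rm = numeric(c), rv = rep(1, c)))
}

fwd_bnact <- function(layer, inputs, train) {
  x <- inputs[[1]]
  st <- new.env(); st$rm <- layer$state$rm; st$rv <- layer$state$rv
  st$momentum <- layer$state$momentum
  bf <- bn_forward(x, layer$params$gamma, layer$params$beta, st, train)
  layer$state$rm <- st$rm; layer$state$rv <- st$rv
  af <- act_forward(bf$y, layer$cfg$act)
  layer$cache <- list(a = bf$y, bn = bf$cache, act = af$cache)
  af$y
}

bwd_bnact <- function(layer, dy) {
  da <- act_backward(dy, layer$cache$a, layer$cfg$act, layer$cache$act)
  bb <- bn_backward(da, layer$cache$bn)
  layer$grads$gamma <- layer$grads$gamma + bb$dgamma
  layer$grads$beta <- layer$grads$beta + bb$dbeta
  list(bb$dx)
}

# ---- parameter-free plumbing layers ----------------------------------------

focus_layer <- function() new_layer("focus")

fwd_focus <- function(layer, inputs, train) {
  x <- inputs[[1]]
  layer$cache <- dim(x)
  focus(x)
}

bwd_focus <- function(layer, dy) list(unfocus(dy))

upsample_layer <- function() new_layer("upsample")

fwd_upsample <- function(layer, inputs, train) {
  x <- inputs[[1]]
  d <- dim(x)
  idx_h <- rep(seq_len(d[1]), each = 2)
  idx_w <- rep(seq_len(d[2]), each = 2)
  x[idx_h, idx_w, , , drop = FALSE]
}

bwd_upsample <- function(layer, dy) {
  d <- dim(dy)
  h <- d[1] / 2; w <- d[2] / 2
  dx <- dy[seq(1, d[1], 2), , , , drop = FALSE] +
    dy[seq(2, d[1], 2), , , , drop = FALSE]
  dx <- dx[, seq(1, d[2], 2), , , drop = FALSE] +
    dx[, seq(2, d[2], 2), , , drop = FALSE]
  list(dx)
}

concat_layer <- function() new_layer("concat")

fwd_concat <- function(layer, inputs, train) {
  d1 <- dim(inputs[[1]])
  cs <- vapply(inputs, function(x) dim(x)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0
  for (x in inputs) {
    out[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  layer$cache <- cs
  out
}

bwd_concat <- function(layer, dy) {
  cs <- layer$cache
  out <- vector("list", length(cs))
  at <- 0
  for (i in seq_along(cs)) {
    out[[i]] <- dy[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}

add_layer <- function() new_layer("add")

fwd_add <- function(layer, inputs, train) inputs[[1]] + inputs[[2]]

bwd_add <- function(layer, dy) list(dy, dy)

maxpool_layer <- function(k) new_layer("maxpool", cfg = list(k = k))

fwd_maxpool <- function(layer, inputs, train) {
  x <- inputs[[1]]
  r <- .maxpool_forward(x, dim(x), layer$cfg$k, 1L, layer$cfg$k %/% 2)
  layer$cache <- list(idx = r$idx, xdim = dim(x))
  r$y
}

bwd_maxpool <- function(layer, dy) {
  list(.maxpool_backward(dy, layer$cache$idx, layer$cache$xdim))
}

# ---- involution layer (engine wrapper over the functional op) --------------

involution_layer <- function(spec) {
  w <- involution_weights(spec)
  new_layer("involution",
            params = w[c("w0", "w1", "gamma", "beta")],
            cfg = list(spec = spec),
            state = list(rm = numeric(spec$C %/% spec$r),
                         rv = rep(1, spec$C %/% spec$r)))
}

fwd_involution <- function(layer, inputs, train) {
  x <- inputs[[1]]
  spec <- layer$cfg$spec
  if (spec$stride != 1) stop("engine involution layer supports stride 1 only")
  d <- dim(x)
  xmat <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])  # C x (H*W*N)
  z0 <- layer$params$w0 %*% xmat
  # bottleneck BN over all pixels and batch
  cr <- nrow(z0)
  if (train) {
    mu <- .rowMeans(z0, cr, ncol(z0))
    va <- pmax(.rowMeans(z0 * z0, cr, ncol(z0)) - mu^2, 0)
    mom <- layer$state$momentum %||% 0.1
    layer$state$rm <- (1 - mom) * layer$state$rm + mom * mu
    layer$state$rv <- (1 - mom) * layer$state$rv + mom * va
  } else { mu <- layer$state$rm; va <- layer$state$rv }
  inv_std <- 1 / sqrt(va + 1e-5)
  zhat <- (z0 - mu) * inv_std
  zb <- zhat * layer$params$gamma + layer$params$beta
  h <- pmax(zb, 0)
  kern <- layer$params$w1 %*% h                 # (K*K*G) x (H*W*N)
  kern_arr <- array(kern, c(nrow(kern), d[1] * d[2], d[4]))
  y <- .involution_apply(x, d, kern_arr, spec$K, spec$G, 1L)
  layer$cache <- list(x = x, xmat = xmat, zhat = zhat, inv_std = inv_std,
                      zb = zb, h = h, kern = kern_arr, train = train)
  y
}

bwd_involution <- function(layer, dy) {
  spec <- layer$cfg$spec
  cc <- layer$cache
  d <- dim(cc$x)
  g <- .involution_apply_backward(cc$x, d, cc$kern, dy, spec$K, spec$G, 1L)
  dkern <- matrix(g$dkern, nrow = spec$K^2 * spec$G)
  layer$grads$w1 <- layer$grads$w1 + dkern %*% t(cc$h)
  dh <- crossprod(layer$params$w1, dkern)
  dzb <- dh * (cc$zb > 0)
  layer$grads$gamma <- layer$grads$gamma + rowSums(dzb * cc$zhat)
  layer$grads$beta <- layer$grads$beta + rowSums(dzb)
  m <- ncol(dzb)
  if (cc$train) {
    s1 <- rowSums(dzb); s2 <- rowSums(dzb * cc$zhat)
    dz0 <- (layer$params$gamma * cc$inv_std / m) *
      (m * dzb - s1 - cc$zhat * s2)
  } else {
    dz0 <- dzb * (layer$params$gamma * cc$inv_std)
  }
  layer$grads$w0 <- layer$grads$w0 + dz0 %*% t(cc$xmat)
  dxmat <- crossprod(layer$params$w0, dz0)
  dx2 <- aperm(array(dxmat, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(g$dx + dx2)
}

# ---- CBAM layer ------------------------------------------------------------

cbam_layer <- function(spec) {
  w <- cbam_weights(spec)
  new_layer("cbam", params = w, cfg = list(spec = spec))
}

fwd_cbam <- function(layer, inputs, train) {
  x <- inputs[[1]]
  spec <- layer$cfg$spec
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, nrow = hw)                       # hw x (C*N)
  avg <- matrix(.colMeans(xm, hw, d[3] * d[4]), d[3], d[4])
  mx_idx <- max.col(t(xm), ties.method = "first")  # argmax per (c,n)
  mx <- matrix(xm[cbind(mx_idx, seq_len(d[3] * d[4]))], d[3], d[4])
  za <- layer$params$w1 %*% avg; ha <- pmax(za, 0)
  zm <- layer$params$w1 %*% mx;  hm <- pmax(zm, 0)
  s_logit <- layer$params$w2 %*% ha + layer$params$w2 %*% hm
  s <- 1 / (1 + exp(-s_logit))                     # C x N channel weights
  xc <- x * bn_expand_batch(s, d)
  # spatial attention on the channel-refined map
  xcm <- matrix(xc, nrow = hw)
  cmean <- sapply(seq_len(d[4]), function(n)
    .rowMeans(xcm[, (n - 1) * d[3] + seq_len(d[3]), drop = FALSE], hw, d[3]))
  sp_idx <- apply(array(xc, c(hw, d[3], d[4])), c(1, 3), which.max)
  cmax <- sapply(seq_len(d[4]), function(n)
    xcm[cbind(seq_len(hw), (n - 1) * d[3] + sp_idx[, n])])
  smap <- array(0, c(d[1], d[2], 2, d[4]))
  smap[, , 1, ] <- cmean; smap[, , 2, ] <- cmax
  conv <- .conv2d_forward(smap, dim(smap), layer$params$ws, layer$params$bs,
                          spec$spatial_kernel, 1L, spec$spatial_kernel %/% 2)
  m <- 1 / (1 + exp(-conv))                        # (H, W, 1, N)
  mrep <- array(m[, , rep(1, d[3]), , drop = FALSE], d)
  y <- xc * mrep
  layer$cache <- list(x = x, s = s, s_logit = s_logit, xc = xc, smap = smap,
                      m = m, mrep = mrep, mx_idx = mx_idx, sp_idx = sp_idx,
                      ha = ha, hm = hm, za = za, zm = zm, avg = avg, mx = mx,
                      conv = conv)
  y
}

bn_expand_batch <- function(v, d) {
  # v is C x N; expand to (H, W, C, N)
  array(rep(as.vector(v), each = d[1] * d[2]), d)
}

bwd_cbam <- function(layer, dy) {
  spec <- layer$cfg$spec
  cc <- layer$cache
  d <- dim(cc$x)
  hw <- d[1] * d[2]
  # y = xc * m
  dxc <- dy * cc$mrep
  dm <- array(0, c(d[1], d[2], 1, d[4]))
  dm[, , 1, ] <- apply(dy * cc$xc, c(1, 2, 4), sum)
  dconv <- dm * cc$m * (1 - cc$m)
  gb <- .conv2d_backward(cc$smap, dim(cc$smap), layer$params$ws, dconv,
                         spec$spatial_kernel, 1L, spec$spatial_kernel %/% 2,
                         TRUE)
  layer$grads$ws <- layer$grads$ws + gb$dw
  layer$grads$bs <- layer$grads$bs + as.numeric(gb$db)
  dsmap <- gb$dx
  # back through channel-wise mean and max maps
  dmean <- dsmap[, , 1, , drop = FALSE]
  dmax <- dsmap[, , 2, , drop = FALSE]
  dxc2 <- array(dmean[, , rep(1, d[3]), , drop = FALSE] / d[3], d)
  dxcm <- matrix(0, hw, d[3] * d[4])
  for (n in seq_len(d[4]))
    dxcm[cbind(seq_len(hw), (n - 1) * d[3] + cc$sp_idx[, n])] <-
      as.vector(dmax[, , 1, n])
  dxc <- dxc + dxc2 + array(dxcm, d)
  # xc = x * s
  dx <- dxc * bn_expand_batch(cc$s, d)
  ds <- matrix(.colSums(matrix(dxc * cc$x, nrow = hw), hw, d[3] * d[4]),
               d[3], d[4])
  dlogit <- ds * cc$s * (1 - cc$s)
  layer$grads$w2 <- layer$grads$w2 + dlogit %*% t(cc$ha) + dlogit %*% t(cc$hm)
  dha <- crossprod(layer$params$w2, dlogit)
  dhm <- dha  # same upstream, separate relu masks below
  dza <- dha * (cc$za > 0)
  dzm <- dhm * (cc$zm > 0)
  layer$grads$w1 <- layer$grads$w1 + dza %*% t(cc$avg) + dzm %*% t(cc$mx)
  davg <- crossprod(layer$params$w1, dza)
  dmx <- crossprod(layer$params$w1, dzm)
  # avg-pool backward: spread evenly; max-pool backward: route to argmax
  dxm <- matrix(rep(as.vector(davg) / hw, each = hw), hw, d[3] * d[4])
  dxm[cbind(cc$mx_idx, seq_len(d[3] * d[4]))] <-
    dxm[cbind(cc$mx_idx, seq_len(d[3] * d[4]))] + as.vector(dmx)
  dx <- dx + array(dxm, d)
  list(dx)
}

# ---- model graph -----------------------------------------------------------

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$layers <- list()
  g$from <- list()
  g$tags <- character()
  g$out_idx <- integer()
  class(g) <- "nn_graph"
  g
}

graph_add <- function(g, layer, from, tag = "") {
  g$layers[[length(g$layers) + 1L]] <- layer
  g$from[[length(g$from) + 1L]] <- as.integer(from)
  g$tags <- c(g$tags, tag)
  length(g$layers)
}

#' @export
print.nn_graph <- function(x, ...) {
  cat(sprintf("nn_graph with %d layers, %d output(s)\n",
              length(x$layers), length(x$out_idx)))
  invisible(x)
}

nn_forward <- function(g, x, train = FALSE, keep = train) {
  x <- as_feature_map(x)
  outs <- vector("list", length(g$layers))
  for (i in seq_along(g$layers)) {
    ins <- lapply(g$from[[i]], function(j) if (j == 0) x else outs[[j]])
    outs[[i]] <- layer_forward(g$layers[[i]], ins, train)
    # free intermediates that no later node consumes (forward-only mode)
    if (!keep && i > 1) {
      still_needed <- function(j)
        j %in% g$out_idx ||
        any(vapply(seq(i + 1, length.out = length(g$layers) - i),
                   function(k) j %in% g$from[[k]], logical(1)))
      for (j in seq_len(i - 1))
        if (!is.null(outs[[j]]) && !still_needed(j)) outs[j] <- list(NULL)
    }
  }
  if (keep) g$.outs <- outs
  outs[g$out_idx]
}

nn_backward <- function(g, douts) {
  acc <- vector("list", length(g$layers))
  for (k in seq_along(g$out_idx)) {
    i <- g$out_idx[k]
    acc[[i]] <- if (is.null(acc[[i]])) douts[[k]] else acc[[i]] + douts[[k]]
  }
  for (i in rev(seq_along(g$layers))) {
    if (is.null(acc[[i]])) next
    dins <- layer_backward(g$layers[[i]], acc[[i]])
    for (k in seq_along(dins)) {
      j <- g$from[[i]][k]
      if (j == 0) next
      acc[[j]] <- if (is.null(acc[[j]])) dins[[k]] else acc[[j]] + dins[[k]]
    }
    acc[i] <- list(NULL)
    g$layers[[i]]$cache <- NULL
  }
  invisible(NULL)
}

nn_zero_grads <- function(g) {
  for (l in g$layers)
    l$grads <- lapply(l$grads, function(gr) { gr[] <- 0; gr })
  invisible(NULL)
}

# ---- Adam optimizer --------------------------------------------------------

adam_new <- function(g, lr = 1e-3, beta1 = 0.6, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(g$layers, function(l) lapply(l$params, function(p) p * 0))
  st$v <- st$m
  st
}

adam_step <- function(g, opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(g$layers)) {
    l <- g$layers[[i]]
    for (nm in names(l$params)) {
      gr <- l$grads[[nm]]
      opt$m[[i]][[nm]] <- b1 * opt$m[[i]][[nm]] + (1 - b1) * gr
      opt$v[[i]][[nm]] <- b2 * opt$v[[i]][[nm]] + (1 - b2) * gr * gr
      mhat <- opt$m[[i]][[nm]] / c1
      vhat <- opt$v[[i]][[nm]] / c2
      l$params[[nm]] <- l$params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(NULL)
}

# ---- (de)serialization of weights as a flat key -> array container ---------

graph_state_dict <- function(g) {
  out <- list()
  for (i in seq_along(g$layers)) {
    l <- g$layers[[i]]
    for (nm in names(l$params))
      out[[sprintf("layer%03d.%s", i, nm)]] <- l$params[[nm]]
    for (nm in names(l$state))
      out[[sprintf("layer%03d.state.%s", i, nm)]] <- l$state[[nm]]
  }
  out
}

graph_load_state_dict <- function(g, sd) {
  for (i in seq_along(g$layers)) {
    l <- g$layers[[i]]
    for (nm in names(l$params)) {
      key <- sprintf("layer%03d.%s", i, nm)
      if (!key %in% names(sd)) stop("missing weight: ", key)
      stopifnot(length(sd[[key]]) == length(l$params[[nm]]))
      l$params[[nm]][] <- sd[[key]]
    }
    for (nm in names(l$state)) {
      key <- sprintf("layer%03d.state.%s", i, nm)
      if (key %in% names(sd)) l$state[[nm]][] <- sd[[key]]
    }
  }
  invisible(g)
}
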