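# Seeded generator of underwater-like scenes with elongated fish-shaped
# targets, used so training, evaluation and tests run without external
# data. All randomness goes through a local RNG that restores the
# caller's state.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic underwater scene specification
#'
#' The generator emulates the statistical structure of a field-collected
#' monitoring dataset: a turbid, unevenly lit water background; one
#' solitary elongated fish-like target in 73% of scenes and a small group
#' otherwise; occasional partial occlusion by foreground strips; and a
#' target-size distribution that is log-uniform in box area from 0.2% to
#' 30% of the image so all three detection scales receive positives.
#'
#' @param image_size square image size in pixels (multiple of 32).
#' @param p_single probability that a scene holds exactly one target.
#' @param max_instances upper bound for multi-target scenes (2..max).
#' @param occlusion_prob probability that a scene gets a partial
#'   occluder strip over one target.
#' @param area_range range of target box area as a fraction of image
#'   area (sampled log-uniformly).
#' @param aspect_range range of target length/width aspect ratios.
#' @param low_light_gain gain range used by the low-light degradation.
#' @param noise_sd Gaussian noise standard deviation (pixel units,
#'   images are in \[0, 1\]).
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param label class label recorded in annotations.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 640, p_single = 0.73, max_instances = 4,
                       occlusion_prob = 0.25, area_range = c(0.002, 0.3),
                       aspect_range = c(2.5, 5),
                       low_light_gain = c(0.3, 0.7), noise_sd = 0.05,
                       blur_sigma = 1.5, label = "Atra-spa") {
  stopifnot(p_single >= 0, p_single <= 1, occlusion_prob >= 0,
            occlusion_prob <= 1, max_instances >= 2,
            area_range[1] > 0, area_range[2] <= 1)
  structure(list(image_size = as.integer(image_size), p_single = p_single,
                 max_instances = as.integer(max_instances),
                 occlusion_prob = occlusion_prob, area_range = area_range,
                 aspect_range = aspect_range,
                 low_light_gain = low_light_gain, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, label = label),
            class = "scene_spec")
}

upsample_bilinear <- function(m, h, w) {
  # simple bilinear resize of a small matrix to (h, w)
  yi <- seq(1, nrow(m), length.out = h)
  xi <- seq(1, ncol(m), length.out = w)
  y0 <- pmin(floor(yi), nrow(m) - 1); fy <- yi - y0
  x0 <- pmin(floor(xi), ncol(m) - 1); fx <- xi - x0
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y0 + 1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x0 + 1, drop = FALSE] * outer(1 - fy, fx) +
    m[y0 + 1, x0 + 1, drop = FALSE] * outer(fy, fx)
  a
}

draw_background <- function(sz) {
  base <- c(stats::runif(1, 0.05, 0.22), stats::runif(1, 0.28, 0.5),
            stats::runif(1, 0.33, 0.55))
  grad <- matrix(seq(1.15, 0.75, length.out = sz), sz, sz)
  tex <- upsample_bilinear(matrix(stats::rnorm(64, sd = 0.06), 8, 8), sz, sz)
  img <- array(0, c(sz, sz, 3))
  for (c in 1:3) img[, , c] <- pmin(pmax(base[c] * grad + tex, 0), 1)
  img
}

# rasterize one fish: a rotated ellipse body with a tail lobe; returns the
# pixel mask
fish_mask <- function(sz, cx, cy, a, b, theta) {
  xs <- matrix(seq_len(sz) - 0.5, sz, sz, byrow = TRUE)
  ys <- matrix(seq_len(sz) - 0.5, sz, sz)
  u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  v <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  body <- (u / a)^2 + (v / b)^2 <= 1
  # tail: a smaller lobe behind the body along the main axis
  tu <- u + 1.15 * a
  tail <- (tu / (0.45 * a))^2 + (v / (0.55 * b))^2 <= 1
  body | tail
}

draw_fish <- function(img, mask, cx, cy, theta) {
  sz <- dim(img)[1]
  xs <- matrix(seq_len(sz) - 0.5, sz, sz, byrow = TRUE)
  ys <- matrix(seq_len(sz) - 0.5, sz, sz)
  u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  lum <- stats::runif(1, 0.5, 0.85)
  stripe <- 0.12 * sin(u * stats::runif(1, 0.2, 0.6) + stats::runif(1, 0, 6))
  tint <- c(stats::runif(1, 0.9, 1.05), stats::runif(1, 0.85, 1.0),
            stats::runif(1, 0.7, 0.9))
  for (c in 1:3) {
    plane <- img[, , c]
    plane[mask] <- pmin(pmax(lum * tint[c] + stripe[mask], 0), 1)
    img[, , c] <- plane
  }
  img
}

#' Generate one annotated synthetic scene
#'
#' Deterministic under `(spec, seed)`: the same pair regenerates a
#' byte-identical image and identical boxes. Each target's recorded box
#' is the exact bounding box of its drawn pixel mask, so the annotation
#' always covers the full target.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed for this scene.
#' @return an [annotated_image()] with the pixel array attached.
#' @export
generate_scene <- function(spec, seed) {
  with_local_seed(seed, {
    sz <- spec$image_size
    img <- draw_background(sz)
    n_inst <- if (stats::runif(1) < spec$p_single) 1L else
      sample(2:spec$max_instances, 1)
    boxes <- NULL
    for (k in seq_len(n_inst)) {
      placed <- FALSE
      for (try in 1:25) {
        area <- exp(stats::runif(1, log(spec$area_range[1]),
                                 log(spec$area_range[2]))) * sz * sz
        aspect <- stats::runif(1, spec$aspect_range[1], spec$aspect_range[2])
        # box area ~ (2a')(2b) with the tail extending the body ellipse
        b <- sqrt(area / (4 * 1.6 * aspect))
        a <- aspect * b
        if (b < 1.2) b <- 1.2
        ext <- 1.6 * a  # half-extent incl. tail
        if (2 * ext > 0.95 * sz) next
        theta <- stats::runif(1, -pi / 6, pi / 6) +
          sample(c(0, pi), 1)  # mostly horizontal swimmers
        margin <- ext + 1
        cx <- stats::runif(1, margin, sz - margin)
        cy <- stats::runif(1, margin, sz - margin)
        mask <- fish_mask(sz, cx, cy, a, b, theta)
        if (!any(mask)) next
        img <- draw_fish(img, mask, cx, cy, theta)
        rows <- range(which(rowSums(mask) > 0))
        cols <- range(which(colSums(mask) > 0))
        boxes <- rbind(boxes,
                       c(cols[1] - 1, rows[1] - 1, cols[2], rows[2]))
        placed <- TRUE
        break
      }
      if (!placed && k == 1)
        stop("generate_scene: could not place a target after 25 tries")
    }
    if (stats::runif(1) < spec$occlusion_prob && nrow(boxes) > 0) {
      # a dark foreground strip over part of one target
      bi <- sample(nrow(boxes), 1)
      bx <- boxes[bi, ]
      w <- (bx[3] - bx[1]) * stats::runif(1, 0.15, 0.4)
      x0 <- stats::runif(1, bx[1], bx[3] - w)
      xs <- max(1, round(x0)):min(sz, round(x0 + w))
      col <- c(stats::runif(1, 0.02, 0.1), stats::runif(1, 0.15, 0.3),
               stats::runif(1, 0.05, 0.15))
      for (c in 1:3) img[, xs, c] <- col[c]
    }
    annotated_image(image = img, boxes = boxes,
                    labels = rep(spec$label, nrow(boxes)),
                    source = sprintf("ardnet-synth seed=%d", seed))
  })
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_sep <- function(plane, k) {
  r <- (length(k) - 1) / 2
  n <- nrow(plane); m <- ncol(plane)
  padv <- plane[pmin(pmax(seq(1 - r, n + r), 1), n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (d in seq_along(k))
    out <- out + k[d] * padv[(d - 1) + seq_len(n), , drop = FALSE]
  padh <- out[, pmin(pmax(seq(1 - r, m + r), 1), m), drop = FALSE]
  out2 <- matrix(0, n, m)
  for (d in seq_along(k))
    out2 <- out2 + k[d] * padh[, (d - 1) + seq_len(m), drop = FALSE]
  out2
}

#' Photometric degradations
#'
#' `low-light` multiplies the image by a gain below one, `noise` adds
#' Gaussian pixel noise, `blur` applies a separable Gaussian filter.
#' Boxes are unaffected (annotations stay valid).
#'
#' @param image array `(H, W, 3)` in \[0, 1\].
#' @param mode one of `"low-light"`, `"noise"`, `"blur"`.
#' @param params named list: `gain` (low-light), `sd` (noise),
#'   `sigma` (blur).
#' @param seed seed for the noise draw.
#' @return the degraded image.
#' @export
degrade <- function(image, mode = c("low-light", "noise", "blur"),
                    params = list(), seed = 0) {
  mode <- match.arg(mode)
  switch(mode,
    "low-light" = {
      gain <- params$gain %||% 0.5
      stopifnot(gain > 0, gain <= 1)
      image * gain
    },
    noise = {
      sd <- params$sd %||% 0.05
      stopifnot(sd >= 0)
      if (sd == 0) return(image)
      with_local_seed(seed, {
        pmin(pmax(image + array(stats::rnorm(length(image), sd = sd),
                                dim(image)), 0), 1)
      })
    },
    blur = {
      sigma <- params$sigma %||% 1.5
      stopifnot(sigma > 0)
      k <- gaussian_kernel_1d(sigma)
      out <- image
      for (c in seq_len(dim(image)[3]))
        out[, , c] <- convolve_sep(image[, , c], k)
      out
    })
}

#' Generate a synthetic dataset
#'
#' Draws `n` scenes with per-scene seeds derived deterministically from
#' `seed`, optionally writing PNG images and Pascal-VOC XML annotations
#' to `dir` (`images/` and `annotations/` subdirectories) together with a
#' `manifest.tsv` of (id, seed) pairs that regenerates the exact files.
#'
#' @param n number of scenes.
#' @param spec a [scene_spec()].
#' @param seed master seed.
#' @param dir optional output directory.
#' @param keep_images logical; `FALSE` drops pixel arrays from the
#'   returned objects (annotations are kept), useful for large n.
#' @return invisibly, a list with `scenes` (list of
#'   [annotated_image()]), `ids`, and `seeds`.
#' @export
generate_dataset <- function(n, spec = scene_spec(), seed = 0, dir = NULL,
                             keep_images = is.null(dir)) {
  stopifnot(n >= 1)
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1, n))
  ids <- sprintf("scene_%05d", seq_len(n))
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "annotations"), recursive = TRUE,
               showWarnings = FALSE)
    utils::write.table(data.frame(id = ids, seed = seeds),
                       file.path(dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_scene(spec, seeds[i])
    if (!is.null(dir)) {
      png::writePNG(sc$image,
                    file.path(dir, "images", paste0(ids[i], ".png")))
      write_voc_xml(sc, file.path(dir, "annotations",
                                  paste0(ids[i], ".xml")),
                    filename = paste0(ids[i], ".png"))
    }
    if (!keep_images) sc$image <- NULL
    scenes[[i]] <- sc
  }
  invisible(list(scenes = scenes, ids = ids, seeds = seeds))
}
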