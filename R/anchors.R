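#' Multi-scale anchor set
#'
#' Nine (width, height) anchor priors in input-image pixels, grouped three
#' per pyramid scale, with one stride (pixels per grid cell) per scale.
#' The default sizes are the standard inventory used by the detector:
#' 10x13, 16x30, 33x23 (stride 8), 30x61, 62x45, 59x119 (stride 16),
#' 116x90, 156x198, 373x326 (stride 32).
#'
#' @param sizes 9x2 numeric matrix of (width, height) pairs, ordered by
#'   scale (rows 1-3 stride 8, 4-6 stride 16, 7-9 stride 32).
#' @param strides integer vector of three strides.
#' @return an object of class `anchor_set`.
#' @export
anchor_set <- function(sizes = default_anchor_sizes(),
                       strides = c(8L, 16L, 32L)) {
  sizes <- matrix(as.numeric(sizes), ncol = 2)
  if (nrow(sizes) != 9) stop("anchor_set: exactly 9 (w, h) pairs required")
  if (length(strides) != 3) stop("anchor_set: exactly 3 strides required")
  structure(list(sizes = sizes, strides = as.integer(strides)),
            class = "anchor_set")
}

#' @rdname anchor_set
#' @export
default_anchor_sizes <- function() {
  matrix(c(10, 13, 16, 30, 33, 23,
           30, 61, 62, 45, 59, 119,
           116, 90, 156, 198, 373, 326),
         ncol = 2, byrow = TRUE)
}

#' @rdname anchor_set
#' @param x an `anchor_set`.
#' @param scale scale index 1..3.
#' @export
anchors_at_scale <- function(x, scale) {
  x$sizes[(scale - 1) * 3 + 1:3, , drop = FALSE]
}

#' Rescale an anchor set to a different input resolution
#'
#' Anchor priors are expressed in input pixels, so a model configured for
#' a smaller input keeps the same nine shapes scaled by
#' `input_size / 640`.
#'
#' @param anchors an `anchor_set`.
#' @param input_size target square input size in pixels.
#' @param reference the resolution the sizes are defined at (640).
#' @export
scale_anchor_set <- function(anchors, input_size, reference = 640) {
  anchor_set(anchors$sizes * input_size / reference, anchors$strides)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Decode raw offsets into a box
#'
#' The decoding rule maps unbounded offsets `(t_x, t_y, t_w, t_h)` through
#' the sigmoid so the result stays in a controlled range around the grid
#' cell and its anchor prior:
#' `b_x = 2 sigmoid(t_x) - 0.5 + c_x` (grid units; same for `b_y`) and
#' `b_w = p_w (2 sigmoid(t_w))^2` (pixels; same for `b_h`). The center can
#' reach into the open interval `(c - 0.5, c + 1.5)` and the size is
#' bounded above by 4 times the anchor, which is what makes the
#' cross-neighborhood matching rule (see [match_targets()]) learnable.
#'
#' @param t numeric vector `(t_x, t_y, t_w, t_h)` or a 4-column matrix.
#' @param anchor `(p_w, p_h)` anchor size in pixels.
#' @param cell `(c_x, c_y)` integer cell offsets at the given scale.
#' @param stride pixels per grid cell (1 keeps centers in grid units).
#' @return box matrix in corner form (pixels).
#' @examples
#' decode_box(c(0, 0, 0, 0), anchor = c(16, 30), cell = c(3, 4), stride = 1)
#' @export
decode_box <- function(t, anchor, cell, stride = 1) {
  if (is.null(dim(t))) t <- matrix(t, ncol = 4)
  bx <- (2 * sigmoid(t[, 1]) - 0.5 + cell[1]) * stride
  by <- (2 * sigmoid(t[, 2]) - 0.5 + cell[2]) * stride
  bw <- anchor[1] * (2 * sigmoid(t[, 3]))^2
  bh <- anchor[2] * (2 * sigmoid(t[, 4]))^2
  box_from_cxcywh(cbind(bx, by, bw, bh))
}

#' Cross-neighborhood positive-sample assignment
#'
#' Each ground-truth box is assigned as a positive sample to anchors in
#' its own grid cell plus up to two nearest neighbor cells: the
#' horizontally and vertically adjacent cells toward which the fractional
#' center offsets lean (offset < 0.5 leans left/up, > 0.5 leans
#' right/down; an offset of exactly 0.5 adds no neighbor). This matches
#' the (-0.5, 1.5) reach of the decoder and multiplies the number of
#' positives per target compared to single-cell matching, which speeds up
#' convergence. At each candidate scale an anchor is retained only if
#' `max(w/p_w, p_w/w, h/p_h, p_h/h) < ratio_threshold`; anchors further
#' away in shape cannot be reached by the 4x decode bound.
#'
#' @param gts ground-truth box matrix (corner form, input pixels).
#' @param anchors an [anchor_set()].
#' @param input_size square input size in pixels (defines the grids).
#' @param ratio_threshold anchor/target size-ratio gate (default 4).
#' @param neighbor_cells logical; `FALSE` restricts matching to the own
#'   cell (plain single-cell assignment, for comparison).
#' @return a data.frame of class `assignment` with columns
#'   `scale, cell_x, cell_y, anchor, gt` (cells 0-based, anchor index
#'   1..3 within the scale, `gt` row index into `gts`).
#' @export
match_targets <- function(gts, anchors, input_size, ratio_threshold = 4,
                          neighbor_cells = TRUE) {
  gts <- as_box_matrix(gts)
  ok <- (gts[, 3] - gts[, 1]) > 0 & (gts[, 4] - gts[, 2]) > 0
  if (any(!ok)) {
    warning(sprintf("match_targets: rejecting %d ground-truth box(es) with nonpositive size",
                    sum(!ok)))
  }
  rows <- list()
  cf <- box_to_cxcywh(gts)
  for (s in 1:3) {
    stride <- anchors$strides[s]
    ng <- input_size %/% stride
    an <- anchors_at_scale(anchors, s)
    for (g in which(ok)) {
      w <- cf[g, 3]; h <- cf[g, 4]
      r <- pmax(pmax(w / an[, 1], an[, 1] / w),
                pmax(h / an[, 2], an[, 2] / h))
      sel <- which(r < ratio_threshold)
      if (length(sel) == 0) next
      gx <- cf[g, 1] / stride; gy <- cf[g, 2] / stride
      cx <- min(floor(gx), ng - 1); cy <- min(floor(gy), ng - 1)
      cells <- list(c(cx, cy))
      if (neighbor_cells) {
        fx <- gx - floor(gx); fy <- gy - floor(gy)
        if (fx < 0.5 && cx > 0)      cells <- c(cells, list(c(cx - 1, cy)))
        if (fx > 0.5 && cx < ng - 1) cells <- c(cells, list(c(cx + 1, cy)))
        if (fy < 0.5 && cy > 0)      cells <- c(cells, list(c(cx, cy - 1)))
        if (fy > 0.5 && cy < ng - 1) cells <- c(cells, list(c(cx, cy + 1)))
      }
      for (cc in cells)
        for (a in sel)
          rows[[length(rows) + 1L]] <-
            c(scale = s, cell_x = cc[1], cell_y = cc[2], anchor = a, gt = g)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(scale = integer(), cell_x = integer(), cell_y = integer(),
               anchor = integer(), gt = integer())
  } else {
    as.data.frame(do.call(rbind, rows))
  }
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("assignment", class(out))
  out
}

grid_channel_slot <- function(a, field, n_classes) {
  # channel index (1-based) of `field` for anchor a in a 3*(5+N) grid
  d <- 5 + n_classes
  base <- (a - 1) * d
  switch(field,
         tx = base + 1, ty = base + 2, tw = base + 3, th = base + 4,
         obj = base + 5, cls = base + 5 + seq_len(n_classes))
}

#' Decode prediction grids into scored detections
#'
#' Every anchor slot of the three prediction grids is decoded with
#' [decode_box()], scored as
#' `sigmoid(class logit) * sigmoid(objectness logit)` (the per-box
#' category confidence), thresholded, and passed through class-wise
#' [nms()].
#'
#' @param grids list of three raw prediction arrays with dim
#'   `(H_s, W_s, 3*(5+N))` (a trailing singleton batch dim is accepted),
#'   ordered stride 8, 16, 32.
#' @param anchors an [anchor_set()].
#' @param n_classes number of classes N.
#' @param score_thresh minimum category confidence score.
#' @param iou_thresh NMS overlap threshold.
#' @return detection data.frame (`class_id`, `score`, corners in pixels).
#' @export
decode_predictions <- function(grids, anchors, n_classes = 1,
                               score_thresh = 0.25, iou_thresh = 0.45) {
  if (length(grids) != 3) stop("decode_predictions: three scales required")
  d <- 5 + n_classes
  out <- list()
  for (s in 1:3) {
    g <- grids[[s]]
    if (length(dim(g)) == 4) {
      if (dim(g)[4] != 1)
        stop("decode_predictions: one image at a time")
      g <- array(g, dim(g)[1:3])
    }
    if (dim(g)[3] != 3 * d)
      stop(sprintf("decode_predictions: scale %d grid depth %d != 3*(5+N) = %d",
                   s, dim(g)[3], 3 * d))
    h <- dim(g)[1]; w <- dim(g)[2]
    stride <- anchors$strides[s]
    an <- anchors_at_scale(anchors, s)
    # cell index arrays: rows are y (i), cols are x (j)
    cy <- matrix(seq_len(h) - 1, h, w)
    cx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    for (a in 1:3) {
      tx <- g[, , grid_channel_slot(a, "tx", n_classes)]
      ty <- g[, , grid_channel_slot(a, "ty", n_classes)]
      tw <- g[, , grid_channel_slot(a, "tw", n_classes)]
      th <- g[, , grid_channel_slot(a, "th", n_classes)]
      obj <- sigmoid(g[, , grid_channel_slot(a, "obj", n_classes)])
      bx <- (2 * sigmoid(tx) - 0.5 + cx) * stride
      by <- (2 * sigmoid(ty) - 0.5 + cy) * stride
      bw <- an[a, 1] * (2 * sigmoid(tw))^2
      bh <- an[a, 2] * (2 * sigmoid(th))^2
      for (k in seq_len(n_classes)) {
        sc <- sigmoid(g[, , grid_channel_slot(a, "cls", n_classes)[k]]) * obj
        sel <- which(sc >= score_thresh)
        if (length(sel) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          class_id = k - 1L, score = as.numeric(sc[sel]),
          x1 = as.numeric(bx[sel] - bw[sel] / 2),
          y1 = as.numeric(by[sel] - bh[sel] / 2),
          x2 = as.numeric(bx[sel] + bw[sel] / 2),
          y2 = as.numeric(by[sel] + bh[sel] / 2))
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(class_id = integer(), score = numeric(),
                      x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  nms(do.call(rbind, out), iou_thresh = iou_thresh, score_thresh = score_thresh)
}
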