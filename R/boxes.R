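#' Axis-aligned boxes
#'
#' Boxes are represented as numeric matrices with columns `x1, y1, x2, y2`
#' in continuous, 0-based image pixels with the origin at the top-left
#' corner. Corners are inclusive real intervals (area = width * height),
#' not half-open pixel index ranges. `box()` builds such a matrix and
#' validates the corner ordering.
#'
#' @param x1,y1,x2,y2 corner coordinates (vectors are recycled to a
#'   common length).
#' @return a numeric matrix with one row per box and columns
#'   `x1, y1, x2, y2`.
#' @examples
#' b <- box(0, 0, 10, 10)
#' box_area(b)
#' @export
box <- function(x1, y1, x2, y2) {
  m <- cbind(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  if (any(m[, "x2"] < m[, "x1"]) || any(m[, "y2"] < m[, "y1"]))
    stop("invalid box: x2 < x1 or y2 < y1")
  m
}

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (ncol(b) < 4) stop("box matrix needs columns x1, y1, x2, y2")
  b <- as.matrix(b[, 1:4, drop = FALSE])
  colnames(b) <- c("x1", "y1", "x2", "y2")
  b
}

#' @rdname box
#' @param b a box matrix.
#' @export
box_area <- function(b) {
  b <- as_box_matrix(b)
  (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
}

#' Convert between corner and center/size box views
#'
#' The two parameterizations are exact round trips of each other:
#' `cxcywh` columns are `cx, cy, w, h`.
#'
#' @param b a box matrix in corner form (`x1, y1, x2, y2`).
#' @param m a matrix in center form (`cx, cy, w, h`).
#' @return the converted matrix.
#' @export
box_to_cxcywh <- function(b) {
  b <- as_box_matrix(b)
  cbind(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
        w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

#' @rdname box_to_cxcywh
#' @export
box_from_cxcywh <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  box(m[, 1] - m[, 3] / 2, m[, 2] - m[, 4] / 2,
      m[, 1] + m[, 3] / 2, m[, 2] + m[, 4] / 2)
}

pair_boxes <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  list(a = a, b = b)
}

intersection_area <- function(a, b) {
  ox <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  oy <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  ox * oy
}

#' Intersection over union of box pairs
#'
#' `iou()` is the overlap ratio |A intersect B| / |A union B|. It is
#' symmetric, 0 for disjoint boxes and 1 only for identical boxes of
#' positive area. When both boxes have zero area the ratio is defined as 0
#' (documented convention; the union is empty).
#'
#' @param a,b box matrices (rows are paired, shorter one recycled).
#' @return numeric vector of ratios in \[0, 1\].
#' @examples
#' iou(box(0, 0, 2, 2), box(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  p <- pair_boxes(a, b)
  inter <- intersection_area(p$a, p$b)
  uni <- box_area(p$a) + box_area(p$b) - inter
  unname(ifelse(uni > 0, inter / uni, 0))
}

#' Generalized IoU
#'
#' Extends IoU with a minimum enclosing box C so that disjoint boxes still
#' produce an informative value: `GIoU = IoU - |C \ (A u B)| / |C|`.
#' Always `giou(a, b) <= iou(a, b)`, with equality when one box encloses
#' the other (the enclosing box then coincides with the larger box).
#'
#' @inheritParams iou
#' @return numeric vector in (-1, 1\].
#' @export
giou <- function(a, b) {
  p <- pair_boxes(a, b)
  inter <- intersection_area(p$a, p$b)
  uni <- box_area(p$a) + box_area(p$b) - inter
  cw <- pmax(p$a[, 3], p$b[, 3]) - pmin(p$a[, 1], p$b[, 1])
  ch <- pmax(p$a[, 4], p$b[, 4]) - pmin(p$a[, 2], p$b[, 2])
  carea <- cw * ch
  if (any(carea <= 0))
    stop("giou: degenerate enclosing box (both boxes have zero area)")
  unname(inter / pmax(uni, .Machine$double.eps) - (carea - uni) / carea)
}

#' Distance-IoU loss
#'
#' `1 - IoU + rho^2 / c^2`, where `rho` is the distance between the two
#' box centers and `c` the diagonal of their minimum enclosing box. The
#' penalty term lies in \[0, 1) so the loss lies in \[0, 2); it is 0 only
#' for identical boxes.
#'
#' @param pred,gt box matrices (rows paired).
#' @return numeric vector of losses.
#' @export
diou_loss <- function(pred, gt) {
  p <- pair_boxes(pred, gt)
  cw <- pmax(p$a[, 3], p$b[, 3]) - pmin(p$a[, 1], p$b[, 1])
  ch <- pmax(p$a[, 4], p$b[, 4]) - pmin(p$a[, 2], p$b[, 2])
  c2 <- cw^2 + ch^2
  if (any(c2 <= 0)) stop("diou_loss: enclosing diagonal is zero")
  ca <- box_to_cxcywh(p$a); cb <- box_to_cxcywh(p$b)
  rho2 <- (ca[, 1] - cb[, 1])^2 + (ca[, 2] - cb[, 2])^2
  unname(1 - iou(p$a, p$b) + rho2 / c2)
}

#' Complete-IoU loss
#'
#' Adds an aspect-ratio consistency term to the distance-IoU loss:
#' `1 - IoU + rho^2/c^2 + alpha * v` with
#' `v = (4/pi^2) (atan(w_gt/h_gt) - atan(w/h))^2` and
#' `alpha = v / ((1 - IoU) + v)`. When the aspect ratios match (`v = 0`)
#' the loss reduces to the distance-IoU loss. Both boxes must have
#' positive width and height.
#'
#' @inheritParams diou_loss
#' @return numeric vector of losses (>= 0).
#' @export
ciou_loss <- function(pred, gt) {
  p <- pair_boxes(pred, gt)
  ca <- box_to_cxcywh(p$a); cb <- box_to_cxcywh(p$b)
  if (any(ca[, 3] <= 0 | ca[, 4] <= 0 | cb[, 3] <= 0 | cb[, 4] <= 0))
    stop("ciou_loss: boxes must have positive width and height")
  i <- iou(p$a, p$b)
  v <- (4 / pi^2) * (atan(cb[, 3] / cb[, 4]) - atan(ca[, 3] / ca[, 4]))^2
  alpha <- ifelse(v > 0, v / ((1 - i) + v), 0)
  unname(diou_loss(p$a, p$b) + alpha * v)
}

# Analytic gradient of ciou_loss with respect to the predicted box in
# center form (cx, cy, w, h), gt held fixed. Includes the dependence of
# alpha on IoU and v, so it matches finite differences of ciou_loss
# wherever the loss is differentiable (away from overlap-boundary kinks).
ciou_loss_grad <- function(pred, gt) {
  p <- pair_boxes(pred, gt)
  a <- p$a; b <- p$b
  ca <- box_to_cxcywh(a); cb <- box_to_cxcywh(b)
  w <- ca[, 3]; h <- ca[, 4]; wg <- cb[, 3]; hg <- cb[, 4]

  ox <- pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1])
  oy <- pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2])
  pos <- ox > 0 & oy > 0
  oxp <- pmax(ox, 0); oyp <- pmax(oy, 0)
  inter <- oxp * oyp
  uni <- w * h + wg * hg - inter
  i <- ifelse(uni > 0, inter / uni, 0)

  # d inter / d (cx, cy, w, h): ox depends on the pred corners that are
  # interior to the overlap span.
  dox_dx1 <- ifelse(pos & a[, 1] > b[, 1], -1, 0)
  dox_dx2 <- ifelse(pos & a[, 3] < b[, 3], 1, 0)
  doy_dy1 <- ifelse(pos & a[, 2] > b[, 2], -1, 0)
  doy_dy2 <- ifelse(pos & a[, 4] < b[, 4], 1, 0)
  # corner derivatives wrt center form: x1 = cx - w/2, x2 = cx + w/2
  dI_dcx <- (dox_dx1 + dox_dx2) * oyp
  dI_dw  <- (-dox_dx1 / 2 + dox_dx2 / 2) * oyp
  dI_dcy <- (doy_dy1 + doy_dy2) * oxp
  dI_dh  <- (-doy_dy1 / 2 + doy_dy2 / 2) * oxp

  dU_dcx <- -dI_dcx; dU_dcy <- -dI_dcy
  dU_dw <- h - dI_dw; dU_dh <- w - dI_dh
  u2 <- pmax(uni, .Machine$double.eps)^2
  dIoU <- cbind((dI_dcx * uni - inter * dU_dcx) / u2,
                (dI_dcy * uni - inter * dU_dcy) / u2,
                (dI_dw * uni - inter * dU_dw) / u2,
                (dI_dh * uni - inter * dU_dh) / u2)

  # rho^2 / c^2 term
  dcx <- ca[, 1] - cb[, 1]; dcy <- ca[, 2] - cb[, 2]
  rho2 <- dcx^2 + dcy^2
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  c2 <- cw^2 + ch^2
  # enclosing width derivative wrt pred corners (indicator of attaining)
  dcw_dx1 <- ifelse(a[, 1] < b[, 1], -1, 0)
  dcw_dx2 <- ifelse(a[, 3] > b[, 3], 1, 0)
  dch_dy1 <- ifelse(a[, 2] < b[, 2], -1, 0)
  dch_dy2 <- ifelse(a[, 4] > b[, 4], 1, 0)
  dcw_dcx <- dcw_dx1 + dcw_dx2;  dcw_dw <- -dcw_dx1 / 2 + dcw_dx2 / 2
  dch_dcy <- dch_dy1 + dch_dy2;  dch_dh <- -dch_dy1 / 2 + dch_dy2 / 2
  dc2 <- cbind(2 * cw * dcw_dcx, 2 * ch * dch_dcy,
               2 * cw * dcw_dw, 2 * ch * dch_dh)
  drho2 <- cbind(2 * dcx, 2 * dcy, 0, 0)
  dpen <- (drho2 * c2 - rho2 * dc2) / c2^2

  # alpha * v term
  dat <- atan(wg / hg) - atan(w / h)
  v <- (4 / pi^2) * dat^2
  wh2 <- w^2 + h^2
  dv_dw <- -(8 / pi^2) * dat * h / wh2
  dv_dh <- (8 / pi^2) * dat * w / wh2
  den <- (1 - i) + v
  alpha <- ifelse(v > 0, v / den, 0)
  # d(alpha v) = alpha dv + v dalpha;
  # dalpha = (dv (1 - IoU) + v dIoU) / den^2
  dav <- matrix(0, nrow(a), 4)
  dv <- cbind(0, 0, dv_dw, dv_dh)
  nz <- v > 0
  if (any(nz)) {
    d2 <- den^2
    for (k in 1:4) {
      dalpha_k <- (dv[, k] * (1 - i) + v * dIoU[, k]) / d2
      dav[, k] <- ifelse(nz, alpha * dv[, k] + v * dalpha_k, 0)
    }
  }
  g <- -dIoU + dpen + dav
  colnames(g) <- c("cx", "cy", "w", "h")
  g
}

#' Non-maximum suppression
#'
#' Greedy class-wise suppression: detections are visited in order of
#' descending score; a detection is dropped if it overlaps an already-kept
#' detection of the same class with IoU above `iou_thresh`. Score ties are
#' broken by larger box area, then by lower original index, so the result
#' is deterministic. Detections with score below `score_thresh` are
#' removed first.
#'
#' @param dets a data.frame with columns `score`, `class_id`,
#'   `x1, y1, x2, y2` (extra columns are carried through).
#' @param iou_thresh suppression overlap threshold in \[0, 1\].
#' @param score_thresh minimum score to keep, in \[0, 1\].
#' @return the surviving detections, sorted by descending score.
#' @export
nms <- function(dets, iou_thresh = 0.45, score_thresh = 0) {
  stopifnot(iou_thresh >= 0, iou_thresh <= 1,
            score_thresh >= 0, score_thresh <= 1)
  if (is.null(dets) || nrow(dets) == 0) return(dets)
  dets <- dets[dets$score >= score_thresh, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  b <- as_box_matrix(as.matrix(dets[, c("x1", "y1", "x2", "y2")]))
  ord <- order(-dets$score, -box_area(b), seq_len(nrow(dets)))
  keep <- logical(nrow(dets))
  for (i in ord) {
    ki <- which(keep & dets$class_id == dets$class_id[i])
    if (length(ki) == 0 ||
        all(iou(b[rep(i, length(ki)), , drop = FALSE],
                b[ki, , drop = FALSE]) <= iou_thresh))
      keep[i] <- TRUE
  }
  out <- dets[ord[keep[ord]], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average precision for one class
#'
#' Detections are greedily matched to ground-truth boxes of the same image
#' in order of descending score: a detection is a true positive if its
#' best-IoU unmatched ground truth overlaps at least `iou_thresh`.
#' Precision/recall points are integrated either with the all-point
#' precision-envelope rule (default; used for both AP50 and AP75) or the
#' 11-point interpolation of the older VOC protocol.
#'
#' @param dets data.frame with columns `image_id`, `score`,
#'   `x1, y1, x2, y2`.
#' @param gts data.frame with columns `image_id`, `x1, y1, x2, y2`.
#' @param iou_thresh matching threshold (0.5 for AP50, 0.75 for AP75).
#' @param interpolation `"all"` (precision envelope) or `"11point"`.
#' @return scalar AP in \[0, 1\].
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5,
                              interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (is.null(gts) || nrow(gts) == 0)
    stop("average_precision: no ground truth boxes; AP is undefined")
  n_gt <- nrow(gts)
  if (is.null(dets) || nrow(dets) == 0) return(0)
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  gb <- as_box_matrix(as.matrix(gts[, c("x1", "y1", "x2", "y2")]))
  db <- as_box_matrix(as.matrix(dets[, c("x1", "y1", "x2", "y2")]))
  matched <- logical(n_gt)
  tp <- numeric(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    cand <- which(gts$image_id == dets$image_id[i] & !matched)
    if (length(cand) == 0) next
    ious <- iou(db[rep(i, length(cand)), , drop = FALSE],
                gb[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      tp[i] <- 1
      matched[cand[j]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  if (interpolation == "11point") {
    pr <- vapply(seq(0, 1, by = 0.1), function(r) {
      p <- precision[recall >= r]
      if (length(p) == 0) 0 else max(p)
    }, numeric(1))
    return(mean(pr))
  }
  # all-point: integrate the precision envelope over recall
  r <- c(0, recall)
  p <- c(0, precision)
  for (i in rev(seq_len(length(p) - 1))) p[i] <- max(p[i], p[i + 1])
  sum((r[-1] - r[-length(r)]) * p[-1])
}

#' Read and write plain-text detection tables
#'
#' Detections are serialized as a tab-separated table with columns
#' `image_id, class, score, x1, y1, x2, y2`.
#'
#' @param dets detection data.frame.
#' @param path file path.
#' @return `read_detections` returns the data.frame.
#' @export
write_detections <- function(dets, path) {
  cols <- c("image_id", "class", "score", "x1", "y1", "x2", "y2")
  if (!"class" %in% names(dets) && "class_id" %in% names(dets))
    dets$class <- dets$class_id
  utils::write.table(dets[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
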