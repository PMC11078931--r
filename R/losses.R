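#' Loss configuration
#'
#' The training loss is the sum of three terms computed over an
#' assignment of positives: binary cross-entropy classification loss on
#' positive anchors, binary cross-entropy objectness (confidence) loss
#' over all anchors with the no-object term down-weighted by
#' `noobj_weight`, and the complete-IoU localization loss on decoded
#' boxes. The published form is an unweighted sum of raw sums;
#' [loss_config_strict()] reproduces it exactly. The default
#' configuration uses the lineage's practical reduction instead: per-term
#' means, term weights `lambda_class/lambda_loc/lambda_conf`, and
#' per-scale objectness balance factors (strides 8/16/32), values the
#' source never pins down.
#'
#' @param noobj_weight confidence weight of anchors without a target.
#' @param lambda_class,lambda_loc,lambda_conf term weights.
#' @param balance per-scale objectness balance factors.
#' @param obj_target `"ciou"` uses the detached complete-IoU of the
#'   decoded box as a soft objectness label (couples confidence to
#'   localization quality); `"one"` is the hard label.
#' @param reduction `"mean"` (per-term means) or `"sum"` (raw sums).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(noobj_weight = 0.5, lambda_class = 0.5,
                        lambda_loc = 0.05, lambda_conf = 1,
                        balance = c(4, 1, 0.4),
                        obj_target = c("ciou", "one"),
                        reduction = c("mean", "sum")) {
  stopifnot(noobj_weight >= 0, lambda_class >= 0, lambda_loc >= 0,
            lambda_conf >= 0, all(balance >= 0))
  structure(list(noobj_weight = noobj_weight, lambda_class = lambda_class,
                 lambda_loc = lambda_loc, lambda_conf = lambda_conf,
                 balance = balance, obj_target = match.arg(obj_target),
                 reduction = match.arg(reduction)),
            class = "loss_config")
}

#' @rdname loss_config
#' @export
loss_config_strict <- function(noobj_weight = 0.5) {
  loss_config(noobj_weight = noobj_weight, lambda_class = 1, lambda_loc = 1,
              lambda_conf = 1, balance = c(1, 1, 1), obj_target = "one",
              reduction = "sum")
}

bce_with_logits <- function(logit, target) {
  # numerically stable: log(1 + exp(-|z|)) + max(z, 0) - z * t
  pmax(logit, 0) - logit * target + log1p(exp(-abs(logit)))
}

#' Composite detection loss and its gradient
#'
#' Computes the three-term loss over a batch and, in the same pass, the
#' gradient with respect to every raw prediction value, ready to feed the
#' network's backward pass.
#'
#' @param preds list of three raw prediction arrays
#'   `(H_s, W_s, 3*(5+N), batch)`.
#' @param targets list (length batch) of lists with elements `boxes`
#'   (corner-form matrix, input pixels) and `classes` (0-based integer
#'   vector).
#' @param cfg an [ardnet_config()] (anchors, input size, class count).
#' @param loss_cfg a [loss_config()].
#' @return list with `total`, `class`, `conf`, `loc`, `n_pos`, and
#'   `dgrids` (gradients, same shapes as `preds`).
#' @export
compute_loss <- function(preds, targets, cfg, loss_cfg = loss_config()) {
  nc <- cfg$n_classes
  d <- 5 + nc
  nb <- dim(preds[[1]])[4]
  anchors <- cfg$anchors
  mean_red <- loss_cfg$reduction == "mean"

  # collect assignments per image once
  assigns <- lapply(seq_len(nb), function(n) {
    t <- targets[[n]]
    if (is.null(t$boxes) || nrow(as_box_matrix(t$boxes)) == 0)
      return(NULL)
    a <- match_targets(t$boxes, anchors, cfg$input_size)
    if (nrow(a) == 0) return(NULL)
    a$image <- n
    a
  })
  asg <- do.call(rbind, assigns)
  n_pos <- if (is.null(asg)) 0L else nrow(asg)

  loss_cls <- 0; loss_loc <- 0; loss_conf <- 0
  dgrids <- lapply(preds, function(p) array(0, dim(p)))

  for (s in 1:3) {
    g <- preds[[s]]
    dg <- dgrids[[s]]
    h <- dim(g)[1]; w <- dim(g)[2]
    stride <- anchors$strides[s]
    an <- anchors_at_scale(anchors, s)
    obj_ch <- vapply(1:3, grid_channel_slot, numeric(1), field = "obj",
                     n_classes = nc)
    obj_logits <- g[, , obj_ch, , drop = FALSE]
    obj_t <- array(0, dim(obj_logits))
    obj_w <- array(loss_cfg$noobj_weight, dim(obj_logits))

    rows <- if (is.null(asg)) NULL else asg[asg$scale == s, , drop = FALSE]
    if (!is.null(rows) && nrow(rows) > 0) {
      i <- rows$cell_y + 1L; j <- rows$cell_x + 1L
      a <- rows$anchor; n <- rows$image
      tx <- g[cbind(i, j, (a - 1) * d + 1, n)]
      ty <- g[cbind(i, j, (a - 1) * d + 2, n)]
      tw <- g[cbind(i, j, (a - 1) * d + 3, n)]
      th <- g[cbind(i, j, (a - 1) * d + 4, n)]
      sx <- sigmoid(tx); sy <- sigmoid(ty)
      sw <- sigmoid(tw); sh <- sigmoid(th)
      bx <- (2 * sx - 0.5 + rows$cell_x) * stride
      by <- (2 * sy - 0.5 + rows$cell_y) * stride
      bw <- an[a, 1] * (2 * sw)^2
      bh <- an[a, 2] * (2 * sh)^2
      pred_box <- box_from_cxcywh(cbind(bx, by, bw, bh))
      gt_box <- t(vapply(seq_len(nrow(rows)), function(k)
        as_box_matrix(targets[[rows$image[k]]]$boxes)[rows$gt[k], ],
        numeric(4)))
      lci <- ciou_loss(pred_box, gt_box)
      gci <- ciou_loss_grad(pred_box, gt_box)
      loc_scale <- loss_cfg$lambda_loc * (if (mean_red) 1 / max(n_pos, 1) else 1)
      loss_loc <- loss_loc + loc_scale * sum(lci)
      # chain through the decode: d b / d t
      dtx <- gci[, 1] * stride * 2 * sx * (1 - sx)
      dty <- gci[, 2] * stride * 2 * sy * (1 - sy)
      dtw <- gci[, 3] * an[a, 1] * 8 * sw * sw * (1 - sw)
      dth <- gci[, 4] * an[a, 2] * 8 * sh * sh * (1 - sh)
      add_at <- function(dg, idx, val) {
        # duplicate-safe scatter-add (few positives; loop is fine)
        for (q in seq_len(nrow(idx)))
          dg[idx[q, 1], idx[q, 2], idx[q, 3], idx[q, 4]] <-
            dg[idx[q, 1], idx[q, 2], idx[q, 3], idx[q, 4]] + val[q]
        dg
      }
      dg <- add_at(dg, cbind(i, j, (a - 1) * d + 1, n), loc_scale * dtx)
      dg <- add_at(dg, cbind(i, j, (a - 1) * d + 2, n), loc_scale * dty)
      dg <- add_at(dg, cbind(i, j, (a - 1) * d + 3, n), loc_scale * dtw)
      dg <- add_at(dg, cbind(i, j, (a - 1) * d + 4, n), loc_scale * dth)
      # objectness targets (detached) and positive weights
      tgt <- if (loss_cfg$obj_target == "ciou")
        pmax(0, pmin(1, 1 - lci)) else rep(1, length(lci))
      for (q in seq_len(nrow(rows))) {
        obj_t[i[q], j[q], a[q], n[q]] <- max(obj_t[i[q], j[q], a[q], n[q]],
                                             tgt[q])
        obj_w[i[q], j[q], a[q], n[q]] <- 1
      }
      # classification on positives
      if (nc > 0) {
        cls_scale <- loss_cfg$lambda_class *
          (if (mean_red) 1 / (max(n_pos, 1) * nc) else 1)
        for (k in seq_len(nc)) {
          ch <- (a - 1) * d + 5 + k
          zl <- g[cbind(i, j, ch, n)]
          tcl <- as.numeric(vapply(seq_len(nrow(rows)), function(q)
            targets[[rows$image[q]]]$classes[rows$gt[q]], numeric(1)) ==
              (k - 1))
          loss_cls <- loss_cls + cls_scale * sum(bce_with_logits(zl, tcl))
          dg <- add_at(dg, cbind(i, j, ch, n),
                       cls_scale * (sigmoid(zl) - tcl))
        }
      }
    }
    # objectness over the whole grid
    conf_scale <- loss_cfg$lambda_conf * loss_cfg$balance[s] *
      (if (mean_red) 1 / length(obj_logits) else 1)
    loss_conf <- loss_conf +
      conf_scale * sum(obj_w * bce_with_logits(obj_logits, obj_t))
    dobj <- conf_scale * obj_w * (sigmoid(obj_logits) - obj_t)
    dg[, , obj_ch, ] <- dg[, , obj_ch, , drop = FALSE] + dobj
    dgrids[[s]] <- dg
  }
  list(total = loss_cls + loss_conf + loss_loc,
       class = loss_cls, conf = loss_conf, loc = loss_loc,
       n_pos = n_pos, dgrids = dgrids)
}

#' Individual loss terms
#'
#' Convenience wrappers that expose the three terms of [compute_loss()]
#' separately (same arguments).
#'
#' @inheritParams compute_loss
#' @return scalar loss value.
#' @export
classification_loss <- function(preds, targets, cfg,
                                loss_cfg = loss_config()) {
  compute_loss(preds, targets, cfg, loss_cfg)$class
}

#' @rdname classification_loss
#' @export
confidence_loss <- function(preds, targets, cfg, loss_cfg = loss_config()) {
  compute_loss(preds, targets, cfg, loss_cfg)$conf
}

#' @rdname classification_loss
#' @export
localization_loss <- function(preds, targets, cfg,
                              loss_cfg = loss_config()) {
  compute_loss(preds, targets, cfg, loss_cfg)$loc
}

#' @rdname classification_loss
#' @export
total_loss <- function(preds, targets, cfg, loss_cfg = loss_config()) {
  r <- compute_loss(preds, targets, cfg, loss_cfg)
  r[c("total", "class", "conf", "loc", "n_pos")]
}
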