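scene_targets <- function(scenes, class_map = NULL) {
  lapply(scenes, function(sc) {
    cls <- if (is.null(class_map)) rep(0L, length(sc$labels)) else {
      unname(class_map[sc$labels])
    }
    list(boxes = sc$boxes, classes = cls)
  })
}

batch_images <- function(scenes) {
  d <- dim(scenes[[1]]$image)
  x <- array(0, c(d[1], d[2], 3, length(scenes)))
  for (i in seq_along(scenes)) x[, , , i] <- scenes[[i]]$image
  x
}

#' Recalibrate batch-normalization statistics
#'
#' With small training batches, the exponentially averaged normalization
#' statistics can sit far from any statistics the heads were actually
#' trained under, which degrades inference badly. This pass recomputes
#' the running mean/variance of every normalization layer as the exact
#' average of batch statistics over the given scenes (cumulative-average
#' momentum 1/t), the "precise BN" recipe. Called automatically at the
#' end of [ardnet_train()].
#'
#' @param model an [ardnet_model()].
#' @param scenes list of [annotated_image()] with pixel arrays.
#' @param batch_size forward batch size for the calibration pass.
#' @return the model, invisibly (statistics updated in place).
#' @export
ardnet_calibrate_bn <- function(model, scenes, batch_size = 8) {
  g <- model$graph
  for (l in g$layers) if (!is.null(l$state$rm)) {
    l$state$rm[] <- 0
    l$state$rv[] <- 1
  }
  t <- 0
  for (b0 in seq(1, length(scenes), by = batch_size)) {
    t <- t + 1
    for (l in g$layers) if (!is.null(l$state$rm)) l$state$momentum <- 1 / t
    idx <- b0:min(b0 + batch_size - 1, length(scenes))
    nn_forward(g, batch_images(scenes[idx]), train = TRUE, keep = FALSE)
  }
  for (l in g$layers) l$state$momentum <- NULL
  invisible(model)
}

#' Train the detector
#'
#' Plain mini-batch training with Adam at a constant learning rate. The
#' defaults mirror the published protocol: learning rate 0.001, momentum
#' (Adam beta1) 0.6, batch size 16, Adam optimizer, no warmup or decay
#' (a cosine schedule is available behind `schedule = "cosine"`). Per
#' step the three loss terms (localization / objectness / classification)
#' are recorded so the loss traces can be plotted. The run is
#' deterministic given `seed` in single-threaded mode; the model (an
#' environment-backed graph) is updated in place.
#'
#' @param model an [ardnet_model()].
#' @param scenes list of [annotated_image()] with pixel arrays of the
#'   model's input size.
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size.
#' @param lr learning rate.
#' @param beta1 Adam first-moment decay (the protocol's "momentum").
#' @param seed RNG seed for shuffling (weights are initialized when the
#'   model is built).
#' @param loss_cfg a [loss_config()].
#' @param class_map named integer vector label -> 0-based class id
#'   (default: every label is class 0).
#' @param schedule `"constant"` (default) or `"cosine"`.
#' @param recalibrate_bn run [ardnet_calibrate_bn()] on the training
#'   scenes after the last step (recommended; see that function).
#' @param verbose print a run header and per-epoch mean losses.
#' @return data.frame history: epoch, step, total, class, conf, loc.
#' @export
ardnet_train <- function(model, scenes, epochs = 10, batch_size = 16,
                         lr = 0.001, beta1 = 0.6, seed = 0,
                         loss_cfg = loss_config(), class_map = NULL,
                         schedule = c("constant", "cosine"),
                         recalibrate_bn = TRUE, verbose = FALSE) {
  schedule <- match.arg(schedule)
  if (length(scenes) == 0) stop("ardnet_train: empty dataset")
  g <- model$graph
  targets <- scene_targets(scenes, class_map)
  opt <- adam_new(g, lr = lr, beta1 = beta1)
  if (verbose)
    message(sprintf(
      "train: optimizer=Adam lr=%g momentum(beta1)=%g batch=%d epochs=%d seed=%d",
      lr, beta1, batch_size, epochs, seed))
  hist <- list()
  n <- length(scenes)
  total_steps <- epochs * ceiling(n / batch_size)
  step <- 0L
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        x <- batch_images(scenes[idx])
        preds <- nn_forward(g, x, train = TRUE)
        ls <- compute_loss(preds, targets[idx], model$cfg, loss_cfg)
        nn_zero_grads(g)
        nn_backward(g, ls$dgrids)
        step <- step + 1L
        opt$lr <- if (schedule == "cosine")
          lr * 0.5 * (1 + cos(pi * step / total_steps)) else lr
        adam_step(g, opt)
        hist[[length(hist) + 1L]] <-
          data.frame(epoch = ep, step = step, total = ls$total,
                     class = ls$class, conf = ls$conf, loc = ls$loc,
                     n_pos = ls$n_pos)
      }
      if (verbose) {
        eh <- do.call(rbind, hist)
        eh <- eh[eh$epoch == ep, ]
        message(sprintf("epoch %d: total=%.4f loc=%.4f conf=%.4f cls=%.4f",
                        ep, mean(eh$total), mean(eh$loc), mean(eh$conf),
                        mean(eh$class)))
      }
    }
  })
  if (recalibrate_bn) ardnet_calibrate_bn(model, scenes)
  do.call(rbind, hist)
}

#' Detect objects in one image
#'
#' @param model a trained [ardnet_model()].
#' @param image array `(H, W, 3)` in \[0, 1\] at the model's input size.
#' @param score_thresh,iou_thresh decoding thresholds (see
#'   [decode_predictions()]).
#' @return detection data.frame.
#' @export
ardnet_detect <- function(model, image, score_thresh = 0.25,
                          iou_thresh = 0.45) {
  preds <- nn_forward(model$graph, image, train = FALSE, keep = FALSE)
  decode_predictions(preds, model$cfg$anchors, model$cfg$n_classes,
                     score_thresh, iou_thresh)
}

#' Evaluate average precision on annotated scenes
#'
#' Runs detection on every scene and scores AP at the requested IoU
#' thresholds (0.5 and 0.75 by default) for the single foreground class.
#'
#' @param model a trained [ardnet_model()].
#' @param scenes list of [annotated_image()] with pixel arrays.
#' @param iou_thresholds matching thresholds.
#' @param score_thresh detection score floor (kept low so the
#'   precision-recall curve is explored).
#' @return named numeric vector, e.g. `c(AP50 = ..., AP75 = ...)`.
#' @export
ardnet_evaluate <- function(model, scenes, iou_thresholds = c(0.5, 0.75),
                            score_thresh = 0.05) {
  dets <- list(); gts <- list()
  for (i in seq_along(scenes)) {
    d <- ardnet_detect(model, scenes[[i]]$image,
                       score_thresh = score_thresh)
    if (nrow(d) > 0) {
      d$image_id <- i
      dets[[length(dets) + 1L]] <- d
    }
    if (nrow(scenes[[i]]$boxes) > 0)
      gts[[length(gts) + 1L]] <-
        data.frame(image_id = i, x1 = scenes[[i]]$boxes[, 1],
                   y1 = scenes[[i]]$boxes[, 2], x2 = scenes[[i]]$boxes[, 3],
                   y2 = scenes[[i]]$boxes[, 4])
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    data.frame(image_id = integer(), score = numeric(), x1 = numeric(),
               y1 = numeric(), x2 = numeric(), y2 = numeric())
  gts <- do.call(rbind, gts)
  out <- vapply(iou_thresholds, function(th)
    average_precision(dets, gts, th), numeric(1))
  names(out) <- paste0("AP", round(iou_thresholds * 100))
  out
}

#' Save and load model checkpoints
#'
#' A checkpoint is the configuration plus the flat weight container
#' (including optimizer-independent normalization statistics), written
#' with `saveRDS`.
#'
#' @param model an [ardnet_model()].
#' @param path checkpoint path.
#' @export
ardnet_save <- function(model, path) {
  cfgl <- unclass(model$cfg)
  cfgl$anchors <- list(sizes = model$cfg$anchors$sizes,
                       strides = model$cfg$anchors$strides)
  saveRDS(list(config = cfgl, state = ardnet_state(model)), path)
  invisible(path)
}

#' @rdname ardnet_save
#' @export
ardnet_load <- function(path) {
  ck <- readRDS(path)
  cl <- ck$config
  cfg <- ardnet_config(
    n_classes = cl$n_classes, input_size = cl$input_size,
    width_multiple = cl$width_multiple, depth_multiple = cl$depth_multiple,
    backbone_involution = cl$backbone_involution, inv20 = cl$inv20,
    inv23 = cl$inv23, cbam10 = cl$cbam10,
    anchors = anchor_set(cl$anchors$sizes, cl$anchors$strides),
    allow_small_involution = cl$allow_small_involution,
    inv_K = cl$inv_K, inv_r = cl$inv_r)
  model <- ardnet_model(cfg)
  ardnet_load_state(model, ck$state)
  model
}
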