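#' Annotated images
#'
#' An `annotated_image` couples an image (array or path) with a set of
#' labeled boxes in the package's internal convention: continuous,
#' 0-based pixel coordinates. Pascal-VOC XML stores corners 1-based
#' inclusive, so reading subtracts 1 from `xmin`/`ymin` and writing adds
#' it back; the shift round-trips exactly.
#'
#' @param image image array `(H, W, 3)` in \[0, 1\], or a file path, or
#'   `NULL`.
#' @param boxes corner-form box matrix (may have zero rows).
#' @param labels character vector of class labels, one per box.
#' @param size `c(width, height)` in pixels (required if `image` is not
#'   an array).
#' @param source free-text provenance string.
#' @return an object of class `annotated_image`.
#' @export
annotated_image <- function(image = NULL, boxes = NULL, labels = character(),
                            size = NULL, source = "ardnet") {
  boxes <- if (is.null(boxes) || length(boxes) == 0) {
    matrix(numeric(0), 0, 4, dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  } else as_box_matrix(boxes)
  if (nrow(boxes) != length(labels))
    stop("annotated_image: one label per box required")
  if (any(!nzchar(labels))) stop("annotated_image: labels must be nonempty")
  if (is.null(size)) {
    if (!is.array(image)) stop("annotated_image: size required")
    size <- c(dim(image)[2], dim(image)[1])
  }
  if (nrow(boxes) > 0 &&
      (any(boxes[, 1] < 0) || any(boxes[, 2] < 0) ||
       any(boxes[, 3] > size[1]) || any(boxes[, 4] > size[2])))
    stop("annotated_image: boxes must lie within image bounds")
  structure(list(image = image, boxes = boxes, labels = labels,
                 size = as.numeric(size), source = source),
            class = "annotated_image")
}

#' Read a Pascal-VOC XML annotation
#'
#' @param path path to the XML file.
#' @return an [annotated_image()] (image field holds the `filename`
#'   entry, not pixels).
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  size_node <- xml2::xml_find_first(doc, "./size")
  if (inherits(size_node, "xml_missing"))
    stop("read_voc_xml: missing <size> node in ", path)
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(size_node, "./width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(size_node, "./height")))
  objs <- xml2::xml_find_all(doc, "./object")
  labels <- character(0)
  boxes <- matrix(numeric(0), 0, 4)
  for (o in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    bb <- xml2::xml_find_first(o, "./bndbox")
    num <- function(f) as.numeric(xml2::xml_text(xml2::xml_find_first(bb, f)))
    b <- c(num("./xmin") - 1, num("./ymin") - 1, num("./xmax"), num("./ymax"))
    if (b[1] < 0 || b[2] < 0 || b[3] > w || b[4] > h)
      stop(sprintf("read_voc_xml: box (%g, %g, %g, %g) outside %gx%g image in %s",
                   b[1], b[2], b[3], b[4], w, h, path))
    boxes <- rbind(boxes, b)
    labels <- c(labels, nm)
  }
  fn <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  annotated_image(image = if (is.na(fn)) NULL else fn, boxes = boxes,
                  labels = labels, size = c(w, h), source = path)
}

#' Write a Pascal-VOC XML annotation
#'
#' @param ann an [annotated_image()].
#' @param path output path.
#' @param filename image filename recorded in the XML.
#' @return the path, invisibly.
#' @export
write_voc_xml <- function(ann, path, filename = NULL) {
  if (is.null(filename))
    filename <- if (is.character(ann$image)) ann$image else
      paste0(tools::file_path_sans_ext(basename(path)), ".png")
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", filename)
  src <- xml2::xml_add_child(doc, "source")
  xml2::xml_add_child(src, "database", ann$source)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(ann$size[1]))
  xml2::xml_add_child(size, "height", format(ann$size[2]))
  xml2::xml_add_child(size, "depth", "3")
  for (k in seq_len(nrow(ann$boxes))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", ann$labels[k])
    xml2::xml_add_child(o, "pose", "Unspecified")
    xml2::xml_add_child(o, "truncated", "0")
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
    xml2::xml_add_child(bb, "xmin", fmt(ann$boxes[k, 1] + 1))
    xml2::xml_add_child(bb, "ymin", fmt(ann$boxes[k, 2] + 1))
    xml2::xml_add_child(bb, "xmax", fmt(ann$boxes[k, 3]))
    xml2::xml_add_child(bb, "ymax", fmt(ann$boxes[k, 4]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Deterministic train/val/test partition
#'
#' Shuffles `ids` with a local RNG seeded by `seed` (the caller's RNG
#' state is untouched) and cuts the permutation into three parts of sizes
#' `round(n * ratio)`, assigning any rounding remainder to the training
#' split. Partitions are disjoint and exhaustive; 1400 ids at the default
#' 0.6/0.2/0.2 give 840/280/280.
#'
#' @param ids vector of identifiers.
#' @param ratios length-3 positive numeric summing to 1
#'   (train, val, test).
#' @param seed integer seed.
#' @return named list `train`, `val`, `test`.
#' @export
split_dataset <- function(ids, ratios = c(0.6, 0.2, 0.2), seed = 0) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop("split_dataset: ratios must be three positive numbers summing to 1")
  n <- length(ids)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  perm <- sample(n)
  n_val <- round(n * ratios[2]); n_test <- round(n * ratios[3])
  n_train <- n - n_val - n_test
  list(train = ids[perm[seq_len(n_train)]],
       val = ids[perm[n_train + seq_len(n_val)]],
       test = ids[perm[n_train + n_val + seq_len(n_test)]])
}
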