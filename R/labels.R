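#' Create a labeled image
#'
#' The central data record: an RGB pixel array, its ground-truth boxes, and
#' (optionally) per-instance binary masks. Masks are *amodal*: they cover
#' the full extent of the instance even where it is occluded, so each fruit
#' mask's tight bounding rectangle equals its box. Fruit masks come first
#' and are aligned one-to-one with `boxes`; leaf-occluder masks (which have
#' no boxes) follow.
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 255]`.
#' @param boxes normalized center-format boxes (see [yolo_boxes()]).
#' @param masks optional list of logical `H x W` matrices.
#' @param mask_categories character vector (`"fruit"`/`"leaf"`), one per mask.
#' @param image_id string identifier.
#' @return an object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, boxes = yolo_boxes(), masks = NULL,
                          mask_categories = NULL, image_id = "img") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (min(pixels) < 0 || max(pixels) > 255) stop("pixel values outside [0,255]")
  validate_boxes(boxes)
  if (!is.null(masks)) {
    stopifnot(is.list(masks), length(mask_categories) == length(masks))
    nf <- sum(mask_categories == "fruit")
    if (nf != nrow(boxes))
      stop("fruit masks must align one-to-one with boxes")
  }
  structure(list(pixels = pixels, boxes = boxes, masks = masks,
                 mask_categories = mask_categories, image_id = image_id),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image '%s'> %dx%d px, %d boxes, %d masks\n",
              x$image_id, d[2], d[1], nrow(x$boxes),
              length(x$masks %||% list())))
  invisible(x)
}

#' Read YOLO-format labels from a text file
#'
#' Each line is `class cx cy w h` with whitespace separation and normalized
#' coordinates. Malformed lines raise an error naming the line number.
#'
#' @param path label file path.
#' @param image_size optional `c(W, H)`; accepted for interface symmetry
#'   with [convert_box()] (the normalized format does not need it).
#' @return a normalized center-format box data.frame.
#' @export
read_labels <- function(path, image_size = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(yolo_boxes())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 5)
      stop(sprintf("parse error at line %d of %s: expected 5 fields, got %d",
                   i, path, length(f)))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop(sprintf("parse error at line %d of %s: non-numeric field", i, path))
    v
  })
  m <- do.call(rbind, rows)
  out <- data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                    w = m[, 4], h = m[, 5])
  tryCatch(validate_boxes(out),
           error = function(e) stop("validation error in ", path, ": ",
                                    conditionMessage(e)))
  out
}

#' Write YOLO-format labels
#'
#' @param boxes normalized center-format boxes.
#' @param path output file path.
#' @export
write_labels <- function(boxes, path) {
  validate_boxes(boxes)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   boxes$class, boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Split dataset ids into train and test sets
#'
#' Deterministic given `seed`; the train set holds `floor(ratio * N)` ids
#' (so 313 ids at ratio 0.7 give a 219/94 split), the rest go to test.
#'
#' @param ids unique id vector (length >= 2).
#' @param ratio train fraction in (0,1); default 0.7.
#' @param seed integer RNG seed.
#' @return list with `train_ids`, `test_ids`, `ratio`.
#' @export
split_dataset <- function(ids, ratio = 0.7, seed = 0L) {
  stopifnot(ratio > 0, ratio < 1)
  if (anyDuplicated(ids)) stop("ids must be unique")
  n <- length(ids)
  if (n < 2) stop("need at least 2 ids to split")
  n_train <- floor(ratio * n)
  train <- with_seed_(seed, sample(ids, n_train))
  list(train_ids = train, test_ids = setdiff(ids, train), ratio = ratio)
}

#' Read an image file into a `[0,255]` array
#' @param path PNG file path.
#' @return `H x W x 3` numeric array.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  round(px[, , 1:3, drop = FALSE] * 255)
}

#' Write a `[0,255]` image array as PNG
#' @param pixels `H x W x 3` array in `[0,255]`.
#' @param path output path.
#' @export
write_image <- function(pixels, path) {
  png::writePNG(clamp(pixels, 0, 255) / 255, path)
  invisible(path)
}

# dataset.yaml describing the on-disk layout (images/{train,test},
# labels/{train,test}, class names).
write_dataset_yaml <- function(dir, class_names = "fruit") {
  yaml::write_yaml(list(path = normalizePath(dir),
                        train = "images/train", test = "images/test",
                        names = as.list(class_names)),
                   file.path(dir, "dataset.yaml"))
}

#' Load a rendered dataset split from disk
#'
#' @param dir dataset root containing `images/` and `labels/`.
#' @param subset `"train"` or `"test"`.
#' @return list of `labeled_image` (without masks).
#' @export
load_dataset <- function(dir, subset = c("train", "test")) {
  subset <- match.arg(subset)
  imgs <- sort(list.files(file.path(dir, "images", subset),
                          pattern = "\\.png$", full.names = TRUE))
  lapply(imgs, function(p) {
    stem <- sub("\\.png$", "", basename(p))
    lab <- file.path(dir, "labels", subset, paste0(stem, ".txt"))
    boxes <- if (file.exists(lab)) read_labels(lab) else yolo_boxes()
    labeled_image(read_image(p), boxes, image_id = stem)
  })
}
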