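#' Construct a set of normalized center-format bounding boxes
#'
#' Boxes follow the YOLO label convention: each row is
#' `(class, cx, cy, w, h)` with all four coordinates normalized to `[0,1]`
#' relative to image width/height and `(cx, cy)` the box center. Pixel
#' coordinates elsewhere in the package are 0-based with half-open boxes
#' `[x1, x2) x [y1, y2)`.
#'
#' @param class integer vector of non-negative category ids.
#' @param cx,cy,w,h numeric vectors in `[0,1]`; `w`, `h` strictly positive.
#' @return a `data.frame` with columns `class, cx, cy, w, h`.
#' @export
yolo_boxes <- function(class = integer(), cx = numeric(), cy = numeric(),
                       w = numeric(), h = numeric()) {
  df <- data.frame(class = as.integer(class), cx = as.numeric(cx),
                   cy = as.numeric(cy), w = as.numeric(w), h = as.numeric(h))
  validate_boxes(df)
  df
}

#' Validate normalized center-format boxes
#'
#' @param boxes data.frame with columns `class, cx, cy, w, h`.
#' @return the validated data.frame, invisibly usable in pipelines.
#' @export
validate_boxes <- function(boxes) {
  stopifnot(is.data.frame(boxes),
            all(c("class", "cx", "cy", "w", "h") %in% names(boxes)))
  if (nrow(boxes) == 0) return(invisible(boxes))
  if (any(boxes$class < 0)) stop("negative category id")
  co <- as.matrix(boxes[, c("cx", "cy", "w", "h")])
  if (any(!is.finite(co))) stop("non-finite box coordinate")
  if (any(co < 0 | co > 1)) stop("box coordinate outside [0,1]")
  if (any(boxes$w <= 0 | boxes$h <= 0)) stop("box with non-positive size")
  invisible(boxes)
}

#' Convert boxes between normalized-center and absolute-corner conventions
#'
#' @param boxes for `"to_abs"`, a normalized center-format data.frame
#'   (`class, cx, cy, w, h`); for `"to_norm"`, a corner-format data.frame
#'   with columns `x1, y1, x2, y2` in pixels (other columns carried along).
#' @param image_size `c(W, H)` in pixels.
#' @param direction `"to_abs"` or `"to_norm"`.
#' @return the converted data.frame.
#' @export
convert_box <- function(boxes, image_size, direction = c("to_abs", "to_norm")) {
  direction <- match.arg(direction)
  W <- image_size[1]; H <- image_size[2]
  stopifnot(W > 0, H > 0)
  if (direction == "to_abs") {
    validate_boxes(boxes)
    out <- data.frame(class = boxes$class,
                      x1 = (boxes$cx - boxes$w / 2) * W,
                      y1 = (boxes$cy - boxes$h / 2) * H,
                      x2 = (boxes$cx + boxes$w / 2) * W,
                      y2 = (boxes$cy + boxes$h / 2) * H)
    if (nrow(out) && any(out$x2 - out$x1 <= 0 | out$y2 - out$y1 <= 0))
      stop("degenerate box after scaling")
    out
  } else {
    stopifnot(all(c("x1", "y1", "x2", "y2") %in% names(boxes)))
    if (nrow(boxes) && any(boxes$x2 <= boxes$x1 | boxes$y2 <= boxes$y1))
      stop("degenerate corner box")
    data.frame(class = boxes$class %||% 0L,
               cx = (boxes$x1 + boxes$x2) / 2 / W,
               cy = (boxes$y1 + boxes$y2) / 2 / H,
               w = (boxes$x2 - boxes$x1) / W,
               h = (boxes$y2 - boxes$y1) / H)
  }
}

#' Intersection-over-union of corner-format boxes
#'
#' Rows of `a` are compared against rows of `b`, returning the full IoU
#' matrix (overlap area divided by union area; 0 for disjoint boxes).
#'
#' @param a,b matrices or data.frames with columns `x1, y1, x2, y2`.
#' @return an `nrow(a) x nrow(b)` matrix of IoU values in `[0,1]`.
#' @export
box_iou <- function(a, b) {
  a <- as.matrix(as.data.frame(a)[, c("x1", "y1", "x2", "y2")])
  b <- as.matrix(as.data.frame(b)[, c("x1", "y1", "x2", "y2")])
  if (any(a[, 3] <= a[, 1] | a[, 4] <= a[, 2]) ||
      any(b[, 3] <= b[, 1] | b[, 4] <= b[, 2]))
    stop("degenerate box in IoU")
  n <- nrow(a); m <- nrow(b)
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- outer(area_a, area_b, `+`) - inter
  inter / un
}

#' Complete IoU (CIoU) between paired corner-format boxes
#'
#' CIoU augments IoU with a normalized center-distance penalty and an
#' aspect-ratio consistency penalty:
#' `CIoU = IoU - rho^2/c^2 - alpha*v`, where `rho` is the distance between
#' box centers, `c` the diagonal of the smallest enclosing box,
#' `v = (4/pi^2) (atan(w_b/h_b) - atan(w_a/h_a))^2` and
#' `alpha = v / (1 - IoU + v)`. Values lie in `(-1, 1]`, with 1 for
#' identical boxes; it is the box-regression quality used by the training
#' loss.
#'
#' @param a,b data.frames/matrices with columns `x1, y1, x2, y2`; compared
#'   row by row (recycled if one has a single row).
#' @return numeric vector of CIoU values.
#' @export
ciou <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), ]; b <- b[rep_len(seq_len(nrow(b)), n), ]
  wa <- a$x2 - a$x1; ha <- a$y2 - a$y1
  wb <- b$x2 - b$x1; hb <- b$y2 - b$y1
  if (any(wa <= 0 | ha <= 0 | wb <= 0 | hb <= 0)) stop("degenerate box in CIoU")
  ix <- pmax(0, pmin(a$x2, b$x2) - pmax(a$x1, b$x1))
  iy <- pmax(0, pmin(a$y2, b$y2) - pmax(a$y1, b$y1))
  inter <- ix * iy
  iou <- inter / (wa * ha + wb * hb - inter)
  cw <- pmax(a$x2, b$x2) - pmin(a$x1, b$x1)
  ch <- pmax(a$y2, b$y2) - pmin(a$y1, b$y1)
  c2 <- cw^2 + ch^2 + 1e-12
  rho2 <- ((a$x1 + a$x2 - b$x1 - b$x2)^2 + (a$y1 + a$y2 - b$y1 - b$y2)^2) / 4
  v <- (4 / pi^2) * (atan(wb / hb) - atan(wa / ha))^2
  alpha <- v / (1 - iou + v + 1e-12)
  iou - rho2 / c2 - alpha * v
}

#' Greedy non-maximum suppression
#'
#' Detections are processed in descending confidence within each category;
#' a box whose IoU with an already-kept box of the same category exceeds
#' `iou_threshold` is suppressed.
#'
#' @param dets data.frame with columns `class, conf, x1, y1, x2, y2`.
#' @param iou_threshold suppression threshold (default 0.45).
#' @return the surviving detections, still sorted by descending confidence.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (nrow(dets) == 0) return(dets)
  keep_all <- list()
  for (cl in unique(dets$class)) {
    d <- dets[dets$class == cl, , drop = FALSE]
    d <- d[order(-d$conf), , drop = FALSE]
    n <- nrow(d)
    b <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
    alive <- rep(TRUE, n)
    keep <- logical(n)
    area <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
    for (i in seq_len(n)) {
      if (!alive[i]) next
      keep[i] <- TRUE
      if (i < n) {
        rest <- which(alive)
        rest <- rest[rest > i]
        if (length(rest)) {
          iw <- pmax(0, pmin(b[i, 3], b[rest, 3]) - pmax(b[i, 1], b[rest, 1]))
          ih <- pmax(0, pmin(b[i, 4], b[rest, 4]) - pmax(b[i, 2], b[rest, 2]))
          inter <- iw * ih
          ious <- inter / (area[i] + area[rest] - inter)
          alive[rest[ious > iou_threshold]] <- FALSE
        }
      }
    }
    keep_all[[as.character(cl)]] <- d[keep, , drop = FALSE]
  }
  out <- do.call(rbind, keep_all)
  rownames(out) <- NULL
  out[order(-out$conf), , drop = FALSE]
}
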