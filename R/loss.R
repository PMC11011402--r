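# Training loss: CIoU box regression, binary cross-entropy objectness with
# CIoU-valued soft targets, binary cross-entropy classification, combined
# with per-term weights and per-scale objectness balancing. The head
# gradient is assembled analytically for the BCE terms and by central
# finite differences (4 scalars per matched box) for the CIoU term, then
# backpropagated through the network tape.

#' Assign ground-truth boxes to anchors and grid cells
#'
#' The ratio rule of the v5 family: a ground truth matches an anchor when
#' `max(w/wa, wa/w, h/ha, ha/h) < 4`; each match is placed in its own grid
#' cell plus the two nearest neighbour cells (by center-fraction), clamped
#' to the grid.
#'
#' @param boxes normalized center-format boxes (`class, cx, cy, w, h`).
#' @param anchors `9 x 2` anchor matrix (pixels).
#' @param img_size network input size (pixels, square).
#' @param strides head strides.
#' @param ratio_threshold the anchor ratio bound (default 4).
#' @return data.frame: scale, anchor (1-3), gx, gy (0-based cell), gt
#'   fields `cx, cy, bw, bh` in grid units of that scale, and `class`.
#' @export
assign_targets <- function(boxes, anchors, img_size,
                           strides = c(8L, 16L, 32L), ratio_threshold = 4) {
  out <- list()
  if (!nrow(boxes)) {
    return(data.frame(scale = integer(), anchor = integer(), gx = integer(),
                      gy = integer(), cx = numeric(), cy = numeric(),
                      bw = numeric(), bh = numeric(), class = integer()))
  }
  nb <- nrow(boxes)
  for (s in seq_along(strides)) {
    stride <- strides[s]
    ng <- img_size %/% stride
    anc <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE] / stride
    bw <- boxes$w * img_size / stride
    bh <- boxes$h * img_size / stride
    cx <- boxes$cx * img_size / stride
    cy <- boxes$cy * img_size / stride
    for (a in 1:3) {
      r <- pmax(pmax(bw / anc[a, 1], anc[a, 1] / bw),
                pmax(bh / anc[a, 2], anc[a, 2] / bh))
      hit <- which(r < ratio_threshold)
      if (!length(hit)) next
      gx0 <- floor(cx[hit]); gy0 <- floor(cy[hit])
      fx <- cx[hit] - gx0; fy <- cy[hit] - gy0
      # own cell + horizontal and vertical nearest neighbours
      gxs <- c(gx0, ifelse(fx < 0.5, gx0 - 1, gx0 + 1), gx0)
      gys <- c(gy0, gy0, ifelse(fy < 0.5, gy0 - 1, gy0 + 1))
      bb <- rep(hit, 3L)
      ok <- gxs >= 0 & gys >= 0 & gxs < ng & gys < ng &
        cx[bb] - gxs > -0.5 & cx[bb] - gxs < 1.5 &
        cy[bb] - gys > -0.5 & cy[bb] - gys < 1.5
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        scale = s, anchor = a, gx = gxs[ok], gy = gys[ok],
        cx = cx[bb][ok], cy = cy[bb][ok], bw = bw[bb][ok], bh = bh[bb][ok],
        class = boxes$class[bb][ok])
    }
  }
  if (!length(out)) return(assign_targets(boxes[0, ], anchors, img_size))
  do.call(rbind, out)
}

# CIoU between a decoded prediction (raw 4-vector, grid units) and a gt
# box in grid units, for one anchor (grid units). Scalar arithmetic only:
# this sits in the innermost training loop (called once per assignment
# plus eight times for the finite-difference box gradient).
decode_ciou <- function(traw, gx, gy, anc, gt) {
  sx <- 1 / (1 + exp(-traw[1])); sy <- 1 / (1 + exp(-traw[2]))
  sw <- 1 / (1 + exp(-traw[3])); sh <- 1 / (1 + exp(-traw[4]))
  px <- 2 * sx - 0.5 + gx; py <- 2 * sy - 0.5 + gy
  pw <- (2 * sw)^2 * anc[1]; ph <- (2 * sh)^2 * anc[2]
  ax1 <- px - pw / 2; ay1 <- py - ph / 2; ax2 <- px + pw / 2; ay2 <- py + ph / 2
  bx1 <- gt[1] - gt[3] / 2; by1 <- gt[2] - gt[4] / 2
  bx2 <- gt[1] + gt[3] / 2; by2 <- gt[2] + gt[4] / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  iou <- inter / (pw * ph + gt[3] * gt[4] - inter)
  cw <- max(ax2, bx2) - min(ax1, bx1)
  chh <- max(ay2, by2) - min(ay1, by1)
  c2 <- cw^2 + chh^2 + 1e-12
  rho2 <- ((ax1 + ax2 - bx1 - bx2)^2 + (ay1 + ay2 - by1 - by2)^2) / 4
  v <- (4 / pi^2) * (atan(gt[3] / gt[4]) - atan(pw / ph))^2
  alpha <- v / (1 - iou + v + 1e-12)
  iou - rho2 / c2 - alpha * v
}

#' Compute the detection loss and its head gradients
#'
#' `box = mean(1 - CIoU)` over assignments; `obj` = mean binary
#' cross-entropy per scale (balanced 4/1/0.4) against soft targets equal
#' to the clamped CIoU of the matched prediction; `cls` = mean BCE over
#' assigned cells. `total = w_box*box + w_obj*obj + w_cls*cls`.
#'
#' @param raw list of 3 raw head arrays `(3*(5+nc), H, W, N)`.
#' @param targets_list list of length N of [assign_targets()] frames.
#' @param n_classes number of categories.
#' @param anchors anchor matrix (pixels); @param strides head strides.
#' @param weights named vector `c(box, obj, cls)`.
#' @return list: `terms` (box, obj, cls, total), `grads` (list of arrays
#'   matching `raw`).
#' @export
compute_loss <- function(raw, targets_list, n_classes, anchors,
                         strides = c(8L, 16L, 32L),
                         weights = c(box = 0.05, obj = 1.0, cls = 0.5)) {
  nf <- 5L + n_classes
  N <- dim(raw[[1]])[4]
  balance <- c(4.0, 1.0, 0.4)
  grads <- lapply(raw, function(m) array(0, dim(m)))
  box_losses <- c(); n_box <- 0L
  cls_loss <- 0; n_cls <- 0L
  obj_loss <- 0
  eps_fd <- 1e-4
  for (s in 1:3) {
    m <- raw[[s]]
    d <- dim(m)
    H <- d[2]; W <- d[3]
    dim(m) <- c(nf, 3L, H, W, N)
    gm <- array(0, dim(m))
    tobj <- array(0, c(3L, H, W, N))
    anc <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE] / strides[s]
    for (n in seq_len(N)) {
      tg <- targets_list[[n]]
      tg <- tg[tg$scale == s, , drop = FALSE]
      for (k in seq_len(nrow(tg))) {
        a <- tg$anchor[k]; gx <- tg$gx[k]; gy <- tg$gy[k]
        iy <- gy + 1L; ix <- gx + 1L
        traw <- m[1:4, a, iy, ix, n]
        gt <- c(tg$cx[k], tg$cy[k], tg$bw[k], tg$bh[k])
        ci <- decode_ciou(traw, gx, gy, anc[a, ], gt)
        box_losses <- c(box_losses, 1 - ci)
        n_box <- n_box + 1L
        # box gradient by central differences on the 4 raw scalars
        for (j in 1:4) {
          tp <- traw; tmn <- traw
          tp[j] <- tp[j] + eps_fd; tmn[j] <- tmn[j] - eps_fd
          gm[j, a, iy, ix, n] <- gm[j, a, iy, ix, n] +
            ((1 - decode_ciou(tp, gx, gy, anc[a, ], gt)) -
             (1 - decode_ciou(tmn, gx, gy, anc[a, ], gt))) / (2 * eps_fd)
        }
        tobj[a, iy, ix, n] <- max(tobj[a, iy, ix, n], clamp(ci, 0, 1))
        # classification BCE at the assigned location
        for (c_ in seq_len(n_classes)) {
          y <- as.numeric(tg$class[k] == c_ - 1L)
          z <- m[5L + c_, a, iy, ix, n]
          p <- 1 / (1 + exp(-z))
          cls_loss <- cls_loss - (y * log(max(p, 1e-12)) +
                                  (1 - y) * log(max(1 - p, 1e-12)))
          n_cls <- n_cls + 1L
          gm[5L + c_, a, iy, ix, n] <- gm[5L + c_, a, iy, ix, n] +
            (p - y)   # scaled later by w_cls / n_cls
        }
      }
    }
    # objectness BCE over every cell of the scale
    zobj <- array(m[5, , , , , drop = FALSE], c(3L, H, W, N))
    pobj <- 1 / (1 + exp(-zobj))
    numel <- length(zobj)
    obj_loss <- obj_loss - balance[s] *
      mean(tobj * log(pmax(pobj, 1e-12)) +
           (1 - tobj) * log(pmax(1 - pobj, 1e-12)))
    obj_g <- array(gm[5, , , , , drop = FALSE], c(3L, H, W, N)) +
      weights["obj"] * balance[s] * (pobj - tobj) / numel
    gm[5, , , , ] <- obj_g
    grads[[s]] <- gm
  }
  box_term <- if (n_box) mean(box_losses) else 0
  cls_term <- if (n_cls) cls_loss / n_cls else 0
  # scale the deferred box/cls gradients
  for (s in 1:3) {
    gm <- grads[[s]]
    d <- dim(gm)
    if (n_box) gm[1:4, , , , ] <- gm[1:4, , , , ] * weights["box"] / n_box
    if (n_cls && n_classes >= 1)
      gm[5L + seq_len(n_classes), , , , ] <-
        gm[5L + seq_len(n_classes), , , , ] * weights["cls"] / n_cls
    dim(gm) <- c(d[1] * d[2], d[3], d[4], d[5])
    grads[[s]] <- gm
  }
  total <- weights["box"] * box_term + weights["obj"] * obj_loss +
    weights["cls"] * cls_term
  list(terms = c(box = box_term, obj = obj_loss, cls = cls_term,
                 total = unname(total)),
       grads = grads)
}
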