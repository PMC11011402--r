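#' Default anchor set
#'
#' The standard nine anchors of the 640-pixel single-stage family, three
#' per detection scale (strides 8, 16, 32), scaled proportionally for
#' other input sizes. Rows are `(w, h)` in pixels, sorted by area within
#' scale.
#'
#' @param img_size network input size in pixels.
#' @return a `9 x 2` matrix of anchor sizes.
#' @export
default_anchors <- function(img_size = 640) {
  a <- matrix(c(10, 13, 16, 30, 33, 23,
                30, 61, 62, 45, 59, 119,
                116, 90, 156, 198, 373, 326),
              ncol = 2, byrow = TRUE)
  a * img_size / 640
}

#' Detector architecture configuration
#'
#' `widths` gives the channel plan `(stem, P2, P3, P4, P5)`; `depths` the
#' number of bottlenecks in the four backbone C3 stages. Conv-AT blocks
#' replace the stride-2 downsampling convolutions between backbone stages.
#'
#' @param widths integer vector of 5 channel counts.
#' @param depths integer vector of 4 C3 depths.
#' @param n_classes number of object categories.
#' @param img_size nominal square input size (pixels).
#' @param r channel-attention reduction ratio.
#' @param use_ca,use_sa attention ablation toggles.
#' @param anchors `9 x 2` anchor matrix (pixels).
#' @return a list of class `gd_arch`.
#' @export
arch_config <- function(widths = c(32L, 64L, 128L, 256L, 512L),
                        depths = c(1L, 2L, 3L, 1L),
                        n_classes = 1L, img_size = 640L, r = 16L,
                        use_ca = TRUE, use_sa = TRUE,
                        anchors = default_anchors(img_size)) {
  stopifnot(length(widths) == 5, length(depths) == 4,
            all(widths %% 2 == 0), nrow(anchors) == 9)
  structure(list(widths = as.integer(widths), depths = as.integer(depths),
                 n_classes = as.integer(n_classes),
                 img_size = as.integer(img_size), r = as.integer(r),
                 use_ca = use_ca, use_sa = use_sa, anchors = anchors),
            class = "gd_arch")
}

#' Miniature architecture for desk-scale experiments
#'
#' A narrow configuration (8-96 channels, single bottlenecks, attention
#' reduction 4) sized so a full train/evaluate cycle runs on one CPU core
#' in minutes at 160-pixel inputs. The deeper stages keep more width than
#' a uniform shrink would give them: at low resolution they are cheap,
#' and the capacity there is what separates fruit from leaf texture.
#'
#' @inheritParams arch_config
#' @return a `gd_arch` configuration.
#' @export
arch_config_mini <- function(n_classes = 1L, img_size = 160L,
                             use_ca = TRUE, use_sa = TRUE) {
  arch_config(widths = c(8L, 16L, 32L, 64L, 96L), depths = c(1L, 1L, 1L, 1L),
              n_classes = n_classes, img_size = img_size, r = 4L,
              use_ca = use_ca, use_sa = use_sa,
              anchors = default_anchors(img_size))
}

#' Build the detector
#'
#' Assembles the backbone (CBS stem, Conv-AT downsampling blocks, C3
#' stages, SPPF), a top-down FPN that carries deep semantic features to
#' the finer scales, a bottom-up PAN that carries localization detail back
#' up, and a three-scale anchor-based head emitting
#' `3 * (5 + n_classes)` channels per grid location at strides 8/16/32.
#'
#' @param arch a `gd_arch` configuration.
#' @param seed integer seed for weight initialization.
#' @return a model object of class `gd_model`.
#' @export
build_detector <- function(arch = arch_config(), seed = 0L) {
  w <- arch$widths; d <- arch$depths
  nc <- arch$n_classes
  no <- 3L * (5L + nc)
  L <- with_seed_(seed, {
    list(
      stem  = layer_conv(3L, w[1], 3L, 2L),
      at1   = layer_conv_at(w[1], w[2], 2L, arch$r, arch$use_ca, arch$use_sa),
      c3_1  = layer_c3(w[2], w[2], d[1]),
      at2   = layer_conv_at(w[2], w[3], 2L, arch$r, arch$use_ca, arch$use_sa),
      c3_2  = layer_c3(w[3], w[3], d[2]),
      at3   = layer_conv_at(w[3], w[4], 2L, arch$r, arch$use_ca, arch$use_sa),
      c3_3  = layer_c3(w[4], w[4], d[3]),
      at4   = layer_conv_at(w[4], w[5], 2L, arch$r, arch$use_ca, arch$use_sa),
      c3_4  = layer_c3(w[5], w[5], d[4]),
      sppf  = layer_sppf(w[5], w[5]),
      lat5  = layer_conv(w[5], w[4], 1L),
      fpn4  = layer_c3(2L * w[4], w[4], 1L, shortcut = FALSE),
      lat4  = layer_conv(w[4], w[3], 1L),
      fpn3  = layer_c3(2L * w[3], w[3], 1L, shortcut = FALSE),
      down3 = layer_conv(w[3], w[3], 3L, 2L),
      pan4  = layer_c3(2L * w[3], w[4], 1L, shortcut = FALSE),
      down4 = layer_conv(w[4], w[4], 3L, 2L),
      pan5  = layer_c3(2L * w[4], w[5], 1L, shortcut = FALSE),
      head3 = layer_conv(w[3], no, 1L, act = "none", bn = FALSE),
      head4 = layer_conv(w[4], no, 1L, act = "none", bn = FALSE),
      head5 = layer_conv(w[5], no, 1L, act = "none", bn = FALSE))
  })
  # Bias the objectness logits towards rarity so early training is stable.
  for (h in c("head3", "head4", "head5")) {
    b <- L[[h]]$params$b$value
    obj_idx <- (0:2) * (5L + nc) + 5L
    b[obj_idx] <- log(8 / (arch$img_size / 32)^2)
    L[[h]]$params$b$value <- b
  }
  model <- structure(
    list(arch = arch, layers = L, anchors = arch$anchors,
         strides = c(8L, 16L, 32L), n_classes = nc,
         class_names = paste0("class", seq_len(nc) - 1L)),
    class = "gd_model")
  model
}

#' @export
print.gd_model <- function(x, ...) {
  np <- sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
  cat(sprintf("<gd_model> widths %s | %d classes | %s parameters\n",
              paste(x$arch$widths, collapse = "/"), x$n_classes,
              format(np, big.mark = ",")))
  invisible(x)
}

#' @export
collect_params.gd_model <- function(layer) {
  out <- list()
  for (nm in names(layer$layers)) {
    ps <- collect_params(layer$layers[[nm]])
    names(ps) <- paste0(nm, ".", names(ps))
    out <- c(out, ps)
  }
  out
}

# Batch-norm running-state environments, for checkpointing.
collect_states <- function(model) {
  out <- list()
  walk <- function(l, prefix) {
    if (!is.null(l$meta$state)) out[[paste0(prefix, "bn")]] <<- l$meta$state
    for (nm in names(l$layers)) walk(l$layers[[nm]], paste0(prefix, nm, "."))
  }
  if (inherits(model, "gd_model")) {
    for (nm in names(model$layers)) walk(model$layers[[nm]], paste0(nm, "."))
  } else walk(model, "")
  out
}

#' Forward pass of the detector
#'
#' @param model a `gd_model`.
#' @param x input array `(3, H, W)` or `(3, H, W, N)`, values scaled to
#'   `[0, 1]`; `H`, `W` must be divisible by 32.
#' @param training use batch statistics in batch norm.
#' @return list of three raw head tensors (strides 8, 16, 32), each
#'   `(3*(5+nc), H/s, W/s, N)`.
#' @export
detector_forward <- function(model, x, training = FALSE) {
  x <- as_chwn(x)
  stopifnot(dim(x)[1] == 3, dim(x)[2] %% 32 == 0, dim(x)[3] %% 32 == 0)
  nodes <- detector_forward_nodes(model, ad_const(x), training)
  lapply(nodes, function(n) n$value)
}

# Tape-building forward used by both inference and the training loop.
detector_forward_nodes <- function(model, xn, training = FALSE) {
  L <- model$layers
  t1 <- L$c3_1$fwd(L$at1$fwd(L$stem$fwd(xn, training), training), training)
  p3 <- L$c3_2$fwd(L$at2$fwd(t1, training), training)
  p4 <- L$c3_3$fwd(L$at3$fwd(p3, training), training)
  p5 <- L$sppf$fwd(L$c3_4$fwd(L$at4$fwd(p4, training), training), training)
  l5 <- L$lat5$fwd(p5, training)
  f4 <- L$fpn4$fwd(op_concat_c(list(op_upsample2(l5), p4)), training)
  l4 <- L$lat4$fwd(f4, training)
  n3 <- L$fpn3$fwd(op_concat_c(list(op_upsample2(l4), p3)), training)
  n4 <- L$pan4$fwd(op_concat_c(list(L$down3$fwd(n3, training), l4)), training)
  n5 <- L$pan5$fwd(op_concat_c(list(L$down4$fwd(n4, training), l5)), training)
  list(L$head3$fwd(n3, training), L$head4$fwd(n4, training),
       L$head5$fwd(n5, training))
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

#' Decode raw head maps into detection boxes
#'
#' Per cell and anchor: `center = (2*sigmoid(t_xy) - 0.5 + grid) * stride`,
#' `size = (2*sigmoid(t_wh))^2 * anchor`, `conf = sigmoid(obj) *
#' max_c sigmoid(cls_c)`. Boxes are clipped to the image and those below
#' `conf_threshold` dropped.
#'
#' @param raw list of three raw head arrays for a single image
#'   (`(3*(5+nc), H/s, W/s)` or with a trailing batch dim of 1).
#' @param anchors `9 x 2` anchor matrix (pixels).
#' @param conf_threshold minimum confidence.
#' @param img_size `c(W, H)` of the network input in pixels.
#' @param n_classes number of categories.
#' @param strides the three head strides.
#' @return data.frame `class, conf, x1, y1, x2, y2` (absolute pixels).
#' @export
decode_predictions <- function(raw, anchors, conf_threshold = 0.001,
                               img_size, n_classes = 1L,
                               strides = c(8L, 16L, 32L)) {
  out <- list()
  nf <- 5L + n_classes
  for (s in seq_along(raw)) {
    m <- raw[[s]]
    if (length(dim(m)) == 4) m <- m[, , , 1, drop = TRUE]
    d <- dim(m)
    H <- d[2]; W <- d[3]
    dim(m) <- c(nf, 3L, H, W)
    stride <- strides[s]
    anc <- anchors[(s - 1) * 3 + 1:3, , drop = FALSE]
    gx <- array(rep(0:(W - 1), each = 3 * H), c(3, H, W))
    gy <- array(rep(rep(0:(H - 1), each = 3), W), c(3, H, W))
    aw <- array(anc[, 1], c(3, H, W))
    ah <- array(anc[, 2], c(3, H, W))
    tx <- sigmoid_(m[1, , , ]); ty <- sigmoid_(m[2, , , ])
    tw <- sigmoid_(m[3, , , ]); th <- sigmoid_(m[4, , , ])
    obj <- sigmoid_(m[5, , , ])
    cls <- sigmoid_(array(m[5L + seq_len(n_classes), , , ],
                          c(n_classes, 3 * H * W)))
    if (n_classes == 1L) {
      best <- array(1L, c(3, H, W))
      bestp <- array(cls, c(3, H, W))
    } else {
      best <- array(max.col(t(cls), ties.method = "first"), c(3, H, W))
      bestp <- array(apply(cls, 2, max), c(3, H, W))
    }
    conf <- obj * bestp
    cx <- (2 * tx - 0.5 + gx) * stride
    cy <- (2 * ty - 0.5 + gy) * stride
    bw <- (2 * tw)^2 * aw
    bh <- (2 * th)^2 * ah
    keep <- which(conf >= conf_threshold)
    if (length(keep)) {
      out[[s]] <- data.frame(
        class = as.integer(best[keep] - 1L), conf = conf[keep],
        x1 = clamp(cx[keep] - bw[keep] / 2, 0, img_size[1]),
        y1 = clamp(cy[keep] - bh[keep] / 2, 0, img_size[2]),
        x2 = clamp(cx[keep] + bw[keep] / 2, 0, img_size[1]),
        y2 = clamp(cy[keep] + bh[keep] / 2, 0, img_size[2]))
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(class = integer(), conf = numeric(), x1 = numeric(),
                      y1 = numeric(), x2 = numeric(), y2 = numeric())
  out <- out[out$x2 > out$x1 & out$y2 > out$y1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Inverse of the decode formulas for a ground-truth box (pixels) against a
# given anchor and cell; used by the encode/decode identity tests.
encode_box <- function(cx, cy, bw, bh, gx, gy, anchor, stride) {
  inv_sig <- function(p) log(p / (1 - p))
  ux <- cx / stride - gx
  uy <- cy / stride - gy
  c(tx = inv_sig((ux + 0.5) / 2), ty = inv_sig((uy + 0.5) / 2),
    tw = inv_sig(sqrt(bw / anchor[1]) / 2), th = inv_sig(sqrt(bh / anchor[2]) / 2))
}

# wh-IoU between box sizes (no positions): used by autoanchor.
wh_iou <- function(wh, centers) {
  iw <- outer(wh[, 1], centers[, 1], pmin)
  ih <- outer(wh[, 2], centers[, 2], pmin)
  inter <- iw * ih
  inter / (outer(wh[, 1] * wh[, 2], centers[, 1] * centers[, 2], `+`) - inter)
}

# Best-possible-recall under the ratio-4 assignment rule.
anchor_bpr <- function(wh, centers, thr = 4) {
  r1 <- outer(wh[, 1], centers[, 1], `/`)
  r2 <- outer(wh[, 2], centers[, 2], `/`)
  worst <- pmax(pmax(r1, 1 / r1), pmax(r2, 1 / r2))
  mean(apply(worst, 1, min) < thr)
}

#' Adaptive anchor estimation
#'
#' Clusters training-box sizes with Lloyd iterations under the `1 - IoU`
#' size distance (a centroid update is only accepted while the objective
#' improves), then applies random multiplicative mutations kept whenever
#' they raise the best-possible recall of the ratio-4 assignment rule.
#' Falls back to [default_anchors()] with a warning when fewer than `k`
#' boxes are available.
#'
#' @param wh matrix of box `(w, h)` in pixels at the training image scale.
#' @param k number of anchors (9).
#' @param iterations Lloyd iteration cap.
#' @param mutations number of mutation proposals.
#' @param img_size used for the fallback anchors.
#' @param seed RNG seed.
#' @return `9 x 2` anchor matrix sorted by area, attribute `bpr` attached.
#' @export
autoanchor <- function(wh, k = 9L, iterations = 50L, mutations = 30L,
                       img_size = 640L, seed = 0L) {
  wh <- as.matrix(wh)
  if (nrow(wh) < k) {
    warning("fewer than ", k, " boxes; falling back to default anchors")
    a <- default_anchors(img_size)
    attr(a, "bpr") <- if (nrow(wh)) anchor_bpr(wh, a) else NA_real_
    return(a)
  }
  with_seed_(seed, {
    centers <- wh[sample(nrow(wh), k), , drop = FALSE]
    obj <- mean(1 - apply(wh_iou(wh, centers), 1, max))
    obj_trace <- obj
    for (it in seq_len(iterations)) {
      assign_ <- max.col(wh_iou(wh, centers))
      newc <- centers
      for (j in seq_len(k)) {
        sel <- assign_ == j
        if (any(sel)) newc[j, ] <- colMeans(wh[sel, , drop = FALSE])
      }
      newobj <- mean(1 - apply(wh_iou(wh, newc), 1, max))
      if (newobj < obj - 1e-12) {
        centers <- newc; obj <- newobj
        obj_trace <- c(obj_trace, obj)
      } else break
    }
    bpr <- anchor_bpr(wh, centers)
    for (m in seq_len(mutations)) {
      cand <- centers * matrix(exp(rnorm(2 * k, sd = 0.1)), k, 2)
      bp <- anchor_bpr(wh, cand)
      if (bp > bpr) { centers <- cand; bpr <- bp }
    }
    centers <- centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
    attr(centers, "bpr") <- bpr
    attr(centers, "objective_trace") <- obj_trace
    centers
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the architecture config, all parameter values,
#' batch-norm running statistics, the anchor set and class names.
#'
#' @param model a `gd_model`.
#' @param path file path (`.rds`).
#' @return `load_checkpoint` returns the reconstructed `gd_model`.
#' @export
save_checkpoint <- function(model, path) {
  ps <- lapply(collect_params(model), function(p) p$value)
  sts <- lapply(collect_states(model), function(e) list(mean = e$mean,
                                                        var = e$var))
  saveRDS(list(version = 1L, arch = model$arch, params = ps, states = sts,
               anchors = model$anchors, class_names = model$class_names),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_detector(ck$arch, seed = 0L)
  ps <- collect_params(model)
  stopifnot(identical(sort(names(ps)), sort(names(ck$params))))
  for (nm in names(ps)) ps[[nm]]$value <- ck$params[[nm]]
  sts <- collect_states(model)
  for (nm in names(sts)) {
    sts[[nm]]$mean <- ck$states[[nm]]$mean
    sts[[nm]]$var <- ck$states[[nm]]$var
  }
  model$anchors <- ck$anchors
  model$class_names <- ck$class_names
  model
}

#' Run detection on images
#'
#' Letterboxes each image to the model's input size, runs the forward
#' pass in mini-batches, decodes, applies NMS and maps boxes back to
#' original-image pixels.
#'
#' @param model a `gd_model`.
#' @param images list of `labeled_image`s / `H x W x 3` arrays in
#'   `[0,255]`.
#' @param conf_threshold,iou_threshold decode / NMS thresholds.
#' @param batch_size images per forward pass.
#' @return list of data.frames `class, conf, x1, y1, x2, y2` in
#'   source-image pixels, one per input image.
#' @export
detect_images <- function(model, images, conf_threshold = 0.25,
                          iou_threshold = 0.45, batch_size = 8L) {
  s <- model$arch$img_size
  pxs <- lapply(images, function(im)
    if (inherits(im, "labeled_image")) im$pixels else im)
  lbs <- lapply(pxs, function(px)
    letterbox(labeled_image(px, image_id = "q"), s))
  out <- vector("list", length(images))
  for (chunk in split(seq_along(images),
                      ceiling(seq_along(images) / batch_size))) {
    x <- array(0, c(3, s, s, length(chunk)))
    for (j in seq_along(chunk))
      x[, , , j] <- aperm(lbs[[chunk[j]]]$image$pixels / 255, c(3, 1, 2))
    raw <- detector_forward(model, x, training = FALSE)
    for (j in seq_along(chunk)) {
      i <- chunk[j]
      raw_j <- lapply(raw, function(m) m[, , , j, drop = FALSE])
      det <- decode_predictions(raw_j, model$anchors, conf_threshold,
                                c(s, s), model$n_classes)
      det <- nms(det, iou_threshold)
      rec <- lbs[[i]]$record
      det$x1 <- (det$x1 - rec$pad[1]) / rec$scale
      det$x2 <- (det$x2 - rec$pad[1]) / rec$scale
      det$y1 <- (det$y1 - rec$pad[2]) / rec$scale
      det$y2 <- (det$y2 - rec$pad[2]) / rec$scale
      W <- dim(pxs[[i]])[2]; H <- dim(pxs[[i]])[1]
      det$x1 <- clamp(det$x1, 0, W); det$x2 <- clamp(det$x2, 0, W)
      det$y1 <- clamp(det$y1, 0, H); det$y2 <- clamp(det$y2, 0, H)
      out[[i]] <- det[det$x2 > det$x1 & det$y2 > det$y1, , drop = FALSE]
    }
  }
  out
}

#' @rdname detect_images
#' @param image a single image for `detect_image`.
#' @export
detect_image <- function(model, image, conf_threshold = 0.25,
                         iou_threshold = 0.45) {
  detect_images(model, list(image), conf_threshold, iou_threshold)[[1]]
}
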