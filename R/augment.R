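#' Augmentation configuration
#'
#' Defaults follow the probabilities and paste counts of the study
#' conditions: Copy-Paste always applied (pasting 4 fruit and 15 leaf
#' instances), Mosaic with probability 0.8, Mixup with probability 0.3.
#' The Mixup coefficient is drawn from a symmetric `Beta(alpha, alpha)`;
#' `alpha = 8` concentrates draws around 0.5 (SD about 0.12), matching
#' blends in the 0.35-0.45 range.
#'
#' @param p_copy_paste,p_mosaic,p_mixup application probabilities.
#' @param n_fruit_paste,n_leaf_paste instances pasted per image.
#' @param mixup_alpha Beta shape parameter (> 0).
#' @param preset_size square network input size (pixels).
#' @param flip_prob horizontal flip probability (basic transform).
#' @param rot_range rotation range in degrees for pasted instances and the
#'   mosaic canvas.
#' @param scale_range multiplicative scale range for pasted instances.
#' @param hsv_jitter `c(h, s, v)` jitter amplitudes (degrees, fractions).
#' @param min_visibility mosaic boxes are dropped when the clipped area
#'   falls below this fraction of the original.
#' @param min_side minimum surviving box side (pixels).
#' @param paste_max_iou maximum IoU of a pasted fruit against existing
#'   fruit boxes.
#' @param paste_retries placement attempts before skipping an instance.
#' @param occlusion_drop drop a pre-existing box when pasted instances
#'   cover more than this fraction of its area.
#' @return list of class `augment_config`.
#' @export
augment_config <- function(p_copy_paste = 1.0, n_fruit_paste = 4L,
                           n_leaf_paste = 15L, p_mosaic = 0.8,
                           p_mixup = 0.3, mixup_alpha = 8,
                           preset_size = 640L, flip_prob = 0.5,
                           rot_range = 10, scale_range = c(0.5, 1.5),
                           hsv_jitter = c(5, 0.2, 0.2),
                           min_visibility = 0.1, min_side = 2,
                           paste_max_iou = 0.3, paste_retries = 20L,
                           occlusion_drop = 0.9) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_copy_paste, cfg$p_mosaic, cfg$p_mixup, cfg$flip_prob)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$mixup_alpha > 0,
            cfg$preset_size > 0)
  structure(cfg, class = "augment_config")
}

#' Build a Copy-Paste instance pool from source scenes
#'
#' Crops every instance (pixels + binary mask) of the given images to its
#' tight bounding window.
#'
#' @param images list of `labeled_image` carrying masks.
#' @return list of `list(pixels, mask, category, source_id)`.
#' @export
make_paste_pool <- function(images) {
  out <- list()
  for (img in images) {
    for (inst in get_instances(img)) {
      ys <- which(rowSums(inst$mask) > 0); xs <- which(colSums(inst$mask) > 0)
      if (!length(ys)) next
      out[[length(out) + 1L]] <- list(
        pixels = img$pixels[min(ys):max(ys), min(xs):max(xs), , drop = FALSE],
        mask = inst$mask[min(ys):max(ys), min(xs):max(xs), drop = FALSE],
        category = inst$category, source_id = inst$source_id)
    }
  }
  out
}

# Nearest-neighbour geometric transform (flip, rotation, isotropic scale)
# of an instance crop. Deterministic in its arguments, so replaying a
# recorded transform reproduces the pasted pixels exactly.
transform_instance <- function(inst, flip = FALSE, angle = 0, scale = 1) {
  h <- nrow(inst$mask); w <- ncol(inst$mask)
  th <- angle * pi / 180
  # output canvas bounds from rotated, scaled corners
  cw <- scale * (abs(cos(th)) * w + abs(sin(th)) * h)
  ch <- scale * (abs(sin(th)) * w + abs(cos(th)) * h)
  wo <- max(1L, ceiling(cw)); ho <- max(1L, ceiling(ch))
  xo <- matrix(rep(seq_len(wo) - 0.5 - wo / 2, each = ho), ho, wo)
  yo <- matrix(rep(seq_len(ho) - 0.5 - ho / 2, wo), ho, wo)
  # inverse map: unrotate, unscale, unflip
  xi <- (cos(-th) * xo - sin(-th) * yo) / scale + w / 2
  yi <- (sin(-th) * xo + cos(-th) * yo) / scale + h / 2
  if (flip) xi <- w - xi
  ci <- ceiling(xi); ri <- ceiling(yi)
  ok <- ci >= 1 & ci <= w & ri >= 1 & ri <= h
  lin <- ifelse(ok, ri + (ci - 1) * h, 1L)
  mask <- matrix(FALSE, ho, wo)
  mask[ok] <- inst$mask[lin[ok]]
  px <- array(0, c(ho, wo, 3))
  for (ch_ in 1:3) {
    plane <- inst$pixels[, , ch_]
    v <- matrix(plane[lin], ho, wo)
    v[!ok] <- 0
    px[, , ch_] <- v
  }
  list(pixels = px, mask = mask)
}

#' Mask-guided Copy-Paste augmentation
#'
#' Pastes `n_fruit` fruit and `n_leaf` leaf instances (sampled from `pool`
#' with replacement) into `target`. Each instance undergoes a random flip,
#' rotation and scale before pasting; pasted pixels replace the target
#' exactly under the instance mask. Fruit placements retry until their box
#' overlaps existing fruit boxes at IoU <= `paste_max_iou` (up to
#' `paste_retries` attempts, then the instance is skipped with a warning).
#' Exactly one new box is appended per pasted fruit; leaves add no boxes.
#' A pre-existing box is dropped only when pasted instances cover more
#' than `occlusion_drop` of its area.
#'
#' @param target a `labeled_image`.
#' @param pool instance pool from [make_paste_pool()].
#' @param n_fruit,n_leaf paste counts.
#' @param config an [augment_config()] (placement/transform settings).
#' @param seed optional RNG seed.
#' @return a `labeled_image`; attribute `paste_records` holds one record
#'   (category, pool index, flip, angle, scale, paste offset) per pasted
#'   instance in paste order, and attribute `skipped` counts skips.
#' @export
copy_paste <- function(target, pool, n_fruit = 4L, n_leaf = 15L,
                       config = augment_config(), seed = NULL) {
  if ((n_fruit > 0 || n_leaf > 0) && !length(pool)) stop("empty paste pool")
  cats <- vapply(pool, `[[`, character(1), "category")
  if (n_fruit > 0 && !any(cats == "fruit")) stop("pool has no fruit instance")
  if (n_leaf > 0 && !any(cats == "leaf")) stop("pool has no leaf instance")
  H <- dim(target$pixels)[1]; W <- dim(target$pixels)[2]
  with_seed_(seed, {
    px <- target$pixels
    boxes <- target$boxes
    fruit_masks <- NULL
    if (!is.null(target$masks)) {
      fruit_masks <- target$masks[target$mask_categories == "fruit"]
    }
    coverage <- matrix(FALSE, H, W)
    records <- list()
    skipped <- 0L
    new_boxes <- yolo_boxes()
    new_masks <- list()
    plan <- c(rep("leaf", n_leaf), rep("fruit", n_fruit))
    for (cat in plan) {
      i <- sample(which(cats == cat), 1)
      flip <- runif(1) < config$flip_prob
      angle <- runif(1, -config$rot_range, config$rot_range)
      scale <- runif(1, config$scale_range[1], config$scale_range[2])
      tr <- transform_instance(pool[[i]], flip, angle, scale)
      ho <- nrow(tr$mask); wo <- ncol(tr$mask)
      if (ho > H || wo > W || !any(tr$mask)) { skipped <- skipped + 1L; next }
      placed_at <- NULL
      all_fruit <- rbind(convert_box(boxes, c(W, H)),
                         if (nrow(new_boxes))
                           convert_box(new_boxes, c(W, H)))
      for (try in seq_len(config$paste_retries)) {
        x0 <- sample.int(W - wo + 1L, 1) - 1L
        y0 <- sample.int(H - ho + 1L, 1) - 1L
        if (cat == "fruit" && !is.null(all_fruit) && nrow(all_fruit)) {
          bb <- mask_to_box(tr$mask)
          cand <- data.frame(x1 = bb$cx * wo - bb$w * wo / 2 + x0,
                             y1 = bb$cy * ho - bb$h * ho / 2 + y0,
                             x2 = bb$cx * wo + bb$w * wo / 2 + x0,
                             y2 = bb$cy * ho + bb$h * ho / 2 + y0)
          if (max(box_iou(cand, all_fruit)) > config$paste_max_iou) next
        }
        placed_at <- c(x0, y0)
        break
      }
      if (is.null(placed_at)) {
        warning("copy_paste: no valid placement for a ", cat,
                " instance; skipped")
        skipped <- skipped + 1L
        next
      }
      rows <- (placed_at[2] + 1):(placed_at[2] + ho)
      cols <- (placed_at[1] + 1):(placed_at[1] + wo)
      sel <- tr$mask
      for (ch_ in 1:3) {
        sub <- px[rows, cols, ch_]
        sub[sel] <- tr$pixels[, , ch_][sel]
        px[rows, cols, ch_] <- sub
      }
      cov <- coverage[rows, cols]; cov[sel] <- TRUE
      coverage[rows, cols] <- cov
      full_mask <- matrix(FALSE, H, W)
      full_mask[rows, cols] <- sel
      if (cat == "fruit") {
        new_boxes <- rbind(new_boxes, mask_to_box(full_mask))
        new_masks[[length(new_masks) + 1L]] <- full_mask
      }
      records[[length(records) + 1L]] <-
        list(category = cat, pool_index = i, flip = flip, angle = angle,
             scale = scale, x = placed_at[1], y = placed_at[2])
    }
    # occlusion rule on pre-existing boxes
    keep <- rep(TRUE, nrow(boxes))
    if (nrow(boxes)) {
      abs_b <- convert_box(boxes, c(W, H))
      for (b in seq_len(nrow(boxes))) {
        r0 <- clamp(floor(abs_b$y1[b]) + 1, 1, H)
        r1 <- clamp(ceiling(abs_b$y2[b]), 1, H)
        c0 <- clamp(floor(abs_b$x1[b]) + 1, 1, W)
        c1 <- clamp(ceiling(abs_b$x2[b]), 1, W)
        frac <- mean(coverage[r0:r1, c0:c1])
        if (frac > config$occlusion_drop) keep[b] <- FALSE
      }
    }
    out_boxes <- rbind(boxes[keep, , drop = FALSE], new_boxes)
    rownames(out_boxes) <- NULL
    out_masks <- NULL; out_cats <- NULL
    if (!is.null(fruit_masks)) {
      leaf_masks <- target$masks[target$mask_categories == "leaf"]
      out_masks <- c(fruit_masks[keep], new_masks, leaf_masks)
      out_cats <- c(rep("fruit", sum(keep) + length(new_masks)),
                    rep("leaf", length(leaf_masks)))
    }
    out <- labeled_image(px, out_boxes, out_masks, out_cats,
                         paste0(target$image_id, "+cp"))
    attr(out, "paste_records") <- records
    attr(out, "skipped") <- skipped
    out
  })
}

resize_image <- function(px, ho, wo) {
  d <- dim(px)
  array(resize_bilinear_cpp(as.vector(px), d[1], d[2], d[3], ho, wo),
        c(ho, wo, d[3]))
}

#' Mosaic augmentation
#'
#' Scales four images to the preset size, splices them around a random
#' center point on a double-size canvas (one per quadrant), crops a
#' preset-size window centred on that point, then applies the basic
#' transforms (horizontal flip, small rotation, HSV jitter). Surviving
#' boxes are clipped; a box is dropped when its clipped area falls below
#' `min_visibility` of the original or a side shrinks under `min_side`
#' pixels.
#'
#' @param images list of exactly 4 `labeled_image`.
#' @param preset_size output size `s` (pixels).
#' @param config an [augment_config()].
#' @param seed optional RNG seed.
#' @param center optional fixed mosaic centre `c(x, y)` in
#'   `[0.5s, 1.5s]^2` (tests/figures); random when `NULL`.
#' @return a `labeled_image` of size `s x s`; attribute `mosaic_records`
#'   stores the per-quadrant offsets and the final flip/rotation, enough
#'   to map any output box back to its source image.
#' @export
mosaic <- function(images, preset_size = 640L, config = augment_config(),
                   seed = NULL, center = NULL) {
  if (length(images) != 4) stop("mosaic needs exactly 4 images")
  s <- as.integer(preset_size)
  with_seed_(seed, {
    cx <- if (is.null(center)) runif(1, 0.5 * s, 1.5 * s) else center[1]
    cy <- if (is.null(center)) runif(1, 0.5 * s, 1.5 * s) else center[2]
    canvas <- array(114, c(2L * s, 2L * s, 3L))
    all_boxes <- list()
    recs <- list()
    # quadrant q: 1 TL, 2 TR, 3 BL, 4 BR; anchor corner at (cx, cy)
    for (q in 1:4) {
      img <- images[[q]]
      px <- resize_image(img$pixels, s, s)
      # canvas region for this quadrant
      xr <- switch(q, c(cx - s, cx), c(cx, cx + s), c(cx - s, cx),
                   c(cx, cx + s))
      yr <- switch(q, c(cy - s, cy), c(cy - s, cy), c(cy, cy + s),
                   c(cy, cy + s))
      x0 <- max(0, xr[1]); x1 <- min(2 * s, xr[2])
      y0 <- max(0, yr[1]); y1 <- min(2 * s, yr[2])
      if (x1 <= x0 || y1 <= y0) next
      # source window: align image corner with the anchor
      sx0 <- x0 - xr[1]; sy0 <- y0 - yr[1]
      wreg <- floor(x1) - floor(x0); hreg <- floor(y1) - floor(y0)
      if (wreg < 1 || hreg < 1) next
      rows_c <- (floor(y0) + 1):(floor(y0) + hreg)
      cols_c <- (floor(x0) + 1):(floor(x0) + wreg)
      rows_s <- (floor(sy0) + 1):(floor(sy0) + hreg)
      cols_s <- (floor(sx0) + 1):(floor(sx0) + wreg)
      rows_s <- clamp(rows_s, 1, s); cols_s <- clamp(cols_s, 1, s)
      canvas[rows_c, cols_c, ] <- px[rows_s, cols_s, ]
      if (nrow(img$boxes)) {
        ab <- convert_box(img$boxes, c(s, s))
        ab$x1 <- ab$x1 + xr[1]; ab$x2 <- ab$x2 + xr[1]
        ab$y1 <- ab$y1 + yr[1]; ab$y2 <- ab$y2 + yr[1]
        ab$orig_area <- (ab$x2 - ab$x1) * (ab$y2 - ab$y1)
        ab$quadrant <- q
        all_boxes[[q]] <- ab
      }
      recs[[q]] <- list(quadrant = q, offset = c(xr[1], yr[1]), scale = 1)
    }
    boxes <- do.call(rbind, all_boxes)
    # crop an s x s window centred on the mosaic centre, clamped to canvas
    wx0 <- clamp(round(cx - s / 2), 0, s)
    wy0 <- clamp(round(cy - s / 2), 0, s)
    out_px <- canvas[(wy0 + 1):(wy0 + s), (wx0 + 1):(wx0 + s), , drop = FALSE]
    keep_boxes <- yolo_boxes()
    box_src <- integer()
    if (!is.null(boxes) && nrow(boxes)) {
      boxes$x1 <- boxes$x1 - wx0; boxes$x2 <- boxes$x2 - wx0
      boxes$y1 <- boxes$y1 - wy0; boxes$y2 <- boxes$y2 - wy0
      cb <- boxes
      cb$x1 <- clamp(cb$x1, 0, s); cb$x2 <- clamp(cb$x2, 0, s)
      cb$y1 <- clamp(cb$y1, 0, s); cb$y2 <- clamp(cb$y2, 0, s)
      area <- (cb$x2 - cb$x1) * (cb$y2 - cb$y1)
      ok <- area >= config$min_visibility * cb$orig_area &
        (cb$x2 - cb$x1) >= config$min_side & (cb$y2 - cb$y1) >= config$min_side
      cb <- cb[ok, , drop = FALSE]
      if (nrow(cb)) {
        keep_boxes <- convert_box(cb[, c("class", "x1", "y1", "x2", "y2")],
                                  c(s, s), "to_norm")
        box_src <- cb$quadrant
      }
    }
    # basic transforms on the spliced image
    flip <- runif(1) < config$flip_prob
    if (flip) {
      out_px <- out_px[, s:1, , drop = FALSE]
      if (nrow(keep_boxes)) keep_boxes$cx <- 1 - keep_boxes$cx
    }
    angle <- runif(1, -config$rot_range, config$rot_range)
    rot <- rotate_labeled(out_px, keep_boxes, angle)
    out_px <- rot$pixels
    keep_boxes <- rot$boxes
    box_src <- box_src[rot$kept]
    out_px <- hsv_jitter_image(out_px, config$hsv_jitter)
    out <- labeled_image(round(clamp(out_px, 0, 255)), keep_boxes,
                         image_id = paste0(images[[1]]$image_id, "+mosaic"))
    attr(out, "mosaic_records") <- list(center = c(cx, cy), crop = c(wx0, wy0),
                                        flip = flip, angle = angle,
                                        quadrants = recs, box_source = box_src)
    out
  })
}

# Rotate an image about its centre by `angle` degrees (nearest-neighbour,
# gray fill), replacing each box by the axis-aligned hull of its rotated
# corners, clipped to the canvas.
rotate_labeled <- function(px, boxes, angle) {
  if (abs(angle) < 1e-9)
    return(list(pixels = px, boxes = boxes, kept = seq_len(nrow(boxes))))
  H <- dim(px)[1]; W <- dim(px)[2]
  th <- angle * pi / 180
  xo <- matrix(rep(seq_len(W) - 0.5 - W / 2, each = H), H, W)
  yo <- matrix(rep(seq_len(H) - 0.5 - H / 2, W), H, W)
  xi <- cos(-th) * xo - sin(-th) * yo + W / 2
  yi <- sin(-th) * xo + cos(-th) * yo + H / 2
  ci <- ceiling(xi); ri <- ceiling(yi)
  ok <- ci >= 1 & ci <= W & ri >= 1 & ri <= H
  lin <- ifelse(ok, ri + (ci - 1) * H, 1L)
  out <- array(114, dim(px))
  for (ch_ in 1:3) {
    plane <- px[, , ch_]
    v <- matrix(plane[lin], H, W)
    v[!ok] <- 114
    out[, , ch_] <- v
  }
  kept <- seq_len(nrow(boxes))
  if (nrow(boxes)) {
    ab <- convert_box(boxes, c(W, H))
    rotc <- function(x, y) {
      list(x = cos(th) * (x - W / 2) - sin(th) * (y - H / 2) + W / 2,
           y = sin(th) * (x - W / 2) + cos(th) * (y - H / 2) + H / 2)
    }
    xs <- cbind(ab$x1, ab$x2, ab$x1, ab$x2)
    ys <- cbind(ab$y1, ab$y1, ab$y2, ab$y2)
    rx <- matrix(0, nrow(ab), 4); ry <- rx
    for (k in 1:4) { r <- rotc(xs[, k], ys[, k]); rx[, k] <- r$x; ry[, k] <- r$y }
    nb <- data.frame(class = ab$class,
                     x1 = clamp(apply(rx, 1, min), 0, W),
                     y1 = clamp(apply(ry, 1, min), 0, H),
                     x2 = clamp(apply(rx, 1, max), 0, W),
                     y2 = clamp(apply(ry, 1, max), 0, H))
    okb <- nb$x2 - nb$x1 >= 2 & nb$y2 - nb$y1 >= 2
    kept <- which(okb)
    boxes <- convert_box(nb[okb, , drop = FALSE], c(W, H), "to_norm")
  }
  list(pixels = out, boxes = boxes, kept = kept)
}

hsv_jitter_image <- function(px, jitter) {
  if (all(jitter == 0)) return(px)
  r <- px[, , 1] / 255; g <- px[, , 2] / 255; b <- px[, , 3] / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  h <- rgb_to_hue(r, g, b)
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  v <- mx
  h <- h + runif(1, -jitter[1], jitter[1])
  s <- clamp(s * (1 + runif(1, -jitter[2], jitter[2])), 0, 1)
  v <- clamp(v * (1 + runif(1, -jitter[3], jitter[3])), 0, 1)
  rgb <- hsv_to_rgb(h, s, v)
  out <- array(0, dim(px))
  out[, , 1] <- rgb$r * 255; out[, , 2] <- rgb$g * 255
  out[, , 3] <- rgb$b * 255
  out
}

#' Draw Mixup coefficients
#'
#' @param alpha Beta shape parameter (> 0); draws are `Beta(alpha, alpha)`.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return numeric vector in `[0, 1]`.
#' @export
sample_mixup_lambda <- function(alpha, n = 1L, seed = NULL) {
  if (alpha <= 0) stop("mixup alpha must be > 0")
  with_seed_(seed, rbeta(n, alpha, alpha))
}

#' Mixup augmentation
#'
#' Blends two equally sized images as `lambda * a + (1 - lambda) * b`
#' (computed in real arithmetic, rounded once to 8-bit) and concatenates
#' both label sets at full weight — detection Mixup does not reweight
#' boxes.
#'
#' @param a,b `labeled_image`s of identical pixel dimensions.
#' @param lambda blend coefficient in `[0, 1]`.
#' @return the blended `labeled_image`.
#' @export
mixup <- function(a, b, lambda) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("mixup: image size mismatch")
  stopifnot(lambda >= 0, lambda <= 1)
  px <- round(lambda * a$pixels + (1 - lambda) * b$pixels)
  boxes <- rbind(a$boxes, b$boxes)
  rownames(boxes) <- NULL
  labeled_image(px, boxes, image_id = paste0(a$image_id, "+mix"))
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving resize by the ratio `min(target/W, target/H)` followed by
#' symmetric padding with gray (114) to `target x target`; boxes are
#' mapped consistently.
#'
#' @param image a `labeled_image`.
#' @param target output side length (pixels).
#' @return `list(image, record)` where `record` holds `scale` and
#'   `pad = c(left, top, right, bottom)`.
#' @export
letterbox <- function(image, target) {
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  r <- min(target / W, target / H)
  nw <- round(r * W); nh <- round(r * H)
  px <- if (nw == W && nh == H) image$pixels else resize_image(image$pixels, nh, nw)
  left <- (target - nw) %/% 2; top <- (target - nh) %/% 2
  out <- array(114, c(target, target, 3))
  out[top + seq_len(nh), left + seq_len(nw), ] <- px
  boxes <- image$boxes
  if (nrow(boxes)) {
    boxes$cx <- (boxes$cx * nw + left) / target
    boxes$cy <- (boxes$cy * nh + top) / target
    boxes$w <- boxes$w * nw / target
    boxes$h <- boxes$h * nh / target
  }
  rec <- list(scale = r, pad = c(left, top, target - nw - left,
                                 target - nh - top))
  list(image = labeled_image(out, boxes, image_id = image$image_id),
       record = rec)
}

#' Draw the augmentation schedule
#'
#' The pipeline's stochastic gate: one Bernoulli draw per stage and
#' sample. Kept separate from the image work so scheduling statistics can
#' be audited cheaply.
#'
#' @param config an [augment_config()].
#' @param n number of samples.
#' @param seed optional RNG seed.
#' @return data.frame with logical columns `copy_paste, mosaic, mixup`
#'   and the Mixup `lambda` draws.
#' @export
schedule_draws <- function(config, n, seed = NULL) {
  with_seed_(seed, {
    data.frame(copy_paste = runif(n) < config$p_copy_paste,
               mosaic = runif(n) < config$p_mosaic,
               mixup = runif(n) < config$p_mixup,
               lambda = rbeta(n, config$mixup_alpha, config$mixup_alpha))
  })
}

# One augmented training sample (optionally without the mixup stage, to
# build mixup partners).
augment_one <- function(dataset, pool, config, draws_row, allow_mixup = TRUE) {
  base <- dataset[[sample(length(dataset), 1)]]
  if (draws_row$copy_paste && !is.null(pool))
    base <- copy_paste(base, pool, config$n_fruit_paste, config$n_leaf_paste,
                       config)
  if (draws_row$mosaic) {
    others <- lapply(sample(length(dataset), 3, replace = TRUE),
                     function(i) dataset[[i]])
    base <- mosaic(c(list(base), others), config$preset_size, config)
  }
  if (allow_mixup && draws_row$mixup) {
    partner_draw <- data.frame(copy_paste = runif(1) < config$p_copy_paste,
                               mosaic = runif(1) < config$p_mosaic,
                               mixup = FALSE, lambda = NA)
    partner <- augment_one(dataset, pool, config, partner_draw, FALSE)
    pa <- letterbox(base, config$preset_size)$image
    pb <- letterbox(partner, config$preset_size)$image
    return(mixup(pa, pb, draws_row$lambda))
  }
  base
}

#' Run the training-time augmentation pipeline
#'
#' Per sample: Copy-Paste with probability `p_copy_paste`, Mosaic with
#' `p_mosaic`, Mixup (against a second, independently augmented sample)
#' with `p_mixup`, then letterboxing to the preset size.
#'
#' @param dataset list of `labeled_image`.
#' @param pool Copy-Paste instance pool (or `NULL` to disable pasting).
#' @param config an [augment_config()].
#' @param n number of samples to emit.
#' @param seed RNG seed for the whole stream.
#' @return list of letterboxed `labeled_image`s; attribute `applied` is
#'   the schedule actually drawn.
#' @export
apply_train_pipeline <- function(dataset, pool, config, n, seed = 0L) {
  if (!length(dataset)) stop("empty dataset")
  draws <- schedule_draws(config, n, seed)
  out <- with_seed_(seed + 1L, {
    lapply(seq_len(n), function(i) {
      img <- augment_one(dataset, pool, config, draws[i, ])
      letterbox(img, config$preset_size)$image
    })
  })
  attr(out, "applied") <- draws
  out
}
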