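#' Synthetic green-on-green scene configuration
#'
#' The generator emulates orchard imagery in which unripe fruit shares hue
#' with the foliage behind it: a mottled green background, shaded
#' elliptical fruits offset from the background hue by only `hue_delta`
#' degrees, elongated leaf-shaped occluders composited over the fruit,
#' per-image exposure jitter (standing in for sunny/cloudy/overcast
#' acquisition) and pixel noise. Every fruit carries an amodal instance
#' mask whose tight bounding rectangle is its ground-truth box.
#'
#' @param image_size `c(W, H)` pixels.
#' @param n_fruit inclusive integer range of fruits per scene.
#' @param fruit_radius pixel range of the fruit semi-major axis.
#' @param fruit_eccentricity range of major/minor axis ratio.
#' @param hue_base background foliage hue (degrees; 110 is leaf green).
#' @param hue_delta fruit-minus-background hue offset (degrees; small, to
#'   preserve the similar-colour premise).
#' @param n_leaf_occluders integer range of leaf occluders.
#' @param occlusion_prob probability that a leaf is deliberately centred
#'   on a fruit boundary (occluding it) rather than placed uniformly.
#' @param exposure_jitter multiplicative brightness range per scene.
#' @param noise_sd additive Gaussian pixel noise SD (8-bit scale).
#' @return list of class `scene_config`.
#' @export
scene_config <- function(image_size = c(640L, 640L),
                         n_fruit = c(1L, 8L),
                         fruit_radius = c(12, 60),
                         fruit_eccentricity = c(1.0, 1.4),
                         hue_base = 110,
                         hue_delta = 12,
                         n_leaf_occluders = c(5L, 20L),
                         occlusion_prob = 0.5,
                         exposure_jitter = c(0.75, 1.25),
                         noise_sd = 4) {
  cfg <- list(image_size = as.integer(image_size), n_fruit = as.integer(n_fruit),
              fruit_radius = fruit_radius,
              fruit_eccentricity = fruit_eccentricity, hue_base = hue_base,
              hue_delta = hue_delta,
              n_leaf_occluders = as.integer(n_leaf_occluders),
              occlusion_prob = occlusion_prob,
              exposure_jitter = exposure_jitter, noise_sd = noise_sd)
  stopifnot(all(cfg$n_fruit >= 0), diff(cfg$n_fruit) >= 0,
            diff(cfg$fruit_radius) >= 0, cfg$occlusion_prob >= 0,
            cfg$occlusion_prob <= 1, abs(cfg$hue_delta) <= 45)
  if (max(cfg$fruit_radius) * 2 >= min(cfg$image_size))
    stop("fruit radius incompatible with image size")
  structure(cfg, class = "scene_config")
}

#' Desk-scale scene configuration
#'
#' 160-pixel scenes with 1-3 fruits of 12-32 px radius and 3-8 leaf
#' occluders: the miniature study conditions used by the package's own
#' training and evaluation checks.
#'
#' @param ... overrides passed to [scene_config()].
#' @export
scene_config_desk <- function(...) {
  defaults <- list(image_size = c(160L, 160L), n_fruit = c(1L, 3L),
                   fruit_radius = c(12, 32), n_leaf_occluders = c(3L, 8L))
  do.call(scene_config, utils::modifyList(defaults, list(...)))
}

# Smooth low-frequency noise field (coarse Gaussian grid, bilinear upsample).
smooth_field <- function(H, W, sd, cells = 8L) {
  coarse <- matrix(rnorm(cells * cells, sd = sd), cells, cells)
  array(resize_bilinear_cpp(as.vector(coarse), cells, cells, 1L, H, W),
        c(H, W))
}

# Tight normalized center-format box of a logical mask (0-based half-open
# pixel convention).
mask_to_box <- function(mask, class = 0L) {
  ys <- which(rowSums(mask) > 0)
  xs <- which(colSums(mask) > 0)
  if (!length(ys)) stop("empty mask")
  H <- nrow(mask); W <- ncol(mask)
  x1 <- min(xs) - 1; x2 <- max(xs); y1 <- min(ys) - 1; y2 <- max(ys)
  yolo_boxes(class, (x1 + x2) / 2 / W, (y1 + y2) / 2 / H,
             (x2 - x1) / W, (y2 - y1) / H)
}

# Evaluate a predicate over a local pixel window and place it into a
# full-size logical matrix (keeps rasterization cost proportional to the
# instance, not the canvas).
raster_window <- function(H, W, cx, cy, radius, pred) {
  x0 <- max(0L, floor(cx - radius)); x1 <- min(W - 1L, ceiling(cx + radius))
  y0 <- max(0L, floor(cy - radius)); y1 <- min(H - 1L, ceiling(cy + radius))
  m <- matrix(FALSE, H, W)
  if (x1 < x0 || y1 < y0) return(m)
  nx <- x1 - x0 + 1L; ny <- y1 - y0 + 1L
  xs <- matrix(rep(x0:x1, each = ny), ny, nx) + 0.5
  ys <- matrix(rep(y0:y1, nx), ny, nx) + 0.5
  m[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] <- pred(xs, ys)
  m
}

# Rasterize an ellipse mask (cx, cy in 0-based pixel coords).
ellipse_mask <- function(H, W, cx, cy, a, b, theta) {
  raster_window(H, W, cx, cy, max(a, b) + 1, function(xs, ys) {
    u <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
    v <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

# Leaf = lens (vesica) shape: intersection of two discs, giving an
# elongated pointed lobe along direction theta.
leaf_mask <- function(H, W, cx, cy, len, wid, theta) {
  R <- (len^2 + wid^2) / (2 * wid)
  off <- R - wid
  ox <- -sin(theta) * off; oy <- cos(theta) * off
  raster_window(H, W, cx, cy, len + 1, function(xs, ys) {
    d1 <- (xs - cx - ox)^2 + (ys - cy - oy)^2
    d2 <- (xs - cx + ox)^2 + (ys - cy + oy)^2
    d1 <= R^2 & d2 <= R^2
  })
}

#' Generate one synthetic orchard scene
#'
#' Deterministic given `seed`. Fruits are shaded ellipses with a specular
#' highlight, drawn in HSV then converted to RGB; leaves are lens-shaped
#' lobes composited *after* the fruit, so they occlude it. Boxes are
#' amodal (they cover the occluded fruit extent) and each instance keeps
#' its full binary mask.
#'
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @param fruits optional data.frame `cx, cy, r, ecc, theta` (pixel units)
#'   overriding random fruit placement (a deterministic hook for tests
#'   and figures).
#' @param image_id identifier stored on the result.
#' @return a [labeled_image()] with per-instance masks (fruits first,
#'   aligned with boxes, then leaves).
#' @export
generate_scene <- function(config = scene_config(), seed = 0L,
                           fruits = NULL, image_id = sprintf("scene_%06d", seed)) {
  W <- config$image_size[1]; H <- config$image_size[2]
  with_seed_(seed, {
    hue <- config$hue_base + smooth_field(H, W, 6)
    sat <- clamp(0.45 + smooth_field(H, W, 0.08), 0.05, 1)
    val <- clamp(0.35 + smooth_field(H, W, 0.12), 0.05, 0.85)

    if (is.null(fruits)) {
      nf <- sample(config$n_fruit[1]:config$n_fruit[2], 1)
      placed <- list()
      for (i in seq_len(nf)) {
        r <- runif(1, config$fruit_radius[1], config$fruit_radius[2])
        ecc <- runif(1, config$fruit_eccentricity[1], config$fruit_eccentricity[2])
        for (try in 1:50) {
          cx <- runif(1, r + 1, W - r - 1)
          cy <- runif(1, r + 1, H - r - 1)
          ok <- TRUE
          for (p in placed) {
            d2 <- (p$cx - cx)^2 + (p$cy - cy)^2
            if (d2 < (0.8 * (r + p$r))^2) { ok <- FALSE; break }
          }
          if (ok) break
        }
        placed[[i]] <- list(cx = cx, cy = cy, r = r, ecc = ecc,
                            theta = runif(1, 0, pi))
      }
    } else {
      placed <- lapply(seq_len(nrow(fruits)), function(i) as.list(fruits[i, ]))
    }

    masks <- list(); cats <- character()
    boxes <- yolo_boxes()
    for (p in placed) {
      m <- ellipse_mask(H, W, p$cx, p$cy, p$r, p$r / p$ecc, p$theta)
      if (!any(m)) next
      masks[[length(masks) + 1L]] <- m
      cats <- c(cats, "fruit")
      boxes <- rbind(boxes, mask_to_box(m))
      # shading: radial falloff + specular highlight toward upper-left
      idx <- which(m)
      xs <- ((idx - 1) %/% H) + 0.5
      ys <- ((idx - 1) %% H) + 0.5
      rho2 <- ((xs - p$cx)^2 + (ys - p$cy)^2) / p$r^2
      hl <- exp(-(((xs - (p$cx - 0.35 * p$r))^2 +
                   (ys - (p$cy - 0.35 * p$r))^2) / (0.35 * p$r)^2))
      fh <- config$hue_base + config$hue_delta + rnorm(1, 0, 1.5)
      hue[idx] <- fh
      sat[idx] <- clamp(0.5 + rnorm(1, 0, 0.03) - 0.25 * hl, 0.05, 1)
      val[idx] <- clamp(0.55 * (1.05 - 0.35 * pmin(rho2, 1)) + 0.3 * hl,
                        0.05, 1)
    }

    n_leaf <- if (config$n_leaf_occluders[2] > 0)
      sample(config$n_leaf_occluders[1]:config$n_leaf_occluders[2], 1) else 0L
    for (j in seq_len(n_leaf)) {
      len <- runif(1, 0.04, 0.09) * min(W, H)
      wid <- len * runif(1, 0.25, 0.45)
      th <- runif(1, 0, pi)
      if (length(boxes$cx) > 0 && runif(1) < config$occlusion_prob) {
        p <- placed[[sample(length(placed), 1)]]
        ang <- runif(1, 0, 2 * pi)
        cx <- clamp(p$cx + cos(ang) * p$r, 1, W - 1)
        cy <- clamp(p$cy + sin(ang) * p$r, 1, H - 1)
      } else {
        cx <- runif(1, 1, W - 1); cy <- runif(1, 1, H - 1)
      }
      m <- leaf_mask(H, W, cx, cy, len, wid, th)
      if (!any(m)) next
      masks[[length(masks) + 1L]] <- m
      cats <- c(cats, "leaf")
      idx <- which(m)
      hue[idx] <- config$hue_base + rnorm(1, 0, 3)
      sat[idx] <- clamp(0.55 + rnorm(1, 0, 0.04), 0.05, 1)
      val[idx] <- clamp(0.45 + rnorm(1, 0, 0.05) +
                        rnorm(length(idx), 0, 0.02), 0.05, 1)
    }

    rgb <- hsv_to_rgb(hue, sat, val)
    expo <- runif(1, config$exposure_jitter[1], config$exposure_jitter[2])
    px <- array(0, c(H, W, 3))
    px[, , 1] <- rgb$r; px[, , 2] <- rgb$g; px[, , 3] <- rgb$b
    px <- px * 255 * expo
    if (config$noise_sd > 0)
      px <- px + array(rnorm(length(px), sd = config$noise_sd), dim(px))
    px <- round(clamp(px, 0, 255))
    labeled_image(px, boxes, masks, cats, image_id)
  })
}

#' Extract instance masks from a labeled image
#'
#' The segmentation-provider contract: for synthetic scenes it returns the
#' stored ground-truth masks (an adapter wrapping a real segmentation
#' model could satisfy the same contract on field images).
#'
#' @param image a `labeled_image` carrying masks.
#' @return list of instances, each `list(mask, category, source_id)`.
#' @export
get_instances <- function(image) {
  if (is.null(image$masks))
    stop("no instance masks available and no segmentation adapter configured")
  lapply(seq_along(image$masks), function(i) {
    list(mask = image$masks[[i]], category = image$mask_categories[i],
         source_id = paste0(image$image_id, "#", i))
  })
}

#' Render a synthetic dataset to disk
#'
#' Writes the standard detection layout: `images/{train,test}/<stem>.png`,
#' `labels/{train,test}/<stem>.txt`, `dataset.yaml`, plus
#' `masks/<stem>.png` (indexed: 0 = background, i = instance i, later
#' instances overwriting earlier ones where they overlap) and `masks.csv`
#' mapping instance index to category. The train/test split follows
#' [split_dataset()] at `ratio`.
#'
#' @param config a [scene_config()].
#' @param n_images number of scenes.
#' @param out_dir output directory (created; cleaned up on failure).
#' @param ratio train fraction (default 0.7).
#' @param seed master seed; per-scene seeds are derived from it.
#' @return `out_dir`, invisibly; attribute `split` carries the id split.
#' @export
render_dataset <- function(config = scene_config(), n_images, out_dir,
                           ratio = 0.7, seed = 0L) {
  created <- !dir.exists(out_dir)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE))
  stems <- sprintf("scene_%04d", seq_len(n_images))
  split <- split_dataset(stems, ratio, seed)
  for (sub in c("train", "test")) {
    dir.create(file.path(out_dir, "images", sub), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", sub), recursive = TRUE,
               showWarnings = FALSE)
  }
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  seeds <- derive_seeds(seed, stems)
  cat_rows <- list()
  for (i in seq_along(stems)) {
    sc <- generate_scene(config, seeds[i], image_id = stems[i])
    sub <- if (stems[i] %in% split$train_ids) "train" else "test"
    write_image(sc$pixels, file.path(out_dir, "images", sub,
                                     paste0(stems[i], ".png")))
    write_labels(sc$boxes, file.path(out_dir, "labels", sub,
                                     paste0(stems[i], ".txt")))
    idx <- matrix(0L, nrow(sc$pixels), ncol(sc$pixels))
    for (j in seq_along(sc$masks)) idx[sc$masks[[j]]] <- j
    png::writePNG(idx / 255, file.path(out_dir, "masks",
                                       paste0(stems[i], ".png")))
    cat_rows[[i]] <- data.frame(stem = stems[i],
                                instance = seq_along(sc$masks),
                                category = sc$mask_categories)
  }
  write.csv(do.call(rbind, cat_rows), file.path(out_dir, "masks.csv"),
            row.names = FALSE)
  write_dataset_yaml(out_dir)
  ok <- TRUE
  invisible(structure(out_dir, split = split))
}
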