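acfg_plain <- function(...) {
  augment_config(preset_size = 96L, flip_prob = 0, rot_range = 0,
                 hsv_jitter = c(0, 0, 0), ...)
}

test_that("copy_paste appends exactly the requested fruit boxes", {
  target <- fixture_scene(21)
  pool <- fixture_pool()
  out <- copy_paste(target, pool, n_fruit = 4, n_leaf = 15,
                    config = augment_config(), seed = 7)
  recs <- attr(out, "paste_records")
  expect_equal(attr(out, "skipped"), 0)
  expect_equal(nrow(out$boxes), nrow(target$boxes) + 4)
  expect_equal(sum(vapply(recs, `[[`, character(1), "category") == "leaf"), 15)
  expect_equal(sum(vapply(recs, `[[`, character(1), "category") == "fruit"), 4)
})

test_that("copy_paste with zero counts is the identity", {
  target <- fixture_scene(22)
  out <- copy_paste(target, fixture_pool(), 0, 0, seed = 1)
  expect_identical(out$pixels, target$pixels)
  expect_identical(out$boxes, target$boxes)
})

test_that("pasted pixels equal the transformed source exactly", {
  target <- fixture_scene(23)
  pool <- fixture_pool()
  out <- copy_paste(target, pool, 3, 5, config = augment_config(), seed = 9)
  recs <- attr(out, "paste_records")
  # replay every paste onto a fresh canvas; the composite must reproduce
  # the augmented image wherever any paste landed
  canvas <- target$pixels
  for (r in recs) {
    tr <- greendet:::transform_instance(pool[[r$pool_index]], r$flip,
                                        r$angle, r$scale)
    rows <- (r$y + 1):(r$y + nrow(tr$mask))
    cols <- (r$x + 1):(r$x + ncol(tr$mask))
    for (ch in 1:3) {
      sub <- canvas[rows, cols, ch]
      sub[tr$mask] <- tr$pixels[, , ch][tr$mask]
      canvas[rows, cols, ch] <- sub
    }
  }
  expect_identical(canvas, out$pixels)
  # and the most recent paste is untouched by later ones
  last <- recs[[length(recs)]]
  tr <- greendet:::transform_instance(pool[[last$pool_index]], last$flip,
                                      last$angle, last$scale)
  rows <- (last$y + 1):(last$y + nrow(tr$mask))
  cols <- (last$x + 1):(last$x + ncol(tr$mask))
  for (ch in 1:3)
    expect_identical(out$pixels[rows, cols, ch][tr$mask],
                     tr$pixels[, , ch][tr$mask])
})

test_that("copy_paste validates its pool", {
  target <- fixture_scene(22)
  expect_error(copy_paste(target, list(), 4, 15), "empty paste pool")
  leaf_only <- Filter(function(e) e$category == "leaf", fixture_pool())
  expect_error(copy_paste(target, leaf_only, 4, 0), "no fruit")
})

test_that("mosaic conserves central boxes at a fixed center and keeps size", {
  imgs <- lapply(1:4, function(i) {
    px <- array(round(runif(96 * 96 * 3) * 255), c(96, 96, 3))
    labeled_image(px, yolo_boxes(0L, 0.5, 0.5, 0.3, 0.3),
                  image_id = paste0("m", i))
  })
  s <- 96L
  out <- mosaic(imgs, s, acfg_plain(), seed = 1, center = c(s, s))
  expect_equal(dim(out$pixels), c(96, 96, 3))
  expect_equal(nrow(out$boxes), 4)
  rec <- attr(out, "mosaic_records")
  # map each output box back through the recorded quadrant transform and
  # check it lands inside its source image bounds
  ab <- convert_box(out$boxes, c(s, s))
  for (i in seq_len(nrow(ab))) {
    q <- rec$box_source[i]
    off <- rec$quadrants[[q]]$offset
    x1 <- ab$x1[i] + rec$crop[1] - off[1]
    y1 <- ab$y1[i] + rec$crop[2] - off[2]
    x2 <- ab$x2[i] + rec$crop[1] - off[1]
    y2 <- ab$y2[i] + rec$crop[2] - off[2]
    expect_gte(x1, -1e-6); expect_gte(y1, -1e-6)
    expect_lte(x2, s + 1e-6); expect_lte(y2, s + 1e-6)
  }
  expect_error(mosaic(imgs[1:3], s, acfg_plain()), "exactly 4")
})

test_that("mixup is the stated convex blend with concatenated labels", {
  a <- fixture_scene(31); b <- fixture_scene(32)
  out <- mixup(a, b, 1)
  expect_identical(out$pixels, a$pixels)
  expect_equal(nrow(out$boxes), nrow(a$boxes) + nrow(b$boxes))

  pa <- labeled_image(array(100, c(4, 4, 3)), image_id = "a")
  pb <- labeled_image(array(20, c(4, 4, 3)), image_id = "b")
  expect_true(all(mixup(pa, pb, 0.35)$pixels == 48))

  lam <- 0.25  # binary-exact so 1 - (1 - lam) == lam bitwise
  expect_identical(mixup(a, b, lam)$pixels, mixup(b, a, 1 - lam)$pixels)

  # convex combination property (before rounding, within rounding error)
  m <- mixup(a, b, 0.6)$pixels
  lo <- pmin(a$pixels, b$pixels) - 0.5
  hi <- pmax(a$pixels, b$pixels) + 0.5
  expect_true(all(m >= lo & m <= hi))

  small <- labeled_image(array(0, c(2, 2, 3)), image_id = "s")
  expect_error(mixup(a, small, 0.5), "size mismatch")
})

test_that("mixup lambda draws follow Beta(alpha, alpha)", {
  n <- 1e5
  for (alpha in c(2, 8)) {
    lam <- sample_mixup_lambda(alpha, n, seed = 12)
    se <- sqrt(1 / (4 * (2 * alpha + 1)) / n)
    expect_lt(abs(mean(lam) - 0.5), 3 * se)
    expect_lt(abs(var(lam) - 1 / (4 * (2 * alpha + 1))),
              0.05 * 1 / (4 * (2 * alpha + 1)))
  }
  expect_identical(sample_mixup_lambda(8, 10, seed = 3),
                   sample_mixup_lambda(8, 10, seed = 3))
  expect_error(sample_mixup_lambda(0), "> 0")
})

test_that("letterbox scales, pads symmetrically and maps boxes", {
  img <- labeled_image(array(100, c(960, 1280, 3)),
                       yolo_boxes(0L, 0.5, 0.5, 0.25, 0.25), image_id = "lb")
  lb <- letterbox(img, 640)
  expect_equal(lb$record$scale, 0.5)
  expect_equal(lb$record$pad, c(0, 80, 0, 80))
  expect_equal(dim(lb$image$pixels), c(640, 640, 3))

  sq <- labeled_image(array(1, c(64, 64, 3)), image_id = "sq")
  lb2 <- letterbox(sq, 64)
  expect_equal(lb2$record$scale, 1)
  expect_identical(lb2$image$pixels, sq$pixels)

  # box corners map by x' = r*x + pad, verified through the inverse
  ab0 <- convert_box(img$boxes, c(1280, 960))
  ab1 <- convert_box(lb$image$boxes, c(640, 640))
  rec <- lb$record
  expect_equal(ab1$x1, ab0$x1 * rec$scale + rec$pad[1], tolerance = 1e-9)
  expect_equal(ab1$y2, ab0$y2 * rec$scale + rec$pad[2], tolerance = 1e-9)
})

test_that("scheduler frequencies follow the configured probabilities", {
  cfg <- augment_config()
  n <- 1e4
  dr <- schedule_draws(cfg, n, seed = 99)
  expect_true(all(dr$copy_paste))  # probability 1
  se_mosaic <- sqrt(0.8 * 0.2 / n)
  se_mixup <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(dr$mosaic) - 0.8), 3 * se_mosaic)
  expect_lt(abs(mean(dr$mixup) - 0.3), 3 * se_mixup)
})

test_that("the pipeline stream is deterministic and letterboxed", {
  ds <- lapply(41:44, fixture_scene)
  pool <- fixture_pool()
  cfg <- augment_config(preset_size = 96L)
  a <- apply_train_pipeline(ds, pool, cfg, 3, seed = 5)
  b <- apply_train_pipeline(ds, pool, cfg, 3, seed = 5)
  for (i in 1:3) {
    expect_identical(a[[i]]$pixels, b[[i]]$pixels)
    expect_identical(a[[i]]$boxes, b[[i]]$boxes)
    expect_equal(dim(a[[i]]$pixels), c(96, 96, 3))
  }
  # all probabilities zero -> letterboxed originals only
  cfg0 <- acfg_plain(p_copy_paste = 0, p_mosaic = 0, p_mixup = 0)
  plain <- apply_train_pipeline(ds[1], pool, cfg0, 1, seed = 2)
  expect_identical(plain[[1]]$pixels,
                   letterbox(ds[[1]], 96)$image$pixels)
})
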