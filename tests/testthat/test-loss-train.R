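test_that("anchor ratio rule gates assignment", {
  anchors <- default_anchors(160)
  # box exactly equal to anchor 4 (stride 16): matched there
  b <- yolo_boxes(0L, 0.5, 0.5, anchors[4, 1] / 160, anchors[4, 2] / 160)
  tg <- assign_targets(b, anchors, 160)
  expect_true(any(tg$scale == 2 & tg$anchor == 1))

  # a gt five times an anchor's width fails that anchor
  b5 <- yolo_boxes(0L, 0.5, 0.5, 5 * anchors[1, 1] / 160,
                   anchors[1, 2] / 160)
  tg5 <- assign_targets(b5, anchors, 160)
  expect_false(any(tg5$scale == 1 & tg5$anchor == 1))

  expect_equal(nrow(assign_targets(yolo_boxes(), anchors, 160)), 0)
})

test_that("each matched anchor claims its cell plus two neighbours", {
  anchors <- default_anchors(160)
  # center exactly on a cell center of the stride-16 grid: cx = 72/160
  b <- yolo_boxes(0L, 72.5 / 160, 72.5 / 160, anchors[4, 1] / 160,
                  anchors[4, 2] / 160)
  tg <- assign_targets(b, anchors, 160)
  tg2 <- tg[tg$scale == 2 & tg$anchor == 1, ]
  expect_equal(nrow(tg2), 3)
  expect_equal(nrow(unique(tg2[, c("gx", "gy")])), 3)
})

test_that("loss terms behave at the analytic corner cases", {
  model <- build_detector(arch_config_mini(), seed = 4)
  anchors <- model$anchors
  b <- yolo_boxes(0L, 0.45, 0.55, 0.25, 0.2)
  tg <- assign_targets(b, anchors, 160)
  nf <- 6L
  raw <- list(array(0, c(18, 20, 20, 1)), array(0, c(18, 10, 10, 1)),
              array(0, c(18, 5, 5, 1)))
  # write exact encodings at every assigned location: box term must vanish
  for (k in seq_len(nrow(tg))) {
    s <- tg$scale[k]
    stride <- c(8, 16, 32)[s]
    anc <- anchors[(s - 1) * 3 + tg$anchor[k], ] / stride
    t <- greendet:::encode_box(tg$cx[k], tg$cy[k], tg$bw[k], tg$bh[k],
                               tg$gx[k], tg$gy[k], anc, 1)
    ch <- (tg$anchor[k] - 1) * nf
    raw[[s]][ch + 1:4, tg$gy[k] + 1, tg$gx[k] + 1, 1] <- t
  }
  ls <- compute_loss(raw, list(tg), 1, anchors)
  expect_lt(ls$terms["box"], 1e-6)

  # empty image: only the objectness term survives
  ls0 <- compute_loss(raw, list(tg[0, ]), 1, anchors)
  expect_equal(unname(ls0$terms["box"]), 0)
  expect_equal(unname(ls0$terms["cls"]), 0)
  expect_gt(ls0$terms["obj"], 0)
  expect_equal(unname(ls0$terms["total"]), unname(ls0$terms["obj"]))

  # doubling the box weight doubles its contribution to the total
  w1 <- c(box = 1, obj = 1, cls = 0.5)
  w2 <- c(box = 2, obj = 1, cls = 0.5)
  set.seed(42)
  rnd <- lapply(raw, function(r) array(rnorm(length(r), sd = 0.5), dim(r)))
  l1 <- compute_loss(rnd, list(tg), 1, anchors, weights = w1)
  l2 <- compute_loss(rnd, list(tg), 1, anchors, weights = w2)
  expect_equal(unname(l2$terms["total"] - l1$terms["total"]),
               unname(l1$terms["box"]), tolerance = 1e-9)
  expect_true(all(vapply(l1$grads, function(g) all(is.finite(g)),
                         logical(1))))
})

test_that("a few gradient steps reduce the loss on one image", {
  sc <- fixture_scene(61, tiny_scene_config())
  arch <- arch_config(widths = c(8L, 8L, 8L, 8L, 8L), depths = c(1, 1, 1, 1),
                      n_classes = 1L, img_size = 96L, r = 4L,
                      anchors = default_anchors(96L))
  model <- build_detector(arch, seed = 6)
  trace <- overfit_steps(model, list(sc), n_steps = 10, lr = 5e-3)
  expect_true(all(is.finite(trace)))
  expect_lt(trace[10], trace[1])
})

test_that("training runs are reproducible under a fixed seed", {
  imgs <- lapply(71:74, function(s) fixture_scene(s, tiny_scene_config()))
  arch <- arch_config(widths = c(8L, 8L, 8L, 8L, 8L), depths = c(1, 1, 1, 1),
                      n_classes = 1L, img_size = 96L, r = 4L,
                      anchors = default_anchors(96L))
  hyp <- train_hyp(epochs = 2L, batch_size = 4L)
  m1 <- train_loop(build_detector(arch, seed = 8), imgs, list(), hyp,
                   seed = 3)
  m2 <- train_loop(build_detector(arch, seed = 8), imgs, list(), hyp,
                   seed = 3)
  expect_equal(attr(m1, "history"), attr(m2, "history"), tolerance = 1e-12)
})
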