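test_that("box conversion matches hand arithmetic and round-trips", {
  b <- yolo_boxes(0L, 0.5, 0.5, 0.2, 0.1)
  ab <- convert_box(b, c(100, 200))
  expect_equal(unlist(ab[, c("x1", "y1", "x2", "y2")], use.names = FALSE),
               c(40, 90, 60, 110))
  full <- convert_box(yolo_boxes(0L, 0.5, 0.5, 1, 1), c(640, 640))
  expect_equal(unlist(full[, -1], use.names = FALSE), c(0, 0, 640, 640))

  set.seed(11)
  for (i in 1:25) {
    w <- runif(1, 0.01, 0.6); h <- runif(1, 0.01, 0.6)
    b <- yolo_boxes(0L, runif(1, w / 2, 1 - w / 2), runif(1, h / 2, 1 - h / 2),
                    w, h)
    sz <- c(sample(50:800, 1), sample(50:800, 1))
    back <- convert_box(convert_box(b, sz), sz, "to_norm")
    expect_lt(max(abs(unlist(back) - unlist(b))), 1e-9)
  }
})

test_that("degenerate boxes are rejected", {
  expect_error(yolo_boxes(0L, 0.5, 0.5, 0, 0.1), "non-positive")
  expect_error(yolo_boxes(0L, 1.5, 0.5, 0.1, 0.1), "outside")
  expect_error(box_iou(data.frame(x1 = 0, y1 = 0, x2 = 0, y2 = 1),
                       data.frame(x1 = 0, y1 = 0, x2 = 1, y2 = 1)),
               "degenerate")
})

test_that("IoU matches hand-computed areas", {
  a <- data.frame(x1 = 0, y1 = 0, x2 = 2, y2 = 2)
  b <- data.frame(x1 = 1, y1 = 1, x2 = 3, y2 = 3)
  expect_equal(box_iou(a, a)[1, 1], 1)
  expect_equal(box_iou(a, b)[1, 1], 1 / 7)
  far <- data.frame(x1 = 10, y1 = 10, x2 = 12, y2 = 12)
  expect_equal(box_iou(a, far)[1, 1], 0)
})

test_that("CIoU combines IoU, center-distance and aspect penalties", {
  a <- data.frame(x1 = 0, y1 = 0, x2 = 2, y2 = 2)
  expect_equal(ciou(a, a), 1)
  # overlap 1/7, centre distance^2 = 2, enclosing diagonal^2 = 18, same
  # aspect ratio: 1/7 - 2/18 = 2/63
  b <- data.frame(x1 = 1, y1 = 1, x2 = 3, y2 = 3)
  expect_equal(ciou(a, b), 2 / 63, tolerance = 1e-9)
  far <- data.frame(x1 = 30, y1 = 0, x2 = 32, y2 = 2)
  expect_lt(ciou(a, far), 0)
})

test_that("NMS keeps the highest-confidence of overlapping boxes", {
  d <- data.frame(class = 0L, conf = c(0.9, 0.8),
                  x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  out <- nms(d, 0.45)
  expect_equal(nrow(out), 1)
  expect_equal(out$conf, 0.9)

  disj <- data.frame(class = 0L, conf = c(0.9, 0.8),
                     x1 = c(0, 50), y1 = 0, x2 = c(10, 60), y2 = 10)
  expect_equal(nrow(nms(disj, 0.45)), 2)

  # IoU exactly 0.5 against a threshold of 0.45 -> suppressed
  pair <- data.frame(class = 0L, conf = c(0.9, 0.8),
                     x1 = 0, y1 = 0, x2 = 2, y2 = c(2, 4))
  expect_equal(box_iou(pair[1, ], pair[2, ])[1, 1], 0.5)
  expect_equal(nrow(nms(pair, 0.45)), 1)
})

test_that("NMS output is an antichain under the IoU relation", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 40
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    d <- data.frame(class = sample(0:1, n, TRUE), conf = runif(n),
                    x1 = x1, y1 = y1, x2 = x1 + runif(n, 5, 20),
                    y2 = y1 + runif(n, 5, 20))
    out <- nms(d, 0.45)
    for (cl in unique(out$class)) {
      o <- out[out$class == cl, , drop = FALSE]
      if (nrow(o) > 1) {
        m <- box_iou(o, o)
        diag(m) <- 0
        expect_lte(max(m), 0.45)
      }
    }
  }
})
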