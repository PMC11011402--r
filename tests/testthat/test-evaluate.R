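mk_det <- function(conf, x1, y1 = 0, w = 10, h = 10, class = 0L) {
  data.frame(class = class, conf = conf, x1 = x1, y1 = y1,
             x2 = x1 + w, y2 = y1 + h)
}
mk_gt <- function(x1, y1 = 0, w = 10, h = 10, class = 0L) {
  data.frame(class = class, x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h)
}

test_that("matching follows the strict IoU-0.5 rule", {
  gts <- mk_gt(c(0, 50, 100))
  m <- match_detections(mk_det(c(0.9, 0.8, 0.7), c(0, 50, 100)), gts)
  expect_equal(sum(m$det$tp), 3)
  expect_equal(m$fn, 0)

  # one detection at IoU 0.4: FP and FN
  # overlap 10x(10*0.4/1.4)? use horizontal shift: iou = (10-d)/(10+d)
  d <- 10 * (1 - 0.4) / (1 + 0.4)  # gives IoU exactly 0.4
  m2 <- match_detections(mk_det(0.9, d), mk_gt(0))
  io <- box_iou(mk_det(0.9, d), mk_gt(0))[1, 1]
  expect_equal(io, 0.4, tolerance = 1e-12)
  expect_equal(sum(m2$det$tp), 0)
  expect_equal(m2$fn, 1)

  # ties at exactly 0.5 are false positives (strict inequality)
  d5 <- 10 / 3  # iou = (10 - 10/3)/(10 + 10/3) = 0.5
  m5 <- match_detections(mk_det(0.9, d5), mk_gt(0))
  expect_equal(box_iou(mk_det(0.9, d5), mk_gt(0))[1, 1], 0.5)
  expect_equal(sum(m5$det$tp), 0)

  # two detections on one gt: greedy by confidence
  m3 <- match_detections(mk_det(c(0.6, 0.9), c(1, 2)), mk_gt(0))
  expect_equal(m3$det$tp, c(TRUE, FALSE))
  expect_equal(m3$det$conf, c(0.9, 0.6))
})

test_that("TP/FP/FN conservation holds on random problems", {
  set.seed(401)
  for (rep in 1:25) {
    pr <- random_match_problem(sample(1:40, 1), sample(1:30, 1))
    m <- match_detections(pr$dets, pr$gts)
    expect_equal(sum(m$det$tp) + sum(!m$det$tp), nrow(pr$dets))
    expect_equal(sum(m$det$tp) + m$fn, nrow(pr$gts))
    matched <- m$det$gt[!is.na(m$det$gt)]
    if (length(matched)) expect_lte(max(table(matched)), 1)  # each gt once
  }
})

test_that("AP reproduces the hand-built three-detection example", {
  # 2 gts; detections: conf 0.9 TP, 0.8 FP, 0.7 TP
  ap <- average_precision(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2)
  expect_equal(ap$ap, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)

  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, TRUE), 2)$ap, 1.0)
  expect_equal(average_precision(numeric(), logical(), 5)$ap, 0)
})

test_that("AP equals the brute-force threshold-sweep oracle", {
  set.seed(402)
  for (rep in 1:40) {
    n_det <- sample(1:50, 1)
    n_gt <- sample(1:50, 1)
    pr <- random_match_problem(n_det, n_gt)
    m <- match_detections(pr$dets, pr$gts)
    ap <- average_precision(m$det$conf, m$det$tp, n_gt)$ap
    expect_equal(ap, oracle_ap(m$det$conf, m$det$tp, n_gt),
                 tolerance = 1e-9)
  }
})

test_that("AP is invariant to monotone confidence transforms", {
  set.seed(403)
  pr <- random_match_problem(30, 20)
  m <- match_detections(pr$dets, pr$gts)
  ap1 <- average_precision(m$det$conf, m$det$tp, 20)$ap
  ap2 <- average_precision(m$det$conf^3, m$det$tp, 20)$ap
  expect_equal(ap1, ap2, tolerance = 1e-12)
  # relabeling a TP as FP cannot increase AP
  if (any(m$det$tp)) {
    worse <- m$det$tp
    worse[which(worse)[1]] <- FALSE
    expect_lte(average_precision(m$det$conf, worse, 20)$ap, ap1)
  }
})

test_that("F1 identities hold, including on printed-table values", {
  expect_equal(f1_score(86.3, 76.3), 81.0, tolerance = 0.05)
  expect_equal(f1_score(0.4, 0.4), 0.4)
  expect_equal(f1_score(0.7, 0), 0)
  expect_equal(f1_score(0, 0), 0)
})

test_that("evaluate_detections scores perfect and empty predictions", {
  set.seed(404)
  gts <- lapply(1:4, function(i) mk_gt(c(0, 30, 60) + i))
  perfect <- lapply(gts, function(g) cbind(g[1], conf = 1.0, g[-1]))
  rep1 <- evaluate_detections(perfect, gts, 1)
  expect_equal(rep1$map, 1.0)
  expect_equal(rep1$per_class$p, 1.0)
  expect_equal(rep1$per_class$r, 1.0)
  expect_equal(rep1$per_class$f1, 1.0)

  empty <- lapply(gts, function(g) mk_det(0.5, 0)[0, ])
  rep0 <- evaluate_detections(empty, gts, 1)
  expect_equal(rep0$map, 0)
  expect_equal(rep0$per_class$r, 0)
})

test_that("metrics pick the max-F1 operating point", {
  # confs 0.9 TP, 0.8 TP, 0.7 FP, 0.6 FP with 3 gts: best F1 at top-2
  dets <- list(mk_det(c(0.9, 0.8, 0.7, 0.6), c(0, 30, 200, 240)))
  gts <- list(mk_gt(c(0, 30, 60)))
  r <- evaluate_detections(dets, gts, 1)
  expect_equal(r$per_class$p, 1.0)
  expect_equal(r$per_class$r, 2 / 3, tolerance = 1e-12)
  expect_equal(r$per_class$f1, f1_score(1, 2 / 3), tolerance = 1e-12)
})
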