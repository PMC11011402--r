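mini_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_detector(arch_config_mini(), seed = 1)
    m
  }
})

test_that("head grids follow the stride contract at 640 and 160", {
  arch <- arch_config(widths = c(4L, 4L, 4L, 4L, 4L), depths = c(1, 1, 1, 1),
                      img_size = 640L, r = 2L)
  model <- build_detector(arch, seed = 2)
  x <- array(runif(3 * 640 * 640), c(3, 640, 640))
  raw <- detector_forward(model, x)
  expect_equal(lapply(raw, function(r) dim(r)[2:3]),
               list(c(80, 80), c(40, 40), c(20, 20)))
  expect_equal(unique(vapply(raw, function(r) dim(r)[1], numeric(1))),
               3 * (5 + 1))
  expect_true(all(vapply(raw, function(r) all(is.finite(r)), logical(1))))

  raw160 <- detector_forward(mini_model(),
                             array(runif(3 * 160 * 160), c(3, 160, 160)))
  expect_equal(lapply(raw160, function(r) dim(r)[2:3]),
               list(c(20, 20), c(10, 10), c(5, 5)))
})

test_that("zero logits decode to cell centers with anchor-sized boxes", {
  model <- mini_model()
  raw0 <- list(array(0, c(18, 20, 20, 1)), array(0, c(18, 10, 10, 1)),
               array(0, c(18, 5, 5, 1)))
  d <- decode_predictions(raw0, model$anchors, 0, c(160, 160), 1)
  # stride-8 scale, cell (i=2, j=3) (0-based), anchor 1
  a1 <- model$anchors[1, ]
  hit <- d[abs((d$x1 + d$x2) / 2 - (2 + 0.5) * 8) < 1e-9 &
           abs((d$y1 + d$y2) / 2 - (3 + 0.5) * 8) < 1e-9, ]
  expect_gte(nrow(hit), 1)
  expect_true(any(abs(hit$x2 - hit$x1 - a1[1]) < 1e-9 &
                  abs(hit$y2 - hit$y1 - a1[2]) < 1e-9))
  # sigma(0)^2 = 0.25 confidence everywhere
  expect_equal(unique(round(d$conf, 12)), 0.25)
  # conf threshold 1.0 excludes everything (sigmoid products < 1)
  expect_equal(nrow(decode_predictions(raw0, model$anchors, 1.0,
                                       c(160, 160), 1)), 0)
  # boxes stay inside the image
  expect_true(all(d$x1 >= 0 & d$y1 >= 0 & d$x2 <= 160 & d$y2 <= 160))
})

test_that("encode and decode are mutually inverse within tolerance", {
  model <- mini_model()
  set.seed(301)
  for (rep in 1:20) {
    s <- sample(1:3, 1)
    stride <- c(8, 16, 32)[s]
    anc <- model$anchors[(s - 1) * 3 + sample(1:3, 1), ]
    ng <- 160 / stride
    gx <- sample(0:(ng - 1), 1); gy <- sample(0:(ng - 1), 1)
    cx <- (gx + runif(1, -0.49, 1.49)) * stride
    cy <- (gy + runif(1, -0.49, 1.49)) * stride
    bw <- anc[1] * runif(1, 0.3, 3.9)
    bh <- anc[2] * runif(1, 0.3, 3.9)
    t <- greendet:::encode_box(cx, cy, bw, bh, gx, gy, anc, stride)
    sg <- function(z) 1 / (1 + exp(-z))
    cx2 <- (2 * sg(t["tx"]) - 0.5 + gx) * stride
    cy2 <- (2 * sg(t["ty"]) - 0.5 + gy) * stride
    bw2 <- (2 * sg(t["tw"]))^2 * anc[1]
    bh2 <- (2 * sg(t["th"]))^2 * anc[2]
    expect_lt(max(abs(c(cx2 - cx, cy2 - cy) / stride),
                  abs(c(bw2 / bw, bh2 / bh) - 1)), 1e-4)
  }
})

test_that("autoanchor clusters box sizes and reports recall", {
  # identical boxes: every anchor collapses onto that size
  wh_same <- matrix(rep(c(30, 40), each = 20), ncol = 2)
  a <- autoanchor(wh_same, img_size = 160, seed = 1)
  expect_lt(max(abs(a[, 1] - 30)), 1e-6)
  expect_lt(max(abs(a[, 2] - 40)), 1e-6)
  expect_equal(attr(a, "bpr"), 1.0)

  # nine distinct sizes: perfect recall is attainable and objective falls
  set.seed(302)
  wh <- cbind(runif(200, 8, 80), runif(200, 8, 80))
  a2 <- autoanchor(wh, img_size = 160, seed = 3)
  expect_equal(dim(a2), c(9, 2))
  expect_true(all(diff(a2[, 1] * a2[, 2]) >= 0))  # sorted by area
  expect_gte(attr(a2, "bpr"), 0.99)
  tr <- attr(a2, "objective_trace")
  expect_true(all(diff(tr) <= 1e-12))

  expect_warning(a3 <- autoanchor(wh[1:5, ], img_size = 160), "fewer than")
  expect_equal(dim(a3), c(9, 2))
})

test_that("checkpoints round-trip the model exactly", {
  model <- mini_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  x <- array(runif(3 * 160 * 160), c(3, 160, 160))
  expect_equal(detector_forward(model, x), detector_forward(back, x),
               tolerance = 1e-12)
})
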