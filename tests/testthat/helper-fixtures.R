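# Shared fixtures and independent oracles for the test suite.

# Small scenes are cached per test run (generation is deterministic).
.fixture_env <- new.env(parent = emptyenv())

tiny_scene_config <- function(...) {
  scene_config_desk(image_size = c(96L, 96L), fruit_radius = c(8, 20),
                    n_leaf_occluders = c(2L, 5L), ...)
}

fixture_scene <- function(seed, config = tiny_scene_config()) {
  key <- paste0("scene_", seed, "_", config$image_size[1])
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_scene(config, seed)
  .fixture_env[[key]]
}

fixture_pool <- function(seeds = 1:2, config = tiny_scene_config()) {
  make_paste_pool(lapply(seeds, fixture_scene, config = config))
}

# Independent AP oracle: explicit confidence-threshold sweep. For every
# distinct confidence, precision/recall are recomputed from scratch; the
# envelope and its area are integrated point by point.
oracle_ap <- function(conf, tp, n_gt) {
  if (!length(conf)) return(0)
  thr <- sort(unique(conf), decreasing = TRUE)
  pts <- t(vapply(thr, function(t0) {
    sel <- conf >= t0
    c(r = sum(tp[sel]) / n_gt, p = sum(tp[sel]) / sum(sel))
  }, numeric(2)))
  pts <- pts[order(pts[, "r"]), , drop = FALSE]
  area <- 0
  r_prev <- 0
  for (i in seq_len(nrow(pts))) {
    r <- unname(pts[i, "r"])
    if (r > r_prev) {
      env <- max(pts[pts[, "r"] >= r, "p"])
      area <- area + (r - r_prev) * env
      r_prev <- r
    }
  }
  unname(area)
}

# Direct elementwise evaluation of the channel-attention formula
# X * sigma(MLP(Avgpool(X)) + MLP(Maxpool(X))) with explicit loops.
oracle_channel_attention <- function(x, W1, W2) {
  C <- dim(x)[1]
  avg <- numeric(C); mx <- numeric(C)
  for (c_ in seq_len(C)) {
    avg[c_] <- mean(x[c_, , ])
    mx[c_] <- max(x[c_, , ])
  }
  mlp <- function(v) as.vector(W2 %*% pmax(W1 %*% v, 0))
  w <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  y <- x
  for (c_ in seq_len(C)) y[c_, , ] <- x[c_, , ] * w[c_]
  y
}

# Direct evaluation of the spatial-attention formula: channel mean/max
# maps, learned 2->1 per-pixel mix, sigmoid, broadcast multiply.
oracle_spatial_attention <- function(x, Wmix) {
  d <- dim(x)
  avg <- apply(x, c(2, 3), mean)
  mx <- apply(x, c(2, 3), max)
  w <- 1 / (1 + exp(-(Wmix[1] * avg + Wmix[2] * mx)))
  y <- x
  for (c_ in seq_len(d[1])) y[c_, , ] <- x[c_, , ] * w
  y
}

# Random detection/ground-truth problem for the metric oracle tests.
random_match_problem <- function(n_det, n_gt, size = 100) {
  mk <- function(n) {
    x1 <- runif(n, 0, size - 10); y1 <- runif(n, 0, size - 10)
    w <- runif(n, 4, 30); h <- runif(n, 4, 30)
    data.frame(class = 0L, x1 = x1, y1 = y1,
               x2 = pmin(x1 + w, size), y2 = pmin(y1 + h, size))
  }
  gts <- mk(n_gt)
  # detections: jittered copies of some gts plus clutter
  base <- gts[sample(n_gt, min(n_det, n_gt), replace = TRUE), , drop = FALSE]
  jit <- function(v, s) v + rnorm(length(v), 0, s)
  dets <- data.frame(class = 0L,
                     conf = runif(nrow(base)),
                     x1 = jit(base$x1, 4), y1 = jit(base$y1, 4),
                     x2 = jit(base$x2, 4), y2 = jit(base$y2, 4))
  extra <- n_det - nrow(base)
  if (extra > 0) {
    e <- mk(extra)
    dets <- rbind(dets, data.frame(class = 0L, conf = runif(extra),
                                   e[, c("x1", "y1", "x2", "y2")]))
  }
  dets$x2 <- pmax(dets$x2, dets$x1 + 1)
  dets$y2 <- pmax(dets$y2, dets$y1 + 1)
  list(dets = dets, gts = gts)
}
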