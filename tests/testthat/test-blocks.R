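test_that("conv_bn_act follows the declared shape contract", {
  set.seed(201)
  x <- array(rnorm(3 * 64 * 64), c(3, 64, 64))
  y <- conv_bn_act(x, c_out = 8L, k = 3L, stride = 2L)
  expect_equal(dim(y), c(8, 32, 32))

  # ReLU variant: all-negative pre-activation gives all zeros
  lyr <- layer_conv(3, 4, 3L, 1L, "relu", bn = FALSE)
  lyr$params$W$value[] <- 0
  lyr$params$b$value[] <- -5
  y2 <- block_forward(lyr, x)
  expect_true(all(y2 == 0))
})

test_that("zero-parameter channel attention is exactly 0.5*X", {
  set.seed(202)
  lyr <- layer_ca(16, 16L)
  for (p in collect_params(lyr)) p$value[] <- 0
  x <- array(rnorm(16 * 6 * 6), c(16, 6, 6))
  expect_identical(channel_attention(x, layer = lyr), 0.5 * x)
})

test_that("channel attention matches its direct formula evaluation", {
  set.seed(203)
  lyr <- layer_ca(8, 4L)
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  # reduction r=4 floors the hidden width; rebuild at matching C
  lyr <- layer_ca(4, 4L)
  y <- channel_attention(x, layer = lyr)
  yo <- oracle_channel_attention(x, lyr$params$W1$value, lyr$params$W2$value)
  expect_lt(max(abs(y - yo)), 1e-6)
  expect_equal(dim(y), dim(x))

  # weights strictly inside (0,1): |Y| < |X| elementwise for nonzero X
  expect_true(all(abs(y[x != 0]) < abs(x[x != 0])))

  # spatially constant input: avg pool equals max pool, so the weight is
  # sigma(2 * MLP(v))
  xc <- array(rep(rnorm(4), 36), c(4, 6, 6))
  wv <- as.vector(lyr$params$W2$value %*%
                    pmax(lyr$params$W1$value %*% xc[, 1, 1], 0))
  expected <- xc * as.vector(1 / (1 + exp(-2 * wv)))
  expect_lt(max(abs(channel_attention(xc, layer = lyr) - expected)), 1e-9)
})

test_that("channel attention rejects C < r", {
  expect_error(layer_ca(4, 16L), "<")
})

test_that("spatial attention matches its direct formula evaluation", {
  set.seed(204)
  lyr <- layer_sa(4)
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  y <- spatial_attention(x, layer = lyr)
  yo <- oracle_spatial_attention(x, lyr$params$Wmix$value)
  expect_lt(max(abs(y - yo)), 1e-6)
  expect_equal(dim(y), dim(x))

  # zero mixing weights: sigma(0) = 0.5 exactly
  lyr0 <- layer_sa(4)
  lyr0$params$Wmix$value[] <- 0
  expect_identical(spatial_attention(x, layer = lyr0), 0.5 * x)

  # channel-wise constant input -> spatially uniform weight map
  xc <- array(1.7, c(3, 5, 5))
  yc <- spatial_attention(xc, layer = layer_sa(3))
  expect_lt(max(abs(yc - yc[1, 1, 1])), 1e-12)
})

test_that("Conv-AT equals the stage-by-stage composition of its parts", {
  set.seed(205)
  lyr <- layer_conv_at(8, 16, stride = 2L, r = 4L)
  x <- array(rnorm(8 * 16 * 16), c(8, 16, 16))
  y <- block_forward(lyr, x)  # inference mode

  avgpool2 <- function(a, s) {
    d <- dim(a)
    out <- array(0, c(d[1], d[2] / s, d[3] / s))
    for (i in 1:s) for (j in 1:s)
      out <- out + a[, seq(i, d[2], s), seq(j, d[3], s), drop = FALSE]
    out / (s * s)
  }
  cat_c <- function(a, b) {
    out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
    out[seq_len(dim(a)[1]), , ] <- a
    out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
    out
  }
  sub <- lyr$layers
  P <- cat_c(avgpool2(block_forward(sub$ca, x), 2),
             block_forward(sub$cbr1, x))
  H <- cat_c(block_forward(sub$cbr2, P),
             avgpool2(block_forward(sub$sa, x), 2))
  W <- cat_c(block_forward(sub$cbr3, H), block_forward(sub$cbr4, x))
  Z <- block_forward(sub$cbr5, W)
  # closing BN in inference mode (fresh running stats: mean 0, var 1)
  g <- lyr$params$gamma$value; b <- lyr$params$beta$value
  st <- lyr$meta$state
  Y <- Z
  for (c_ in seq_len(dim(Z)[1]))
    Y[c_, , ] <- g[c_] * (Z[c_, , ] - st$mean[c_]) /
      sqrt(st$var[c_] + 1e-5) + b[c_]
  expect_lt(max(abs(y - Y)), 1e-6)
  expect_equal(dim(y), c(16, 8, 8))
})

test_that("Conv-AT channel plan follows the concatenation arithmetic", {
  lyr <- layer_conv_at(64, 128, stride = 2L, r = 16L)
  x <- array(rnorm(64 * 8 * 8), c(64, 8, 8))
  expect_equal(dim(block_forward(lyr, x))[1], 128)
  # P = concat(CA(X), CBR1(X)) has c_in + c_out/2 channels
  Pn <- lyr$layers$cbr2$meta$c_in
  expect_equal(Pn, 64 + 64)
  expect_error(layer_conv_at(8, 15), "even")
})

test_that("C3 preserves space, halves internally and fuses", {
  set.seed(206)
  x <- array(rnorm(6 * 10 * 10), c(6, 10, 10))
  lyr <- layer_c3(6, 8, n = 2L)
  y <- block_forward(lyr, x)
  expect_equal(dim(y), c(8, 10, 10))
  expect_error(layer_c3(6, 7), "even")

  # n = 0 degenerates to two 1x1 convs + fuse
  lyr0 <- layer_c3(6, 8, n = 0L)
  y0 <- block_forward(lyr0, x)
  expect_equal(dim(y0), c(8, 10, 10))

  # zeroed bottleneck convs: the residual path passes cv1's output through
  lyrz <- layer_c3(6, 8, n = 1L)
  lyrz$layers$b1b$params$W$value[] <- 0
  lyrz$layers$b1b$params$beta$value[] <- 0
  cv1_out <- block_forward(lyrz$layers$cv1, x)
  split_in <- block_forward(lyrz$layers$b1a, cv1_out)  # irrelevant, zeroed next
  bz <- block_forward(lyrz$layers$b1b, split_in)
  # silu(bn(0)) = 0 when beta = 0 and running stats are fresh
  expect_true(all(abs(bz) < 1e-9))
})

test_that("SPPF cascaded pools equal single pools of growing kernels", {
  set.seed(207)
  x <- array(rnorm(4 * 9 * 9), c(4, 9, 9))
  lyr <- layer_sppf(4, 6, k = 5L)
  y <- block_forward(lyr, x)
  expect_equal(dim(y), c(6, 9, 9))

  mp <- function(a, k) {
    xn <- greendet:::ad_const(greendet:::as_chwn(a))
    out <- greendet:::op_maxpool(xn, k, 1L, k %/% 2L)$value
    array(out, dim(out)[1:3])
  }
  p1 <- mp(x, 5L)
  expect_equal(mp(p1, 5L), mp(x, 9L))
  expect_equal(mp(mp(p1, 5L), 5L), mp(x, 13L))

  # constant input: pooling changes nothing
  xc <- array(3.3, c(2, 7, 7))
  expect_identical(mp(xc, 5L), xc)
})
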