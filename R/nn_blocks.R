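# Network building blocks. A layer is a list with fields
#   $params  named list of ad_param nodes,
#   $layers  named list of sub-layers (for composites),
#   $fwd     function(x_node, training) -> ad_node.
# Feature maps are channel-first (C,H,W[,N]) arrays; weight matrices for a
# k x k convolution have one row per output channel and columns indexed by
# (c, ki, kj) as c + C*(ki + k*kj) (0-based), matching the im2col kernel.

new_layer <- function(fwd, params = list(), layers = list(), meta = list()) {
  structure(list(fwd = fwd, params = params, layers = layers, meta = meta),
            class = "gd_layer")
}

#' Collect all trainable parameters of a layer or model
#' @param layer a layer or model object.
#' @return flat named list of parameter nodes.
#' @export
collect_params <- function(layer) UseMethod("collect_params")

#' @export
collect_params.gd_layer <- function(layer) {
  out <- list()
  walk <- function(l, prefix) {
    for (nm in names(l$params))
      out[[paste0(prefix, nm)]] <<- l$params[[nm]]
    for (nm in names(l$layers))
      walk(l$layers[[nm]], paste0(prefix, nm, "."))
  }
  walk(layer, "")
  out
}

kaiming_init <- function(c_out, fan_in) {
  matrix(rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)), c_out, fan_in)
}

bn_state <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mean <- numeric(C)
  e$var <- rep(1, C)
  e
}

#' Convolution + batch norm + activation layer (CBS / CBR)
#'
#' The CBS block (SiLU activation) is the generic feature-extraction
#' convolution; the CBR variant (ReLU) is the workhorse inside the Conv-AT
#' block, chosen for its faster convergence and resistance to vanishing
#' gradients. Spatial size maps as `floor((H + 2p - k)/s) + 1` with
#' same-padding `p = k %/% 2`.
#'
#' @param c_in,c_out input/output channel counts.
#' @param k kernel size; @param stride stride.
#' @param act `"silu"`, `"relu"` or `"none"`.
#' @param bn apply batch normalization (bias-free convolution) if `TRUE`.
#' @return a layer object.
#' @export
layer_conv <- function(c_in, c_out, k = 1L, stride = 1L,
                       act = c("silu", "relu", "none"), bn = TRUE) {
  act <- match.arg(act)
  pad <- k %/% 2L
  params <- list(W = ad_param(kaiming_init(c_out, c_in * k * k)))
  if (bn) {
    params$gamma <- ad_param(rep(1, c_out))
    params$beta <- ad_param(numeric(c_out))
    state <- bn_state(c_out)
  } else {
    params$b <- ad_param(numeric(c_out))
    state <- NULL
  }
  fwd <- function(x, training = FALSE) {
    y <- op_conv(x, params$W, if (bn) NULL else params$b,
                 k = k, stride = stride, pad = pad)
    if (bn) y <- op_bn(y, params$gamma, params$beta, state, training)
    switch(act, silu = op_silu(y), relu = op_relu(y), none = y)
  }
  new_layer(fwd, params,
            meta = list(type = "conv", c_in = c_in, c_out = c_out, k = k,
                        stride = stride, act = act, state = state))
}

#' Channel attention (CA) layer
#'
#' Computes `X * sigma(MLP(Avgpool(X)) + MLP(Maxpool(X)))`: global average
#' and max pooling over the spatial dimensions feed a shared two-layer
#' bottleneck MLP (`C -> C/r -> C`, ReLU between, no biases); the summed
#' outputs pass through a sigmoid to give per-channel weights in (0,1)
#' that rescale the input. Output shape equals input shape.
#'
#' @param C input channel count (must satisfy `C >= r`).
#' @param r bottleneck reduction ratio (default 16); the hidden width is
#'   `max(8, C %/% r)` capped at `C`.
#' @return a layer object.
#' @export
layer_ca <- function(C, r = 16L) {
  if (C < r) stop("channel attention: C (", C, ") < reduction r (", r, ")")
  hidden <- max(1L, min(C, max(8L, C %/% r)))
  params <- list(W1 = ad_param(kaiming_init(hidden, C)),
                 W2 = ad_param(kaiming_init(C, hidden)))
  mlp <- function(v) op_conv(op_relu(op_conv(v, params$W1)), params$W2)
  fwd <- function(x, training = FALSE) {
    w <- op_sigmoid(op_add(mlp(op_gap(x)), mlp(op_gmp(x))))
    op_cmul(x, w)
  }
  new_layer(fwd, params, meta = list(type = "ca", C = C, r = r, hidden = hidden))
}

#' Spatial attention (SA) layer
#'
#' Average and max pooling *across channels* yield two `1 x H x W` maps;
#' their 2-channel concatenation is reduced to one channel by a learned
#' per-pixel linear mix (a 1x1 convolution), and a sigmoid turns it into a
#' spatial weight map in (0,1) that rescales every channel of the input.
#'
#' @param C input channel count.
#' @return a layer object.
#' @export
layer_sa <- function(C) {
  params <- list(Wmix = ad_param(kaiming_init(1L, 2L)))
  fwd <- function(x, training = FALSE) {
    pooled <- op_concat_c(list(op_cmean(x), op_cmax(x)))
    w <- op_sigmoid(op_conv(pooled, params$Wmix))
    op_smul(x, w)
  }
  new_layer(fwd, params, meta = list(type = "sa", C = C))
}

#' Conv-AT attention-integration block
#'
#' Four concatenation stages combine channel-attended, spatially-attended
#' and convolved views of the input:
#' \deqn{P = concat(CA(X); CBR_1(X))}
#' \deqn{H = concat(CBR_2(P); SA(X))}
#' \deqn{W = concat(CBR_3(H); CBR_4(X))}
#' \deqn{Y = BN(CBR_5(W))}
#' All internal CBRs use 3x3 kernels. `CBR_1` and `CBR_4` carry the block's
#' stride and project to `c_out/2`; `CBR_2`/`CBR_3` project back to
#' `c_out/2`; `CBR_5` maps to `c_out`. The attention paths preserve the
#' input and are stride-matched by non-overlapping average pooling so all
#' concatenations align spatially. The closing batch normalization is
#' applied on top of `CBR_5`'s own (both kept deliberately: it tames the
#' value spread the concatenations produce).
#'
#' @param c_in,c_out channel counts (`c_out` even).
#' @param stride block stride (downsampling factor).
#' @param r channel-attention reduction.
#' @param use_ca,use_sa include the attention mechanisms (ablation toggles;
#'   when off, the path passes the input through unattended).
#' @return a layer object.
#' @export
layer_conv_at <- function(c_in, c_out, stride = 2L, r = 16L,
                          use_ca = TRUE, use_sa = TRUE) {
  if (c_out %% 2L != 0L) stop("conv_at: c_out must be even")
  half <- c_out %/% 2L
  layers <- list(
    cbr1 = layer_conv(c_in, half, 3L, stride, act = "relu"),
    cbr2 = layer_conv(c_in + half, half, 3L, 1L, act = "relu"),
    cbr3 = layer_conv(half + c_in, half, 3L, 1L, act = "relu"),
    cbr4 = layer_conv(c_in, half, 3L, stride, act = "relu"),
    cbr5 = layer_conv(c_out, c_out, 3L, 1L, act = "relu"))
  if (use_ca) layers$ca <- layer_ca(c_in, r)
  if (use_sa) layers$sa <- layer_sa(c_in)
  params <- list(gamma = ad_param(rep(1, c_out)),
                 beta = ad_param(numeric(c_out)))
  state <- bn_state(c_out)
  fwd <- function(x, training = FALSE) {
    ca_path <- if (use_ca) layers$ca$fwd(x, training) else x
    ca_path <- op_avgpool_s(ca_path, stride)
    P <- op_concat_c(list(ca_path, layers$cbr1$fwd(x, training)))
    sa_path <- if (use_sa) layers$sa$fwd(x, training) else x
    sa_path <- op_avgpool_s(sa_path, stride)
    H <- op_concat_c(list(layers$cbr2$fwd(P, training), sa_path))
    W <- op_concat_c(list(layers$cbr3$fwd(H, training),
                          layers$cbr4$fwd(x, training)))
    op_bn(layers$cbr5$fwd(W, training), params$gamma, params$beta,
          state, training)
  }
  new_layer(fwd, params, layers,
            meta = list(type = "conv_at", c_in = c_in, c_out = c_out,
                        stride = stride, state = state))
}

#' Cross-stage-partial (C3) layer
#'
#' Splits computation into a bottleneck path (1x1 reduce, `n` residual
#' bottlenecks) and a 1x1 bypass, concatenates the two halves and fuses
#' them with a final 1x1 convolution. Spatial size is preserved.
#'
#' @param c_in,c_out channel counts (`c_out` even).
#' @param n number of bottlenecks.
#' @param shortcut use residual additions inside bottlenecks.
#' @return a layer object.
#' @export
layer_c3 <- function(c_in, c_out, n = 1L, shortcut = TRUE) {
  if (c_out %% 2L != 0L) stop("c3: c_out must be even")
  half <- c_out %/% 2L
  layers <- list(cv1 = layer_conv(c_in, half, 1L),
                 cv2 = layer_conv(c_in, half, 1L),
                 cv3 = layer_conv(c_out, c_out, 1L))
  for (i in seq_len(n)) {
    layers[[paste0("b", i, "a")]] <- layer_conv(half, half, 1L)
    layers[[paste0("b", i, "b")]] <- layer_conv(half, half, 3L)
  }
  fwd <- function(x, training = FALSE) {
    y <- layers$cv1$fwd(x, training)
    for (i in seq_len(n)) {
      z <- layers[[paste0("b", i, "b")]]$fwd(
        layers[[paste0("b", i, "a")]]$fwd(y, training), training)
      y <- if (shortcut) op_add(y, z) else z
    }
    layers$cv3$fwd(op_concat_c(list(y, layers$cv2$fwd(x, training))), training)
  }
  new_layer(fwd, list(), layers,
            meta = list(type = "c3", c_in = c_in, c_out = c_out, n = n))
}

#' Spatial pyramid pooling (fast) layer
#'
#' A 1x1 reduction followed by three cascaded max-pools (kernel `k`,
#' stride 1, same padding) whose outputs are concatenated with the input
#' path (4x channels) and fused by a 1x1 convolution. Cascading `k = 5`
#' pools is equivalent to single pools with receptive fields 5, 9, 13.
#'
#' @param c_in,c_out channel counts.
#' @param k pooling kernel (odd; default 5).
#' @return a layer object.
#' @export
layer_sppf <- function(c_in, c_out, k = 5L) {
  half <- max(1L, c_in %/% 2L)
  layers <- list(cv1 = layer_conv(c_in, half, 1L),
                 cv2 = layer_conv(half * 4L, c_out, 1L))
  pad <- k %/% 2L
  fwd <- function(x, training = FALSE) {
    y <- layers$cv1$fwd(x, training)
    p1 <- op_maxpool(y, k, 1L, pad)
    p2 <- op_maxpool(p1, k, 1L, pad)
    p3 <- op_maxpool(p2, k, 1L, pad)
    layers$cv2$fwd(op_concat_c(list(y, p1, p2, p3)), training)
  }
  new_layer(fwd, list(), layers,
            meta = list(type = "sppf", c_in = c_in, c_out = c_out, k = k))
}

#' Run a layer on a plain feature array
#'
#' Convenience wrapper: promotes a `(C,H,W)` array to a batch of one, runs
#' the layer's forward pass off-tape and returns a plain array.
#'
#' @param layer a layer object.
#' @param x numeric `(C,H,W)` or `(C,H,W,N)` array.
#' @param training use batch statistics in batch-norm layers.
#' @return array of the same rank as `x`.
#' @export
block_forward <- function(layer, x, training = FALSE) {
  rank3 <- length(dim(x)) == 3
  y <- layer$fwd(ad_const(as_chwn(x)), training)$value
  if (rank3) {
    d <- dim(y)
    dim(y) <- d[1:3]
  }
  y
}

#' One-shot functional block applications
#'
#' These helpers build a randomly initialized layer (under the caller's RNG
#' state) and apply it to `x`; pass an existing layer to reuse weights.
#'
#' @param x `(C,H,W)` feature array.
#' @param r channel-attention reduction ratio.
#' @param layer optional pre-built layer.
#' @param training forwarded to [block_forward()].
#' @return transformed feature array, same shape as `x` for the attention
#'   blocks.
#' @name functional-blocks
NULL

#' @rdname functional-blocks
#' @export
channel_attention <- function(x, r = 16L, layer = NULL, training = FALSE) {
  layer <- layer %||% layer_ca(dim(x)[1], r)
  block_forward(layer, x, training)
}

#' @rdname functional-blocks
#' @export
spatial_attention <- function(x, layer = NULL, training = FALSE) {
  layer <- layer %||% layer_sa(dim(x)[1])
  block_forward(layer, x, training)
}

#' @rdname functional-blocks
#' @param c_out output channels; @param k kernel; @param stride stride;
#'   @param act activation (`"silu"` for CBS, `"relu"` for CBR).
#' @export
conv_bn_act <- function(x, c_out, k = 3L, stride = 1L, act = "silu",
                        layer = NULL, training = FALSE) {
  layer <- layer %||% layer_conv(dim(x)[1], c_out, k, stride, act)
  block_forward(layer, x, training)
}

#' @rdname functional-blocks
#' @export
conv_at_block <- function(x, c_out, stride = 2L, r = 16L, layer = NULL,
                          training = FALSE) {
  layer <- layer %||% layer_conv_at(dim(x)[1], c_out, stride, r)
  block_forward(layer, x, training)
}

#' @rdname functional-blocks
#' @param n number of bottlenecks.
#' @export
c3_block <- function(x, c_out, n = 1L, layer = NULL, training = FALSE) {
  layer <- layer %||% layer_c3(dim(x)[1], c_out, n)
  block_forward(layer, x, training)
}

#' @rdname functional-blocks
#' @export
sppf_block <- function(x, c_out, k = 5L, layer = NULL, training = FALSE) {
  layer <- layer %||% layer_sppf(dim(x)[1], c_out, k)
  block_forward(layer, x, training)
}
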