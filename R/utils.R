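# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG alone.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fan a master seed out to named per-stage seeds (kept below 2^31).
derive_seeds <- function(seed, stages) {
  s <- vapply(seq_along(stages), function(i) {
    (as.double(seed) * 48271 + i * 9973) %% 2147483647
  }, numeric(1))
  setNames(as.integer(s), stages)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Vectorised HSV -> RGB on [0,1] scales (h in degrees).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

# RGB [0,1] -> hue in degrees (for the colour-premise checks).
rgb_to_hue <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- 60 * (((g[hr] - b[hr]) / d[hr]) %% 6)
  h[hg] <- 60 * ((b[hg] - r[hg]) / d[hg] + 2)
  h[hb] <- 60 * ((r[hb] - g[hb]) / d[hb] + 4)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a
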