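# Independent pure-R reference implementation of the CSAE forward pass,
# used as the oracle for the compiled implementation. Mirrors the documented
# weight layout: (27*cin) x cout matrices, spatial offset fastest (dx, dy,
# dz in -1..1) within each input channel; feature maps V x C, x fastest.

ref_shift3 <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  lo <- pmax(1, 1 - off)
  hi <- pmin(d, d - off)
  if (any(hi < lo)) return(out)  # shift larger than the axis: all zeros
  tx <- lo[1]:hi[1]; ty <- lo[2]:hi[2]; tz <- lo[3]:hi[3]
  out[tx, ty, tz] <- a[tx + off[1], ty + off[2], tz + off[3]]
  out
}

ref_conv3 <- function(X, d, W, b) {
  cin <- ncol(X); cout <- length(b)
  out <- matrix(0, prod(d), cout)
  o <- 0
  for (ci in seq_len(cin)) {
    a <- array(X[, ci], d)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      o <- o + 1
      sh <- as.numeric(ref_shift3(a, c(dx, dy, dz)))
      out <- out + sh %o% W[o, ]
    }
  }
  sweep(out, 2, b, "+")
}

ref_lrelu <- function(X, slope) ifelse(X > 0, X, slope * X)

ref_pool2 <- function(X, d) {
  h <- d %/% 2
  out <- matrix(0, prod(h), ncol(X))
  for (c in seq_len(ncol(X))) {
    a <- array(X[, c], d)
    m <- array(-Inf, h)
    for (kz in 0:1) for (ky in 0:1) for (kx in 0:1)
      m <- pmax(m, a[seq(1 + kx, d[1], 2), seq(1 + ky, d[2], 2),
                     seq(1 + kz, d[3], 2), drop = FALSE])
    out[, c] <- as.numeric(m)
  }
  out
}

ref_upsample2 <- function(X, h) {
  d <- 2 * h
  out <- matrix(0, prod(d), ncol(X))
  for (c in seq_len(ncol(X))) {
    a <- array(X[, c], h)
    out[, c] <- as.numeric(a[rep(seq_len(h[1]), each = 2),
                             rep(seq_len(h[2]), each = 2),
                             rep(seq_len(h[3]), each = 2)])
  }
  out
}

# full eval-mode forward: encoder + head + decoder
ref_forward <- function(weights, config, xvec) {
  d <- config$target_extent
  S <- config$n_stages
  slope <- config$leaky_slope
  conv <- weights$conv
  li <- 0
  cur <- matrix(xvec, ncol = 1)
  for (s in seq_len(S)) {
    for (rep_ in 1:2) {
      li <- li + 1
      cur <- ref_lrelu(ref_conv3(cur, d, conv[[li]]$W, conv[[li]]$b), slope)
    }
    if (s < S) { cur <- ref_pool2(cur, d); d <- d %/% 2 }
  }
  z <- as.numeric(cur)
  logits <- as.numeric(t(weights$head$W) %*% z + weights$head$b)
  p <- exp(logits - max(logits)); p <- p / sum(p)
  if (S > 1) for (s in S:2) {
    cur <- ref_upsample2(cur, d); d <- d * 2
    for (rep_ in 1:2) {
      li <- li + 1
      cur <- ref_lrelu(ref_conv3(cur, d, conv[[li]]$W, conv[[li]]$b), slope)
    }
  }
  li <- li + 1
  recon <- ref_conv3(cur, d, conv[[li]]$W, conv[[li]]$b)[, 1]
  list(logits = logits, probs = p, recon = recon)
}

# brute-force pairwise AUROC oracle (ties count 1/2)
ref_auroc <- function(labels, scores, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# tiny deterministic phantom settings for fast tests
tiny_params <- function(...) {
  phantom_params(base_extent = c(32, 32, 20), head_radius_range = c(8, 10),
                 lesion_radius_range = c(3, 4.5), lesion_count_range = c(1, 2),
                 texture_smoothness = 2, ...)
}

tiny_config <- function(extent = c(8, 8, 4), channels = c(2L, 3L),
                        dropout = 0, lambda = 0.9) {
  csae_config(extent, n_stages = length(channels),
              channels_per_stage = channels, dropout_rate = dropout,
              lambda_weight = lambda)
}
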