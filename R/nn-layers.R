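# Layer primitives for the feature-extraction U-Net and the pointwise head.
# Activations are (H, W, C, N) arrays; every layer exposes an `_init` (draws
# from the caller-seeded RNG), `_fw` (returns list(y, cache)) and `_bw`
# (returns list(dx, grad)) so the whole network is trained by explicit
# reverse-mode passes with no autodiff dependency.

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

conv3_init <- function(cin, cout) {
  list(w = he_init(c(3, 3, cin, cout), 9 * cin), b = numeric(cout))
}

conv3_fw <- function(p, x) {
  y <- cpp_conv3_fw(x, p$w, p$b)
  list(y = y, cache = x)
}

conv3_bw <- function(p, cache, dy) {
  g <- cpp_conv3_bw(cache, p$w, dy)
  list(dx = g$dx, grad = list(w = g$dw, b = as.numeric(g$db)))
}

convt2_init <- function(cin, cout) {
  list(w = he_init(c(2, 2, cin, cout), 4 * cin), b = numeric(cout))
}

convt2_fw <- function(p, x) {
  list(y = cpp_convt2_fw(x, p$w, p$b), cache = x)
}

convt2_bw <- function(p, cache, dy) {
  g <- cpp_convt2_bw(cache, p$w, dy)
  list(dx = g$dx, grad = list(w = g$dw, b = as.numeric(g$db)))
}

maxpool_fw <- function(x) {
  r <- cpp_maxpool_fw(x)
  list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}

maxpool_bw <- function(cache, dy) {
  cpp_maxpool_bw(cache$idx, dy, cache$H, cache$W)
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)

relu_bw <- function(cache, dy) dy * cache

sigmoid_fw <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}

sigmoid_bw <- function(cache, dy) dy * cache * (1 - cache)

# GroupNorm with `gsize` channels per group (clamped to C); normalizes over
# (H, W, group) per sample, learnable per-channel gamma/beta.
gn_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

gn_groups <- function(C, gsize = 16) {
  g <- min(gsize, C)
  while (C %% g != 0) g <- g - 1  # keep groups equal-sized
  g
}

gn_fw <- function(p, x, gsize = 16, eps = 1e-5) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  g <- gn_groups(C, gsize)
  m <- H * W * g
  xm <- matrix(x, nrow = m)             # columns: (group, sample)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = m)) * rep(istd, each = m)
  gam <- rep(rep(p$gamma, each = H * W), times = N)
  bet <- rep(rep(p$beta, each = H * W), times = N)
  y <- array(as.numeric(xhat) * gam + bet, d)
  list(y = y, cache = list(xhat = xhat, istd = istd, dims = d, g = g))
}

gn_bw <- function(p, cache, dy) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  g <- cache$g
  m <- H * W * g
  dym <- matrix(dy, nrow = H * W)       # columns: (channel, sample)
  xhatc <- matrix(as.numeric(cache$xhat), nrow = H * W)
  dgamma <- rowSums(matrix(colSums(dym * xhatc), nrow = C))
  dbeta <- rowSums(matrix(colSums(dym), nrow = C))
  gam <- rep(rep(p$gamma, each = H * W), times = N)
  dxhat <- matrix(as.numeric(dy) * gam, nrow = m)
  sum1 <- colSums(dxhat)
  sum2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(sum1 / m, each = m) -
           cache$xhat * rep(sum2 / m, each = m)) *
    rep(cache$istd, each = m)
  list(dx = array(dx, d), grad = list(gamma = dgamma, beta = dbeta))
}

# DoubleConv: (3x3 conv -> GroupNorm -> ReLU) x 2
dc_init <- function(cin, cout) {
  list(c1 = conv3_init(cin, cout), g1 = gn_init(cout),
       c2 = conv3_init(cout, cout), g2 = gn_init(cout))
}

dc_fw <- function(p, x, gsize = 16) {
  a <- conv3_fw(p$c1, x)
  b <- gn_fw(p$g1, a$y, gsize)
  r1 <- relu_fw(b$y)
  a2 <- conv3_fw(p$c2, r1$y)
  b2 <- gn_fw(p$g2, a2$y, gsize)
  r2 <- relu_fw(b2$y)
  list(y = r2$y,
       cache = list(a = a$cache, b = b$cache, r1 = r1$cache,
                    a2 = a2$cache, b2 = b2$cache, r2 = r2$cache))
}

dc_bw <- function(p, cache, dy, gsize = 16) {
  dy <- relu_bw(cache$r2, dy)
  g2 <- gn_bw(p$g2, cache$b2, dy)
  c2 <- conv3_bw(p$c2, cache$a2, g2$dx)
  dy <- relu_bw(cache$r1, c2$dx)
  g1 <- gn_bw(p$g1, cache$b, dy)
  c1 <- conv3_bw(p$c1, cache$a, g1$dx)
  list(dx = c1$dx,
       grad = list(c1 = c1$grad, g1 = g1$grad, c2 = c2$grad, g2 = g2$grad))
}

# Pointwise (1x1) convolution: a per-voxel dense layer. w is (Cin, Cout).
conv1_init <- function(cin, cout) {
  list(w = matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

conv1_fw <- function(p, x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  cout <- ncol(p$w)
  y <- array(0, c(d[1], d[2], cout, d[4]))
  xm <- array(x, c(HW, d[3], d[4]))
  for (n in seq_len(d[4])) {
    y[, , , n] <- xm[, , n] %*% p$w + rep(p$b, each = HW)
  }
  list(y = y, cache = x)
}

conv1_bw <- function(p, cache, dy) {
  d <- dim(cache)
  HW <- d[1] * d[2]
  cout <- ncol(p$w)
  xm <- array(cache, c(HW, d[3], d[4]))
  dym <- array(dy, c(HW, cout, d[4]))
  dw <- matrix(0, d[3], cout)
  db <- numeric(cout)
  dx <- array(0, d)
  dxm <- array(dx, c(HW, d[3], d[4]))
  for (n in seq_len(d[4])) {
    dw <- dw + t(xm[, , n]) %*% dym[, , n]
    db <- db + colSums(dym[, , n])
    dxm[, , n] <- dym[, , n] %*% t(p$w)
  }
  list(dx = array(dxm, d), grad = list(w = dw, b = db))
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_c <- function(dy, c1) {
  d <- dim(dy)
  list(a = dy[, , seq_len(c1), , drop = FALSE],
       b = dy[, , (c1 + 1):d[3], , drop = FALSE])
}

# ---- parameter-tree helpers (flatten for the optimizer) ----

flatten_params <- function(p, prefix = "") {
  if (is.list(p)) {
    out <- list()
    for (nm in names(p)) {
      out <- c(out, flatten_params(p[[nm]], paste0(prefix, nm, ".")))
    }
    out
  } else {
    setNames(list(p), substr(prefix, 1, nchar(prefix) - 1))
  }
}

unflatten_into <- function(p, flat, prefix = "") {
  if (is.list(p)) {
    for (nm in names(p)) {
      p[[nm]] <- unflatten_into(p[[nm]], flat, paste0(prefix, nm, "."))
    }
    p
  } else {
    flat[[substr(prefix, 1, nchar(prefix) - 1)]]
  }
}
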