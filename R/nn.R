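# Minimal convolutional-network machinery for the staining GAN: layer
# forward/backward passes over (H, W, C) arrays, parameter trees, and Adam.
# Convolutions run through the im2col/GEMM kernels in src/; everything else
# is vectorized R. Feature maps are plain numeric arrays, parameters nested
# lists whose leaves are arrays, gradients trees of identical shape.

# ---- parameter trees -------------------------------------------------------

tmap <- function(x, f) if (is.list(x)) lapply(x, tmap, f = f) else f(x)

tmap2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- x
    for (i in seq_along(x)) out[[i]] <- tmap2(x[[i]], y[[i]], f)
    out
  } else f(x, y)
}

tree_zeros_like <- function(p) tmap(p, function(a) a * 0)

adam_init <- function(params) tmap(params, function(a) list(m = a * 0, v = a * 0))

# One Adam update; returns list(params, state). Branching follows the params
# tree, so state leaves (lists with m, v) are handled opaquely.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  rec <- function(p, g, s) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], s[[i]])
        p[[i]] <- r[[1]]; s[[i]] <- r[[2]]
      }
      list(p, s)
    } else {
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      mh <- s$m / (1 - beta1^t)
      vh <- s$v / (1 - beta2^t)
      list(p - lr * mh / (sqrt(vh) + eps), s)
    }
  }
  r <- rec(params, grads, state)
  list(params = r[[1]], state = r[[2]])
}

# ---- parameter init --------------------------------------------------------

init_conv <- function(kh, kw, cin, cout) {
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = rep(0, cout))
}

init_norm <- function(c) list(g = rep(1, c), b = rep(0, c))

init_se <- function(c, reduction = 2) {
  ch <- max(1L, c %/% reduction)
  list(w1 = matrix(stats::rnorm(ch * c, sd = sqrt(2 / c)), ch, c),
       b1 = rep(0, ch),
       w2 = matrix(stats::rnorm(c * ch, sd = sqrt(2 / ch)), c, ch),
       b2 = rep(0, c))
}

# ---- primitive layers ------------------------------------------------------

as_fm <- function(x) if (is.matrix(x)) array(x, c(dim(x), 1L)) else x

# conv forward keeps the unfolded input (im2col matrix) in its cache so the
# backward pass skips re-unfolding
conv_fwd <- function(p, x, stride = 1L, pad = 1L) {
  x <- as_fm(x)
  r <- conv2d_fwd_cpp(x, as.numeric(p$w), dim(p$w), p$b, stride, pad)
  r$xdim <- dim(x)
  r
}

conv_bwd <- function(p, cache, gy, stride = 1L, pad = 1L) {
  r <- conv2d_bwd_cpp(cache$K, as.numeric(p$w), dim(p$w), gy, cache$xdim,
                      stride, pad)
  list(gx = r$gx, grads = list(w = array(r$gw, dim(p$w)), b = as.numeric(r$gb)))
}

# column-broadcast helpers (avoid sweep(): it transposes via aperm)
bc_sub <- function(m, v) m - rep(v, each = nrow(m))
bc_mul <- function(m, v) m * rep(v, each = nrow(m))

inorm_fwd <- function(p, x, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- bc_sub(xm, mu)
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat <- bc_mul(xc, istd)
  y <- bc_sub(bc_mul(xhat, p$g), -p$b)
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, d = d))
}

inorm_bwd <- function(p, cache, gy) {
  d <- cache$d; n <- d[1] * d[2]
  gym <- matrix(gy, n, d[3])
  gg <- colSums(gym * cache$xhat)
  gb <- colSums(gym)
  gxh <- bc_mul(gym, p$g)
  s1 <- colMeans(gxh)
  s2 <- colMeans(gxh * cache$xhat)
  gx <- bc_sub(gxh, s1) - bc_mul(cache$xhat, s2)
  gx <- bc_mul(gx, cache$istd)
  list(gx = array(gx, d), grads = list(g = gg, b = gb))
}

lrelu_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, cache = neg)
}

lrelu_bwd <- function(cache, gy, slope) {
  gy[cache] <- gy[cache] * slope
  gy
}

se_fwd <- function(p, x) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  s <- colMeans(xm)
  z1 <- as.numeric(p$w1 %*% s + p$b1)
  a1 <- pmax(z1, 0)
  z2 <- as.numeric(p$w2 %*% a1 + p$b2)
  g <- 1 / (1 + exp(-z2))
  y <- bc_mul(xm, g)
  list(y = array(y, d), cache = list(x = x, s = s, z1 = z1, a1 = a1, g = g, d = d))
}

se_bwd <- function(p, cache, gy) {
  d <- cache$d; n <- d[1] * d[2]
  gym <- matrix(gy, n, d[3])
  xm <- matrix(cache$x, n, d[3])
  gg <- colSums(gym * xm)
  gx <- bc_mul(gym, cache$g)
  gz2 <- gg * cache$g * (1 - cache$g)
  gw2 <- outer(gz2, cache$a1)
  ga1 <- as.numeric(t(p$w2) %*% gz2)
  gz1 <- ga1 * (cache$z1 > 0)
  gw1 <- outer(gz1, cache$s)
  gs <- as.numeric(t(p$w1) %*% gz1)
  gx <- gx + matrix(rep(gs / n, each = n), n, d[3])
  list(gx = array(gx, d),
       grads = list(w1 = gw1, b1 = gz1, w2 = gw2, b2 = gz2))
}

pool2_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (c in seq_len(d[3])) y[, , c] <- downsample2(x[, , c])
  y
}

pool2_bwd <- function(gy, in_dim) {
  gx <- array(0, in_dim)
  for (c in seq_len(in_dim[3])) {
    g <- gy[, , c] / 4
    gx[, , c] <- g[rep(seq_len(nrow(g)), each = 2), rep(seq_len(ncol(g)), each = 2)]
  }
  gx
}

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

up2_bwd <- function(gy) {
  d <- dim(gy)
  gx <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (c in seq_len(d[3]))
    gx[, , c] <- downsample2(gy[, , c]) * 4
  gx
}

# Batch normalization at batch size 1: per-sample statistics are degenerate
# (they reduce to instance norm and erase absolute intensity), so the layers
# declared as batch-norm normalize with tracked running statistics instead:
# the running mean/var (momentum-updated from the real-data stream) stand in
# for the batch statistics, and the backward pass treats them as constants.
# This keeps the discriminator sensitive to global intensity, which the
# adversarial term needs in order to anchor the generator's output scale.

bn_state_init <- function(c) list(mean = rep(0, c), var = rep(1, c))

bn_fwd <- function(p, x, rs, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  istd <- 1 / sqrt(rs$var + eps)
  xhat <- bc_mul(bc_sub(xm, rs$mean), istd)
  y <- bc_sub(bc_mul(xhat, p$g), -p$b)
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, d = d))
}

bn_update <- function(rs, x, momentum = 0.1) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  v <- colMeans(bc_sub(xm, mu)^2)
  list(mean = (1 - momentum) * rs$mean + momentum * mu,
       var = (1 - momentum) * rs$var + momentum * v)
}

bn_bwd <- function(p, cache, gy) {
  d <- cache$d; n <- d[1] * d[2]
  gym <- matrix(gy, n, d[3])
  gg <- colSums(gym * cache$xhat)
  gb <- colSums(gym)
  gx <- bc_mul(bc_mul(gym, p$g), cache$istd)
  list(gx = array(gx, d), grads = list(g = gg, b = gb))
}

# ---- composite conv block: conv3x3 -> instance norm -> leaky ReLU -> SE ----

block_init <- function(cin, cout, se_reduction = 2) {
  list(conv = init_conv(3, 3, cin, cout), norm = init_norm(cout),
       se = init_se(cout, se_reduction))
}

block_fwd <- function(p, x, slope) {
  x <- as_fm(x)
  cv <- conv_fwd(p$conv, x, 1L, 1L)
  nr <- inorm_fwd(p$norm, cv$out)
  ac <- lrelu_fwd(nr$y, slope)
  se <- se_fwd(p$se, ac$y)
  list(y = se$y, cache = list(conv = cv[c("K", "xdim")], nr = nr$cache,
                              neg = ac$cache, se = se$cache))
}

block_bwd <- function(p, cache, gy, slope) {
  sb <- se_bwd(p$se, cache$se, gy)
  ga <- lrelu_bwd(cache$neg, sb$gx, slope)
  nb <- inorm_bwd(p$norm, cache$nr, ga)
  cb <- conv_bwd(p$conv, cache$conv, nb$gx, 1L, 1L)
  list(gx = cb$gx,
       grads = list(conv = cb$grads, norm = nb$grads, se = sb$grads))
}
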