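# Small shared image helpers.

# Run `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Separable Gaussian blur
#'
#' Replicate-edge padded Gaussian smoothing of a 2-D image (or each channel of
#' a `(y, x, c)` array). Kernel radius is `ceiling(3 * sigma)`.
#'
#' @param img matrix or `(y, x, c)` array.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the input.
#' @return blurred array of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (length(dim(img)) == 3) {
    for (c in seq_len(dim(img)[3])) img[, , c] <- gaussian_blur(img[, , c], sigma)
    return(img)
  }
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_rows <- function(m) {
    n <- nrow(m)
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k)) out <- out + k[o] * m[idx[seq_len(n) + o - 1L], , drop = FALSE]
    out
  }
  t(blur_rows(t(blur_rows(img))))
}

# Luminance reduction of an (y, x, 3) RGB array (ITU-R BT.601 weights).
luminance <- function(rgb) {
  if (is.matrix(rgb)) return(rgb)
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Clamp to a range.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 2x block-mean downsample of a matrix (trailing odd row/col dropped).
downsample2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (m[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
          m[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
          m[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
          m[seq(2, h, 2), seq(2, w, 2), drop = FALSE])
}
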