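# Deterministic overlap tiling of wide-field images and seam-free feathered
# stitching of per-patch predictions. Anchors are 0-based; patch windows are
# half-open [anchor, anchor + patch_size).

#' Tile grid for overlapping patches
#'
#' Anchors sit at multiples of `stride = round(patch_size * (1 -
#' overlap_fraction))` along each axis; if the last stride-aligned patch does
#' not reach the image edge, one extra anchor is placed flush with the edge,
#' so the union of patches always covers the image.
#'
#' @param shape `c(height, width)` of the image.
#' @param patch_size square patch side, pixels.
#' @param overlap_fraction fractional overlap in `[0, 1)`.
#' @return object of class `tile_grid`: list with `shape`, `patch_size`,
#'   `stride`, and `anchors` (`n x 2` matrix of 0-based (y0, x0), row-major).
#' @export
tile_grid <- function(shape, patch_size, overlap_fraction = 0.5) {
  H <- shape[1]; W <- shape[2]
  if (patch_size > H || patch_size > W)
    vs_error("vistain_value_error", "patch larger than image")
  stride <- max(1L, as.integer(round(patch_size * (1 - overlap_fraction))))
  axis_anchors <- function(D) {
    a <- seq(0L, by = stride, length.out = max(1L, (D - patch_size) %/% stride + 1L))
    if (a[length(a)] + patch_size < D) a <- c(a, D - patch_size)
    as.integer(a)
  }
  ay <- axis_anchors(H); ax <- axis_anchors(W)
  anchors <- cbind(y0 = rep(ay, each = length(ax)), x0 = rep(ax, length(ay)))
  structure(list(shape = c(H, W), patch_size = as.integer(patch_size),
                 stride = stride, anchors = anchors),
            class = "tile_grid")
}

#' Crop an image into overlapping patches
#'
#' @param image matrix or `(y, x, c)` array.
#' @inheritParams tile_grid
#' @return list with `patches` (list, row-major over the grid) and `grid`.
#' @export
tile <- function(image, patch_size, overlap_fraction = 0.5) {
  grid <- tile_grid(dim(image)[1:2], patch_size, overlap_fraction)
  P <- grid$patch_size
  patches <- lapply(seq_len(nrow(grid$anchors)), function(a) {
    y0 <- grid$anchors[a, 1]; x0 <- grid$anchors[a, 2]
    if (length(dim(image)) == 3)
      image[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P), , drop = FALSE]
    else image[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P), drop = FALSE]
  })
  list(patches = patches, grid = grid)
}

# 1-D feather profile: triangular weights decaying linearly to the patch
# border, floored at eps so lone-coverage pixels stay defined
feather_profile <- function(P, eps = 1e-6) {
  i <- seq_len(P)
  pmax(pmin(i, P + 1 - i) / ((P + 1) / 2), eps)
}

#' Stitch patches back into a wide-field image
#'
#' Per-pixel weighted average over every patch covering the pixel. With
#' `blend = "feather"` the weights are a separable triangular profile that
#' decays linearly to zero at the patch border (floored at a small epsilon);
#' with `blend = "uniform"` all covering patches weigh equally. Weights are
#' renormalized to sum to one per pixel, so stitching the untouched tiles of
#' an image reproduces it exactly (up to uint8 rounding if re-quantized).
#'
#' @param patches list of patches as produced by [tile()] (possibly
#'   transformed by a model), each `patch_size` square, matrix or `(y, x, c)`.
#' @param grid the [tile_grid()] the patches came from.
#' @param blend `"feather"` or `"uniform"`.
#' @return stitched matrix or array of shape `grid$shape` (times channels).
#' @export
stitch <- function(patches, grid, blend = c("feather", "uniform")) {
  blend <- match.arg(blend)
  n <- nrow(grid$anchors)
  if (length(patches) != n)
    vs_error("vistain_value_error",
             sprintf("expected %d patches for this grid, got %d",
                     n, length(patches)))
  P <- grid$patch_size
  H <- grid$shape[1]; W <- grid$shape[2]
  nch <- if (length(dim(patches[[1]])) == 3) dim(patches[[1]])[3] else 1L
  w1 <- if (blend == "feather") feather_profile(P) else rep(1, P)
  wp <- outer(w1, w1)
  acc <- array(0, c(H, W, nch))
  wacc <- matrix(0, H, W)
  for (a in seq_len(n)) {
    pa <- patches[[a]]
    if (!all(dim(pa)[1:2] == P))
      vs_error("vistain_value_error", "patch size inconsistent with grid")
    ys <- (grid$anchors[a, 1] + 1):(grid$anchors[a, 1] + P)
    xs <- (grid$anchors[a, 2] + 1):(grid$anchors[a, 2] + P)
    for (c in seq_len(nch)) {
      pl <- if (nch > 1 || length(dim(pa)) == 3) pa[, , c] else pa
      acc[ys, xs, c] <- acc[ys, xs, c] + wp * pl
    }
    wacc[ys, xs] <- wacc[ys, xs] + wp
  }
  if (any(wacc == 0))
    vs_error("vistain_value_error", "grid does not cover the image")
  for (c in seq_len(nch)) acc[, , c] <- acc[, , c] / wacc
  if (nch == 1) acc[, , 1] else acc
}
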