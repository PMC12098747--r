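# Affine registration of stained brightfield images onto label-free images by
# minimizing the Pearson-correlation loss, plus curation of training pairs.
#
# Transform convention: a 2x3 matrix [a11 a12 tx; a21 a22 ty] mapping moving
# (x, y) pixel coordinates into fixed coordinates, 0-based pixel centres.

#' Pearson correlation between two images
#'
#' Population-moment form `E[(x - mu_x)(y - mu_y)] / (sigma_x sigma_y)` over
#' the valid (unmasked) pixels; the registration and curation objective.
#'
#' @param x,y numeric arrays of identical shape.
#' @param mask optional logical array of valid pixels.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pcc <- function(x, y, mask = NULL) {
  if (!identical(dim(x), dim(y)))
    vs_error("vistain_value_error", "pcc: images must have identical shape")
  x <- as.numeric(x); y <- as.numeric(y)
  if (!is.null(mask)) {
    m <- as.logical(mask)
    x <- x[m]; y <- y[m]
  }
  if (length(x) < 2)
    vs_error("vistain_value_error", "pcc needs at least 2 valid pixels")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(mean(dx^2)); sy <- sqrt(mean(dy^2))
  if (sx == 0 || sy == 0)
    vs_error("vistain_value_error",
             "pcc undefined: an image has zero variance over the valid pixels")
  clamp(mean(dx * dy) / (sx * sy), -1, 1)
}

#' Pearson correlation loss
#'
#' `1 - pcc(x, y)`: 0 for perfectly positively correlated images, 2 for
#' perfectly anti-correlated ones. Used both as the registration objective
#' and as the reconstruction term of the staining network.
#'
#' @inheritParams pcc
#' @return loss in `[0, 2]`.
#' @export
pcc_loss <- function(x, y, mask = NULL) 1 - pcc(x, y, mask)

#' Construct / manipulate planar affine transforms
#'
#' `affine_transform()` wraps a 2x3 matrix; `affine_identity()`,
#' `affine_from_params()` (rotation in degrees about `center`, isotropic
#' scale, x-shear, translation), `affine_compose()` (apply `b` then `a`),
#' `affine_invert()` and `affine_apply()` (map `n x 2` point sets in (x, y))
#' provide the algebra.
#'
#' @param m 2x3 numeric matrix.
#' @return an `affine_transform`.
#' @export
affine_transform <- function(m) {
  m <- matrix(as.numeric(m), 2, 3)
  if (abs(det(m[, 1:2])) < 1e-12)
    vs_error("vistain_value_error", "singular affine transform")
  structure(m, class = "affine_transform")
}

#' @rdname affine_transform
#' @export
affine_identity <- function() affine_transform(cbind(diag(2), c(0, 0)))

#' @rdname affine_transform
#' @param rotation angle in degrees (counter-clockwise).
#' @param scale isotropic scale factor.
#' @param shear x-shear coefficient.
#' @param dx,dy translation in pixels.
#' @param center length-2 (x, y) centre of rotation/scaling.
#' @export
affine_from_params <- function(rotation = 0, scale = 1, shear = 0,
                               dx = 0, dy = 0, center = c(0, 0)) {
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, shear, 1), 2, 2)
  A <- scale * R %*% S
  t <- c(dx, dy) + center - A %*% center
  affine_transform(cbind(A, t))
}

#' @rdname affine_transform
#' @param a,b transforms to compose.
#' @export
affine_compose <- function(a, b) {
  A <- a[, 1:2] %*% b[, 1:2]
  t <- a[, 1:2] %*% b[, 3] + a[, 3]
  affine_transform(cbind(A, t))
}

#' @rdname affine_transform
#' @param tr transform to invert.
#' @export
affine_invert <- function(tr) {
  Ai <- solve(tr[, 1:2])
  affine_transform(cbind(Ai, -Ai %*% tr[, 3]))
}

#' @rdname affine_transform
#' @param pts `n x 2` matrix of (x, y) coordinates.
#' @export
affine_apply <- function(tr, pts) {
  pts <- matrix(pts, ncol = 2)
  t(tr[, 1:2] %*% t(pts) + tr[, 3])
}

#' Warp an image under an affine transform
#'
#' Resamples `moving` onto the fixed frame by bilinear interpolation:
#' `warped(p) = moving(T^{-1} p)`. The validity mask marks output pixels whose
#' source location lies inside the moving frame; out-of-frame pixels take
#' `fill` and must be excluded from any subsequent correlation.
#'
#' @param moving 2-D matrix or `(y, x, c)` array.
#' @param transform [affine_transform()] mapping moving into fixed coordinates.
#' @param output_shape `c(height, width)` of the fixed frame.
#' @param fill value for out-of-frame pixels.
#' @return list with `warped` and logical `valid`.
#' @export
warp_affine <- function(moving, transform, output_shape = NULL, fill = 0) {
  multi <- length(dim(moving)) == 3
  hs <- if (multi) dim(moving)[1:2] else dim(moving)
  output_shape <- output_shape %||% hs
  H <- output_shape[1]; W <- output_shape[2]
  inv <- affine_invert(transform)
  gx <- rep(seq_len(W) - 1, each = H)
  gy <- rep(seq_len(H) - 1, W)
  src <- affine_apply(inv, cbind(gx, gy))
  sx <- src[, 1]; sy <- src[, 2]
  valid <- sx >= 0 & sx <= hs[2] - 1 & sy >= 0 & sy <= hs[1] - 1
  x0 <- floor(sx); y0 <- floor(sy)
  x0 <- clamp(x0, 0, hs[2] - 2); y0 <- clamp(y0, 0, hs[1] - 2)
  fx <- clamp(sx - x0, 0, 1); fy <- clamp(sy - y0, 0, 1)
  i00 <- (y0 + 1) + hs[1] * x0            # column-major linear index
  sample_plane <- function(m) {
    v <- (1 - fy) * (1 - fx) * m[i00] + fy * (1 - fx) * m[i00 + 1] +
         (1 - fy) * fx * m[i00 + hs[1]] + fy * fx * m[i00 + hs[1] + 1]
    v[!valid] <- fill
    matrix(v, H, W)
  }
  warped <- if (multi) {
    out <- array(0, c(H, W, dim(moving)[3]))
    for (c in seq_len(dim(moving)[3])) out[, , c] <- sample_plane(moving[, , c])
    out
  } else sample_plane(moving)
  list(warped = warped, valid = matrix(valid, H, W))
}

#' Estimate the affine transform minimizing the correlation loss
#'
#' Finds the transform `T` minimizing `pcc_loss(warp(moving, T), fixed)` by
#' multi-resolution direct search: a coarse translation grid scan at the top
#' of a block-mean pyramid seeds Nelder-Mead refinement of the six affine
#' parameters at each level, coarse to fine. RGB inputs are reduced to
#' luminance. If the optimum fails to improve on the identity baseline the
#' result is flagged (`improved = FALSE`) so callers can fall back.
#'
#' @param moving,fixed grayscale matrices (or RGB arrays, reduced internally).
#' @param options list; `levels` (pyramid depth, default 3), `maxit`
#'   (Nelder-Mead iterations per level, default 200), `grid_radius` /
#'   `grid_step` (coarse translation scan, in coarsest-level pixels),
#'   `init` (optional starting [affine_transform()]).
#' @return list with `transform`, `loss`, `identity_loss`, `improved`.
#' @export
estimate_affine <- function(moving, fixed, options = list()) {
  o <- utils::modifyList(list(levels = 3L, maxit = 200L, grid_radius = 10L,
                              grid_step = 2L, init = NULL), options)
  mv <- if (length(dim(moving)) == 3) luminance(moving) else moving
  fx <- if (length(dim(fixed)) == 3) luminance(fixed) else fixed
  pyr_m <- list(mv); pyr_f <- list(fx)
  while (length(pyr_m) < o$levels && min(dim(pyr_m[[length(pyr_m)]])) >= 64) {
    pyr_m[[length(pyr_m) + 1]] <- downsample2(pyr_m[[length(pyr_m)]])
    pyr_f[[length(pyr_f) + 1]] <- downsample2(pyr_f[[length(pyr_f)]])
  }
  nlev <- length(pyr_m)
  # parameters p = (a11-1, a12, a21, a22-1, tx, ty) about the fixed centre,
  # translations expressed at the current level's scale
  level_loss <- function(p, m, f, center) {
    A <- matrix(c(1 + p[1], p[3], p[2], 1 + p[4]), 2, 2)
    if (abs(det(A)) < 1e-6) return(2)
    t <- c(p[5], p[6]) + center - A %*% center
    w <- warp_affine(m, affine_transform(cbind(A, t)), dim(f))
    if (sum(w$valid) < 16) return(2)
    tryCatch(pcc_loss(w$warped, f, w$valid), error = function(e) 2)
  }
  scale0 <- 2^(nlev - 1)
  p <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(o$init)) {
    A <- o$init[, 1:2]
    center <- (rev(dim(fx)) - 1) / 2
    tc <- o$init[, 3] - center + A %*% center
    p <- c(A[1, 1] - 1, A[1, 2], A[2, 1], A[2, 2] - 1, tc[1], tc[2])
  }
  for (lev in seq(nlev, 1)) {
    m <- pyr_m[[lev]]; f <- pyr_f[[lev]]
    center <- (rev(dim(f)) - 1) / 2
    sc <- 2^(lev - 1)
    pl <- p; pl[5:6] <- p[5:6] / sc
    obj <- function(p) level_loss(p, m, f, center)
    if (lev == nlev && is.null(o$init)) {       # coarse translation scan
      g <- seq(-o$grid_radius, o$grid_radius, by = o$grid_step)
      best <- c(0, 0); bl <- Inf
      for (ty in g) for (tx in g) {
        l <- obj(c(0, 0, 0, 0, tx, ty))
        if (l < bl) { bl <- l; best <- c(tx, ty) }
      }
      pl[5:6] <- best
    }
    opt <- stats::optim(pl, obj, method = "Nelder-Mead",
                        control = list(maxit = o$maxit, reltol = 1e-8,
                                       parscale = c(rep(0.02, 4), 1, 1)))
    pl <- opt$par
    p <- pl; p[5:6] <- pl[5:6] * sc
  }
  center <- (rev(dim(fx)) - 1) / 2
  A <- matrix(c(1 + p[1], p[3], p[2], 1 + p[4]), 2, 2)
  t <- c(p[5], p[6]) + center - A %*% center
  tr <- affine_transform(cbind(A, t))
  final_loss <- level_loss(p, mv, fx, center)
  id_loss <- tryCatch(pcc_loss(mv, fx), error = function(e) 2)
  list(transform = tr, loss = final_loss, identity_loss = id_loss,
       improved = final_loss <= id_loss + 1e-9)
}

#' Mean endpoint error between two transforms
#'
#' Average displacement, in pixels, between the two mappings over the image
#' corners and centre; the standard registration-recovery score.
#'
#' @param est,truth [affine_transform()]s.
#' @param shape `c(height, width)` of the image the transforms act on.
#' @return mean endpoint error in pixels.
#' @export
endpoint_error <- function(est, truth, shape) {
  H <- shape[1]; W <- shape[2]
  pts <- rbind(c(0, 0), c(W - 1, 0), c(0, H - 1), c(W - 1, H - 1),
               c((W - 1) / 2, (H - 1) / 2))
  d <- affine_apply(est, pts) - affine_apply(truth, pts)
  mean(sqrt(rowSums(d^2)))
}

#' Curate co-registered training pairs
#'
#' Implements the two-level curation scheme: wide-field pairs (already
#' registered) are cropped into patches; each patch pair is optionally
#' re-registered (second-stage affine refinement); and a patch is kept iff the
#' Pearson correlation between the label-free reference and the (registered)
#' RGB patch, reduced to luminance, is at or above `threshold` — patches
#' strictly below the threshold are excluded. Curation is a pure filter: the
#' kept and excluded sets partition the input and no patch is modified in the
#' report.
#'
#' @param pairs list of wide-field pairs, each a list with elements `ri`
#'   (matrix), `scbf` (matrix, label-free single-channel reference) and `rgb`
#'   (`(y, x, 3)` stained image).
#' @param threshold minimum PCC to keep a patch (default 0.65).
#' @param patch_size square patch side (pixels).
#' @param overlap fractional overlap between patches (0 = disjoint grid).
#' @param refine logical; run the per-patch second-stage registration.
#' @return object of class `paired_patch_set`: list with `patches` (each
#'   holding `ri`, `scbf`, `rgb`, `pcc`, `kept`, anchor) and `report`
#'   (a tibble with one row per patch).
#' @export
curate_pairs <- function(pairs, threshold = 0.65, patch_size = 1024L,
                         overlap = 0, refine = TRUE) {
  patches <- list(); rows <- list(); k <- 0L
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    grid <- tile_grid(dim(pr$scbf), patch_size, overlap)
    for (a in seq_len(nrow(grid$anchors))) {
      y0 <- grid$anchors[a, 1]; x0 <- grid$anchors[a, 2]
      ys <- (y0 + 1):(y0 + patch_size); xs <- (x0 + 1):(x0 + patch_size)
      ri_p <- pr$ri[ys, xs]
      sc_p <- pr$scbf[ys, xs]
      rgb_p <- pr$rgb[ys, xs, , drop = FALSE]
      mask <- NULL
      rgb_reg <- rgb_p
      if (refine) {
        fit <- estimate_affine(luminance(rgb_p), sc_p,
                               options = list(levels = 2L, maxit = 80L,
                                              grid_radius = 4L, grid_step = 2L))
        if (fit$improved) {
          w <- warp_affine(rgb_p, fit$transform, dim(sc_p), fill = 255)
          rgb_reg <- w$warped
          mask <- w$valid
        }
      }
      score <- tryCatch(pcc(sc_p, luminance(rgb_reg), mask),
                        error = function(e) NA_real_)
      kept <- !is.na(score) && score >= threshold
      k <- k + 1L
      patches[[k]] <- list(ri = ri_p, scbf = sc_p, rgb = rgb_reg,
                           pcc = score, kept = kept, pair = pi,
                           y0 = y0, x0 = x0)
      rows[[k]] <- tibble::tibble(pair = pi, patch = a, y0 = y0, x0 = x0,
                                  pcc = score, kept = kept)
    }
  }
  report <- do.call(rbind, rows)
  if (!any(report$kept))
    warning("curation kept no patches: every pair fell below the PCC threshold",
            call. = FALSE)
  message(sprintf("curation: kept %d / %d patches (threshold %.2f)",
                  sum(report$kept), nrow(report), threshold))
  structure(list(patches = patches, report = report, threshold = threshold),
            class = "paired_patch_set")
}

#' @export
print.paired_patch_set <- function(x, ...) {
  cat(sprintf("<paired_patch_set> %d patches, %d kept (PCC >= %.2f)\n",
              nrow(x$report), sum(x$report$kept), x$threshold))
  invisible(x)
}
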