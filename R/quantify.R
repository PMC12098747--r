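# Evaluation and morphometrics: band-limit matching, RGB structural
# similarity, Jaccard overlap, per-slice region metrics, axial profiles of
# lumen geometry, and 3-D nucleus volume/surface.

#' Match the spatial band limits of two images
#'
#' Low-pass filters both images to a common cutoff with a radially symmetric
#' frequency response (flat pass band up to `cutoff_frequency`, Gaussian
#' rolloff beyond), then matches intensity ranges by linearly rescaling the
#' second image to the first's mean and standard deviation. Equalizing
#' resolution this way makes structural-similarity comparisons between
#' instruments with different optical band limits fair.
#'
#' @param image_a,image_b numeric matrices of identical shape.
#' @param cutoff_frequency cutoff in cycles/pixel, in (0, 0.5]; the Nyquist
#'   default leaves the pass band untouched.
#' @param rolloff_sigma Gaussian rolloff width in cycles/pixel.
#' @return list with `a` and `b`, the filtered (and, for `b`, rescaled)
#'   images.
#' @export
bandlimit_match <- function(image_a, image_b, cutoff_frequency = 0.5,
                            rolloff_sigma = 0.05) {
  if (!identical(dim(image_a), dim(image_b)))
    vs_error("vistain_value_error", "images must have identical shape")
  if (cutoff_frequency <= 0)
    vs_error("vistain_value_error", "cutoff frequency must be > 0")
  H <- nrow(image_a); W <- ncol(image_a)
  fftfreq <- function(n) {
    k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
    k / n
  }
  f <- sqrt(outer(fftfreq(H)^2, fftfreq(W)^2, `+`))
  # at (or above) Nyquist the pass band spans the whole representable
  # spectrum, including the diagonal corners beyond the axial Nyquist radius
  Hf <- if (cutoff_frequency >= 0.5) matrix(1, H, W) else
    ifelse(f <= cutoff_frequency, 1,
           exp(-(f - cutoff_frequency)^2 / (2 * rolloff_sigma^2)))
  lp <- function(m) Re(stats::fft(stats::fft(m) * Hf, inverse = TRUE)) / (H * W)
  fa <- lp(image_a); fb <- lp(image_b)
  if (stats::sd(fb) > 0)
    fb <- (fb - mean(fb)) / stats::sd(fb) * stats::sd(fa) + mean(fa)
  list(a = fa, b = fb)
}

# windowed means over all valid window positions (stride-subsampled), via
# summed-area tables; returns a matrix of window means
box_means <- function(m, w, stride) {
  P <- sat(m)
  ys <- seq(1, nrow(m) - w + 1, by = stride)
  xs <- seq(1, ncol(m) - w + 1, by = stride)
  (P[ys + w, xs + w, drop = FALSE] + P[ys, xs, drop = FALSE] -
     P[ys + w, xs, drop = FALSE] - P[ys, xs + w, drop = FALSE]) / (w * w)
}

#' Structural similarity between two RGB images
#'
#' Per channel and per window,
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) / ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 +
#' sigma_y^2 + C2))` with population moments; channel values are averaged
#' first over the three channels, then over windows. The default constants
#' `C1 = 6.5025`, `C2 = 58.5225` presuppose the 8-bit 0-255 intensity scale.
#' `window_size = NULL` evaluates one window spanning the whole image.
#'
#' @param x_rgb,y_rgb `(y, x, 3)` arrays on the 0-255 scale (2-D matrices are
#'   treated as single-channel).
#' @param window_size square window side (default 11) or `NULL`.
#' @param stride window stride in pixels.
#' @param C1,C2 stabilizing constants.
#' @return list with `score` (scalar mean SSIM) and `map` (per-window means
#'   across channels).
#' @export
ssim_rgb <- function(x_rgb, y_rgb, window_size = 11L, stride = 1L,
                     C1 = 6.5025, C2 = 58.5225) {
  if (!identical(dim(x_rgb), dim(y_rgb)))
    vs_error("vistain_value_error", "images must have identical shape")
  x <- as_fm(x_rgb * 1.0); y <- as_fm(y_rgb * 1.0)
  d <- dim(x)
  w <- if (is.null(window_size)) min(d[1], d[2]) else as.integer(window_size)
  if (w > d[1] || w > d[2])
    vs_error("vistain_value_error", "window larger than image")
  acc <- NULL
  for (c in seq_len(d[3])) {
    xc <- x[, , c]; yc <- y[, , c]
    mx <- box_means(xc, w, stride); my <- box_means(yc, w, stride)
    sxx <- box_means(xc * xc, w, stride) - mx^2
    syy <- box_means(yc * yc, w, stride) - my^2
    sxy <- box_means(xc * yc, w, stride) - mx * my
    sm <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
      ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    acc <- if (is.null(acc)) sm / d[3] else acc + sm / d[3]
  }
  list(score = mean(acc), map = acc)
}

#' Jaccard index of two binary masks
#'
#' Intersection over union; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b logical/0-1 arrays of identical shape.
#' @return index in `[0, 1]`.
#' @export
jaccard <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    vs_error("vistain_value_error", "masks must have identical shape")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# marching-squares boundary length of a binary matrix at the 0.5 level
# (midpoint interpolation): the anti-aliased digital perimeter
perimeter_ms <- function(b) {
  s2 <- sqrt(2) / 2
  lens <- c(0, s2, s2, 1, s2, 1, 2 * s2, s2, s2, 2 * s2, 1, s2, 1, s2, s2, 0)
  p <- matrix(0L, nrow(b) + 2, ncol(b) + 2)
  p[2:(nrow(b) + 1), 2:(ncol(b) + 1)] <- b != 0
  n <- nrow(p); m <- ncol(p)
  case <- p[1:(n - 1), 1:(m - 1)] + 2L * p[1:(n - 1), 2:m] +
    4L * p[2:n, 1:(m - 1)] + 8L * p[2:n, 2:m]
  sum(lens[case + 1L])
}

# per-label second-moment shape metrics from pixel coordinates
moments_table <- function(mask2d) {
  idx <- which(mask2d != 0)
  if (!length(idx))
    return(tibble::tibble(label = integer(), area_px = numeric(),
                          centroid_y = numeric(), centroid_x = numeric(),
                          eccentricity = numeric(), major_axis_px = numeric()))
  labs <- mask2d[idx]
  ys <- ((idx - 1) %% nrow(mask2d))          # 0-based
  xs <- ((idx - 1) %/% nrow(mask2d))
  ul <- sort(unique(labs))
  fl <- factor(labs, levels = ul)
  n <- as.numeric(table(fl))
  rs <- function(v) unname(rowsum(v, fl)[, 1])
  cy <- rs(ys) / n; cx <- rs(xs) / n
  Syy <- rs(ys^2) / n - cy^2
  Sxx <- rs(xs^2) / n - cx^2
  Sxy <- rs(ys * xs) / n - cy * cx
  com <- sqrt(((Sxx - Syy) / 2)^2 + Sxy^2)
  l1 <- (Sxx + Syy) / 2 + com
  l2 <- (Sxx + Syy) / 2 - com
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / l1)), 0)
  tibble::tibble(label = as.integer(ul), area_px = n,
                 centroid_y = cy, centroid_x = cx,
                 eccentricity = ecc, major_axis_px = 4 * sqrt(pmax(l1, 0)))
}

#' Per-region 2-D morphometrics
#'
#' One record per label per slice: area (px^2 and um^2), perimeter (um,
#' marching-squares contour at the 0.5 level), eccentricity and major axis
#' length of the ellipse with matching second central moments, and centroid
#' (0-based pixel coordinates). Units convert via `meta$pixel_size_xy`.
#' Regions touching borders are included. An empty mask yields an empty
#' table.
#'
#' @param label_mask integer label matrix or `(z, y, x)` volume.
#' @param meta an [image_meta()] (pixel calibration).
#' @return tibble of class `region_metrics`.
#' @export
region_metrics_2d <- function(label_mask, meta = image_meta(kind = "label")) {
  vol <- normalize_axes(label_mask, "label")
  px <- meta$pixel_size_xy
  out <- list()
  for (z in seq_len(dim(vol)[1])) {
    sl <- vol[z, , ]
    tb <- moments_table(sl)
    if (!nrow(tb)) next
    tb$perimeter_px <- vapply(tb$label, function(l) perimeter_ms(sl == l),
                              numeric(1))
    tb$slice <- z - 1L
    out[[length(out) + 1]] <- tb
  }
  if (!length(out))
    return(tibble::tibble(label = integer(), slice = integer(),
                          area_px = numeric(), area_um2 = numeric(),
                          perimeter_um = numeric(), eccentricity = numeric(),
                          major_axis_um = numeric(), centroid_y = numeric(),
                          centroid_x = numeric()))
  tb <- do.call(rbind, out)
  tibble::tibble(label = tb$label, slice = tb$slice, area_px = tb$area_px,
                 area_um2 = tb$area_px * px^2,
                 perimeter_um = tb$perimeter_px * px,
                 eccentricity = tb$eccentricity,
                 major_axis_um = tb$major_axis_px * px,
                 centroid_y = tb$centroid_y, centroid_x = tb$centroid_x)
}

#' Axial profile of nuclei and lumen morphometrics
#'
#' Per-slice aggregates over a 3-D label volume: labels listed in
#' `target_labels` are treated as lumina (summed area, perimeter and mean
#' major axis per slice); all other labels are treated as nuclei (count,
#' mean area, mean eccentricity per slice). For every target label present in
#' both end slices the bottom/top area ratio is reported — the designed
#' readout of a tapering gland.
#'
#' @param label_volume integer `(z, y, x)` label array.
#' @param target_labels integer labels to profile as lumina (may be `NULL`).
#' @param meta an [image_meta()].
#' @return tibble of class `axial_profile` with attribute `area_ratio`
#'   (named per target label).
#' @export
axial_profile <- function(label_volume, target_labels = NULL,
                          meta = image_meta(kind = "label")) {
  vol <- normalize_axes(label_volume, "label")
  Z <- dim(vol)[1]
  rm2 <- region_metrics_2d(vol, meta)
  for (l in target_labels) {
    if (!any(rm2$label == l))
      vs_error("vistain_value_error",
               sprintf("target label %d absent from all slices", l))
  }
  rows <- lapply(seq_len(Z) - 1L, function(z) {
    sl <- rm2[rm2$slice == z, ]
    nuc <- sl[!(sl$label %in% target_labels), ]
    lum <- sl[sl$label %in% target_labels, ]
    tibble::tibble(
      slice = z,
      n_nuclei = nrow(nuc),
      mean_nucleus_area_um2 = if (nrow(nuc)) mean(nuc$area_um2) else NA_real_,
      mean_nucleus_ecc = if (nrow(nuc)) mean(nuc$eccentricity) else NA_real_,
      lumen_area_um2 = if (nrow(lum)) sum(lum$area_um2) else NA_real_,
      lumen_perimeter_um = if (nrow(lum)) sum(lum$perimeter_um) else NA_real_,
      lumen_major_axis_um = if (nrow(lum)) mean(lum$major_axis_um) else NA_real_)
  })
  prof <- do.call(rbind, rows)
  ratios <- vapply(target_labels %||% integer(0), function(l) {
    top <- rm2$area_um2[rm2$label == l & rm2$slice == 0]
    bot <- rm2$area_um2[rm2$label == l & rm2$slice == Z - 1]
    if (length(top) && length(bot)) bot / top else NA_real_
  }, numeric(1))
  names(ratios) <- as.character(target_labels %||% integer(0))
  structure(prof, area_ratio = ratios,
            class = c("axial_profile", class(prof)))
}

#' @export
autoplot.axial_profile <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = slice, y = lumen_area_um2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "axial slice", y = expression(lumen~area~(mu*m^2)))
}

# replicate-padded 3x3x3 box smoothing of a (z, y, x) volume
box3 <- function(v) {
  d <- dim(v)
  out <- array(0, d)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    out <- out + v[cl(seq_len(d[1]) + dz, d[1]),
                   cl(seq_len(d[2]) + dy, d[2]),
                   cl(seq_len(d[3]) + dx, d[3]), drop = FALSE]
  out / 27
}

#' 3-D nucleus morphometrics
#'
#' Volume is voxel count times the physical voxel volume; surface area is the
#' marching-tetrahedra iso-surface at the 0.5 level of the (lightly smoothed)
#' binary indicator, with anisotropic voxel spacing from the metadata. The
#' 3x3x3 box pre-smoothing suppresses the staircase overestimation a binary
#' iso-surface suffers; set `smooth = FALSE` for the raw binary surface.
#'
#' @param label_volume integer `(z, y, x)` label array.
#' @param meta an [image_meta()] supplying `pixel_size_xy` and `z_step`.
#' @param smooth pre-smooth the indicator before meshing.
#' @return tibble of class `nucleus_metrics`: label, `volume_um3`,
#'   `surface_um2` and bounding box (0-based, inclusive).
#' @export
nucleus_metrics_3d <- function(label_volume, meta = image_meta(kind = "label"),
                               smooth = TRUE) {
  vol <- normalize_axes(label_volume, "label")
  labs <- sort(setdiff(unique(as.integer(vol)), 0L))
  px <- meta$pixel_size_xy; zs <- meta$z_step
  voxel <- px * px * zs
  rows <- lapply(labs, function(l) {
    w <- which(vol == l, arr.ind = TRUE)
    if (!nrow(w)) {
      warning(sprintf("label %d is empty; skipped", l), call. = FALSE)
      return(NULL)
    }
    rng <- apply(w, 2, range)
    # crop with a 2-voxel pad so the iso-surface closes
    lo <- pmax(rng[1, ] - 2L, 1L)
    hi <- pmin(rng[2, ] + 2L, dim(vol))
    sub <- array(0, hi - lo + 1L)
    sub[] <- as.numeric(vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == l)
    # zero-pad one more layer so surfaces close even at volume borders
    padded <- array(0, dim(sub) + 2L)
    padded[2:(dim(sub)[1] + 1), 2:(dim(sub)[2] + 1), 2:(dim(sub)[3] + 1)] <- sub
    if (smooth) padded <- box3(padded)
    surf <- mt_surface_area_cpp(padded, c(zs, px, px), 0.5)
    tibble::tibble(label = l, volume_um3 = nrow(w) * voxel,
                   surface_um2 = surf,
                   z0 = rng[1, 1] - 1L, z1 = rng[2, 1] - 1L,
                   y0 = rng[1, 2] - 1L, y1 = rng[2, 2] - 1L,
                   x0 = rng[1, 3] - 1L, x1 = rng[2, 3] - 1L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- tibble::tibble(label = integer(), volume_um3 = numeric(),
                          surface_um2 = numeric(), z0 = integer(),
                          z1 = integer(), y0 = integer(), y1 = integer(),
                          x0 = integer(), x1 = integer())
  class(out) <- c("nucleus_metrics", class(out))
  out
}

#' Threshold segmenter for phantom nuclei
#'
#' Classifies each pixel of an H&E-like RGB image to the nearest forward-model
#' anchor colour and labels the connected components of the nucleus class.
#' Intended for phantom images only — real-tissue nucleus segmentation is the
#' job of a dedicated model whose masks this package consumes.
#'
#' @param rgb `(y, x, 3)` array on the 0-255 scale.
#' @param model a [color_model()].
#' @param min_size discard components smaller than this many pixels.
#' @return integer label matrix.
#' @export
segment_nuclei <- function(rgb, model = color_model(), min_size = 5L) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  d2 <- prod(dim(rgb)[1:2])
  pix <- matrix(as.numeric(rgb), d2, 3)
  dists <- vapply(1:3, function(k)
    rowSums(sweep(pix, 2, model$colors[k, ])^2), numeric(d2))
  cls <- max.col(-dists)
  nuc <- matrix(cls == 3, dim(rgb)[1], dim(rgb)[2])
  lab <- EBImage::bwlabel(nuc)
  sz <- table(lab[lab > 0])
  drop <- as.integer(names(sz)[sz < min_size])
  lab[lab %in% drop] <- 0
  relab <- matrix(match(lab, sort(unique(as.integer(lab)))) - 1L,
                  nrow(lab), ncol(lab))
  storage.mode(relab) <- "integer"
  relab
}

#' Write / read a metrics table as CSV
#'
#' Plain-text round trip for the morphometrics tables; numeric columns are
#' written at full precision so the round trip is lossless.
#'
#' @param tbl a tibble/data frame.
#' @param path CSV path.
#' @return the path / the restored tibble.
#' @export
write_metrics_csv <- function(tbl, path) {
  df <- as.data.frame(tbl)
  for (c in names(df))
    if (is.numeric(df[[c]]) && !is.integer(df[[c]]))
      df[[c]] <- sprintf("%.17g", df[[c]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
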