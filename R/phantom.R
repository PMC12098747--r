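# Synthetic tissue phantoms. Every downstream stage (focus compositing,
# registration, curation, GAN training, morphometrics) is exercised against
# phantoms with known ground truth: paired (RI, H&E-RGB) slides linked by a
# smooth forward colour model, defocus stacks with a known focus surface,
# pairs with known affine misalignment, and 3-D volumes whose lumen tapers by
# a designed area fraction.

#' Phantom specification
#'
#' Describes one synthetic tissue slide/volume. The background refractive
#' index defaults to 1.495, the mounting-medium value, so "non-sample"
#' masking is meaningful; cytoplasm and nuclei sit above it. `taper_fraction`
#' is the designed relative reduction in lumen cross-sectional area from the
#' top slice to the bottom slice of a volume (0.40 emulates a contracting
#' colonic crypt).
#'
#' @param canvas side of the square canvas, pixels.
#' @param n_nuclei number of elliptical nuclei (>= 0). With 0 nuclei the
#'   phantom degenerates to pure mounting medium.
#' @param nucleus_radius length-2 range of nucleus semi-major axes, pixels.
#' @param nucleus_ecc length-2 range of nucleus eccentricities in `[0, 1)`.
#' @param n_lumen number of lumina (glandular holes).
#' @param lumen_radius lumen radius in pixels (default `canvas / 7`).
#' @param taper_fraction designed top-to-bottom lumen area reduction, `[0, 1)`.
#' @param ri_background,ri_cytoplasm,ri_nucleus compartment refractive indices.
#' @param noise_sd additive Gaussian noise on the returned RI image.
#' @param texture_sd sd of the smooth intra-tissue RI texture.
#' @param seed integer seed; phantoms are pure functions of the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(canvas = 256L, n_nuclei = 25L,
                         nucleus_radius = c(6, 12), nucleus_ecc = c(0, 0.6),
                         n_lumen = 1L, lumen_radius = NULL,
                         taper_fraction = 0.40,
                         ri_background = 1.495, ri_cytoplasm = 1.525,
                         ri_nucleus = 1.560,
                         noise_sd = 0.004, texture_sd = 0.003, seed = 1L) {
  if (taper_fraction < 0 || taper_fraction >= 1)
    vs_error("vistain_value_error", "taper_fraction must lie in [0, 1)")
  if (n_nuclei < 0) vs_error("vistain_value_error", "n_nuclei must be >= 0")
  ris <- c(ri_background, ri_cytoplasm, ri_nucleus)
  if (any(ris < 1.33) || any(ris > 1.60))
    vs_error("vistain_value_error", "RI levels must lie within [1.33, 1.60]")
  structure(list(canvas = as.integer(canvas), n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius, nucleus_ecc = nucleus_ecc,
                 n_lumen = as.integer(n_lumen),
                 lumen_radius = lumen_radius %||% (canvas / 7),
                 taper_fraction = taper_fraction,
                 ri_background = ri_background, ri_cytoplasm = ri_cytoplasm,
                 ri_nucleus = ri_nucleus, noise_sd = noise_sd,
                 texture_sd = texture_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Forward colour model: refractive index to H&E-like RGB
#'
#' A deterministic, continuous (piecewise-linear) map standing in for the
#' chemical stain: background RI maps to white, cytoplasm-level RI to an
#' eosin-like pink, nucleus-level RI to a hematoxylin-like purple. The three
#' compartment colours are mutually separated by more than 80 RGB units, so
#' recovering the map from paired data is well posed.
#'
#' @param ri_levels numeric anchors (background, cytoplasm, nucleus).
#' @param colors 3x3 integer matrix of anchor RGB rows.
#' @return object of class `color_model`.
#' @export
color_model <- function(ri_levels = c(1.495, 1.525, 1.560),
                        colors = rbind(c(255, 255, 255),
                                       c(236, 144, 180),
                                       c(88, 60, 150))) {
  stopifnot(length(ri_levels) == 3, all(dim(colors) == c(3, 3)))
  d <- as.matrix(stats::dist(colors))
  if (min(d[upper.tri(d)]) < 80)
    vs_error("vistain_value_error",
             "anchor colours closer than 80 RGB units; mapping ill-posed")
  structure(list(ri = ri_levels, colors = colors), class = "color_model")
}

#' Apply the forward colour model
#'
#' @param ri numeric vector/matrix/array of refractive indices.
#' @param model a [color_model()].
#' @return integer RGB array with one extra trailing axis of length 3.
#' @export
ri_to_rgb <- function(ri, model = color_model()) {
  d <- dim(ri) %||% length(ri)
  out <- array(0L, c(d, 3))
  flat <- as.numeric(ri)
  ch <- vapply(1:3, function(i)
    stats::approx(model$ri, model$colors[, i], xout = flat, rule = 2)$y,
    numeric(length(flat)))
  out[] <- as.integer(round(clamp(ch, 0, 255)))
  out
}

# rasterize a rotated ellipse; returns logical matrix (y, x), 1-based centres
ellipse_mask <- function(n, cy, cx, a, b, theta) {
  Y <- row(matrix(0, n, n)) - cy
  X <- col(matrix(0, n, n)) - cx
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# smooth wobbly cytoplasm region covering most of the canvas
cytoplasm_mask <- function(n) {
  cy <- (n + 1) / 2; cx <- (n + 1) / 2
  Y <- (row(matrix(0, n, n)) - cy) / (0.44 * n)
  X <- (col(matrix(0, n, n)) - cx) / (0.40 * n)
  wob <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), n / 16)
  wob <- 0.25 * wob / max(stats::sd(wob), 1e-12)
  sqrt(X^2 + Y^2) + wob <= 1
}

#' Generate one paired (RI, H&E) phantom slide
#'
#' The returned RGB image is the forward colour model applied to the
#' noise-free compartment RI map (compartments plus smooth texture); additive
#' Gaussian noise is applied only to the returned RI image. Nuclei are
#' non-overlapping rotated ellipses with unique labels.
#'
#' @param spec a [phantom_spec()].
#' @param model a [color_model()].
#' @return list with `ri` (matrix), `rgb` (`(y, x, 3)` integer array),
#'   `mask` (integer label matrix) and `spec`.
#' @export
make_paired_slide <- function(spec, model = color_model()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$canvas
  with_seed(spec$seed, {
    mask <- matrix(0L, n, n)
    if (spec$n_nuclei == 0) {
      ri_clean <- matrix(spec$ri_background, n, n)
    } else {
      cyto <- cytoplasm_mask(n)
      lumen <- matrix(FALSE, n, n)
      if (spec$n_lumen > 0) {
        for (l in seq_len(spec$n_lumen)) {
          ang <- 2 * pi * (l - 1) / spec$n_lumen
          off <- if (spec$n_lumen == 1) 0 else 0.18 * n
          lc <- (n + 1) / 2 + off * c(sin(ang), cos(ang))
          lumen <- lumen | ellipse_mask(n, lc[1], lc[2],
                                        spec$lumen_radius, spec$lumen_radius, 0)
        }
        lumen <- lumen & cyto
      }
      amax <- max(spec$nucleus_radius)
      for (i in seq_len(spec$n_nuclei)) {
        placed <- FALSE
        for (try in seq_len(300)) {
          cy <- stats::runif(1, amax + 2, n - amax - 1)
          cx <- stats::runif(1, amax + 2, n - amax - 1)
          a <- stats::runif(1, spec$nucleus_radius[1], spec$nucleus_radius[2])
          ecc <- stats::runif(1, spec$nucleus_ecc[1], spec$nucleus_ecc[2])
          b <- a * sqrt(1 - ecc^2)
          th <- stats::runif(1, 0, pi)
          cand <- ellipse_mask(n, cy, cx, a, b, th)
          if (!any(cand & !cyto) && !any(cand & lumen) &&
              !any(mask[cand] != 0L)) {
            mask[cand] <- i
            placed <- TRUE
            break
          }
        }
        if (!placed)
          vs_error("vistain_value_error",
                   sprintf("canvas too small: could not place nucleus %d of %d",
                           i, spec$n_nuclei))
      }
      ri_clean <- matrix(spec$ri_background, n, n)
      ri_clean[cyto] <- spec$ri_cytoplasm
      ri_clean[lumen] <- spec$ri_background
      ri_clean[mask != 0L] <- spec$ri_nucleus
      if (spec$texture_sd > 0) {
        tex <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), 2)
        tex <- tex / max(stats::sd(tex), 1e-12) * spec$texture_sd
        tissue <- cyto & !lumen
        ri_clean[tissue] <- ri_clean[tissue] + tex[tissue]
      }
    }
    rgb <- ri_to_rgb(ri_clean, model)
    ri <- ri_clean
    if (spec$noise_sd > 0) ri <- ri + stats::rnorm(n * n, sd = spec$noise_sd)
    list(ri = ri, rgb = rgb, mask = mask, spec = spec)
  })
}

#' Generate a 3-D phantom volume with a tapering lumen
#'
#' The lumen is a vertical tube whose cross-sectional area decreases linearly
#' from the top slice to the bottom slice by `spec$taper_fraction` (radius
#' `r(z) = r0 * sqrt(1 - taper * z / (Z - 1))`), so the designed bottom/top
#' area ratio is `1 - taper_fraction`. Nuclei are ellipsoids spanning several
#' slices at distinct axial offsets.
#'
#' @param spec a [phantom_spec()].
#' @param n_slices number of axial slices (>= 2).
#' @return list with `ri` (`(z, y, x)`), `nuclei` and `lumen` (integer label
#'   volumes), `lumen_radii` (designed per-slice radii) and `spec`.
#' @export
make_volume <- function(spec, n_slices) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_slices < 2) vs_error("vistain_value_error", "n_slices must be >= 2")
  n <- spec$canvas; Z <- as.integer(n_slices)
  r0 <- spec$lumen_radius
  zfrac <- (seq_len(Z) - 1) / (Z - 1)
  radii <- r0 * sqrt(1 - spec$taper_fraction * zfrac)
  if (spec$n_lumen > 0 && min(radii) < 1.5)
    vs_error("vistain_value_error",
             "taper produces a sub-voxel lumen; enlarge lumen_radius")
  with_seed(spec$seed, {
    cyto <- cytoplasm_mask(n)
    lumen <- array(0L, c(Z, n, n))
    lc <- c((n + 1) / 2, (n + 1) / 2)
    if (spec$n_lumen > 0) {
      for (z in seq_len(Z)) {
        m <- ellipse_mask(n, lc[1], lc[2], radii[z], radii[z], 0)
        lumen[z, , ][m] <- 1L
      }
    }
    nuclei <- array(0L, c(Z, n, n))
    amax <- max(spec$nucleus_radius)
    keepout <- r0 + amax + 3
    zc_base <- seq(2, Z - 1, length.out = max(spec$n_nuclei, 1))
    for (i in seq_len(spec$n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(300)) {
        zc <- zc_base[i] + stats::runif(1, -0.5, 0.5)
        cy <- stats::runif(1, amax + 2, n - amax - 1)
        cx <- stats::runif(1, amax + 2, n - amax - 1)
        if (spec$n_lumen > 0 &&
            sqrt((cy - lc[1])^2 + (cx - lc[2])^2) < keepout) next
        a <- stats::runif(1, spec$nucleus_radius[1], spec$nucleus_radius[2])
        ecc <- stats::runif(1, spec$nucleus_ecc[1], spec$nucleus_ecc[2])
        b <- a * sqrt(1 - ecc^2)
        az <- stats::runif(1, 1.5, min(3, (Z - 1) / 2))
        th <- stats::runif(1, 0, pi)
        zs <- which(abs(seq_len(Z) - zc) <= az)
        if (!length(zs)) next
        ok <- TRUE
        sl <- vector("list", length(zs))
        for (k in seq_along(zs)) {
          s <- sqrt(max(0, 1 - ((zs[k] - zc) / az)^2))
          if (s * b < 0.7) { sl[[k]] <- matrix(FALSE, n, n); next }
          m <- ellipse_mask(n, cy, cx, a * s, b * s, th)
          if (any(m & !cyto) || any(nuclei[zs[k], , ][m] != 0L)) { ok <- FALSE; break }
          sl[[k]] <- m
        }
        if (!ok) next
        for (k in seq_along(zs)) nuclei[zs[k], , ][sl[[k]]] <- i
        placed <- TRUE
        break
      }
      if (!placed)
        vs_error("vistain_value_error",
                 sprintf("canvas too small: could not place nucleus %d", i))
    }
    ri <- array(spec$ri_background, c(Z, n, n))
    for (z in seq_len(Z)) {
      sl <- matrix(spec$ri_background, n, n)
      sl[cyto] <- spec$ri_cytoplasm
      sl[lumen[z, , ] != 0L] <- spec$ri_background
      sl[nuclei[z, , ] != 0L] <- spec$ri_nucleus
      if (spec$texture_sd > 0) {
        tex <- gaussian_blur(matrix(stats::rnorm(n * n), n, n), 2)
        tex <- tex / max(stats::sd(tex), 1e-12) * spec$texture_sd
        tissue <- cyto & lumen[z, , ] == 0L
        sl[tissue] <- sl[tissue] + tex[tissue]
      }
      if (spec$noise_sd > 0) sl <- sl + stats::rnorm(n * n, sd = spec$noise_sd)
      ri[z, , ] <- sl
    }
    list(ri = ri, nuclei = nuclei, lumen = lumen, lumen_radii = radii,
         spec = spec)
  })
}

#' Synthesize a defocus stack with a known focus surface
#'
#' Slice `z` is the sharp image blurred with a Gaussian kernel of width
#' `blur_rate * |z - z*(y, x)|`, where `z*` is the per-pixel focus surface
#' (0-based slice indices). At `z = z*(y, x)` the local patch is unblurred.
#'
#' @param sharp sharp 2-D image (matrix).
#' @param focus_surface scalar or matrix of best-focus slice indices.
#' @param blur_rate kernel-width growth per slice of defocus (> 0).
#' @param n_slices number of slices; default `floor(max(focus_surface)) + 1`.
#' @return `(z, y, x)` array.
#' @export
make_defocus_stack <- function(sharp, focus_surface, blur_rate,
                               n_slices = NULL) {
  stopifnot(is.matrix(sharp))
  if (blur_rate <= 0) vs_error("vistain_value_error", "blur_rate must be > 0")
  if (length(focus_surface) == 1)
    focus_surface <- matrix(focus_surface, nrow(sharp), ncol(sharp))
  stopifnot(all(dim(focus_surface) == dim(sharp)))
  n_slices <- n_slices %||% (floor(max(focus_surface)) + 1L)
  if (min(focus_surface) < 0 || max(focus_surface) > n_slices - 1)
    vs_error("vistain_value_error", "focus_surface outside stack range")
  stack <- array(0, c(n_slices, nrow(sharp), ncol(sharp)))
  for (z in seq_len(n_slices)) {
    sig <- round(blur_rate * abs((z - 1) - focus_surface), 4)
    us <- sort(unique(as.numeric(sig)))
    if (length(us) > 12) {          # cap distinct kernels; quantize widths
      lev <- seq(min(us), max(us), length.out = 12)
      sig[] <- lev[max.col(-abs(outer(as.numeric(sig), lev, "-")))]
      us <- sort(unique(as.numeric(sig)))
    }
    sl <- sharp
    for (s in us) {
      if (s <= 0) next
      b <- gaussian_blur(sharp, s)
      sel <- abs(sig - s) < 1e-9
      sl[sel] <- b[sel]
    }
    stack[z, , ] <- sl
  }
  stack
}

#' Construct a misaligned image pair with known ground-truth transform
#'
#' `moving` is the input image warped by the inverse of the returned
#' transform (plus optional noise), so `warp_affine(moving, true_transform)`
#' recovers the fixed image; the returned transform is the registration
#' ground truth.
#'
#' @param image fixed 2-D image.
#' @param affine_params named list/vector with `rotation` (degrees), `scale`,
#'   `shear`, `dx`, `dy` (pixels).
#' @param noise_sd additive Gaussian noise applied to the moving image.
#' @return list with `fixed`, `moving`, `true_transform`.
#' @export
make_misaligned_pair <- function(image, affine_params, noise_sd = 0) {
  p <- as.list(affine_params)
  tr <- affine_from_params(rotation = p$rotation %||% 0,
                           scale = p$scale %||% 1,
                           shear = p$shear %||% 0,
                           dx = p$dx %||% 0, dy = p$dy %||% 0,
                           center = (rev(dim(image)) - 1) / 2)
  w <- warp_affine(image, affine_invert(tr), dim(image), fill = mean(image))
  if (mean(w$valid) < 0.5)
    vs_error("vistain_value_error",
             "transform pushes more than half of the content out of frame")
  moving <- w$warped
  if (noise_sd > 0)
    moving <- moving + stats::rnorm(length(moving), sd = noise_sd)
  list(fixed = image, moving = moving, true_transform = tr)
}

#' Smooth random texture
#'
#' Band-limited Gaussian random field used as registration test content.
#'
#' @param size side length in pixels.
#' @param smoothness Gaussian correlation length in pixels.
#' @param seed integer seed.
#' @return matrix with values in `[0, 1]`.
#' @export
make_texture <- function(size, smoothness = 6, seed = 1L) {
  with_seed(seed, {
    t <- gaussian_blur(matrix(stats::rnorm(size * size), size, size), smoothness)
    t <- (t - mean(t)) / max(stats::sd(t), 1e-12)
    clamp(0.5 + 0.15 * t, 0, 1)
  })
}

#' Materialize a phantom dataset on disk
#'
#' Writes train/val/test splits of paired slides (RI, RGB, nucleus labels as
#' TIFF) plus a JSON manifest; this is the `simulate` CLI subcommand's
#' workhorse. Item seeds are drawn once from `seed`, so the dataset is a pure
#' function of `(spec, counts, seed)`.
#'
#' @param dir output directory (created if needed).
#' @param spec template [phantom_spec()]; per-item seeds are replaced.
#' @param n_train,n_val,n_test split sizes.
#' @param seed master seed.
#' @param meta [image_meta()] template for pixel calibration.
#' @return path to the manifest JSON, invisibly.
#' @export
make_phantom_dataset <- function(dir, spec = phantom_spec(), n_train = 20,
                                 n_val = 5, n_test = 5, seed = 1L,
                                 meta = image_meta()) {
  counts <- c(train = n_train, val = n_val, test = n_test)
  total <- sum(counts)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  items <- list(); k <- 0L
  for (split in names(counts)) {
    sdir <- file.path(dir, split)
    dir.create(sdir, showWarnings = FALSE)
    for (i in seq_len(counts[[split]])) {
      k <- k + 1L
      sp <- spec; sp$seed <- seeds[k]
      slide <- make_paired_slide(sp)
      base <- file.path(sdir, sprintf("%s_%03d", split, i))
      write_image(slide$ri, paste0(base, "_ri.tif"),
                  image_meta(meta$pixel_size_xy, meta$z_step, "ri"))
      write_image(slide$rgb, paste0(base, "_rgb.tif"),
                  image_meta(meta$pixel_size_xy, meta$z_step, "rgb"))
      write_image(slide$mask, paste0(base, "_mask.tif"),
                  image_meta(meta$pixel_size_xy, meta$z_step, "label"))
      items[[k]] <- list(split = split, index = i, seed = seeds[k],
                         ri = paste0(base, "_ri.tif"),
                         rgb = paste0(base, "_rgb.tif"),
                         mask = paste0(base, "_mask.tif"))
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, canvas = spec$canvas,
                            counts = as.list(counts), items = items),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
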