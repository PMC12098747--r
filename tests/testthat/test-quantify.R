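test_that("SSIM matches self-comparison, constant closed form and a loop oracle", {
  set.seed(6)
  x <- array(sample(0:255, 24 * 24 * 3, TRUE), c(24, 24, 3))
  expect_equal(ssim_rgb(x, x)$score, 1, tolerance = 1e-12)
  # constant images: contrast/structure terms cancel, luminance term remains
  mx <- c(100, 150, 200); my <- c(120, 150, 180)
  a <- array(rep(mx, each = 64), c(8, 8, 3))
  b <- array(rep(my, each = 64), c(8, 8, 3))
  closed <- mean((2 * mx * my + 6.5025) / (mx^2 + my^2 + 6.5025))
  expect_equal(ssim_rgb(a, b, window_size = 5)$score, closed, tolerance = 1e-12)
  # explicit-loop evaluation with C1 = 6.5025, C2 = 58.5225
  y <- array(sample(0:255, 24 * 24 * 3, TRUE), c(24, 24, 3))
  w <- 8L; st <- 4L
  pos <- seq(1, 24 - w + 1, by = st)
  oracle <- 0; nw <- 0
  for (i in pos) for (j in pos) {
    acc <- 0
    for (c in 1:3) {
      xs <- as.numeric(x[i:(i + w - 1), j:(j + w - 1), c])
      ys <- as.numeric(y[i:(i + w - 1), j:(j + w - 1), c])
      mxx <- mean(xs); myy <- mean(ys)
      vx <- mean((xs - mxx)^2); vy <- mean((ys - myy)^2)
      cxy <- mean((xs - mxx) * (ys - myy))
      acc <- acc + (2 * mxx * myy + 6.5025) * (2 * cxy + 58.5225) /
        ((mxx^2 + myy^2 + 6.5025) * (vx + vy + 58.5225)) / 3
    }
    oracle <- oracle + acc; nw <- nw + 1
  }
  r <- ssim_rgb(x, y, window_size = w, stride = st)
  expect_equal(r$score, oracle / nw, tolerance = 1e-9)
  # symmetry
  expect_equal(ssim_rgb(y, x, window_size = w, stride = st)$score, r$score,
               tolerance = 1e-12)
  expect_error(ssim_rgb(x, y[1:10, 1:10, ]), class = "vistain_value_error")
})

test_that("jaccard satisfies its set identities", {
  a <- matrix(FALSE, 10, 10); a[2:7, 2:7] <- TRUE
  expect_equal(jaccard(a, a), 1)
  b <- matrix(FALSE, 10, 10); b[9:10, 9:10] <- TRUE
  expect_equal(jaccard(a, b), 0)
  h <- matrix(FALSE, 10, 10); h[2:7, 2:4] <- TRUE   # half of a, nested
  expect_equal(jaccard(a, h), 0.5)
  expect_equal(jaccard(a & FALSE, b & FALSE), 1)    # both empty
  expect_error(jaccard(a, b[1:5, ]), class = "vistain_value_error")
})

test_that("region metrics recover closed-form ellipse shape parameters", {
  n <- 128
  mask <- matrix(0L, n, n)
  cy <- 64.5; cx <- 64.5
  Y <- row(mask) - cy; X <- col(mask) - cx
  mask[(X / 50)^2 + (Y / 30)^2 <= 1] <- 1L
  tb <- region_metrics_2d(mask, image_meta(pixel_size_xy = 1, kind = "label"))
  expect_equal(nrow(tb), 1)
  expect_equal(tb$eccentricity, 0.8, tolerance = 0.02)
  expect_equal(tb$area_px, pi * 50 * 30, tolerance = 0.02 * pi * 50 * 30)
  expect_equal(tb$major_axis_um, 100, tolerance = 1)
  expect_equal(tb$centroid_x, cx - 1, tolerance = 0.1)   # 0-based centroid
  # single-pixel region
  m1 <- matrix(0L, 5, 5); m1[3, 3] <- 1L
  t1 <- region_metrics_2d(m1, image_meta(pixel_size_xy = 1, kind = "label"))
  expect_equal(t1$area_px, 1)
  expect_equal(t1$eccentricity, 0)
  # random blob vs a brute-force moments oracle
  set.seed(8)
  blob <- matrix(0L, 40, 40)
  blob[(row(blob) - 20)^2 + (col(blob) - 17)^2 <= 81] <- 1L
  blob[sample(which(blob == 1L), 30)] <- 0L
  tb2 <- region_metrics_2d(blob, image_meta(pixel_size_xy = 1, kind = "label"))
  idx <- which(blob == 1L)
  ys <- (idx - 1) %% 40; xs <- (idx - 1) %/% 40
  muyy <- mean((ys - mean(ys))^2); muxx <- mean((xs - mean(xs))^2)
  muxy <- mean((ys - mean(ys)) * (xs - mean(xs)))
  l1 <- (muxx + muyy) / 2 + sqrt(((muxx - muyy) / 2)^2 + muxy^2)
  l2 <- (muxx + muyy) / 2 - sqrt(((muxx - muyy) / 2)^2 + muxy^2)
  expect_equal(tb2$eccentricity, sqrt(1 - l2 / l1), tolerance = 1e-9)
  expect_equal(tb2$major_axis_um, 4 * sqrt(l1), tolerance = 1e-9)
  expect_equal(tb2$area_px, length(idx))
  # empty mask: empty table, not an error
  expect_equal(nrow(region_metrics_2d(matrix(0L, 8, 8))), 0)
})

test_that("band-limit matching passes low frequencies and matches an FFT oracle", {
  set.seed(9)
  a <- matrix(rnorm(32 * 32), 32)
  b <- matrix(rnorm(32 * 32), 32)
  # Nyquist cutoff: pass band covers everything; a unchanged, b rescaled
  r <- bandlimit_match(a, b, cutoff_frequency = 0.5)
  expect_equal(r$a, a, tolerance = 1e-9)
  expect_equal(mean(r$b), mean(a), tolerance = 1e-9)
  expect_equal(sd(r$b), sd(a), tolerance = 1e-9)
  # constant images are fixed points (DC only)
  cst <- matrix(3.2, 16, 16)
  expect_equal(bandlimit_match(cst, cst, 0.2)$a, cst, tolerance = 1e-12)
  # impulse response equals the kernel computed by a direct FFT oracle
  imp <- matrix(0, 16, 16); imp[1, 1] <- 1
  rimp <- bandlimit_match(imp, imp, cutoff_frequency = 0.15,
                          rolloff_sigma = 0.05)
  fftfreq <- function(n) c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
  f <- sqrt(outer(fftfreq(16)^2, fftfreq(16)^2, `+`))
  H <- ifelse(f <= 0.15, 1, exp(-(f - 0.15)^2 / (2 * 0.05^2)))
  kernel <- Re(fft(H, inverse = TRUE)) / 256
  expect_equal(rimp$a, kernel, tolerance = 1e-9)
  expect_error(bandlimit_match(a, b, 0), class = "vistain_value_error")
})

test_that("axial profiles track designed lumen geometry and nucleus placement", {
  spec <- phantom_spec(canvas = 96, n_nuclei = 5, nucleus_radius = c(3, 6),
                       lumen_radius = 14, taper_fraction = 0.4, seed = 5)
  v <- make_volume(spec, n_slices = 9)
  lab <- v$nuclei
  lab[v$lumen != 0L] <- 1000L
  prof <- axial_profile(lab, target_labels = 1000L,
                        meta = image_meta(pixel_size_xy = 1, kind = "label"))
  ratio <- attr(prof, "area_ratio")[["1000"]]
  expect_equal(ratio, 0.6, tolerance = 0.03)
  expect_lt(cor(prof$slice, prof$lumen_area_um2), -0.99)
  # per-slice nucleus counts match the constructed volume
  truth <- apply(v$nuclei, 1, function(m) length(setdiff(unique(as.integer(m)), 0L)))
  expect_equal(prof$n_nuclei, truth)
  expect_error(axial_profile(lab, target_labels = 77L),
               class = "vistain_value_error")
  # constant-radius tube: flat profile
  v0 <- make_volume(phantom_spec(canvas = 64, n_nuclei = 0, lumen_radius = 10,
                                 taper_fraction = 0, seed = 2), 5)
  p0 <- axial_profile(v0$lumen, target_labels = 1L,
                      meta = image_meta(pixel_size_xy = 1, kind = "label"))
  expect_equal(max(p0$lumen_area_um2) / min(p0$lumen_area_um2), 1,
               tolerance = 1e-12)
})

test_that("3-D nucleus metrics match sphere closed forms and scale with voxels", {
  n <- 25
  vol <- array(0L, c(n, n, n))
  ctr <- 13
  for (z in 1:n) {
    r2 <- 100 - (z - ctr)^2
    if (r2 <= 0) next
    sl <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2 <= r2
    vol[z, , ][sl] <- 1L
  }
  m <- nucleus_metrics_3d(vol, image_meta(pixel_size_xy = 1, z_step = 1,
                                          kind = "label"))
  expect_equal(m$volume_um3, 4 / 3 * pi * 1000,
               tolerance = 0.05 * 4 / 3 * pi * 1000)
  expect_equal(m$surface_um2, 4 * pi * 100, tolerance = 0.10 * 4 * pi * 100)
  # anisotropic z-step doubles the volume exactly
  m2 <- nucleus_metrics_3d(vol, image_meta(pixel_size_xy = 1, z_step = 2,
                                           kind = "label"))
  expect_equal(m2$volume_um3, 2 * m$volume_um3, tolerance = 1e-12)
})

test_that("phantom segmentation recovers nucleus masks from rendered colour", {
  sl <- make_paired_slide(tiny_spec(seed = 31))
  seg <- segment_nuclei(sl$rgb)
  expect_gte(jaccard(seg > 0, sl$mask > 0), 0.9)
  n_true <- length(setdiff(unique(as.integer(sl$mask)), 0L))
  expect_equal(length(setdiff(unique(as.integer(seg)), 0L)), n_true)
})

test_that("metric tables survive a CSV round trip losslessly", {
  sl <- make_paired_slide(tiny_spec(seed = 41))
  tb <- region_metrics_2d(sl$mask, image_meta(kind = "label"))
  d <- withr::local_tempdir()
  p <- file.path(d, "metrics.csv")
  write_metrics_csv(tb, p)
  back <- read_metrics_csv(p)
  expect_equal(as.data.frame(back), as.data.frame(tb), tolerance = 1e-15)
})
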