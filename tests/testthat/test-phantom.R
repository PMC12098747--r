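test_that("zero-nucleus phantom degenerates to pure mounting medium", {
  sl <- make_paired_slide(phantom_spec(canvas = 32, n_nuclei = 0,
                                       noise_sd = 0, seed = 3))
  expect_true(all(sl$ri == 1.495))
  expect_true(all(sl$rgb == 255L))
  expect_true(all(sl$mask == 0L))
})

test_that("phantom slides carry exactly the requested nuclei, deterministically", {
  spec <- phantom_spec(canvas = 256, n_nuclei = 25, seed = 11)
  sl <- make_paired_slide(spec)
  expect_setequal(setdiff(unique(as.integer(sl$mask)), 0L), 1:25)
  sl2 <- make_paired_slide(spec)
  expect_identical(sl$ri, sl2$ri)
  expect_identical(sl$rgb, sl2$rgb)
  expect_identical(sl$mask, sl2$mask)
  # a different seed produces different content
  sl3 <- make_paired_slide(phantom_spec(canvas = 256, n_nuclei = 25, seed = 12))
  expect_false(identical(sl$ri, sl3$ri))
})

test_that("forward colour model is continuous, deterministic and well-separated", {
  m <- color_model()
  d <- as.matrix(dist(m$colors))
  expect_gt(min(d[upper.tri(d)]), 80)
  ri <- seq(1.45, 1.60, by = 1e-4)
  rgb <- ri_to_rgb(ri, m)
  # continuity: neighbouring RI values map to neighbouring colours
  expect_lt(max(abs(diff(rgb[, 1]))), 3)
  expect_identical(rgb, ri_to_rgb(ri, m))
  expect_error(color_model(colors = rbind(c(255, 255, 255), c(250, 250, 250),
                                          c(0, 0, 0))),
               class = "vistain_value_error")
})

test_that("volume lumen tapers by design and honours degenerate cases", {
  spec <- phantom_spec(canvas = 96, n_nuclei = 5, nucleus_radius = c(3, 6),
                       lumen_radius = 14, taper_fraction = 0.4, seed = 5)
  v <- make_volume(spec, n_slices = 9)
  expect_equal((v$lumen_radii[9] / v$lumen_radii[1])^2, 0.6, tolerance = 1e-12)
  areas <- apply(v$lumen, 1, function(m) sum(m != 0))
  expect_true(all(diff(areas) < 0))
  # taper 0: constant designed area, near-constant voxel area
  v0 <- make_volume(phantom_spec(canvas = 64, n_nuclei = 0, lumen_radius = 10,
                                 taper_fraction = 0, seed = 5), n_slices = 5)
  a0 <- apply(v0$lumen, 1, function(m) sum(m != 0))
  expect_true(all(a0 == a0[1]))
  expect_error(make_volume(phantom_spec(canvas = 64, lumen_radius = 1.6,
                                        taper_fraction = 0.5, seed = 1), 5),
               class = "vistain_value_error")
  expect_error(make_volume(spec, n_slices = 1), class = "vistain_value_error")
})

test_that("defocus stacks are sharp exactly on the focus surface", {
  sharp <- make_texture(48, smoothness = 3, seed = 7)
  st <- make_defocus_stack(sharp, focus_surface = 2, blur_rate = 1.2,
                           n_slices = 5)
  expect_equal(dim(st), c(5, 48, 48))
  expect_identical(st[3, , ], sharp)            # slice index 2 (0-based)
  expect_false(identical(st[1, , ], sharp))
  expect_error(make_defocus_stack(sharp, 2, blur_rate = 0),
               class = "vistain_value_error")
  expect_error(make_defocus_stack(sharp, 9, blur_rate = 1, n_slices = 5),
               class = "vistain_value_error")
})

test_that("misaligned pairs return the exact ground-truth transform", {
  img <- make_texture(96, smoothness = 5, seed = 9)
  id <- make_misaligned_pair(img, list(rotation = 0, scale = 1, shear = 0,
                                       dx = 0, dy = 0))
  expect_equal(id$moving, id$fixed, tolerance = 1e-12)
  tr <- make_misaligned_pair(img, list(dx = 7, dy = -4))
  expect_equal(unclass(tr$true_transform),
               matrix(c(1, 0, 0, 1, 7, -4), 2, 3), tolerance = 1e-12)
  expect_error(make_misaligned_pair(img, list(dx = 90)),
               class = "vistain_value_error")
})
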