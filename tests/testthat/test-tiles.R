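test_that("anchor grids follow the stride and edge-flush rules", {
  g <- tile_grid(c(2048, 2048), 1024, 0.5)
  expect_equal(g$stride, 512L)
  expect_equal(unique(g$anchors[, 1]), c(0L, 512L, 1024L))
  expect_equal(nrow(g$anchors), 9)
  g1 <- tile_grid(c(1024, 1024), 1024, 0.5)
  expect_equal(nrow(g1$anchors), 1)
  expect_equal(as.integer(g1$anchors[1, ]), c(0L, 0L))
  # non-multiple size: one stride-aligned anchor plus one flush with the edge
  g2 <- tile_grid(c(1500, 1500), 1024, 0.5)
  expect_equal(unique(g2$anchors[, 1]), c(0L, 476L))
  expect_equal(nrow(g2$anchors), 4)
  expect_error(tile_grid(c(100, 100), 128, 0.5), class = "vistain_value_error")
})

test_that("tiling then stitching is the identity up to quantization", {
  for (shape in list(c(96, 96), c(131, 97))) {
    img <- matrix(runif(prod(shape), 0, 255), shape[1], shape[2])
    for (ov in c(0.25, 0.5)) {
      tl <- tile(img, 32, ov)
      out <- stitch(tl$patches, tl$grid)
      expect_lt(max(abs(out - img)), 1e-9)
      expect_lte(max(abs(round(out) - round(img))), 1)
    }
  }
  # multi-channel round trip
  rgb <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  tl <- tile(rgb, 32, 0.5)
  expect_lt(max(abs(stitch(tl$patches, tl$grid) - rgb)), 1e-9)
})

test_that("blend weights are convex: constants stay constant, sums are 1", {
  img <- matrix(0, 80, 80)
  tl <- tile(img, 32, 0.5)
  const <- lapply(tl$patches, function(p) p + 42)
  expect_equal(stitch(const, tl$grid), matrix(42, 80, 80), tolerance = 1e-12)
  ones <- lapply(tl$patches, function(p) p + 1)
  expect_equal(stitch(ones, tl$grid), matrix(1, 80, 80), tolerance = 1e-12)
})

test_that("feathering blends overlapping patches monotonically", {
  img <- matrix(0, 32, 48)
  tl <- tile(img, 32, 0.5)              # anchors x = 0, 16
  expect_equal(nrow(tl$grid$anchors), 2)
  vals <- list(tl$patches[[1]] + 0, tl$patches[[2]] + 100)
  out <- stitch(vals, tl$grid)
  profile <- out[16, ]                  # crosses the overlap columns 17..32
  expect_true(all(diff(profile) >= -1e-12))
  expect_equal(profile[1], 0)
  expect_equal(profile[48], 100)
  # oracle: feather weights evaluated directly at a column inside the overlap
  w1 <- vistain:::feather_profile(32)
  x <- 24                               # 1-based image column
  wa <- w1[x]; wb <- w1[x - 16]
  expect_equal(out[16, x], 100 * wb / (wa + wb), tolerance = 1e-12)
  expect_error(stitch(vals[1], tl$grid), class = "vistain_value_error")
})
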