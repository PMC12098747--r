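test_that("pcc matches its hand-computed oracle and the defining identities", {
  # x = (1,2,3,4), y = (1,2,4,3): covariance 1, sd^2 = 1.25 each -> rho = 0.8
  expect_equal(pcc(matrix(1:4, 2), matrix(c(1, 2, 4, 3), 2)), 0.8)
  set.seed(1)
  x <- matrix(rnorm(400), 20)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, 2.5 * x + 7), 1)
  expect_equal(pcc(x, -0.3 * x + 1), -1)
  y <- matrix(rnorm(400), 20)
  expect_equal(pcc(x, y), pcc_oracle(x, y), tolerance = 1e-12)
  # masked evaluation equals direct evaluation on the subset
  m <- matrix(rep(c(TRUE, FALSE), 200), 20)
  expect_equal(pcc(x, y, m), pcc_oracle(x[m], y[m]), tolerance = 1e-12)
  expect_error(pcc(x, matrix(1, 20, 20)), class = "vistain_value_error")
  expect_error(pcc(x, matrix(rnorm(4), 2)), class = "vistain_value_error")
})

test_that("pcc loss spans [0, 2] with the documented endpoints", {
  set.seed(2)
  x <- matrix(rnorm(256), 16)
  expect_equal(pcc_loss(x, x), 0)
  x0 <- x - mean(x)
  expect_equal(pcc_loss(x0, -x0), 2)
  n <- matrix(rnorm(1e4), 100)
  m <- matrix(rnorm(1e4), 100)
  expect_lt(abs(pcc_loss(n, m) - 1), 0.05)
})

test_that("warp_affine interpolates correctly and tracks validity", {
  img <- make_texture(64, smoothness = 4, seed = 3)
  w <- warp_affine(img, affine_identity())
  expect_equal(w$warped, img, tolerance = 1e-12)
  expect_true(all(w$valid))
  # a delta moves by exactly the translation
  delta <- matrix(0, 32, 32); delta[10, 12] <- 1
  tr <- affine_from_params(dx = 7, dy = -4)
  wd <- warp_affine(delta, tr)
  expect_equal(wd$warped[10 - 4, 12 + 7], 1)
  expect_equal(sum(wd$warped), 1)
  # warp then inverse-warp: near-lossless on the valid region
  tr2 <- affine_from_params(rotation = 8, dx = 3, dy = 2,
                            center = c(31.5, 31.5))
  fwd <- warp_affine(img, tr2)
  back <- warp_affine(fwd$warped, affine_invert(tr2))
  ok <- back$valid & warp_affine(fwd$valid * 1, affine_invert(tr2))$warped > 0.999
  expect_gte(pcc(back$warped, img, ok), 0.999)
  expect_error(affine_transform(matrix(c(1, 2, 2, 4, 0, 0), 2, 3)),
               class = "vistain_value_error")
})

test_that("affine algebra composes and inverts consistently", {
  a <- affine_from_params(rotation = 10, scale = 1.05, dx = 3, dy = -2,
                          center = c(20, 20))
  b <- affine_from_params(shear = 0.1, dx = -1, dy = 4)
  pts <- cbind(c(0, 5, 13.2), c(0, -3, 7.7))
  expect_equal(affine_apply(affine_compose(a, b), pts),
               affine_apply(a, affine_apply(b, pts)), tolerance = 1e-12)
  expect_equal(affine_apply(affine_compose(a, affine_invert(a)), pts), pts,
               tolerance = 1e-12)
})

test_that("registration recovers null, translated and rotated misalignments", {
  tex <- make_texture(128, smoothness = 5, seed = 4)
  fit0 <- estimate_affine(tex, tex)
  expect_lt(max(abs(fit0$transform[, 3])), 0.1)
  expect_lt(max(abs(fit0$transform[, 1:2] - diag(2))), 1e-3)
  pr <- make_misaligned_pair(tex, list(dx = 7, dy = -4))
  fit1 <- estimate_affine(pr$moving, pr$fixed)
  expect_lt(endpoint_error(fit1$transform, pr$true_transform, dim(tex)), 0.5)
  pr2 <- make_misaligned_pair(tex, list(rotation = 3, dx = 5, dy = 5),
                              noise_sd = 0.01)
  fit2 <- estimate_affine(pr2$moving, pr2$fixed)
  expect_lt(endpoint_error(fit2$transform, pr2$true_transform, dim(tex)), 1)
  expect_true(fit2$improved)
})

test_that("curation keeps exactly the patches at or above the threshold", {
  sl <- make_paired_slide(tiny_spec(seed = 21))
  pair <- list(ri = sl$ri, scbf = 0.299 * sl$rgb[, , 1] +
                 0.587 * sl$rgb[, , 2] + 0.114 * sl$rgb[, , 3],
               rgb = sl$rgb)
  set <- suppressMessages(
    curate_pairs(list(pair), threshold = 0.65, patch_size = 32,
                 overlap = 0, refine = FALSE))
  expect_equal(nrow(set$report), 4)
  expect_true(all(set$report$kept))
  expect_equal(set$report$pcc, rep(1, 4), tolerance = 1e-12)
  # corrupt two known patches with independent noise -> exactly those excluded
  bad <- pair
  set.seed(9)
  bad$rgb[1:32, 1:32, ] <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  bad$rgb[33:64, 33:64, ] <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  set2 <- suppressMessages(
    curate_pairs(list(bad), threshold = 0.65, patch_size = 32,
                 overlap = 0, refine = FALSE))
  expect_equal(sum(!set2$report$kept), 2)
  excluded <- set2$report[!set2$report$kept, ]
  expect_setequal(paste(excluded$y0, excluded$x0),
                  c("0 0", "32 32"))
  # boundary semantics: a patch at exactly the threshold is kept
  x <- as.numeric(sl$ri[1:32, 1:32])
  y <- corr_pair(x, 0.65, seed = 2)
  thr <- pcc(matrix(x, 32), matrix(y, 32))
  gray <- (y - min(y)) / diff(range(y)) * 255
  pair3 <- list(ri = matrix(x, 32),
                scbf = matrix(x, 32),
                rgb = array(rep(gray, 3), c(32, 32, 3)))
  thr3 <- pcc(pair3$scbf, 0.299 * pair3$rgb[, , 1] + 0.587 * pair3$rgb[, , 2] +
                0.114 * pair3$rgb[, , 3])
  set3 <- suppressMessages(
    curate_pairs(list(pair3), threshold = thr3, patch_size = 32,
                 refine = FALSE))
  expect_true(set3$report$kept[1])
  # curation partitions its input without mutating patches
  expect_equal(sum(set2$report$kept) + sum(!set2$report$kept),
               nrow(set2$report))
  expect_identical(set2$patches[[2]]$rgb, bad$rgb[1:32, 33:64, , drop = FALSE])
})

test_that("curation warns when nothing survives", {
  set.seed(3)
  a <- matrix(rnorm(1024), 32)
  pair <- list(ri = a, scbf = a,
               rgb = array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)))
  expect_warning(
    suppressMessages(curate_pairs(list(pair), threshold = 0.9,
                                  patch_size = 32, refine = FALSE)),
    "kept no patches")
})
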