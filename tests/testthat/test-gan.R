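test_that("adversarial value matches closed forms and a loop oracle", {
  half <- array(0.5, c(4, 4, 1))
  expect_equal(cgan_loss(half, half), 2 * log(0.5), tolerance = 1e-12)
  # perfect discriminator: value approaches its upper bound 0 from below
  good <- cgan_loss(array(1 - 1e-9, c(4, 4, 1)), array(1e-9, c(4, 4, 1)))
  expect_lt(good, 0)
  expect_gt(good, -1e-5)
  set.seed(4)
  dr <- array(runif(64, 0.01, 0.99), c(8, 8, 1))
  df <- array(runif(64, 0.01, 0.99), c(8, 8, 1))
  oracle <- 0
  for (i in seq_along(dr)) oracle <- oracle + log(dr[i]) / 64 + log(1 - df[i]) / 64
  expect_equal(cgan_loss(dr, df), oracle, tolerance = 1e-9)
})

test_that("generator objective composes adversarial and correlation terms", {
  set.seed(5)
  x <- matrix(rnorm(64), 8)
  y <- array(rnorm(192), c(8, 8, 3))
  d_const <- function(x, yhat) array(0.3, c(2, 2, 1))
  # exact reproduction: PCC term 0, objective = adversarial term alone
  g_exact <- function(x) y
  r <- generator_objective(x, y, g_exact, d_const, lambda = 100)
  expect_equal(r$pcc_term, 0, tolerance = 1e-12)
  expect_equal(r$total, log(0.7), tolerance = 1e-12)
  # lambda = 0 reduces to the adversarial term for any generator
  g_off <- function(x) y + rnorm(length(y))
  r0 <- generator_objective(x, y, g_off, d_const, lambda = 0)
  expect_equal(r0$total, r0$adversarial)
  # arithmetic composition: channels with sample correlation exactly 0.9
  yhat <- y
  for (c in 1:3) yhat[, , c] <- corr_pair(y[, , c], 0.9, seed = c)
  g_corr <- function(x) yhat
  rc <- generator_objective(x, y, g_corr, d_const, lambda = 100)
  expect_equal(rc$pcc_term, 0.1, tolerance = 1e-9)
  expect_equal(rc$total - rc$adversarial, 10, tolerance = 1e-9)
})

test_that("augmentation honours probabilities, noise level and the seed", {
  pair <- list(x = make_texture(256, seed = 1) * 2 - 1,
               y = array(runif(256 * 256 * 3, -1, 1), c(256, 256, 3)))
  off <- list(p_blur = 0, blur_sigma = c(0.5, 1), p_brightness = 0,
              brightness = c(-0.1, 0.1), p_noise = 0, noise_sd = c(0.01, 0.02))
  set.seed(1)
  expect_identical(augment_pair(pair, off), pair)
  noisy <- off; noisy$p_noise <- 1; noisy$noise_sd <- c(0.05, 0.05)
  set.seed(2)
  a <- augment_pair(pair, noisy)
  expect_equal(dim(a$x), dim(pair$x))
  expect_lt(abs(sd(a$x - pair$x) - 0.05) / 0.05, 0.1)
  expect_identical(a$y, pair$y)        # photometric input-only augmentation
  set.seed(7); a1 <- augment_pair(pair, augment_defaults())
  set.seed(7); a2 <- augment_pair(pair, augment_defaults())
  expect_identical(a1, a2)
})

test_that("generator output matches input size; incompatible sizes error", {
  G <- vistain:::build_generator(reduced_gen())
  for (n in c(32, 64)) {
    y <- vistain:::gen_forward(G, matrix(0.1, n, n))$y
    expect_equal(dim(y), c(n, n, 3))
  }
  expect_error(vistain:::gen_forward(G, matrix(0.1, 33, 33)),
               class = "vistain_value_error")
})

test_that("zero-epoch training returns an untrained but usable checkpoint", {
  tp <- gan_pairs(2, 100)
  fit <- train_stain_gan(tp, tp[1], gen_config = reduced_gen(),
                         disc_config = reduced_disc(),
                         config = reduced_train(epochs = 0, seed = 1))
  expect_s3_class(fit, "stain_gan_fit")
  expect_equal(fit$epochs_run, 0L)
  expect_equal(nrow(fit$history), 0)
  out <- predict_slide(fit, tp[[1]]$ri)
  expect_equal(dim(out), c(64, 64, 3))
})

test_that("training is bit-reproducible and checkpoints round-trip", {
  tp <- gan_pairs(6, 200); vp <- gan_pairs(2, 300)
  cfgs <- list(gen_config = reduced_gen(), disc_config = reduced_disc(),
               config = reduced_train(epochs = 2, seed = 5))
  f1 <- do.call(train_stain_gan, c(list(tp, vp), cfgs))
  f2 <- do.call(train_stain_gan, c(list(tp, vp), cfgs))
  expect_identical(f1$generator$params, f2$generator$params)
  expect_identical(f1$history, f2$history)
  d <- withr::local_tempdir()
  p <- file.path(d, "ck.rds")
  save_checkpoint(f1, p)
  f3 <- load_checkpoint(p)
  s <- tp[[1]]$ri
  expect_identical(predict_slide(f1, s), predict_slide(f3, s))
  expect_identical(predict_slide(f1, s), predict_slide(f1, s))
  expect_error(load_checkpoint(file.path(d, "none.rds")),
               class = "vistain_io_error")
  # tidy/glance expose the training history
  expect_equal(nrow(tidy(f1)), f1$epochs_run)
  expect_equal(glance(f1)$best_epoch, f1$best_epoch)
})

test_that("volume inference is slice-consistent and masks non-sample regions", {
  tp <- gan_pairs(4, 400)
  fit <- train_stain_gan(tp, tp[1:2], gen_config = reduced_gen(),
                         disc_config = reduced_disc(),
                         config = reduced_train(epochs = 1, seed = 2))
  vol <- array(tp[[1]]$ri, c(1, 64, 64))
  expect_identical(predict_volume(fit, vol)[1, , , ],
                   predict_slide(fit, tp[[1]]$ri))
  bgvol <- array(1.495, c(1, 64, 64))
  out <- predict_volume(fit, bgvol, mask_background = TRUE)
  expect_true(all(out == 255L))
  expect_error(predict_slide(fit, tp[[1]]$ri, patch_size = 33),
               class = "vistain_value_error")
})
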