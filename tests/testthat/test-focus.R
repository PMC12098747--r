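test_that("normalized variance matches hand arithmetic and a direct oracle", {
  expect_equal(normalized_variance(rep(2.5, 9)), 0)
  # var_pop([1,1,1,3]) = 0.75, mean = 1.5 -> 0.5
  expect_equal(normalized_variance(c(1, 1, 1, 3)), 0.5)
  set.seed(42)
  w <- runif(200, 0.5, 2)
  direct <- mean((w - mean(w))^2) / mean(w)
  expect_equal(normalized_variance(w), direct, tolerance = 1e-12)
  expect_error(normalized_variance(c(-1, -2)), class = "vistain_value_error")
  expect_error(normalized_variance(numeric(0)), class = "vistain_value_error")
})

test_that("single-slice stacks pass through unchanged", {
  sl <- make_texture(40, seed = 2) + 1
  vol <- array(sl, c(1, 40, 40))
  r <- all_in_focus(vol, vignette = 16, step = 4)
  expect_identical(r$composite, sl)
  expect_true(all(r$focus_map == 0L))
})

test_that("windowed selection recovers constant and step focus surfaces", {
  sharp <- make_texture(96, smoothness = 2, seed = 5) + 0.5
  stack <- make_defocus_stack(sharp, focus_surface = 2, blur_rate = 1.5,
                              n_slices = 5)
  r <- all_in_focus(stack, vignette = 16, step = 4)
  expect_gte(mean(r$window_index == 2L), 0.99)
  # step surface: left half focused at slice 1, right half at slice 4
  surf <- matrix(1, 96, 96); surf[, 49:96] <- 4
  st2 <- make_defocus_stack(sharp, surf, blur_rate = 1.5, n_slices = 5)
  r2 <- all_in_focus(st2, vignette = 16, step = 4)
  truth <- matrix(1L, nrow(r2$window_index), ncol(r2$window_index))
  centers_x <- r2$anchors$x + (16 - 1) / 2
  truth[, centers_x >= 48] <- 4L
  expect_gte(mean(r2$window_index == truth), 0.95)
  # composite is sharper than any single slice
  nv <- function(m) normalized_variance(m)
  best_single <- max(apply(st2, 1, nv))
  expect_gte(nv(r2$composite), best_single)
})

test_that("slice selection is invariant to positive rescaling of the stack", {
  sharp <- make_texture(64, smoothness = 2, seed = 8) + 0.5
  surf <- matrix(1, 64, 64); surf[33:64, ] <- 3
  st <- make_defocus_stack(sharp, surf, blur_rate = 1.2, n_slices = 4)
  r1 <- all_in_focus(st, vignette = 16, step = 4)
  r2 <- all_in_focus(st * 3.7, vignette = 16, step = 4)
  expect_identical(r1$window_index, r2$window_index)
  expect_error(all_in_focus(st, vignette = 100, step = 10),
               class = "vistain_value_error")
})
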