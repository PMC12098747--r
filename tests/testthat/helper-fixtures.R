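# Shared fixtures: all synthetic, generated in code at test time.

# desk-scale phantom: 64 px canvas, a handful of nuclei, one lumen
tiny_spec <- function(seed = 1L, ...) {
  phantom_spec(canvas = 64L, n_nuclei = 4L, nucleus_radius = c(3, 6),
               nucleus_ecc = c(0, 0.6), lumen_radius = 8, seed = seed, ...)
}

# paired (RI, RGB) training examples drawn from distinct phantom seeds
gan_pairs <- function(n, seed0) {
  lapply(seq_len(n), function(i) {
    sl <- make_paired_slide(tiny_spec(seed = seed0 + i))
    list(ri = sl$ri, rgb = sl$rgb)
  })
}

# reduced network used by the mapping-recovery experiments
reduced_gen <- function() generator_config(n_stages = 2L, base_features = 8L)
reduced_disc <- function() discriminator_config(base_features = 8L,
                                                final_relu = FALSE)
reduced_train <- function(epochs, seed, lambda = 100) {
  train_config(epochs = epochs, lambda = lambda, seed = seed,
               patience = Inf, non_saturating = TRUE)
}

# brute-force Pearson correlation (independent of the package implementation)
pcc_oracle <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my)) / length(x)
  num / (sqrt(sum((x - mx)^2) / length(x)) * sqrt(sum((y - my)^2) / length(y)))
}

# construct y with an exact target sample correlation to x (Gram-Schmidt)
corr_pair <- function(x, rho, seed = 1L) {
  with_seed <- getFromNamespace("with_seed", "vistain")
  x <- as.numeric(x)
  with_seed(seed, {
    z <- stats::rnorm(length(x))
    xs <- (x - mean(x)) / stats::sd(x)
    r <- stats::residuals(stats::lm(z ~ xs))
    rs <- (r - mean(r)) / stats::sd(r)
    rho * xs + sqrt(1 - rho^2) * rs
  })
}
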