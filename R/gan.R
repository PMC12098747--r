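# The conditional staining GAN. The generator is a U-Net-like encoder-decoder
# with skip connections, instance normalization, leaky-ReLU activations and a
# squeeze-excitation block per stage; the discriminator is a five-layer
# strided PatchGAN conditioned on the input RI image. The generator objective
# is the adversarial term plus lambda times the Pearson-correlation
# reconstruction loss, computed per RGB channel and averaged.

#' Generator configuration
#'
#' The reference architecture uses 12 initial feature maps, a feature
#' multiplier of 2 and 8 layers, read here as 4 encoder stages plus 4 decoder
#' convolutions (3 skip-merge blocks and the 1x1 output head). Input size
#' must be divisible by `2^(n_stages - 1)`.
#'
#' @param n_stages number of resolution levels (encoder stages), >= 2.
#' @param base_features feature maps at the first stage.
#' @param feature_mult per-stage feature multiplier.
#' @param leaky_slope slope of the leaky-ReLU activations.
#' @param se_reduction squeeze-excitation bottleneck reduction factor.
#' @param in_channels,out_channels image channels (1 RI in, 3 RGB out).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_stages = 4L, base_features = 12L,
                             feature_mult = 2L, leaky_slope = 0.2,
                             se_reduction = 2L, in_channels = 1L,
                             out_channels = 3L) {
  stopifnot(n_stages >= 2, base_features >= 1)
  structure(list(n_stages = as.integer(n_stages),
                 base_features = as.integer(base_features),
                 feature_mult = as.integer(feature_mult),
                 leaky_slope = leaky_slope, se_reduction = as.integer(se_reduction),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Five convolutional layers with kernel 4 and stride 2; leaky ReLU (slope
#' 0.2) on the first four, ReLU on the fifth, then a sigmoid, giving a score
#' map in (0, 1). The stated final ReLU bounds scores to `[0.5, 1)`;
#' `final_relu = FALSE` drops it. At batch size 1 the stated batch
#' normalization on the first and last layers coincides with per-sample
#' (instance) normalization, which is how all norms are computed here.
#'
#' @param base_features feature maps of the first layer.
#' @param leaky_slope leaky-ReLU slope.
#' @param final_relu keep the ReLU before the sigmoid (as specified).
#' @param norm `"paper"` (batch norm on the first and last layers — realized
#'   with running statistics at batch size 1 — instance norm on the middle
#'   layers) or `"instance"` (instance norm everywhere).
#' @param in_channels channels of the conditioned input (RI + RGB = 4).
#' @return object of class `discriminator_config`.
#' @export
discriminator_config <- function(base_features = 16L, leaky_slope = 0.2,
                                 final_relu = TRUE,
                                 norm = c("paper", "instance"),
                                 in_channels = 4L) {
  norm <- match.arg(norm)
  structure(list(n_layers = 5L, base_features = as.integer(base_features),
                 leaky_slope = leaky_slope, final_relu = isTRUE(final_relu),
                 norm = norm, in_channels = as.integer(in_channels)),
            class = "discriminator_config")
}

#' Training configuration
#'
#' Adam with learning rate 1e-4, 40 epochs at batch size 1, early stopping on
#' the validation correlation loss. `lambda` weighs the correlation
#' reconstruction term against the adversarial term; it is not pinned by the
#' reference description, so the conventional image-translation weight 100 is
#' the default.
#'
#' @param lr learning rate (> 0).
#' @param epochs training epochs.
#' @param lambda weight of the PCC reconstruction term (>= 0).
#' @param patience early-stopping patience, in epochs without validation
#'   improvement; `Inf` disables early stopping.
#' @param augment named list of augmentation settings (see [augment_pair()]);
#'   `NULL` disables augmentation.
#' @param non_saturating use the non-saturating generator loss instead of the
#'   minimax form.
#' @param ri_range physical RI window mapped to `[-1, 1]` network inputs.
#' @param seed integer seed controlling init, shuffling and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 40L, lambda = 100,
                         patience = 5L, augment = augment_defaults(),
                         non_saturating = FALSE,
                         ri_range = c(1.33, 1.60), seed = 1L) {
  if (lambda < 0) vs_error("vistain_value_error", "lambda must be >= 0")
  if (lr <= 0) vs_error("vistain_value_error", "learning rate must be > 0")
  structure(list(lr = lr, epochs = as.integer(epochs), lambda = lambda,
                 patience = patience, augment = augment,
                 non_saturating = isTRUE(non_saturating),
                 ri_range = ri_range, seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname augment_pair
#' @export
augment_defaults <- function() {
  list(p_blur = 0.3, blur_sigma = c(0.5, 1.5),
       p_brightness = 0.3, brightness = c(-0.1, 0.1),
       p_noise = 0.3, noise_sd = c(0.005, 0.02))
}

# ---- builders --------------------------------------------------------------

# `output_prior`: per-channel mean of the normalized training targets. The
# output head's bias is initialized at its inverse tanh, so the generator
# starts at the data's global colour balance (the classifier analogue of
# initializing the output bias at the class-prior log-odds). The correlation
# reconstruction term is shift-invariant, so without this the global colour
# level would have to be recovered through the adversarial term alone.
build_generator <- function(cfg, output_prior = NULL) {
  S <- cfg$n_stages
  f <- cfg$base_features * cfg$feature_mult^(seq_len(S) - 1)
  enc <- vector("list", S)
  for (k in seq_len(S)) {
    cin <- if (k == 1) cfg$in_channels else f[k - 1]
    enc[[k]] <- block_init(cin, f[k], cfg$se_reduction)
  }
  dec <- if (S > 1) lapply(seq_len(S - 1), function(k)
    block_init(f[k + 1] + f[k], f[k], cfg$se_reduction)) else list()
  head <- init_conv(1, 1, f[1], cfg$out_channels)
  if (!is.null(output_prior))
    head$b <- atanh(clamp(output_prior, -0.99, 0.99))
  list(cfg = cfg, params = list(enc = enc, dec = dec, head = head))
}

is_bn_layer <- function(cfg, l) {
  cfg$norm == "paper" && (l == 1L || l == cfg$n_layers)
}

build_discriminator <- function(cfg) {
  f <- cfg$base_features * 2^(0:3)
  chans <- c(cfg$in_channels, f, 1L)
  layers <- lapply(seq_len(cfg$n_layers), function(l)
    list(conv = init_conv(4, 4, chans[l], chans[l + 1]),
         norm = init_norm(chans[l + 1])))
  state <- lapply(seq_len(cfg$n_layers), function(l)
    if (is_bn_layer(cfg, l)) bn_state_init(chans[l + 1]) else NULL)
  list(cfg = cfg, params = list(layers = layers), state = state)
}

ccat <- function(a, b) array(c(a, b), c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))

gen_check_size <- function(cfg, shape) {
  div <- 2^(cfg$n_stages - 1)
  if (any(shape[1:2] %% div != 0))
    vs_error("vistain_value_error",
             sprintf("input size %dx%d incompatible with network depth (needs divisibility by %d)",
                     shape[1], shape[2], div))
}

gen_forward <- function(G, x) {
  cfg <- G$cfg; S <- cfg$n_stages
  x <- as_fm(x)
  gen_check_size(cfg, dim(x))
  caches <- list(enc = vector("list", S), dec = vector("list", max(S - 1, 0)))
  skips <- vector("list", max(S - 1, 0))
  h <- x
  for (k in seq_len(S)) {
    b <- block_fwd(G$params$enc[[k]], h, cfg$leaky_slope)
    caches$enc[[k]] <- b$cache
    h <- b$y
    if (k < S) { skips[[k]] <- h; h <- pool2_fwd(h) }
  }
  for (k in rev(seq_len(S - 1))) {
    h <- up2_fwd(h)
    h <- ccat(h, skips[[k]])
    b <- block_fwd(G$params$dec[[k]], h, cfg$leaky_slope)
    caches$dec[[k]] <- b$cache
    h <- b$y
  }
  cv <- conv_fwd(G$params$head, h, 1L, 0L)
  y <- tanh(cv$out)
  caches$head_conv <- cv[c("K", "xdim")]
  caches$y <- y
  caches$skip_dims <- lapply(skips, dim)
  list(y = y, cache = caches)
}

gen_backward <- function(G, cache, gy) {
  cfg <- G$cfg; S <- cfg$n_stages
  f <- cfg$base_features * cfg$feature_mult^(seq_len(S) - 1)
  grads <- list(enc = vector("list", S), dec = vector("list", max(S - 1, 0)),
                head = NULL)
  gv <- gy * (1 - cache$y^2)
  hb <- conv_bwd(G$params$head, cache$head_conv, gv, 1L, 0L)
  grads$head <- hb$grads
  gh <- hb$gx
  gskips <- vector("list", max(S - 1, 0))
  for (k in seq_len(S - 1)) {
    b <- block_bwd(G$params$dec[[k]], cache$dec[[k]], gh, cfg$leaky_slope)
    grads$dec[[k]] <- b$grads
    cup <- f[k + 1]
    gup <- b$gx[, , seq_len(cup), drop = FALSE]
    gskips[[k]] <- b$gx[, , cup + seq_len(f[k]), drop = FALSE]
    gh <- up2_bwd(gup)
  }
  for (k in rev(seq_len(S))) {
    gout <- if (k == S) gh else gskips[[k]] + pool2_bwd(gh, dim(gskips[[k]]))
    b <- block_bwd(G$params$enc[[k]], cache$enc[[k]], gout, cfg$leaky_slope)
    grads$enc[[k]] <- b$grads
    gh <- b$gx
  }
  list(gx = gh, grads = grads)
}

disc_forward <- function(D, x, update_stats = FALSE) {
  cfg <- D$cfg
  h <- as_fm(x)
  caches <- vector("list", cfg$n_layers)
  state <- D$state
  for (l in seq_len(cfg$n_layers)) {
    p <- D$params$layers[[l]]
    cv <- conv_fwd(p$conv, h, 2L, 1L)
    bn <- is_bn_layer(cfg, l)
    if (bn) {
      nr <- bn_fwd(p$norm, cv$out, state[[l]])
      if (update_stats) state[[l]] <- bn_update(state[[l]], cv$out)
    } else {
      nr <- inorm_fwd(p$norm, cv$out)
    }
    if (l < cfg$n_layers || cfg$final_relu) {
      slope <- if (l < cfg$n_layers) cfg$leaky_slope else 0
      ac <- lrelu_fwd(nr$y, slope)
      h <- ac$y
      caches[[l]] <- list(conv = cv[c("K", "xdim")], nr = nr$cache,
                          neg = ac$cache, bn = bn)
    } else {
      h <- nr$y
      caches[[l]] <- list(conv = cv[c("K", "xdim")], nr = nr$cache,
                          neg = NULL, bn = bn)
    }
  }
  s <- 1 / (1 + exp(-h))
  list(score = s, cache = list(layers = caches, s = s), state = state)
}

disc_backward <- function(D, cache, gscore) {
  cfg <- D$cfg
  s <- cache$s
  gh <- gscore * s * (1 - s)
  grads <- list(layers = vector("list", cfg$n_layers))
  for (l in rev(seq_len(cfg$n_layers))) {
    p <- D$params$layers[[l]]
    cl <- cache$layers[[l]]
    slope <- if (l < cfg$n_layers) cfg$leaky_slope else 0
    if (!is.null(cl$neg)) gh <- lrelu_bwd(cl$neg, gh, slope)
    nb <- if (cl$bn) bn_bwd(p$norm, cl$nr, gh)
          else inorm_bwd(p$norm, cl$nr, gh)
    cb <- conv_bwd(p$conv, cl$conv, nb$gx, 2L, 1L)
    grads$layers[[l]] <- list(conv = cb$grads, norm = nb$grads)
    gh <- cb$gx
  }
  list(gx = gh, grads = grads)
}

# ---- losses ----------------------------------------------------------------

#' Conditional-GAN value function
#'
#' `E[log D(x, y)] + E[log(1 - D(x, G(x)))]` with natural logarithms,
#' averaged over the score maps; the discriminator ascends it, the generator
#' descends its second term. Scores are clamped to `[1e-7, 1 - 1e-7]` before
#' the logs.
#'
#' @param d_real_scores,d_fake_scores discriminator score maps in (0, 1).
#' @param eps clamping epsilon guarding the logarithms.
#' @return scalar value (upper bound 0, attained as D becomes perfect).
#' @export
cgan_loss <- function(d_real_scores, d_fake_scores, eps = 1e-7) {
  r <- clamp(as.numeric(d_real_scores), eps, 1 - eps)
  f <- clamp(as.numeric(d_fake_scores), eps, 1 - eps)
  mean(log(r)) + mean(log(1 - f))
}

# PCC reconstruction loss and its gradient wrt yhat, averaged per channel.
pcc_loss_grad <- function(yhat, y, eps = 1e-8) {
  d <- dim(yhat); nch <- d[3]; n <- d[1] * d[2]
  g <- array(0, d)
  loss <- 0
  flagged <- FALSE
  for (c in seq_len(nch)) {
    xc <- yhat[, , c] - mean(yhat[, , c])
    yc <- y[, , c] - mean(y[, , c])
    sx <- sqrt(mean(xc^2)); sy <- sqrt(mean(yc^2))
    if (sx < eps || sy < eps) {
      flagged <- TRUE
      sx <- sx + eps; sy <- sy + eps
    }
    rho <- mean(xc * yc) / (sx * sy)
    loss <- loss + (1 - rho)
    # d rho / d yhat = (yc - rho * (sy/sx) * xc) / (n * sx * sy)
    g[, , c] <- -(yc - rho * (sy / sx) * xc) / (n * sx * sy) / nch
  }
  list(loss = loss / nch, grad = g, flagged = flagged)
}

#' Generator objective
#'
#' The full generator objective: adversarial term plus `lambda` times the
#' per-channel-averaged Pearson correlation loss between `G(x)` and `y`.
#' `G` and `D` may be fitted networks or plain functions (useful for
#' closed-form checks): a functional `G` is called as `G(x)`, a functional
#' `D` as `D(x, yhat)` and must return a score map in (0, 1).
#'
#' @param x conditioning input (normalized RI image).
#' @param y target image (normalized RGB array).
#' @param G generator (network list or function).
#' @param D discriminator (network list or function).
#' @param lambda reconstruction weight.
#' @param non_saturating use `-E[log D]` instead of `E[log(1 - D)]`.
#' @return list with `total`, `adversarial` and `pcc_term` (unweighted).
#' @export
generator_objective <- function(x, y, G, D, lambda = 100,
                                non_saturating = FALSE) {
  yhat <- if (is.function(G)) G(x) else gen_forward(G, x)$y
  s <- if (is.function(D)) D(x, yhat)
       else disc_forward(D, ccat(as_fm(x), yhat))$score
  s <- clamp(as.numeric(s), 1e-7, 1 - 1e-7)
  adv <- if (non_saturating) -mean(log(s)) else mean(log(1 - s))
  pl <- pcc_loss_grad(yhat, as_fm(y))
  if (pl$flagged)
    warning("constant generator output: PCC term stabilized by epsilon",
            call. = FALSE)
  list(total = adv + lambda * pl$loss, adversarial = adv, pcc_term = pl$loss)
}

# ---- augmentation ----------------------------------------------------------

#' Augment a normalized training pair
#'
#' Photometric augmentation drawn from the current RNG stream: Gaussian blur
#' and additive Gaussian noise are applied to the input RI channel only,
#' brightness shifts to the input. All probabilities zero (or `config =
#' NULL`) is the identity; shapes never change.
#'
#' @param pair list with `x` (matrix, normalized RI) and `y` (array,
#'   normalized RGB).
#' @param config settings as produced by `augment_defaults()`.
#' @return augmented pair.
#' @export
augment_pair <- function(pair, config = augment_defaults()) {
  if (is.null(config)) return(pair)
  x <- pair$x
  if (stats::runif(1) < config$p_blur) {
    sg <- stats::runif(1, config$blur_sigma[1], config$blur_sigma[2])
    x <- gaussian_blur(x, sg)
  }
  if (stats::runif(1) < config$p_brightness) {
    db <- stats::runif(1, config$brightness[1], config$brightness[2])
    x <- clamp(x + db, -1.2, 1.2)
  }
  if (stats::runif(1) < config$p_noise) {
    sdn <- stats::runif(1, config$noise_sd[1], config$noise_sd[2])
    x <- x + stats::rnorm(length(x), sd = sdn)
  }
  pair$x <- x
  pair
}

# ---- normalization ---------------------------------------------------------

normalize_ri <- function(ri, range) {
  clamp((ri - range[1]) / (range[2] - range[1]), 0, 1) * 2 - 1
}

normalize_rgb <- function(rgb) rgb / 127.5 - 1

denormalize_rgb <- function(y) {
  r <- round((y + 1) * 127.5)
  array(as.integer(clamp(r, 0, 255)), dim(y))
}

# ---- training --------------------------------------------------------------

extract_pairs <- function(pairs) {
  if (inherits(pairs, "paired_patch_set"))
    pairs <- lapply(Filter(function(p) p$kept, pairs$patches),
                    function(p) list(ri = p$ri, rgb = p$rgb))
  pairs
}

#' Train the conditional staining network
#'
#' Alternating discriminator/generator Adam updates at batch size 1. The
#' discriminator ascends the conditional-GAN value; the generator descends
#' its adversarial term plus `lambda` times the per-channel Pearson
#' correlation loss. The validation correlation loss is logged each epoch;
#' the checkpoint with the best validation loss is returned, with early
#' stopping after `patience` epochs without improvement. All randomness
#' derives from `config$seed`, so training is bit-reproducible.
#'
#' @param train_pairs,val_pairs [curate_pairs()] output or a plain list of
#'   `list(ri = matrix, rgb = (y, x, 3) integer array)` pairs (raw physical
#'   units; normalization happens internally).
#' @param gen_config a [generator_config()].
#' @param disc_config a [discriminator_config()].
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return object of class `stain_gan_fit`.
#' @export
train_stain_gan <- function(train_pairs, val_pairs,
                            gen_config = generator_config(),
                            disc_config = discriminator_config(),
                            config = train_config(), verbose = FALSE) {
  tp <- extract_pairs(train_pairs)
  vp <- extract_pairs(val_pairs)
  if (!length(tp)) vs_error("vistain_value_error", "no training pairs")
  norm_pair <- function(p) list(x = normalize_ri(p$ri, config$ri_range),
                                y = normalize_rgb(p$rgb))
  tp <- lapply(tp, norm_pair)
  vp <- lapply(vp, norm_pair)
  eps <- 1e-7
  with_seed(config$seed, {
    prior <- Reduce(`+`, lapply(tp, function(p) apply(p$y, 3, mean))) / length(tp)
    G <- build_generator(gen_config, output_prior = prior)
    D <- build_discriminator(disc_config)
    optG <- adam_init(G$params)
    optD <- adam_init(D$params)
    tG <- 0L; tD <- 0L
    hist <- list()
    best <- list(loss = Inf, epoch = 0L, G = G$params, D = D$params,
                 Dstate = D$state)
    wait <- 0L
    val_loss <- function(Gc) {
      if (!length(vp)) return(NA_real_)
      mean(vapply(vp, function(p) {
        yh <- gen_forward(Gc, p$x)$y
        pcc_loss_grad(yh, p$y)$loss
      }, numeric(1)))
    }
    epochs_run <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(tp))
      ds <- 0; gs <- 0; ps <- 0
      for (i in ord) {
        pair <- augment_pair(tp[[i]], config$augment)
        x <- as_fm(pair$x); y <- as_fm(pair$y)
        gf <- gen_forward(G, x)
        yhat <- gf$y
        # simultaneous updates: both players' gradients are taken at the
        # current (pre-update) discriminator, letting the fake-pass caches be
        # shared between the D and G steps
        fr <- disc_forward(D, ccat(x, y), update_stats = TRUE)
        D$state <- fr$state        # BN running stats track the real stream
        ff <- disc_forward(D, ccat(x, yhat))
        sr <- clamp(fr$score, eps, 1 - eps)
        sf <- clamp(ff$score, eps, 1 - eps)
        nd <- length(sr)
        gr <- -1 / (nd * sr)                 # d(-mean log sr)/dsr
        gfk <- 1 / (nd * (1 - sf))           # d(-mean log(1-sf))/dsf
        br <- disc_backward(D, fr$cache, array(gr, dim(sr)))
        bf <- disc_backward(D, ff$cache, array(gfk, dim(sf)))
        gs2 <- if (config$non_saturating) -1 / (nd * sf)
               else -1 / (nd * (1 - sf))
        bg <- disc_backward(D, ff$cache, array(gs2, dim(sf)))
        gy_adv <- bg$gx[, , disc_config$in_channels - dim(y)[3] + seq_len(dim(y)[3]),
                        drop = FALSE]
        gD <- tmap2(br$grads, bf$grads, `+`)
        tD <- tD + 1L
        ud <- adam_step(D$params, gD, optD, config$lr, tD)
        D$params <- ud$params; optD <- ud$state
        ds <- ds - (mean(log(sr)) + mean(log(1 - sf)))
        pl <- pcc_loss_grad(yhat, y)
        gy_tot <- gy_adv + config$lambda * pl$grad
        gb <- gen_backward(G, gf$cache, gy_tot)
        tG <- tG + 1L
        ug <- adam_step(G$params, gb$grads, optG, config$lr, tG)
        G$params <- ug$params; optG <- ug$state
        adv_val <- if (config$non_saturating) -mean(log(sf)) else mean(log(1 - sf))
        gs <- gs + adv_val + config$lambda * pl$loss
        ps <- ps + pl$loss
      }
      vl <- val_loss(G)
      if (is.nan(vl))
        vs_error("vistain_diverged", "validation loss is NaN: training diverged")
      n <- length(tp)
      hist[[ep]] <- tibble::tibble(epoch = ep, d_loss = ds / n,
                                   g_objective = gs / n, g_pcc = ps / n,
                                   val_pcc_loss = vl)
      epochs_run <- ep
      if (verbose)
        message(sprintf("epoch %d: d %.3f g %.3f pcc %.3f val %.3f",
                        ep, ds / n, gs / n, ps / n, vl))
      track <- if (is.na(vl)) ps / n else vl
      if (track < best$loss - 1e-9) {
        best <- list(loss = track, epoch = ep, G = G$params, D = D$params,
                     Dstate = D$state)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (is.finite(config$patience) && wait >= config$patience) break
      }
    }
    history <- if (length(hist)) do.call(rbind, hist) else
      tibble::tibble(epoch = integer(), d_loss = numeric(),
                     g_objective = numeric(), g_pcc = numeric(),
                     val_pcc_loss = numeric())
    if (config$epochs == 0L) best <- list(loss = NA_real_, epoch = 0L,
                                          G = G$params, D = D$params,
                                          Dstate = D$state)
    structure(list(generator = list(cfg = gen_config, params = best$G),
                   discriminator = list(cfg = disc_config, params = best$D,
                                        state = best$Dstate),
                   train_config = config, history = history,
                   best_epoch = best$epoch, best_val_loss = best$loss,
                   epochs_run = epochs_run, seed = config$seed),
              class = "stain_gan_fit")
  })
}

#' @export
print.stain_gan_fit <- function(x, ...) {
  cat(sprintf("<stain_gan_fit> %d epoch(s) run, best epoch %d (val PCC loss %.4f)\n",
              x$epochs_run, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
tidy.stain_gan_fit <- function(x, ...) x$history

#' @export
glance.stain_gan_fit <- function(x, ...) {
  tibble::tibble(epochs_run = x$epochs_run, best_epoch = x$best_epoch,
                 best_val_pcc_loss = x$best_val_loss,
                 lambda = x$train_config$lambda, seed = x$seed)
}

#' @export
autoplot.stain_gan_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(data.frame(epoch = h$epoch, loss = h$g_pcc, curve = "train PCC loss"),
              data.frame(epoch = h$epoch, loss = h$val_pcc_loss,
                         curve = "validation PCC loss"))
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = loss, colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "PCC loss", colour = NULL)
}

#' Save / load a training checkpoint
#'
#' Checkpoints are self-contained R objects (parameters, configs, history,
#' seed); inference from a reloaded checkpoint is deterministic.
#'
#' @param fit a `stain_gan_fit`.
#' @param path destination file.
#' @return `path` / the restored fit.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "stain_gan_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    vs_error("vistain_io_error", sprintf("checkpoint not found: %s", path))
  fit <- readRDS(path)
  if (!inherits(fit, "stain_gan_fit"))
    vs_error("vistain_value_error", "file is not a stain_gan_fit checkpoint")
  fit
}

# ---- inference -------------------------------------------------------------

#' Virtually stain a single RI slice
#'
#' Tiles the slice into overlapping patches, runs the generator on each and
#' feather-stitches the predictions back. With `mask_background = TRUE`,
#' pixels whose RI lies within `mask_delta` of `background_ri` (the mounting
#' medium) are set to white, masking non-sample regions.
#'
#' @param fit trained `stain_gan_fit` (or checkpoint path).
#' @param ri 2-D RI matrix.
#' @param patch_size inference patch side; defaults to the whole image when
#'   compatible with the network depth.
#' @param overlap fractional patch overlap (default 0.5).
#' @param mask_background,background_ri,mask_delta non-sample masking.
#' @return `(y, x, 3)` integer RGB array.
#' @export
predict_slide <- function(fit, ri, patch_size = NULL, overlap = 0.5,
                          mask_background = FALSE, background_ri = 1.495,
                          mask_delta = 0.003) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  stopifnot(inherits(fit, "stain_gan_fit"))
  G <- fit$generator
  div <- 2^(G$cfg$n_stages - 1)
  patch_size <- patch_size %||% min(dim(ri))
  if (patch_size %% div != 0)
    vs_error("vistain_value_error",
             sprintf("patch size %d incompatible with network depth (needs multiple of %d)",
                     patch_size, div))
  x <- normalize_ri(ri, fit$train_config$ri_range)
  if (all(dim(ri) == patch_size)) {
    out <- gen_forward(G, x)$y
  } else {
    tl <- tile(x, patch_size, overlap)
    preds <- lapply(tl$patches, function(p) gen_forward(G, p)$y)
    out <- stitch(preds, tl$grid)
  }
  rgb <- denormalize_rgb(out)
  if (mask_background) {
    bg <- abs(ri - background_ri) <= mask_delta
    for (c in 1:3) { pl <- rgb[, , c]; pl[bg] <- 255L; rgb[, , c] <- pl }
  }
  rgb
}

#' Virtually stain a 3-D RI volume slice by slice
#'
#' Each axial slice is tiled, inferred and stitched independently (the
#' network is 2-D); the result is an RGB volume. Single-slice volumes give
#' exactly the 2-D prediction of that slice.
#'
#' @inheritParams predict_slide
#' @param ri_volume `(z, y, x)` RI array.
#' @return `(z, y, x, 3)` integer RGB array.
#' @export
predict_volume <- function(fit, ri_volume, patch_size = NULL, overlap = 0.5,
                           mask_background = FALSE, background_ri = 1.495,
                           mask_delta = 0.003) {
  stopifnot(length(dim(ri_volume)) == 3)
  Z <- dim(ri_volume)[1]
  out <- array(0L, c(Z, dim(ri_volume)[2], dim(ri_volume)[3], 3))
  for (z in seq_len(Z))
    out[z, , , ] <- predict_slide(fit, ri_volume[z, , ], patch_size, overlap,
                                  mask_background, background_ri, mask_delta)
  out
}
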