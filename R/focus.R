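# All-in-focus compositing of a focal stack by windowed normalized variance.

#' Normalized variance focus score
#'
#' The classic autofocus metric: population variance of the window divided by
#' its mean. Dimensionless and non-negative; invariant in argmax to positive
#' rescaling of the whole stack (the score scales linearly with intensity).
#'
#' @param x numeric vector/matrix of window values; finite, mean > 0.
#' @return scalar score.
#' @export
normalized_variance <- function(x) {
  x <- as.numeric(x)
  if (!length(x) || any(!is.finite(x)))
    vs_error("vistain_value_error", "window must be non-empty and finite")
  m <- mean(x)
  if (m <= 0)
    vs_error("vistain_value_error",
             "normalized variance undefined for non-positive window mean")
  mean((x - m)^2) / m
}

# summed-area table with zero padding row/col: P[i+1, j+1] = sum(sl[1:i, 1:j])
sat <- function(sl) {
  P <- matrix(0, nrow(sl) + 1, ncol(sl) + 1)
  P[-1, -1] <- t(apply(apply(sl, 2, cumsum), 1, cumsum))
  P
}

#' All-in-focus composite of an RI stack
#'
#' Slides a square vignette over the image on a regular step grid; in each
#' vignette position the slice maximizing the normalized variance is selected
#' as the best focal plane (ties broken toward the lowest slice index). The
#' window-grid focus map is upsampled to pixels by nearest window centre, and
#' the composite takes each pixel from its selected slice. Border pixels
#' beyond the last full vignette inherit the nearest valid window's index.
#'
#' @param volume `(z, y, x)` numeric array with positive values (RI data).
#' @param vignette square window size in pixels (default 100).
#' @param step grid step between window anchors in pixels (default 10).
#' @return list with `composite` (matrix), `focus_map` (per-pixel 0-based
#'   slice indices), `window_index` (grid matrix of selected slices) and
#'   `anchors` (0-based y/x anchor vectors).
#' @export
all_in_focus <- function(volume, vignette = 100L, step = 10L) {
  stopifnot(length(dim(volume)) == 3)
  Z <- dim(volume)[1]; H <- dim(volume)[2]; W <- dim(volume)[3]
  if (vignette > H || vignette > W)
    vs_error("vistain_value_error", "vignette larger than image extent")
  if (Z == 1)
    return(list(composite = volume[1, , ],
                focus_map = matrix(0L, H, W),
                window_index = matrix(0L, 1, 1), anchors = list(y = 0L, x = 0L)))
  ay <- seq(0L, H - vignette, by = step)          # 0-based anchors
  ax <- seq(0L, W - vignette, by = step)
  v <- vignette
  npx <- v * v
  best <- matrix(1L, length(ay), length(ax))
  best_score <- matrix(-Inf, length(ay), length(ax))
  for (z in seq_len(Z)) {
    sl <- volume[z, , ]
    P1 <- sat(sl); P2 <- sat(sl * sl)
    wsum <- function(P) {
      P[ay + v + 1, ax + v + 1, drop = FALSE] + P[ay + 1, ax + 1, drop = FALSE] -
        P[ay + v + 1, ax + 1, drop = FALSE] - P[ay + 1, ax + v + 1, drop = FALSE]
    }
    s1 <- wsum(P1); s2 <- wsum(P2)
    mu <- s1 / npx
    if (any(mu <= 0))
      vs_error("vistain_value_error",
               "non-positive window mean; normalized variance undefined")
    sc <- (s2 / npx - mu^2) / mu
    upd <- sc > best_score                        # strict: ties keep low z
    best[upd] <- z
    best_score[upd] <- sc[upd]
  }
  centers_y <- ay + (v - 1) / 2
  centers_x <- ax + (v - 1) / 2
  near <- function(p, centers, stepw) {
    k <- round((p - centers[1]) / stepw) + 1
    as.integer(clamp(k, 1, length(centers)))
  }
  ky <- near(seq_len(H) - 1, centers_y, step)
  kx <- near(seq_len(W) - 1, centers_x, step)
  zmap <- best[ky, kx, drop = FALSE]
  idx <- cbind(as.integer(zmap), rep(seq_len(H), W), rep(seq_len(W), each = H))
  composite <- matrix(volume[idx], H, W)
  list(composite = composite, focus_map = zmap - 1L,
       window_index = best - 1L, anchors = list(y = ay, x = ax))
}
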