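# Shared fixtures and independent brute-force oracles.

tiny_net_cfg <- function() {
  network_config(channels_per_level = c(4L, 8L, 16L, 32L),
                 n_residual_blocks = 2L,
                 head_hidden_width = 16L,
                 representation_dim = 32L)
}

# Tiny configuration used for the end-to-end smoke training (~110k params).
smoke_net_cfg <- function() {
  network_config(channels_per_level = c(6L, 12L, 24L, 48L),
                 n_residual_blocks = 2L,
                 head_hidden_width = 32L,
                 representation_dim = 64L)
}

# Hole filling by flood fill: background reachable from the image border
# stays background, unreachable background (holes) becomes foreground.
oracle_fill_holes <- function(b) {
  H <- nrow(b); W <- ncol(b)
  reach <- matrix(FALSE, H, W)
  queue <- integer(0)
  push <- function(i, j) {
    if (i >= 1 && i <= H && j >= 1 && j <= W && !reach[i, j] && b[i, j] == 0L) {
      reach[i, j] <<- TRUE
      queue <<- c(queue, (j - 1L) * H + i)
    }
  }
  for (i in 1:H) { push(i, 1L); push(i, W) }
  for (j in 1:W) { push(1L, j); push(H, j) }
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    i <- (k - 1L) %% H + 1L; j <- (k - 1L) %/% H + 1L
    push(i - 1L, j); push(i + 1L, j); push(i, j - 1L); push(i, j + 1L)
  }
  matrix(as.integer(b == 1L | !reach), H, W)
}

# 3x3 erosion/dilation by direct enumeration. Out-of-bounds pixels count as
# foreground for erosion (replicated border) and as background for dilation,
# the convention of the morphology backend.
oracle_erode3 <- function(b) {
  H <- nrow(b); W <- ncol(b); r <- matrix(0L, H, W)
  for (i in 1:H) for (j in 1:W) {
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      inb <- ii >= 1 && ii <= H && jj >= 1 && jj <= W
      if (inb && b[ii, jj] == 0L) ok <- FALSE
    }
    r[i, j] <- as.integer(ok && b[i, j] == 1L)
  }
  r
}

oracle_dilate3 <- function(b) {
  H <- nrow(b); W <- ncol(b); r <- matrix(0L, H, W)
  for (i in 1:H) for (j in 1:W) {
    any1 <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && b[ii, jj] == 1L) any1 <- TRUE
    }
    r[i, j] <- as.integer(any1)
  }
  r
}

oracle_opening3 <- function(b) oracle_dilate3(oracle_erode3(b))

# Windowed local mean by direct enumeration (window cropped at the edges).
oracle_local_mean <- function(x, b) {
  H <- nrow(x); W <- ncol(x); r <- (b - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    out[i, j] <- mean(x[max(1, i - r):min(H, i + r), max(1, j - r):min(W, j + r)])
  }
  out
}

mean_iou_on <- function(net, patches, morph_par = morph_params(),
                        patch_size = 48L) {
  mean(vapply(patches, function(lp) {
    w <- segment_image(lp$image, net, morph_par, patch_size = patch_size)
    v <- seg_metrics(confusion_counts(w, lp$border_mask))$iou
    if (is.na(v)) 0 else v
  }, 0))
}
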