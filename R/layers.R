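# Minimal CPU neural-network layer framework with hand-written backpropagation.
#
# Tensors are numeric arrays of dim c(H, W, C) (column-major); vectors are plain
# numeric vectors. Each layer is an environment holding parameters ($par),
# accumulated gradients ($grad) and Adam state. Forward passes are functional:
# they return list(out, cache) so two Siamese passes through the SAME layers can
# coexist; backward passes consume the cache and accumulate into $grad.
# Convolutions are computed as im2col + BLAS matrix multiply, with the unfolding
# index matrices memoised per input geometry.

.idx_cache <- new.env(parent = emptyenv())

.conv_index <- function(H, W, C, k, s, p) {
  key <- paste(H, W, C, k, s, p, sep = "x")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  # rows of the unfolded matrix run over output pixels, column-major in (Ho, Wo)
  base_r <- rep.int((seq_len(Ho) - 1L) * s, Wo)
  base_c <- rep((seq_len(Wo) - 1L) * s, each = Ho)
  dr <- rep.int(seq_len(k), k * C)
  dc <- rep(rep(seq_len(k), each = k), C)
  ch <- rep(seq_len(C), each = k * k)
  off <- dr + (dc - 1L) * Hp + (ch - 1L) * (Hp * Wp)
  idx <- outer(base_r + base_c * Hp, off, "+")
  # scatter plan for the backward pass: positions sorted by target element,
  # so gradient accumulation is a cumsum segment sum instead of a re-sort
  ord <- order(c(idx))
  sorted <- c(idx)[ord]
  ends <- which(c(sorted[-1] != sorted[-length(sorted)], TRUE))
  geom <- list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = idx,
               ord = ord, ends = ends, targets = sorted[ends])
  .idx_cache[[key]] <- geom
  geom
}

.pad3 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  xp
}

new_layer <- function(type, par = list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- par
  e$grad <- lapply(par, function(a) array(0, dim(a) %||% length(a)))
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

he_init <- function(fan_in, n) {
  stats::rnorm(n, 0, sqrt(2 / fan_in))
}

layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  W <- matrix(he_init(k * k * cin, k * k * cin * cout), k * k * cin, cout)
  new_layer("conv", list(W = W, b = numeric(cout)),
            list(cin = cin, cout = cout, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad)))
}

# 2x2-kernel stride-2 transposed convolution: each output pixel receives exactly
# one kernel tap, so forward is a single matmul plus an interleaved scatter.
layer_convt2 <- function(cin, cout) {
  W <- matrix(he_init(cin, cin * 4L * cout), cin, 4L * cout)
  new_layer("convt2", list(W = W, b = numeric(cout)),
            list(cin = cin, cout = cout))
}

# Per-sample per-channel normalization with learned affine (instance norm).
layer_cnorm <- function(C, eps = 1e-5) {
  new_layer("cnorm", list(gamma = rep(1, C), beta = numeric(C)),
            list(C = C, eps = eps))
}

layer_relu <- function() new_layer("relu")
layer_sigmoid <- function() new_layer("sigmoid")
layer_gap <- function() new_layer("gap")

layer_dense <- function(n_in, n_out) {
  W <- matrix(he_init(n_in, n_in * n_out), n_in, n_out)
  new_layer("dense", list(W = W, b = numeric(n_out)),
            list(n_in = n_in, n_out = n_out))
}

layer_res <- function(C) {
  new_layer("res", list(),
            list(conv1 = layer_conv(C, C), n1 = layer_cnorm(C),
                 conv2 = layer_conv(C, C), n2 = layer_cnorm(C)))
}

layer_forward <- function(l, x) {
  switch(l$type,
    conv = {
      d <- dim(x)
      stopifnot(length(d) == 3L, d[3] == l$cin)
      g <- .conv_index(d[1], d[2], d[3], l$k, l$stride, l$pad)
      xp <- .pad3(x, l$pad)
      col <- matrix(xp[c(g$idx)], nrow = g$Ho * g$Wo)
      out <- col %*% l$par$W
      out <- out + rep(l$par$b, each = nrow(out))
      list(out = array(out, c(g$Ho, g$Wo, l$cout)),
           cache = list(col = col, g = g, H = d[1], W = d[2]))
    },
    convt2 = {
      d <- dim(x)
      inmat <- matrix(x, d[1] * d[2], d[3])
      om <- inmat %*% l$par$W
      y <- array(0, c(2L * d[1], 2L * d[2], l$cout))
      for (o in 1:4) {
        dr <- (o - 1L) %% 2L
        dc <- (o - 1L) %/% 2L
        cols <- seq.int(o, by = 4L, length.out = l$cout)
        y[seq.int(1L + dr, 2L * d[1], 2L),
          seq.int(1L + dc, 2L * d[2], 2L), ] <- om[, cols]
      }
      y <- y + rep(l$par$b, each = 4L * d[1] * d[2])
      list(out = y, cache = list(inmat = inmat, H = d[1], W = d[2]))
    },
    cnorm = {
      d <- dim(x)
      n <- d[1] * d[2]
      xm <- matrix(x, n, d[3])
      mu <- colMeans(xm)
      xc <- xm - rep(mu, each = n)
      sd_ <- sqrt(colMeans(xc * xc) + l$eps)
      xhat <- xc / rep(sd_, each = n)
      y <- xhat * rep(l$par$gamma, each = n) + rep(l$par$beta, each = n)
      list(out = array(y, d), cache = list(xhat = xhat, sd = sd_, d = d))
    },
    relu = {
      y <- x
      y[y < 0] <- 0
      list(out = y, cache = x)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(out = y, cache = y)
    },
    gap = {
      d <- dim(x)
      list(out = colMeans(matrix(x, d[1] * d[2], d[3])), cache = d)
    },
    dense = {
      list(out = c(x %*% l$par$W) + l$par$b, cache = x)
    },
    res = {
      f1 <- layer_forward(l$conv1, x)
      f2 <- layer_forward(l$n1, f1$out)
      r <- f2$out
      r[r < 0] <- 0
      f3 <- layer_forward(l$conv2, r)
      f4 <- layer_forward(l$n2, f3$out)
      s <- x + f4$out
      y <- s
      y[y < 0] <- 0
      list(out = y,
           cache = list(c1 = f1$cache, c2 = f2$cache, pre1 = f2$out,
                        c3 = f3$cache, c4 = f4$cache, s = s))
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, cache, dy) {
  switch(l$type,
    conv = {
      g <- cache$g
      dmat <- matrix(dy, g$Ho * g$Wo, l$cout)
      l$grad$W <- l$grad$W + crossprod(cache$col, dmat)
      l$grad$b <- l$grad$b + colSums(dmat)
      dcol <- tcrossprod(dmat, l$par$W)
      cs <- cumsum(c(dcol)[g$ord])[g$ends]
      dxp <- numeric(g$Hp * g$Wp * l$cin)
      dxp[g$targets] <- cs - c(0, cs[-length(cs)])
      dim(dxp) <- c(g$Hp, g$Wp, l$cin)
      p <- l$pad
      if (p > 0L) {
        dxp[(p + 1L):(p + cache$H), (p + 1L):(p + cache$W), , drop = FALSE]
      } else dxp
    },
    convt2 = {
      H <- cache$H; W <- cache$W
      dm <- matrix(0, H * W, 4L * l$cout)
      for (o in 1:4) {
        dr <- (o - 1L) %% 2L
        dc <- (o - 1L) %/% 2L
        cols <- seq.int(o, by = 4L, length.out = l$cout)
        dm[, cols] <- dy[seq.int(1L + dr, 2L * H, 2L),
                         seq.int(1L + dc, 2L * W, 2L), ]
      }
      l$grad$W <- l$grad$W + crossprod(cache$inmat, dm)
      l$grad$b <- l$grad$b + colSums(matrix(dy, 4L * H * W, l$cout))
      dx <- tcrossprod(dm, l$par$W)
      array(dx, c(H, W, l$cin))
    },
    cnorm = {
      d <- cache$d
      n <- d[1] * d[2]
      dym <- matrix(dy, n, d[3])
      l$grad$gamma <- l$grad$gamma + colSums(dym * cache$xhat)
      l$grad$beta <- l$grad$beta + colSums(dym)
      dxhat <- dym * rep(l$par$gamma, each = n)
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cache$xhat)
      dx <- (dxhat - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) /
        rep(cache$sd, each = n)
      array(dx, d)
    },
    relu = {
      dx <- dy
      dx[cache <= 0] <- 0
      dx
    },
    sigmoid = {
      dy * cache * (1 - cache)
    },
    gap = {
      n <- cache[1] * cache[2]
      array(rep(dy / n, each = n), cache)
    },
    dense = {
      l$grad$W <- l$grad$W + outer(c(cache), dy)
      l$grad$b <- l$grad$b + dy
      c(l$par$W %*% dy)
    },
    res = {
      ds <- dy
      ds[cache$s <= 0] <- 0
      dbr <- layer_backward(l$n2, cache$c4, ds)
      dbr <- layer_backward(l$conv2, cache$c3, dbr)
      dbr[cache$pre1 <= 0] <- 0
      dbr <- layer_backward(l$n1, cache$c2, dbr)
      dbr <- layer_backward(l$conv1, cache$c1, dbr)
      ds + dbr
    },
    stop("unknown layer type: ", l$type)
  )
}

chain_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- layer_forward(layers[[i]], x)
    x <- f$out
    caches[[i]] <- f$cache
  }
  list(out = x, caches = caches)
}

chain_backward <- function(layers, caches, dy) {
  for (i in rev(seq_along(layers))) {
    dy <- layer_backward(layers[[i]], caches[[i]], dy)
  }
  dy
}

# -- parameter bookkeeping ----------------------------------------------------

.flatten_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "res") {
      out <- c(out, list(l$conv1, l$n1, l$conv2, l$n2))
    } else if (length(l$par)) {
      out <- c(out, list(l))
    }
  }
  out
}

zero_grads <- function(layers) {
  for (l in layers) {
    for (nm in names(l$grad)) l$grad[[nm]][] <- 0
  }
  invisible(NULL)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      grad_scale = 1) {
  for (l in layers) {
    if (is.null(l$adam_m)) {
      l$adam_m <- lapply(l$par, function(a) a * 0)
      l$adam_v <- lapply(l$par, function(a) a * 0)
    }
    for (nm in names(l$par)) {
      g <- l$grad[[nm]] * grad_scale
      l$adam_m[[nm]] <- beta1 * l$adam_m[[nm]] + (1 - beta1) * g
      l$adam_v[[nm]] <- beta2 * l$adam_v[[nm]] + (1 - beta2) * g * g
      mh <- l$adam_m[[nm]] / (1 - beta1^t)
      vh <- l$adam_v[[nm]] / (1 - beta2^t)
      l$par[[nm]] <- l$par[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  invisible(NULL)
}

sgd_step <- function(layers, lr, grad_scale = 1) {
  for (l in layers) {
    for (nm in names(l$par)) {
      l$par[[nm]] <- l$par[[nm]] - lr * l$grad[[nm]] * grad_scale
    }
  }
  invisible(NULL)
}

n_parameters <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$par, length, 1L)), 1))
}
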