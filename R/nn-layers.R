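# Layer primitives built on the tape engine: dense, 1-D/2-D convolution
# (as primitives with internal im2col), pooling, nearest upsampling, and a
# GRU cell. Activation arrays are (batch, time, channels) for 1-D and
# (batch, height, width, channels) for 2-D layers.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

init_dense <- function(n_in, n_out)
  list(W = new_param(glorot(n_in, n_out)),
       b = new_param(matrix(0, 1, n_out)))

apply_dense <- function(tape, x, layer)
  nd_add(nd_matmul(x, nd_param(tape, layer$W)),
         nd_param(tape, layer$b))

layer_params <- function(layers)
  unlist(lapply(layers, function(l)
    Filter(function(e) is.environment(e) && !is.null(e$value), l)),
    use.names = FALSE)

## ---- 1-D convolution ------------------------------------------------------

init_conv1d <- function(k, c_in, c_out)
  list(W = new_param(glorot(k * c_in, c_out)),
       b = new_param(matrix(0, 1, c_out)), k = k,
       c_in = c_in, c_out = c_out, cache = new.env(parent = emptyenv()))

# Row-index maps for the matrix-form im2col of a (B, T, C) array whose
# (b, t) pair lives at row b + (t - 1) B; cached per input length.
conv1d_maps <- function(layer, B, T_in, stride) {
  key <- sprintf("%d_%d_%d", B, T_in, stride)
  mp <- layer$cache[[key]]
  if (!is.null(mp)) return(mp)
  k <- layer$k; pad <- k %/% 2L
  T_out <- (T_in + 2L * pad - k) %/% stride + 1L
  bs <- seq_len(B)
  taps <- lapply(seq_len(k), function(kk) {
    p <- (seq_len(T_out) - 1L) * stride + kk - pad
    ok <- p >= 1L & p <= T_in
    list(rows_in = as.vector(outer(bs, (p[ok] - 1L) * B, "+")),
         rows_out = as.vector(outer(bs, (which(ok) - 1L) * B, "+")))
  })
  mp <- list(T_out = T_out, taps = taps)
  layer$cache[[key]] <- mp
  mp
}

# x: (B, T, C) node; "same"-style padding pad = floor(k/2).
nd_conv1d <- function(tape, x, layer, stride = 1L) {
  v <- x$value
  d <- dim(v); B <- d[1]; T_in <- d[2]; C <- d[3]
  k <- layer$k
  mp <- conv1d_maps(layer, B, T_in, stride)
  T_out <- mp$T_out
  Wn <- nd_param(tape, layer$W)
  bn <- nd_param(tape, layer$b)
  Fo <- layer$c_out

  vmat <- v; dim(vmat) <- c(B * T_in, C)
  xmat <- matrix(0, B * T_out, k * C)
  for (kk in seq_len(k)) {
    tp <- mp$taps[[kk]]
    if (length(tp$rows_out))
      xmat[tp$rows_out, ((kk - 1L) * C + 1L):(kk * C)] <-
        vmat[tp$rows_in, , drop = FALSE]
  }
  y <- xmat %*% layer$W$value
  y <- y + rep(as.numeric(layer$b$value), each = B * T_out)
  dim(y) <- c(B, T_out, Fo)

  nd_node(tape, y, function(g) {
    dim(g) <- c(B * T_out, Fo)
    nd_accum(Wn, crossprod(xmat, g))
    nd_accum(bn, matrix(colSums(g), 1L))
    gcol <- tcrossprod(g, layer$W$value)    # (B*T_out, k*C)
    gx <- matrix(0, B * T_in, C)
    for (kk in seq_len(k)) {
      tp <- mp$taps[[kk]]
      if (length(tp$rows_out))
        gx[tp$rows_in, ] <- gx[tp$rows_in, , drop = FALSE] +
          gcol[tp$rows_out, ((kk - 1L) * C + 1L):(kk * C), drop = FALSE]
    }
    dim(gx) <- c(B, T_in, C)
    nd_accum(x, gx)
  })
}

nd_upsample1d <- function(x) {
  v <- x$value
  d <- dim(v); B <- d[1]; T_in <- d[2]; C <- d[3]
  idx <- rep(seq_len(T_in), each = 2L)
  y <- v[, idx, , drop = FALSE]
  nd_node(x$tape, y, function(g) {
    gx <- g[, seq(1L, 2L * T_in, by = 2L), , drop = FALSE] +
      g[, seq(2L, 2L * T_in, by = 2L), , drop = FALSE]
    nd_accum(x, gx)
  })
}

## ---- 2-D convolution ------------------------------------------------------

init_conv2d <- function(k, c_in, c_out)
  list(W = new_param(glorot(k * k * c_in, c_out)),
       b = new_param(matrix(0, 1, c_out)), k = k,
       c_in = c_in, c_out = c_out, cache = new.env(parent = emptyenv()))

conv2d_maps <- function(layer, B, H, W_) {
  key <- sprintf("%d_%d_%d", B, H, W_)
  mp <- layer$cache[[key]]
  if (!is.null(mp)) return(mp)
  k <- layer$k; pad <- k %/% 2L
  grid_h <- rep(seq_len(H), times = W_)
  grid_w <- rep(seq_len(W_), each = H)
  bs <- seq_len(B)
  taps <- list()
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    hi <- grid_h + kh - 1L - pad
    wi <- grid_w + kw - 1L - pad
    ok <- hi >= 1L & hi <= H & wi >= 1L & wi <= W_
    s_in <- hi[ok] + (wi[ok] - 1L) * H
    s_out <- which(ok)
    taps[[length(taps) + 1L]] <-
      list(rows_in = as.vector(outer(bs, (s_in - 1L) * B, "+")),
           rows_out = as.vector(outer(bs, (s_out - 1L) * B, "+")))
  }
  mp <- list(taps = taps)
  layer$cache[[key]] <- mp
  mp
}

# x: (B, H, W, C) node; stride 1, "same" padding.
nd_conv2d <- function(tape, x, layer) {
  v <- x$value
  d <- dim(v); B <- d[1]; H <- d[2]; W_ <- d[3]; C <- d[4]
  k <- layer$k
  Fo <- layer$c_out
  S <- H * W_
  mp <- conv2d_maps(layer, B, H, W_)

  vmat <- v; dim(vmat) <- c(B * S, C)
  xmat <- matrix(0, B * S, k * k * C)
  for (ti in seq_along(mp$taps)) {
    tp <- mp$taps[[ti]]
    xmat[tp$rows_out, ((ti - 1L) * C + 1L):(ti * C)] <-
      vmat[tp$rows_in, , drop = FALSE]
  }
  Wn <- nd_param(tape, layer$W)
  bn <- nd_param(tape, layer$b)
  y <- xmat %*% layer$W$value
  y <- y + rep(as.numeric(layer$b$value), each = B * S)
  dim(y) <- c(B, H, W_, Fo)

  nd_node(tape, y, function(g) {
    dim(g) <- c(B * S, Fo)
    nd_accum(Wn, crossprod(xmat, g))
    nd_accum(bn, matrix(colSums(g), 1L))
    gcol <- tcrossprod(g, layer$W$value)
    gx <- matrix(0, B * S, C)
    for (ti in seq_along(mp$taps)) {
      tp <- mp$taps[[ti]]
      gx[tp$rows_in, ] <- gx[tp$rows_in, , drop = FALSE] +
        gcol[tp$rows_out, ((ti - 1L) * C + 1L):(ti * C), drop = FALSE]
    }
    dim(gx) <- c(B, H, W_, C)
    nd_accum(x, gx)
  })
}

nd_maxpool2d <- function(x) {
  v <- x$value
  d <- dim(v); B <- d[1]; H <- d[2]; W_ <- d[3]; C <- d[4]
  Ho <- H %/% 2L; Wo <- W_ %/% 2L
  i1 <- seq(1L, 2L * Ho, by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * Wo, by = 2L); j2 <- j1 + 1L
  a <- list(v[, i1, j1, , drop = FALSE], v[, i2, j1, , drop = FALSE],
            v[, i1, j2, , drop = FALSE], v[, i2, j2, , drop = FALSE])
  y <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  taken <- array(FALSE, dim(y))
  masks <- lapply(a, function(ai) {
    m <- (ai == y) & !taken
    taken <<- taken | m
    m
  })
  ii <- list(list(i1, j1), list(i2, j1), list(i1, j2), list(i2, j2))
  nd_node(x$tape, y, function(g) {
    gx <- array(0, dim(v))
    for (q in 1:4)
      gx[, ii[[q]][[1]], ii[[q]][[2]], ] <- g * masks[[q]]
    nd_accum(x, gx)
  })
}

nd_upsample2d <- function(x) {
  v <- x$value
  d <- dim(v); B <- d[1]; H <- d[2]; W_ <- d[3]; C <- d[4]
  ih <- rep(seq_len(H), each = 2L)
  iw <- rep(seq_len(W_), each = 2L)
  y <- v[, ih, iw, , drop = FALSE]
  nd_node(x$tape, y, function(g) {
    o1 <- seq(1L, 2L * H, by = 2L); o2 <- o1 + 1L
    p1 <- seq(1L, 2L * W_, by = 2L); p2 <- p1 + 1L
    gx <- g[, o1, p1, , drop = FALSE] + g[, o2, p1, , drop = FALSE] +
      g[, o1, p2, , drop = FALSE] + g[, o2, p2, , drop = FALSE]
    nd_accum(x, gx)
  })
}

## ---- GRU cell -------------------------------------------------------------

init_gru <- function(n_in, n_h) {
  mk <- function(a, b) new_param(glorot(a, b))
  list(Wxz = mk(n_in, n_h), Whz = mk(n_h, n_h), bz = new_param(matrix(0, 1, n_h)),
       Wxr = mk(n_in, n_h), Whr = mk(n_h, n_h), br = new_param(matrix(0, 1, n_h)),
       Wxn = mk(n_in, n_h), Whn = mk(n_h, n_h), bn = new_param(matrix(0, 1, n_h)),
       n_h = n_h)
}

# One GRU step; x, h are (B, n) nodes. h' = n + z * (h - n).
gru_step <- function(tape, x, h, cell) {
  lin <- function(Wx, Wh, b)
    nd_add(nd_add(nd_matmul(x, nd_param(tape, Wx)),
                  nd_matmul(h, nd_param(tape, Wh))),
           nd_param(tape, b))
  z <- nd_sigmoid(lin(cell$Wxz, cell$Whz, cell$bz))
  r <- nd_sigmoid(lin(cell$Wxr, cell$Whr, cell$br))
  rh <- nd_mul(r, h)
  n <- nd_tanh(nd_add(nd_add(nd_matmul(x, nd_param(tape, cell$Wxn)),
                             nd_matmul(rh, nd_param(tape, cell$Whn))),
                      nd_param(tape, cell$bn)))
  nd_add(n, nd_mul(z, nd_sub(h, n)))
}
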