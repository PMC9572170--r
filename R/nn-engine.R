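# Minimal reverse-mode automatic differentiation on a tape. Node values
# are numeric vectors/matrices/arrays; each operation records a backward
# closure that accumulates gradients into its parents. The tape's creation
# order is a topological order, so backpropagation is a single reverse
# sweep. This is deliberately small: just the operations the autoencoder
# architectures in this package need.

nn_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

nd_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  nd$tape <- tape
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

nd_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

nd_const <- function(tape, value) nd_node(tape, value)

# Leaf bound to a persistent parameter environment (fields value, grad).
nd_param <- function(tape, p) {
  nd <- nd_node(tape, p$value)
  nd$param <- p
  nd
}

# Reverse sweep from a scalar loss node; copies leaf gradients back into
# their parameter environments.
nn_backward <- function(loss) {
  tape <- loss$tape
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad)) {
      if (!is.null(nd$backward)) nd$backward(nd$grad)
      if (!is.null(nd$param))
        nd$param$grad <- if (is.null(nd$param$grad)) nd$grad
                         else nd$param$grad + nd$grad
    }
  }
  invisible(NULL)
}

## ---- arithmetic -----------------------------------------------------------

nd_add <- function(a, b) {
  va <- a$value; vb <- b$value
  if (identical(dim(va), dim(vb)) || is.null(dim(va)))
    nd_node(a$tape, va + vb, function(g) { nd_accum(a, g); nd_accum(b, g) })
  else if (is.matrix(va) && is.matrix(vb) && nrow(vb) == 1L)
    # matrix + broadcast row (bias)
    nd_node(a$tape, sweep(va, 2, as.numeric(vb), "+"), function(g) {
      nd_accum(a, g)
      nd_accum(b, matrix(colSums(g), 1L))
    })
  else stop("nd_add: incompatible shapes")
}

nd_sub <- function(a, b)
  nd_node(a$tape, a$value - b$value,
          function(g) { nd_accum(a, g); nd_accum(b, -g) })

nd_mul <- function(a, b)
  nd_node(a$tape, a$value * b$value, function(g) {
    nd_accum(a, g * b$value); nd_accum(b, g * a$value)
  })

nd_scale <- function(a, k)
  nd_node(a$tape, a$value * k, function(g) nd_accum(a, g * k))

nd_matmul <- function(a, b)
  nd_node(a$tape, a$value %*% b$value, function(g) {
    nd_accum(a, tcrossprod(g, b$value))
    nd_accum(b, crossprod(a$value, g))
  })

nd_transpose <- function(a)
  nd_node(a$tape, t(a$value), function(g) nd_accum(a, t(g)))

nd_reshape <- function(a, dims) {
  old <- dim(a$value) %||% length(a$value)
  v <- a$value
  dim(v) <- dims
  nd_node(a$tape, v, function(g) { dim(g) <- old; nd_accum(a, g) })
}

## ---- nonlinearities -------------------------------------------------------

nd_relu <- function(a) {
  m <- a$value > 0
  nd_node(a$tape, a$value * m, function(g) nd_accum(a, g * m))
}

nd_leaky_relu <- function(a, slope = 0.01) {
  m <- slope + (1 - slope) * (a$value > 0)
  nd_node(a$tape, a$value * m, function(g) nd_accum(a, g * m))
}

nd_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  nd_node(a$tape, y, function(g) nd_accum(a, g * y * (1 - y)))
}

nd_tanh <- function(a) {
  y <- tanh(a$value)
  nd_node(a$tape, y, function(g) nd_accum(a, g * (1 - y^2)))
}

nd_exp <- function(a) {
  y <- exp(a$value)
  nd_node(a$tape, y, function(g) nd_accum(a, g * y))
}

nd_square <- function(a)
  nd_node(a$tape, a$value^2, function(g) nd_accum(a, 2 * g * a$value))

nd_dropout <- function(a, rate, training) {
  if (!training || rate <= 0) return(a)
  mask <- (runif(length(a$value)) >= rate) / (1 - rate)
  dim(mask) <- dim(a$value)
  nd_node(a$tape, a$value * mask, function(g) nd_accum(a, g * mask))
}

# Row-wise softmax on a matrix.
nd_softmax_rows <- function(a) {
  v <- a$value
  v <- v - apply(v, 1, max)
  e <- exp(v)
  y <- e / rowSums(e)
  nd_node(a$tape, y, function(g) {
    dot <- rowSums(g * y)
    nd_accum(a, (g - dot) * y)
  })
}

## ---- reductions and losses ------------------------------------------------

nd_sum <- function(a)
  nd_node(a$tape, sum(a$value), function(g) {
    gr <- array(g, dim(a$value) %||% length(a$value))
    nd_accum(a, gr)
  })

nd_mean <- function(a) {
  n <- length(a$value)
  nd_node(a$tape, mean(a$value), function(g) {
    gr <- array(g / n, dim(a$value) %||% length(a$value))
    nd_accum(a, gr)
  })
}

# Mean squared error against a constant target.
nd_mse <- function(a, target) {
  diffv <- a$value - target
  n <- length(diffv)
  nd_node(a$tape, sum(diffv^2) / n,
          function(g) nd_accum(a, g * 2 * diffv / n))
}

## ---- normalization --------------------------------------------------------

# Layer normalization over the columns of each row, with affine gain/bias
# parameter nodes (row vectors).
nd_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  v <- a$value
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gm <- as.numeric(gamma$value)
  y <- sweep(xhat, 2, gm, "*")
  y <- sweep(y, 2, as.numeric(beta$value), "+")
  nd_node(a$tape, y, function(g) {
    nd_accum(gamma, matrix(colSums(g * xhat), 1L))
    nd_accum(beta, matrix(colSums(g), 1L))
    gg <- sweep(g, 2, gm, "*")
    m1 <- rowMeans(gg)
    m2 <- rowMeans(gg * xhat)
    nd_accum(a, inv * (gg - m1 - xhat * m2))
  })
}

# Batch normalization over all but the channel (last) axis of an array,
# with running statistics kept in the layer environment `st`.
nd_batchnorm <- function(a, gamma, beta, st, training, eps = 1e-5,
                         momentum = 0.1) {
  v <- a$value
  dims <- dim(v)
  C <- dims[length(dims)]
  m <- matrix(v, ncol = C)      # rows = all positions, cols = channels
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(sweep(m, 2, mu)^2)
    if (is.null(st$mu)) { st$mu <- mu; st$va <- va }
    else {
      st$mu <- (1 - momentum) * st$mu + momentum * mu
      st$va <- (1 - momentum) * st$va + momentum * va
    }
  } else {
    mu <- st$mu %||% colMeans(m)
    va <- st$va %||% colMeans(sweep(m, 2, mu)^2)
  }
  n <- nrow(m)
  ex <- function(v) rep(v, each = n)       # broadcast per-channel vector
  inv <- 1 / sqrt(va + eps)
  xhat <- (m - ex(mu)) * ex(inv)
  gm <- as.numeric(gamma$value)
  y <- xhat * ex(gm) + ex(as.numeric(beta$value))
  dim(y) <- dims
  nd_node(a$tape, y, function(g) {
    gmat <- g; dim(gmat) <- c(n, C)
    nd_accum(gamma, matrix(colSums(gmat * xhat), 1L))
    nd_accum(beta, matrix(colSums(gmat), 1L))
    gg <- gmat * ex(gm)
    dx <- if (training)
      (gg - ex(colMeans(gg)) - xhat * ex(colMeans(gg * xhat))) * ex(inv)
    else gg * ex(inv)
    dim(dx) <- dims
    nd_accum(a, dx)
  })
}

## ---- optimizers -----------------------------------------------------------

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

make_optimizer <- function(name, params, lr) {
  name <- match.arg(name, c("adam", "rmsprop"))
  step <- 0L
  if (name == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (p in params) { p$m <- 0 * p$value; p$v <- 0 * p$value }
    function() {
      step <<- step + 1L
      for (p in params) {
        if (is.null(p$grad)) next
        p$m <- b1 * p$m + (1 - b1) * p$grad
        p$v <- b2 * p$v + (1 - b2) * p$grad^2
        mh <- p$m / (1 - b1^step)
        vh <- p$v / (1 - b2^step)
        p$value <- p$value - lr * mh / (sqrt(vh) + eps)
      }
    }
  } else {
    alpha <- 0.99; eps <- 1e-8
    for (p in params) p$v <- 0 * p$value
    function() {
      step <<- step + 1L
      for (p in params) {
        if (is.null(p$grad)) next
        p$v <- alpha * p$v + (1 - alpha) * p$grad^2
        p$value <- p$value - lr * p$grad / (sqrt(p$v) + eps)
      }
    }
  }
}
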