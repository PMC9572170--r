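# Autoencoder architectures. Sequence models consume (batch, time,
# feature) tensors of day-tensor sub-sequences; the spectrogram models
# consume (batch, 128, 64, 1) slices; the 1-D CVAE consumes (batch, 30, 5)
# hourly HRV tensors.

## extra tape primitives used by the recurrent/attention models ------------

nd_rows <- function(a, idx) {
  v <- a$value[idx, , drop = FALSE]
  nd_node(a$tape, v, function(g) {
    gx <- matrix(0, nrow(a$value), ncol(a$value))
    gx[idx, ] <- g
    nd_accum(a, gx)
  })
}

nd_assemble_rows <- function(tape, nodes, idx_list, total_rows) {
  nc <- ncol(nodes[[1]]$value)
  v <- matrix(0, total_rows, nc)
  for (i in seq_along(nodes)) v[idx_list[[i]], ] <- nodes[[i]]$value
  nd_node(tape, v, function(g) {
    for (i in seq_along(nodes))
      nd_accum(nodes[[i]], g[idx_list[[i]], , drop = FALSE])
  })
}

nd_rowsums <- function(a)
  nd_node(a$tape, matrix(rowSums(a$value), ncol = 1), function(g)
    nd_accum(a, matrix(as.numeric(g), nrow(a$value), ncol(a$value))))

nd_concat_cols <- function(tape, nodes) {
  v <- do.call(cbind, lapply(nodes, `[[`, "value"))
  nd_node(tape, v, function(g) {
    at <- 0L
    for (nd in nodes) {
      w <- ncol(nd$value)
      nd_accum(nd, g[, (at + 1L):(at + w), drop = FALSE])
      at <- at + w
    }
  })
}

nd_col <- function(a, j)
  nd_node(a$tape, a$value[, j, drop = FALSE], function(g) {
    gx <- matrix(0, nrow(a$value), ncol(a$value))
    gx[, j] <- g
    nd_accum(a, gx)
  })

nd_mul_colvec <- function(a, cv) {
  cvv <- as.numeric(cv$value)
  nd_node(a$tape, a$value * cvv, function(g) {
    nd_accum(a, g * cvv)
    nd_accum(cv, matrix(rowSums(g * a$value), ncol = 1))
  })
}

# stack a list of (B, D) nodes into (B, T, D)
nd_stack_time <- function(tape, nodes) {
  B <- nrow(nodes[[1]]$value); D <- ncol(nodes[[1]]$value)
  T_ <- length(nodes)
  v <- array(0, c(B, T_, D))
  for (t in seq_len(T_)) v[, t, ] <- nodes[[t]]$value
  nd_node(tape, v, function(g) {
    for (t in seq_len(T_))
      nd_accum(nodes[[t]], array(g[, t, , drop = FALSE], c(B, D)))
  })
}

nd_time_slice <- function(a, t) {
  d <- dim(a$value)
  v <- array(a$value[, t, , drop = FALSE], c(d[1], d[3]))
  nd_node(a$tape, v, function(g) {
    gx <- array(0, d)
    gx[, t, ] <- g
    nd_accum(a, gx)
  })
}

nd_trim_time <- function(a, T_keep) {
  d <- dim(a$value)
  nd_node(a$tape, a$value[, seq_len(T_keep), , drop = FALSE], function(g) {
    gx <- array(0, d)
    gx[, seq_len(T_keep), ] <- g
    nd_accum(a, gx)
  })
}

## ---- configuration --------------------------------------------------------

#' Architecture width configuration
#'
#' Hidden widths, filter counts and kernel sizes of the autoencoders. The
#' GRU hidden size of 100 and the four-block structure of the
#' convolutional models are fixed design points; the rest are free widths.
#'
#' @param fnn_hidden,fnn_latent dense autoencoder widths.
#' @param cnn_filters,cnn_kernel 1-D convolutional encoder filters (4
#'   downsampling blocks) and kernel length.
#' @param gru_hidden GRU hidden units.
#' @param tr_dmodel,tr_layers,tr_ff transformer width, encoder/decoder
#'   depth, and feed-forward width.
#' @param cae_filters,cae_kernel 2-D convolutional encoder filters and
#'   kernel size.
#' @param latent_ch latent channels of the variational models.
#' @param cvae1d_filters 1-D CVAE encoder filters (2 blocks + latent).
#' @param dropout dropout rate of the dense decoder.
#' @return list of class `model_config`.
#' @export
model_config <- function(fnn_hidden = 64L, fnn_latent = 32L,
                         cnn_filters = c(32L, 64L, 128L, 256L),
                         cnn_kernel = 5L, gru_hidden = 100L,
                         tr_dmodel = 32L, tr_layers = 4L, tr_ff = 64L,
                         cae_filters = c(16L, 32L, 64L, 128L),
                         cae_kernel = 3L, latent_ch = 32L,
                         cvae1d_filters = c(16L, 32L),
                         dropout = 0.1) {
  structure(as.list(environment()), class = "model_config")
}

ARCHS <- c("fnn", "cnn", "gru", "transformer", "cae", "cvae", "cvae1d")

#' Training specification
#'
#' Optimization settings per architecture family. Physiological sequence
#' autoencoders train with batch 64 for up to 50 epochs at learning rate
#' 1e-4 (1e-3 for the transformer), Adam for the dense and transformer
#' models and RMSprop for the convolutional and recurrent ones; the
#' spectrogram/HRV-tensor models train with Adam at 3e-4, batch 8, up to
#' 200 epochs with patience 10 and loss weights W_MSE = 1, W_KL = 0.01.
#'
#' @param architecture one of `"fnn"`, `"cnn"`, `"gru"`, `"transformer"`,
#'   `"cae"`, `"cvae"`, `"cvae1d"`.
#' @param optimizer,lr,batch_size,max_epochs,patience,w_mse,w_kl overrides
#'   of the family defaults.
#' @param seed integer seed controlling initialization, batching and
#'   latent sampling.
#' @return list of class `train_spec`.
#' @export
train_spec <- function(architecture, optimizer = NULL, lr = NULL,
                       batch_size = NULL, max_epochs = NULL,
                       patience = NULL, w_mse = 1, w_kl = NULL,
                       seed = 1L) {
  architecture <- match.arg(architecture, ARCHS)
  audio <- architecture %in% c("cae", "cvae", "cvae1d")
  optimizer <- optimizer %||%
    if (audio || architecture %in% c("fnn", "transformer")) "adam"
    else "rmsprop"
  lr <- lr %||% if (audio) 3e-4
    else if (architecture == "transformer") 1e-3 else 1e-4
  batch_size <- batch_size %||% if (audio) 8L else 64L
  max_epochs <- max_epochs %||% if (audio) 200L else 50L
  patience <- patience %||% if (audio) 10L else 5L
  w_kl <- w_kl %||% if (architecture %in% c("cvae", "cvae1d")) 0.01 else 0
  structure(list(architecture = architecture, optimizer = optimizer,
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 w_mse = w_mse, w_kl = w_kl, seed = as.integer(seed)),
            class = "train_spec")
}

#' Build an untrained autoencoder
#'
#' @param spec a [train_spec()].
#' @param input_shape instance shape without the batch axis: `c(T, D)` for
#'   the sequence models, `c(128, 64)` for the spectrogram models,
#'   `c(30, 5)` for the 1-D CVAE.
#' @param config a [model_config()].
#' @return object of class `rk_model` with elements `arch`, `spec`,
#'   `layers`, `params`, `input_shape`, `n_parameters`.
#' @export
build_model <- function(spec, input_shape, config = model_config()) {
  arch <- spec$architecture
  with_seed(spec$seed, {
    layers <- switch(arch,
      fnn = build_fnn(input_shape, config),
      cnn = build_cnn(input_shape, config),
      gru = build_gru_ae(input_shape, config),
      transformer = build_transformer(input_shape, config),
      cae = build_cae(input_shape, config, variational = FALSE),
      cvae = build_cae(input_shape, config, variational = TRUE),
      cvae1d = build_cvae1d(input_shape, config))
    params <- collect_params(layers)
    structure(list(arch = arch, spec = spec, layers = layers,
                   params = params, input_shape = input_shape,
                   config = config,
                   n_parameters = sum(vapply(params, function(p)
                     length(p$value), numeric(1)))),
              class = "rk_model")
  })
}

#' @export
print.rk_model <- function(x, ...) {
  cat(sprintf("<rk_model> %s, input %s, %d parameters\n", x$arch,
              paste(x$input_shape, collapse = "x"), x$n_parameters))
  invisible(x)
}

collect_params <- function(x) {
  if (is.environment(x)) return(if (!is.null(x$value)) list(x) else list())
  if (is.list(x)) return(unlist(lapply(x, collect_params),
                                use.names = FALSE))
  list()
}

## ---- architecture builders ------------------------------------------------

build_fnn <- function(shape, cfg) {
  nin <- prod(shape)
  list(enc1 = init_dense(nin, cfg$fnn_hidden),
       enc2 = init_dense(cfg$fnn_hidden, cfg$fnn_latent),
       dec1 = init_dense(cfg$fnn_latent, cfg$fnn_hidden),
       dec2 = init_dense(cfg$fnn_hidden, nin),
       dropout = cfg$dropout)
}

build_cnn <- function(shape, cfg) {
  T_ <- shape[1]; D <- shape[2]
  if (T_ %% 16L != 0L)
    stop("cnn: sub-sequence length must be divisible by 16", call. = FALSE)
  f <- cfg$cnn_filters; k <- cfg$cnn_kernel
  enc <- list(); cin <- D
  for (i in 1:4) {
    enc[[i]] <- list(conv = init_conv1d(k, cin, f[i]),
                     bn_g = new_param(matrix(1, 1, f[i])),
                     bn_b = new_param(matrix(0, 1, f[i])),
                     bn_st = new.env(parent = emptyenv()))
    cin <- f[i]
  }
  fd <- rev(f)[-1]; fd <- c(fd, fd[length(fd)] %/% 2L)  # e.g. 128,64,32,16
  dec <- list()
  for (i in 1:4) {
    dec[[i]] <- list(conv = init_conv1d(k, cin, fd[i]),
                     bn_g = new_param(matrix(1, 1, fd[i])),
                     bn_b = new_param(matrix(0, 1, fd[i])),
                     bn_st = new.env(parent = emptyenv()))
    cin <- fd[i]
  }
  list(enc = enc, dec = dec, head = init_dense(cin, D))
}

build_gru_ae <- function(shape, cfg) {
  D <- shape[2]
  list(enc = init_gru(D, cfg$gru_hidden),
       dec = init_gru(cfg$gru_hidden, cfg$gru_hidden),
       head = init_dense(cfg$gru_hidden, D))
}

build_transformer <- function(shape, cfg) {
  D <- shape[2]; dm <- cfg$tr_dmodel
  block <- function() list(
    Wq = init_dense(dm, dm), Wk = init_dense(dm, dm),
    Wv = init_dense(dm, dm), Wo = init_dense(dm, dm),
    ff1 = init_dense(dm, cfg$tr_ff), ff2 = init_dense(cfg$tr_ff, dm),
    ln1_g = new_param(matrix(1, 1, dm)), ln1_b = new_param(matrix(0, 1, dm)),
    ln2_g = new_param(matrix(1, 1, dm)), ln2_b = new_param(matrix(0, 1, dm)))
  list(proj = init_dense(D, dm),
       enc = lapply(seq_len(cfg$tr_layers), function(i) block()),
       dec = lapply(seq_len(cfg$tr_layers), function(i) block()),
       head = init_dense(dm, D),
       pe = positional_encoding(shape[1], dm))
}

positional_encoding <- function(T_, dm) {
  pos <- seq_len(T_) - 1
  i <- seq_len(dm) - 1
  ang <- outer(pos, 1 / 10000^(2 * (i %/% 2) / dm))
  pe <- matrix(0, T_, dm)
  even <- seq(1, dm, by = 2); odd <- seq(2, dm, by = 2)
  pe[, even] <- sin(ang[, even, drop = FALSE])
  pe[, odd] <- cos(ang[, odd, drop = FALSE])
  pe
}

build_cae <- function(shape, cfg, variational) {
  f <- cfg$cae_filters; k <- cfg$cae_kernel
  enc <- list(); cin <- 1L
  n_enc <- if (variational) 3L else 4L
  for (i in seq_len(n_enc)) {
    enc[[i]] <- list(conv = init_conv2d(k, cin, f[i]))
    cin <- f[i]
  }
  out <- list(enc = enc)
  if (variational) {
    out$mu_head <- list(conv = init_conv2d(k, cin, cfg$latent_ch))
    out$lv_head <- list(conv = init_conv2d(k, cin, cfg$latent_ch))
    cin <- cfg$latent_ch
  }
  fd <- c(rev(f)[-1], 1L)                    # 64, 32, 16, 1
  dec <- list()
  for (i in 1:4) {
    dec[[i]] <- list(conv = init_conv2d(k, cin, fd[i]))
    cin <- fd[i]
  }
  out$dec <- dec
  out$variational <- variational
  out
}

build_cvae1d <- function(shape, cfg) {
  D <- shape[2]; f <- cfg$cvae1d_filters
  enc <- list(); cin <- D
  for (i in seq_along(f)) {
    enc[[i]] <- list(conv = init_conv1d(3L, cin, f[i]))
    cin <- f[i]
  }
  latent <- cfg$latent_ch %/% 2L
  list(enc = enc,
       mu_head = list(conv = init_conv1d(3L, cin, latent)),
       lv_head = list(conv = init_conv1d(3L, cin, latent)),
       dec1 = init_conv1d(3L, latent, f[2]),
       dec2 = init_conv1d(3L, f[2], f[1]),
       dec3 = init_conv1d(3L, f[1], max(f[1] %/% 2L, D)),
       head = init_dense(max(f[1] %/% 2L, D), D),
       variational = TRUE)
}

## ---- forward passes -------------------------------------------------------

# Returns list(recon = node, kl = node or NULL). X is a plain array.
model_forward <- function(model, X, tape, training = FALSE) {
  switch(model$arch,
    fnn = forward_fnn(model, X, tape, training),
    cnn = forward_cnn(model, X, tape, training),
    gru = forward_gru(model, X, tape, training),
    transformer = forward_transformer(model, X, tape, training),
    cae = forward_cae(model, X, tape, training),
    cvae = forward_cae(model, X, tape, training),
    cvae1d = forward_cvae1d(model, X, tape, training))
}

forward_fnn <- function(model, X, tape, training) {
  d <- dim(X); B <- d[1]
  L <- model$layers
  x <- nd_const(tape, matrix(X, B, prod(d[-1])))
  h <- nd_relu(apply_dense(tape, x, L$enc1))
  h <- nd_relu(apply_dense(tape, h, L$enc2))
  h <- nd_relu(apply_dense(tape, h, L$dec1))
  h <- nd_dropout(h, L$dropout, training)
  y <- apply_dense(tape, h, L$dec2)
  list(recon = nd_reshape(y, d), kl = NULL)
}

forward_cnn <- function(model, X, tape, training) {
  L <- model$layers
  h <- nd_const(tape, X)
  for (blk in L$enc) {
    h <- nd_conv1d(tape, h, blk$conv, stride = 2L)
    h <- nd_batchnorm(h, nd_param(tape, blk$bn_g), nd_param(tape, blk$bn_b),
                      blk$bn_st, training)
    h <- nd_leaky_relu(h)
  }
  for (blk in L$dec) {
    h <- nd_upsample1d(h)
    h <- nd_conv1d(tape, h, blk$conv, stride = 1L)
    h <- nd_batchnorm(h, nd_param(tape, blk$bn_g), nd_param(tape, blk$bn_b),
                      blk$bn_st, training)
    h <- nd_leaky_relu(h)
  }
  d <- dim(h$value)
  hm <- nd_reshape(h, c(d[1] * d[2], d[3]))
  y <- apply_dense(tape, hm, L$head)
  list(recon = nd_reshape(y, c(d[1], d[2], ncol(y$value))), kl = NULL)
}

forward_gru <- function(model, X, tape, training) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  L <- model$layers
  H <- L$enc$n_h
  h <- nd_const(tape, matrix(0, B, H))
  enc_outs <- vector("list", T_)
  for (t in seq_len(T_)) {
    xt <- nd_const(tape, array(X[, t, , drop = FALSE], c(B, d[3])))
    h <- gru_step(tape, xt, h, L$enc)
    enc_outs[[t]] <- h
  }
  hd <- h
  outs <- vector("list", T_)
  for (t in seq_len(T_)) {
    scores <- nd_concat_cols(tape, lapply(enc_outs, function(e)
      nd_rowsums(nd_mul(e, hd))))
    alpha <- nd_softmax_rows(nd_scale(scores, 1 / sqrt(H)))
    ctx <- NULL
    for (i in seq_len(T_)) {
      term <- nd_mul_colvec(enc_outs[[i]], nd_col(alpha, i))
      ctx <- if (is.null(ctx)) term else nd_add(ctx, term)
    }
    hd <- gru_step(tape, ctx, hd, L$dec)
    outs[[t]] <- apply_dense(tape, hd, L$head)
  }
  list(recon = nd_stack_time(tape, outs), kl = NULL)
}

forward_transformer <- function(model, X, tape, training) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  L <- model$layers
  dm <- ncol(L$pe)
  x <- nd_const(tape, matrix(X, B * T_, d[3]))
  h <- apply_dense(tape, x, L$proj)
  pe_full <- L$pe[as.vector(matrix(seq_len(T_), B, T_, byrow = TRUE)), ,
                  drop = FALSE]
  h <- nd_add(h, nd_const(tape, pe_full))
  rows_of <- lapply(seq_len(B), function(b) seq(b, B * T_, by = B))
  for (blk in L$enc) h <- transformer_block(tape, h, blk, rows_of, dm)
  # reverse the sequence before decoding
  rev_idx <- as.vector(vapply(seq_len(T_), function(t)
    seq_len(B) + (T_ - t) * B, numeric(B)))
  h <- nd_rows(h, rev_idx)
  for (blk in L$dec) h <- transformer_block(tape, h, blk, rows_of, dm)
  y <- apply_dense(tape, h, L$head)
  list(recon = nd_reshape(y, c(B, T_, d[3])), kl = NULL)
}

transformer_block <- function(tape, h, blk, rows_of, dm) {
  q <- apply_dense(tape, h, blk$Wq)
  k <- apply_dense(tape, h, blk$Wk)
  v <- apply_dense(tape, h, blk$Wv)
  outs <- lapply(rows_of, function(idx) {
    qi <- nd_rows(q, idx); ki <- nd_rows(k, idx); vi <- nd_rows(v, idx)
    att <- nd_softmax_rows(nd_scale(nd_matmul(qi, nd_transpose(ki)),
                                    1 / sqrt(dm)))
    nd_matmul(att, vi)
  })
  att <- nd_assemble_rows(tape, outs, rows_of, nrow(h$value))
  att <- apply_dense(tape, att, blk$Wo)
  h <- nd_layernorm(nd_add(h, att), nd_param(tape, blk$ln1_g),
                    nd_param(tape, blk$ln1_b))
  ff <- apply_dense(tape, nd_relu(apply_dense(tape, h, blk$ff1)), blk$ff2)
  nd_layernorm(nd_add(h, ff), nd_param(tape, blk$ln2_g),
               nd_param(tape, blk$ln2_b))
}

forward_cae <- function(model, X, tape, training) {
  L <- model$layers
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  h <- nd_const(tape, X)
  for (blk in L$enc)
    h <- nd_maxpool2d(nd_relu(nd_conv2d(tape, h, blk$conv)))
  kl <- NULL
  if (isTRUE(L$variational)) {
    mu <- nd_maxpool2d(nd_conv2d(tape, h, L$mu_head$conv))
    lv <- nd_maxpool2d(nd_conv2d(tape, h, L$lv_head$conv))
    kl <- kl_node(tape, mu, lv)
    h <- vae_sample(tape, mu, lv, training)
    attr(kl, "mu") <- mu$value
    attr(kl, "lv") <- lv$value
  }
  n_dec <- length(L$dec)
  for (i in seq_len(n_dec)) {
    h <- nd_conv2d(tape, nd_upsample2d(h), L$dec[[i]]$conv)
    if (i < n_dec) h <- nd_relu(h)
  }
  list(recon = h, kl = kl)
}

forward_cvae1d <- function(model, X, tape, training) {
  L <- model$layers
  d <- dim(X)
  h <- nd_const(tape, X)
  for (blk in L$enc) h <- nd_relu(nd_conv1d(tape, h, blk$conv, stride = 2L))
  mu <- nd_conv1d(tape, h, L$mu_head$conv, stride = 2L)
  lv <- nd_conv1d(tape, h, L$lv_head$conv, stride = 2L)
  kl <- kl_node(tape, mu, lv)
  attr(kl, "mu") <- mu$value
  attr(kl, "lv") <- lv$value
  z <- vae_sample(tape, mu, lv, training)
  h <- nd_relu(nd_conv1d(tape, nd_upsample1d(z), L$dec1, stride = 1L))
  h <- nd_relu(nd_conv1d(tape, nd_upsample1d(h), L$dec2, stride = 1L))
  h <- nd_relu(nd_conv1d(tape, nd_upsample1d(h), L$dec3, stride = 1L))
  h <- nd_trim_time(h, d[2])
  dd <- dim(h$value)
  y <- apply_dense(tape, nd_reshape(h, c(dd[1] * dd[2], dd[3])), L$head)
  list(recon = nd_reshape(y, c(dd[1], dd[2], d[3])), kl = kl)
}

# KL(N(mu, sigma^2) || N(0, I)) averaged over the batch:
# 0.5 * sum(mu^2 + exp(lv) - lv - 1) / B
kl_node <- function(tape, mu, lv) {
  B <- dim(mu$value)[1]
  ones <- nd_const(tape, array(1, dim(mu$value)))
  inner <- nd_sub(nd_add(nd_square(mu), nd_exp(lv)), nd_add(lv, ones))
  nd_scale(nd_sum(inner), 0.5 / B)
}

vae_sample <- function(tape, mu, lv, training) {
  if (!training) return(mu)
  eps <- nd_const(tape, array(rnorm(length(mu$value)), dim(mu$value)))
  nd_add(mu, nd_mul(nd_exp(nd_scale(lv, 0.5)), eps))
}
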