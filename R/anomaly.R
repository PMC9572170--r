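# Training loop and anomaly probes: reconstruction-error vectors, the
# expected-error Gaussian fitted on the second validation subset, the
# Mahalanobis anomaly score, and the KL probe of the variational models.

#' Train an autoencoder on normal data
#'
#' Mini-batch training with the spec's optimizer and loss
#' `w_mse * MSE + w_kl * KL`, early stopping on the first validation
#' subset with the spec's patience, and restoration of the best-validation
#' weights. Deterministic given `spec$seed`.
#'
#' @param model an [build_model()] model.
#' @param x_train,x_val1 arrays of normal-only instances (batch axis
#'   first). `x_val1 = NULL` disables early stopping.
#' @param spec the [train_spec()] (defaults to the model's).
#' @param verbose print per-epoch losses.
#' @return the model (parameters updated in place) with a `history`
#'   element: data frame of epoch, train and validation loss.
#' @export
train_model <- function(model, x_train, x_val1 = NULL, spec = model$spec,
                        verbose = FALSE) {
  stopifnot(inherits(model, "rk_model"))
  n <- dim(x_train)[1]
  if (spec$max_epochs == 0L) {
    model$history <- data.frame(epoch = integer(), train_loss = numeric(),
                                val_loss = numeric())
    return(model)
  }
  opt <- make_optimizer(spec$optimizer, model$params, spec$lr)
  best <- list(loss = Inf, values = NULL, wait = 0L)
  hist <- list()

  with_seed(derive_seed(spec$seed, 71), {
    for (epoch in seq_len(spec$max_epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / spec$batch_size))
      tl <- 0
      for (bi in batches) {
        tape <- nn_tape()
        xb <- take_batch(x_train, bi)
        fw <- model_forward(model, xb, tape, training = TRUE)
        loss <- nd_scale(nd_mse(fw$recon, target_of(xb, fw$recon)),
                         spec$w_mse)
        if (!is.null(fw$kl) && spec$w_kl > 0)
          loss <- nd_add(loss, nd_scale(fw$kl, spec$w_kl))
        if (!is.finite(loss$value))
          stop(sprintf("NaN/Inf loss at epoch %d (arch %s)", epoch,
                       model$arch), call. = FALSE)
        zero_grads(model$params)
        nn_backward(loss)
        opt()
        tl <- tl + loss$value * length(bi)
      }
      tl <- tl / n
      vl <- if (!is.null(x_val1)) eval_loss(model, x_val1, spec) else tl
      hist[[epoch]] <- c(epoch, tl, vl)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tl, vl))
      if (vl < best$loss - 1e-9) {
        best$loss <- vl
        best$values <- lapply(model$params, function(p) p$value)
        best$wait <- 0L
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= spec$patience) break
      }
    }
  })
  if (!is.null(best$values))
    for (i in seq_along(model$params))
      model$params[[i]]$value <- best$values[[i]]
  h <- do.call(rbind, hist)
  model$history <- data.frame(epoch = h[, 1], train_loss = h[, 2],
                              val_loss = h[, 3])
  model
}

take_batch <- function(x, idx) {
  d <- dim(x)
  out <- switch(length(d) - 1L,
    x[idx, , drop = FALSE],
    x[idx, , , drop = FALSE],
    x[idx, , , , drop = FALSE])
  out
}

target_of <- function(xb, recon_node) {
  tg <- xb
  if (!identical(dim(tg), dim(recon_node$value)))
    dim(tg) <- dim(recon_node$value)   # implicit channel axis
  tg
}

eval_loss <- function(model, x, spec) {
  tape <- nn_tape()
  fw <- model_forward(model, x, tape, training = FALSE)
  l <- spec$w_mse * nd_mse(fw$recon, target_of(x, fw$recon))$value
  if (!is.null(fw$kl) && spec$w_kl > 0) l <- l + spec$w_kl * fw$kl$value
  l
}

#' Reconstruct instances with a trained model
#'
#' @param model trained `rk_model`.
#' @param x instance array (batch axis first).
#' @return reconstruction array of the input's shape.
#' @export
reconstruct <- function(model, x) {
  tape <- nn_tape()
  fw <- model_forward(model, x, tape, training = FALSE)
  r <- fw$recon$value
  if (!identical(dim(r), dim(x))) dim(r) <- dim(x)
  r
}

#' Per-point mean-absolute-error vectors
#'
#' For sequence models each time point of each instance yields one
#' d-dimensional vector of absolute feature errors; for the spectrogram
#' models each slice yields its per-mel-band mean absolute error (128
#' values); for the 1-D CVAE each hour tensor yields its per-feature mean
#' absolute error over the 30 slots.
#'
#' @param model trained model.
#' @param x instance array.
#' @return matrix, one error vector per row, with attribute `"instance"`
#'   giving the instance index of each row.
#' @export
error_vectors <- function(model, x) {
  err <- abs(reconstruct(model, x) - x)
  d <- dim(err)
  if (model$arch %in% c("cae", "cvae")) {
    # (B, H, W): mean over spectrogram frames -> per-band vector
    B <- d[1]
    E <- t(apply(err, 1, function(s) rowMeans(matrix(s, d[2], d[3]))))
    attr(E, "instance") <- seq_len(B)
    return(E)
  }
  if (model$arch == "cvae1d") {
    B <- d[1]
    E <- t(apply(err, 1, function(s) colMeans(matrix(s, d[2], d[3]))))
    attr(E, "instance") <- seq_len(B)
    return(E)
  }
  B <- d[1]; T_ <- d[2]; D <- d[3]
  E <- matrix(aperm(err, c(1, 2, 3)), B * T_, D)
  attr(E, "instance") <- rep(seq_len(B), times = T_)
  E
}

#' Fit the expected error distribution (val2)
#'
#' Sample mean and covariance of the error vectors on the second
#' validation subset, with a scaled-trace ridge added to the diagonal so
#' the Mahalanobis form is always defined.
#'
#' @param model trained model (or `NULL` when `errors` are supplied
#'   directly).
#' @param x_val2 normal-only instance array.
#' @param errors optional precomputed error-vector matrix.
#' @param ridge_scale ridge as a fraction of `tr(Sigma)/d` (default 1e-6).
#' @return object of class `error_distribution`: list with `mu`, `sigma`
#'   (ridged), `sigma_inv`, `ridge`, `n`.
#' @export
fit_error_distribution <- function(model = NULL, x_val2 = NULL,
                                   errors = NULL, ridge_scale = 1e-6) {
  E <- errors %||% error_vectors(model, x_val2)
  if (is.null(dim(E))) E <- matrix(E, ncol = 1)
  d <- ncol(E)
  if (nrow(E) < 1) stop("empty validation subset", call. = FALSE)
  mu <- colMeans(E)
  sigma <- if (nrow(E) > 1) cov(E) else matrix(0, d, d)
  if (nrow(E) <= d)
    warning("fewer error vectors than dimensions; ridge ensures ",
            "invertibility", call. = FALSE)
  ridge <- ridge_scale * max(sum(diag(sigma)), .Machine$double.eps) / d
  sigma <- sigma + diag(ridge, d)
  structure(list(mu = mu, sigma = sigma, sigma_inv = chol2inv(chol(sigma)),
                 ridge = ridge, n = nrow(E)),
            class = "error_distribution")
}

#' Mahalanobis anomaly score
#'
#' `a(i) = (e(i) - mu)' Sigma^-1 (e(i) - mu)` for each error vector, the
#' squared covariance-whitened distance from the expected error
#' distribution.
#'
#' @param dist an [fit_error_distribution()] object.
#' @param errors error-vector matrix (rows scored individually).
#' @return non-negative score vector.
#' @export
mahalanobis_score <- function(dist, errors) {
  if (is.null(dim(errors))) errors <- matrix(errors, ncol = length(dist$mu))
  X <- sweep(errors, 2, dist$mu)
  rowSums((X %*% dist$sigma_inv) * X)
}

#' Anomaly scores of instances under a trained model
#'
#' Reconstruction-error vectors are scored against the expected error
#' distribution (per time point for sequence models, per slice/hour for
#' the convolutional ones).
#'
#' @param model trained model.
#' @param dist an [fit_error_distribution()].
#' @param x instance array.
#' @return data frame with `instance` (index into `x`) and `score`.
#' @export
anomaly_score <- function(model, dist, x) {
  E <- error_vectors(model, x)
  data.frame(instance = attr(E, "instance"),
             score = mahalanobis_score(dist, E))
}

#' KL-divergence anomaly probe of a variational model
#'
#' Per-instance `KL(N(mu(x), sigma^2(x)) || N(0, I))` summed over the
#' latent units.
#'
#' @param model a trained `cvae` or `cvae1d` model.
#' @param x instance array.
#' @return non-negative score per instance.
#' @export
kl_score <- function(model, x) {
  if (!model$arch %in% c("cvae", "cvae1d"))
    stop("KL probe requires a variational model", call. = FALSE)
  tape <- nn_tape()
  fw <- model_forward(model, x, tape, training = FALSE)
  mu <- attr(fw$kl, "mu"); lv <- attr(fw$kl, "lv")
  B <- dim(mu)[1]
  per <- 0.5 * (mu^2 + exp(lv) - lv - 1)
  rowSums(matrix(per, B))
}

#' Model-free Mahalanobis baseline
#'
#' Fits the mean and covariance of the raw feature rows in the validation
#' set and scores the test rows with the same Mahalanobis form -- the
#' untrained reference the autoencoders must beat.
#'
#' @param val_features,test_features numeric matrices over the same
#'   feature space.
#' @return list with `dist` and `scores` (one per test row).
#' @export
random_baseline <- function(val_features, test_features) {
  dist <- fit_error_distribution(errors = as.matrix(val_features))
  list(dist = dist,
       scores = mahalanobis_score(dist, as.matrix(test_features)))
}
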