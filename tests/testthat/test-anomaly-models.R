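# Compact widths keep the architecture tests fast; gradient correctness is
# checked against central differences with biases perturbed off the ReLU
# kinks.

small_cfg <- model_config(
  fnn_hidden = 8L, fnn_latent = 4L, cnn_filters = c(4L, 6L, 8L, 8L),
  gru_hidden = 8L, tr_dmodel = 8L, tr_layers = 2L, tr_ff = 8L,
  cae_filters = c(2L, 3L, 4L, 4L), latent_ch = 4L,
  cvae1d_filters = c(4L, 6L), dropout = 0)

gradcheck_model <- function(arch, shape, n_probe = 3L, eps = 1e-6) {
  spec <- train_spec(arch, seed = 42)
  m <- build_model(spec, shape, small_cfg)
  set.seed(9)
  for (p in m$params) p$value <- p$value + rnorm(length(p$value), 0, 0.05)
  X <- array(rnorm(3 * prod(shape)), c(3, shape))
  if (arch == "cnn") {   # populate batch-norm running stats, then freeze
    tp <- nn_tape()
    invisible(relapsekit:::model_forward(m, X, tp, training = TRUE))
  }
  lossf <- function() {
    tp <- nn_tape()
    fw <- relapsekit:::model_forward(m, X, tp, training = FALSE)
    l <- relapsekit:::nd_mse(fw$recon, relapsekit:::target_of(X, fw$recon))
    if (!is.null(fw$kl)) l <- relapsekit:::nd_add(
      l, relapsekit:::nd_scale(fw$kl, 0.01))
    l
  }
  l <- lossf()
  relapsekit:::zero_grads(m$params)
  relapsekit:::nn_backward(l)
  worst <- 0
  for (p in m$params) {
    if (is.null(p$grad)) next
    for (i in sample(length(p$value), min(n_probe, length(p$value)))) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps; lp <- lossf()$value
      p$value[i] <- v0 - eps; lm <- lossf()$value
      p$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      an <- p$grad[i]
      if (abs(num) + abs(an) < 1e-6) next   # below finite-difference noise
      worst <- max(worst, abs(num - an) / (abs(num) + abs(an)))
    }
  }
  worst
}

test_that("every architecture backpropagates exact gradients", {
  expect_lt(gradcheck_model("fnn", c(16L, 5L)), 1e-4)
  expect_lt(gradcheck_model("cnn", c(16L, 5L)), 1e-4)
  expect_lt(gradcheck_model("gru", c(6L, 5L)), 1e-4)
  expect_lt(gradcheck_model("transformer", c(6L, 5L)), 1e-4)
  expect_lt(gradcheck_model("cae", c(32L, 16L)), 1e-4)
  expect_lt(gradcheck_model("cvae", c(32L, 16L)), 1e-4)
  expect_lt(gradcheck_model("cvae1d", c(30L, 5L)), 1e-4)
})

test_that("architectures satisfy their structural contracts", {
  # autoencoder contract: CAE decoder restores the 128 x 64 input
  m <- build_model(train_spec("cae", seed = 1), c(128L, 64L),
                   model_config(cae_filters = c(2L, 2L, 2L, 2L)))
  X <- array(runif(2 * 128 * 64), c(2, 128, 64))
  expect_equal(dim(reconstruct(m, X)), dim(X))

  # GRU hidden width is 100 by default
  mg <- build_model(train_spec("gru", seed = 1), c(48L, 10L))
  expect_equal(mg$layers$enc$n_h, 100L)

  # sequence models reconstruct their own shape
  for (arch in c("fnn", "cnn", "transformer")) {
    ms <- build_model(train_spec(arch, seed = 1), c(48L, 10L), small_cfg)
    Xs <- array(runif(4 * 48 * 10), c(4, 48, 10))
    expect_equal(dim(reconstruct(ms, Xs)), dim(Xs))
  }
  expect_error(build_model(train_spec("cnn", seed = 1), c(50L, 10L)),
               "divisible")
})

test_that("training follows the published optimization settings", {
  s <- train_spec("fnn")
  expect_equal(s$optimizer, "adam"); expect_equal(s$lr, 1e-4)
  expect_equal(s$batch_size, 64L); expect_equal(s$max_epochs, 50L)
  s <- train_spec("transformer"); expect_equal(s$lr, 1e-3)
  s <- train_spec("cnn"); expect_equal(s$optimizer, "rmsprop")
  s <- train_spec("gru"); expect_equal(s$optimizer, "rmsprop")
  s <- train_spec("cvae")
  expect_equal(s$optimizer, "adam"); expect_equal(s$lr, 3e-4)
  expect_equal(s$batch_size, 8L); expect_equal(s$max_epochs, 200L)
  expect_equal(s$patience, 10L)
  expect_equal(s$w_mse, 1); expect_equal(s$w_kl, 0.01)
})

test_that("training reduces the loss, restores best weights, and is
           deterministic", {
  X <- toy_sequences(40); V <- toy_sequences(10, seed = 2)
  spec <- train_spec("fnn", max_epochs = 20L, seed = 5)
  m <- build_model(spec, c(48L, 10L), small_cfg)
  m <- train_model(m, X, V, spec)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])

  spec0 <- train_spec("fnn", max_epochs = 0L, seed = 5)
  m0 <- build_model(spec0, c(48L, 10L), small_cfg)
  m0 <- train_model(m0, X, V, spec0)
  expect_equal(nrow(m0$history), 0L)

  mA <- train_model(build_model(spec, c(48L, 10L), small_cfg), X, V, spec)
  mB <- train_model(build_model(spec, c(48L, 10L), small_cfg), X, V, spec)
  expect_identical(mA$history, mB$history)
  expect_identical(mA$params[[1]]$value, mB$params[[1]]$value)
})

test_that("the CVAE loss decomposes exactly into W_MSE * MSE + W_KL * KL", {
  spec <- train_spec("cvae1d", seed = 3)
  m <- build_model(spec, c(30L, 5L), small_cfg)
  X <- array(runif(4 * 30 * 5), c(4, 30, 5))
  tp <- relapsekit:::nn_tape()
  fw <- relapsekit:::model_forward(m, X, tp, training = FALSE)
  mse <- relapsekit:::nd_mse(fw$recon,
                             relapsekit:::target_of(X, fw$recon))$value
  kl <- fw$kl$value
  total <- relapsekit:::eval_loss(m, X, spec)
  expect_equal(total, spec$w_mse * mse + spec$w_kl * kl, tolerance = 1e-12)
})

test_that("the expected-error distribution and Eq.-4 scoring behave per the
           closed forms", {
  # perfect reconstructor: mu = 0, sigma = ridge * I
  Z <- matrix(0, 10, 4)
  d0 <- fit_error_distribution(errors = Z)
  expect_equal(d0$mu, rep(0, 4))
  expect_equal(d0$sigma, diag(d0$ridge, 4))

  # hand-computed moments on a 3-point error set
  E <- rbind(c(1, 2), c(3, 4), c(5, 9))
  dh <- fit_error_distribution(errors = E, ridge_scale = 0)
  expect_equal(dh$mu, c(3, 5))
  expect_equal(dh$sigma, cov(E), tolerance = 1e-12)

  # ridge keeps sigma symmetric positive definite
  set.seed(10)
  Er <- matrix(rnorm(30), 10, 3)
  dr <- fit_error_distribution(errors = Er)
  expect_true(isSymmetric(dr$sigma))
  expect_true(all(eigen(dr$sigma, symmetric = TRUE,
                        only.values = TRUE)$values > 0))

  # a(e = mu) = 0; identity covariance gives the squared norm
  expect_equal(mahalanobis_score(dh, dh$mu), 0, tolerance = 1e-12)
  di <- list(mu = rep(0, 3), sigma = diag(3), sigma_inv = diag(3))
  e <- c(1, -2, 0.5)
  expect_equal(mahalanobis_score(di, e), sum(e^2))

  # 3-dim agreement with an explicit inverse and with stats::mahalanobis
  set.seed(11)
  E3 <- matrix(rnorm(60), 20, 3)
  d3 <- fit_error_distribution(errors = E3)
  x <- rnorm(3)
  hand <- as.numeric(t(x - d3$mu) %*% solve(d3$sigma) %*% (x - d3$mu))
  expect_equal(mahalanobis_score(d3, x), hand, tolerance = 1e-10)
  expect_equal(mahalanobis_score(d3, x),
               as.numeric(stats::mahalanobis(matrix(x, 1), d3$mu,
                                             d3$sigma)),
               tolerance = 1e-10)

  # permutation invariance of the score
  pm <- c(3, 1, 2)
  dperm <- fit_error_distribution(errors = E3[, pm])
  expect_equal(mahalanobis_score(dperm, x[pm]), mahalanobis_score(d3, x),
               tolerance = 1e-8)

  expect_warning(fit_error_distribution(errors = matrix(rnorm(8), 2, 4)),
                 "ridge")
})

test_that("the KL probe matches its closed form and a quadrature oracle", {
  # mu = 0, sigma = 1 -> 0; scalar mu = 1, sigma = 1 -> 0.5
  klf <- function(mu, lv) 0.5 * sum(mu^2 + exp(lv) - lv - 1)
  expect_equal(klf(0, 0), 0)
  expect_equal(klf(1, 0), 0.5)

  # numerical integration of KL(N(mu, s^2) || N(0,1)) for a 2-unit latent
  mu <- c(0.7, -0.4); s2 <- c(1.3, 0.6)
  num <- sum(vapply(1:2, function(i) {
    integrate(function(z) {
      p <- dnorm(z, mu[i], sqrt(s2[i]))
      ifelse(p > 0, p * (dnorm(z, mu[i], sqrt(s2[i]), log = TRUE) -
                           dnorm(z, log = TRUE)), 0)
    }, -12, 12, rel.tol = 1e-10)$value
  }, numeric(1)))
  expect_equal(klf(mu, log(s2)), num, tolerance = 1e-4)

  # the model-level probe agrees with the closed form on its own encoder
  m <- build_model(train_spec("cvae1d", seed = 4), c(30L, 5L), small_cfg)
  X <- array(runif(3 * 30 * 5), c(3, 30, 5))
  ks <- kl_score(m, X)
  expect_true(all(ks >= 0))
  expect_length(ks, 3L)
  expect_error(kl_score(build_model(train_spec("fnn", seed = 1),
                                    c(16L, 5L), small_cfg), X),
               "variational")
})

test_that("the untrained baseline scores raw features by Eq. 4", {
  set.seed(12)
  val <- matrix(rnorm(200), 50, 4)
  test <- rbind(colMeans(val), matrix(rnorm(40, 2), 10, 4))
  rb <- random_baseline(val, test)
  expect_equal(rb$scores[1], 0, tolerance = 1e-6)
  expect_true(all(rb$scores[-1] > rb$scores[1]))
  lab <- c(FALSE, rep(TRUE, 10))
  more <- rbind(matrix(rnorm(80), 20, 4), matrix(rnorm(40, 2), 10, 4))
  rb2 <- random_baseline(val, more)
  ev <- evaluate_scores(rb2$scores, c(rep(FALSE, 20), rep(TRUE, 10)))
  expect_gt(ev$roc_auc, 0.5)
})
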