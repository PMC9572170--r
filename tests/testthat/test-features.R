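test_that("short-time energy is the mean squared 3-axis norm", {
  expect_equal(short_time_energy(matrix(0, 100, 3)), 0)
  expect_equal(short_time_energy(matrix(rep(c(1, 0, 0), each = 50), 50, 3)),
               1)
  set.seed(1)
  m <- matrix(rnorm(300), 100, 3)
  loops <- sum(sapply(seq_len(100), function(i) sum(m[i, ]^2))) / 100
  expect_equal(short_time_energy(m), loops, tolerance = 1e-9)
})

test_that("Lomb-Scargle matches its direct definition, the FFT periodogram
           under uniform sampling, and recovers a planted peak", {
  set.seed(7)
  t <- sort(runif(120, 0, 280)); x <- cos(2 * pi * 0.1 * t) + rnorm(120, 0, 0.2)
  # degenerate input
  expect_equal(max(lomb_scargle(t, rep(0, 120))$power), 0)
  expect_error(lomb_scargle(c(1, 1, 2, 3), rnorm(4), freqs = 0.1),
               "strictly increasing")
  # peak recovery within one grid step
  freqs <- seq(0.001, 0.5, length.out = 1024)
  pg <- lomb_scargle(t, x, freqs)
  expect_lt(abs(freqs[which.max(pg$power)] - 0.1), diff(freqs)[1] + 1e-12)
  # direct evaluation of the printed estimator (with and without centering)
  for (f in c(0.05, 0.1, 0.33)) {
    expect_equal(lomb_scargle(t, x, freqs = f)$power,
                 oracle_lomb_scargle(t, x, f), tolerance = 1e-10)
    expect_equal(lomb_scargle(t, x, freqs = f, center = FALSE)$power,
                 oracle_lomb_scargle(t, x, f, center = FALSE),
                 tolerance = 1e-10)
  }
  # classical periodogram equivalence under uniform sampling
  n <- 256; tu <- 0:(n - 1); xu <- rnorm(n)
  fk <- (1:40) / n
  pls <- lomb_scargle(tu, xu, freqs = fk)$power
  pfft <- (Mod(fft(xu - mean(xu)))^2 / n)[2:41]
  expect_lt(max(abs(pls - pfft) / pfft), 1e-6)
})

test_that("band powers follow the percent-of-(LF+HF) convention", {
  # flat spectrum: lf share equals the band-width ratio
  f <- seq(0.001, 0.5, length.out = 2048)
  flat <- structure(list(freqs = f, power = rep(1, length(f)), n = 100),
                    class = "periodogram")
  bp <- band_powers(flat)
  expect_equal(bp$lf_pct, 100 * 0.11 / 0.36, tolerance = 1e-3)
  expect_equal(bp$lf_pct + bp$hf_pct, 100, tolerance = 1e-9)
  # all power inside HF
  hf_only <- structure(list(freqs = f,
                            power = as.numeric(f > 0.2 & f < 0.3), n = 100),
                       class = "periodogram")
  bph <- band_powers(hf_only)
  expect_equal(bph$lf_pct, 0)
  expect_equal(bph$hf_pct, 100)
  # complementarity on random spectra
  set.seed(2)
  for (i in 1:5) {
    p <- structure(list(freqs = f, power = runif(length(f)), n = 50),
                   class = "periodogram")
    b <- band_powers(p)
    expect_equal(b$lf_pct + b$hf_pct, 100, tolerance = 1e-9)
    expect_gte(b$ratio, 0)
  }
  # zero band power flags the window
  z <- structure(list(freqs = f, power = rep(0, length(f)), n = 10),
                 class = "periodogram")
  expect_true(band_powers(z)$flagged)
})

test_that("sample entropy equals the exhaustive pair-count oracle and is 0
           for constants", {
  expect_equal(sample_entropy(rep(5, 50)), 0)
  set.seed(3)
  for (i in 1:3) {
    x <- rnorm(30)
    expect_equal(sample_entropy(x, 2, 0.2), oracle_sampen(x, 2, 0.2))
  }
  x <- rnorm(40)
  expect_equal(sample_entropy(x, 3, 0.15), oracle_sampen(x, 3, 0.15))
  # independent library cross-check
  if (requireNamespace("pracma", quietly = TRUE)) {
    z <- rnorm(120)
    expect_equal(sample_entropy(z, 2, 0.2),
                 pracma::sample_entropy(z, edim = 2, r = 0.2 * sd(z),
                                        tau = 1),
                 tolerance = 1e-10)
  }
})

test_that("iid noise has higher sample entropy than its cumulative sum", {
  set.seed(4)
  wins <- 0L
  for (i in 1:100) {
    e <- rnorm(200)
    a <- sample_entropy(e, 2, 0.2)
    b <- sample_entropy(cumsum(e), 2, 0.2)
    if (is.na(b) || a > b) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("Higuchi curve lengths match per-offset brute force; line and
           noise hit their known limits", {
  set.seed(5)
  x <- rnorm(100)
  expect_equal(higuchi_lengths(x, 10), oracle_higuchi_lengths(x, 10),
               tolerance = 1e-12)
  expect_equal(higuchi_fd(seq(0, 5, length.out = 200)), 1.0,
               tolerance = 0.02)
  fds <- vapply(1:20, function(i) higuchi_fd(rnorm(1000)), numeric(1))
  expect_lt(abs(mean(fds) - 2), 0.1)
  expect_error(higuchi_fd(c(rnorm(50), NA)), "finite")
})

test_that("morphological covers equal brute-force neighborhood extremes", {
  set.seed(6)
  x <- rnorm(200)
  cov <- morph_covers(x, 12)
  for (s in c(1, 5, 12)) {
    bf <- oracle_morph(x, s)
    expect_equal(cov$dilation[s, ], bf$dilation, tolerance = 1e-12)
    expect_equal(cov$erosion[s, ], bf$erosion, tolerance = 1e-12)
  }
})

test_that("MFD profile is 1 for lines, bounded in [1,2], and internally
           consistent", {
  line <- seq(0, 10, length.out = 1000)
  mp <- mfd_profile(line)
  expect_true(all(abs(mp$D - 1) < 1e-9))
  expect_equal(mp$fd1, 1, tolerance = 1e-9)

  set.seed(7)
  for (x in list(rnorm(1000), cumsum(rnorm(1000)),
                 sin(2 * pi * (1:1000) / 100))) {
    m <- mfd_profile(x)
    expect_true(all(m$D >= 1 & m$D <= 2))
    expect_lte(m$min, m$mean)
    expect_lte(m$mean, m$max)
  }
  # constant signal: dimension 1 everywhere, not an error
  mc <- mfd_profile(rep(3, 500))
  expect_true(all(mc$D == 1))
  # noise is rougher than a smooth sinusoid at the finest scales
  expect_gt(mfd_profile(rnorm(1000))$fd1,
            mfd_profile(sin(2 * pi * (1:1000) / 200))$fd1)
})

test_that("Poincare descriptors satisfy the RMSSD and variance identities", {
  expect_equal(poincare_sd(rep(800, 50)), list(sd1 = 0, sd2 = 0))
  set.seed(8)
  rr <- rnorm(200, 800, 50)
  ps <- poincare_sd(rr)
  expect_equal(ps$sd1, sqrt(mean(diff(rr)^2)) / sqrt(2), tolerance = 1e-12)
  # rotated-coordinate variance identity (population moments on the
  # paired vectors; sd1 is uncentered, the correction is mean(d)^2 / 2)
  u <- rr[-1]; v <- rr[-length(rr)]
  vp <- function(z) mean((z - mean(z))^2)
  expect_equal(ps$sd1^2 + ps$sd2^2,
               vp(u) + vp(v) + mean(diff(rr))^2 / 2, tolerance = 1e-9)
  expect_gte(ps$sd1, 0); expect_gte(ps$sd2, 0)
})

test_that("Welch band peaks localize oscillations to their HRV band", {
  t <- cumsum(rep(0.8, 400))
  lf_sig <- welch_band_peaks(t, 800 + 40 * sin(2 * pi * 0.1 * t))
  hf_sig <- welch_band_peaks(t, 800 + 40 * sin(2 * pi * 0.3 * t))
  expect_gt(lf_sig$lf_peak, 100 * lf_sig$hf_peak)
  expect_gt(hf_sig$hf_peak, 100 * hf_sig$lf_peak)
  expect_error(welch_band_peaks(c(1, 1, 2, 3, 4, 5, 6, 7), rnorm(8)),
               "strictly increasing")
})

test_that("daily activity honours the 20-recorded-hour rule and the diary
           ratio", {
  daily <- data.frame(subject_id = "S", day = 0:2,
                      steps = c(4000, 6000, 8000),
                      recorded_hours = c(19.9, 20, 24))
  diary <- data.frame(day = 0:2,
                      sleep_start = 0:2 * 86400 + 22 * 3600,
                      sleep_end = 1:3 * 86400 + 6 * 3600)
  out <- daily_activity(daily, diary)
  expect_equal(out$day, 1:2)          # 19.9 h day excluded
  expect_equal(out$sleep_hours, c(8, 8), tolerance = 1e-9)
  expect_equal(out$sleep_wake_ratio, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("interval features compose the per-window descriptors
           consistently", {
  # time-of-day encoding conventions
  f0 <- interval_features(0)
  expect_equal(f0$sin_t, 0, tolerance = 1e-12)
  expect_equal(f0$cos_t, 1, tolerance = 1e-12)
  f6 <- interval_features(6 * 3600)
  expect_equal(f6$sin_t, 1, tolerance = 1e-12)
  expect_equal(f6$cos_t, 0, tolerance = 1e-12)

  set.seed(9)
  rr <- rnorm(350, 800, 40)
  ev <- data.frame(t_sec = cumsum(rr) / 1000, rr_ms = rr)
  rw <- clean_rr_window(ev)
  acc <- clean_motion_window(matrix(rnorm(18000), 6000, 3), "acc")
  feats <- interval_features(3600, rw, acc, NULL,
                             diary = data.frame(sleep_start = 0,
                                                sleep_end = 1000))
  expect_identical(feats$state, "awake")
  expect_true(is.na(feats$ste_gyr))           # missing modality recorded
  # componentwise agreement with the individual estimators
  expect_equal(feats$ste_acc, short_time_energy(acc))
  expect_equal(feats$sampen, sample_entropy(rw$rr, 2, 0.2))
  expect_equal(feats$higuchi, higuchi_fd(rw$rr, 10))
  expect_equal(feats$sd1, poincare_sd(rw$rr)$sd1)
  expect_equal(feats$rr_mean, mean(rw$rr))
  expect_equal(feats$hr_mean, mean(60000 / rw$rr))
  bp <- band_powers(lomb_scargle(3600 + cumsum(rw$rr) / 1000, rw$rr))
  expect_equal(feats$lf_pct, bp$lf_pct)
  mp <- mfd_profile(rw$rr)
  expect_equal(feats$mfd_fd1, mp$fd1)
  expect_equal(feats$mfd_mean, mp$mean)

  # purity: identical inputs give identical vectors
  feats2 <- interval_features(3600, rw, acc, NULL,
                              diary = data.frame(sleep_start = 0,
                                                 sleep_end = 1000))
  expect_identical(feats, feats2)
})
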