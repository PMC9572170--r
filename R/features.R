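# Linear and nonlinear 5-min window descriptors: short-time energy,
# Lomb-Scargle band powers, sample entropy, Higuchi and multiscale
# morphological fractal dimensions, Poincare SD1/SD2.

#' Feature extraction configuration
#'
#' Tunable parameters of the nonlinear estimators. Defaults follow common
#' HRV practice: SampEn embedding m = 2 with tolerance 0.2 x SD, Higuchi
#' k_max = 10, morphological covers up to scale 30 samples regressed over
#' sliding 5-scale windows, and a linear 1024-point Lomb-Scargle grid on
#' [0.001, 0.5] Hz.
#'
#' @param sampen_m SampEn embedding length (>= 1).
#' @param sampen_r SampEn tolerance as a fraction of the series SD (> 0).
#' @param higuchi_kmax maximum Higuchi delay (>= 2).
#' @param mfd_max_scale largest morphological scale, in samples.
#' @param mfd_reg_window scales per log-log regression window.
#' @param mfd_frame_len samples per short-time frame of the MFD profile.
#' @param ls_grid numeric `c(fmin, fmax, n)` for the Lomb-Scargle grid (Hz).
#' @param ls_center mean-center the signal before the periodogram
#'   (standard practice; the literal estimator without centering leaks the
#'   DC component into the LF band).
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(sampen_m = 2L, sampen_r = 0.2,
                           higuchi_kmax = 10L, mfd_max_scale = 30L,
                           mfd_reg_window = 5L, mfd_frame_len = 64L,
                           ls_grid = c(0.001, 0.5, 1024),
                           ls_center = TRUE) {
  stopifnot(sampen_m >= 1, sampen_r > 0, higuchi_kmax >= 2,
            mfd_max_scale >= mfd_reg_window, length(ls_grid) == 3)
  structure(list(sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
                 higuchi_kmax = as.integer(higuchi_kmax),
                 mfd_max_scale = as.integer(mfd_max_scale),
                 mfd_reg_window = as.integer(mfd_reg_window),
                 mfd_frame_len = as.integer(mfd_frame_len),
                 ls_grid = ls_grid, ls_center = isTRUE(ls_center)),
            class = "feature_config")
}

#' Short-time energy of a triaxial window
#'
#' Mean over samples of the squared Euclidean norm of the 3-axis vector
#' (window-length invariant by the mean convention).
#'
#' @param window a `motion_window` or a numeric n x 3 matrix.
#' @return scalar energy, in (m/s^2)^2 or (deg/s^2)^2.
#' @export
short_time_energy <- function(window) {
  m <- if (inherits(window, "motion_window")) window$samples else
    as.matrix(window)
  mean(rowSums(m^2))
}

#' Lomb-Scargle periodogram
#'
#' Least-squares spectral estimate for unevenly sampled series. For each
#' angular frequency `2*pi*f` the phase origin `tau` is
#' `atan2(sum sin 2wt, sum cos 2wt) / (2w)` and the power is half the sum
#' of the squared cosine and sine projections, each normalized by its own
#' basis energy. The input is mean-centered first unless `center = FALSE`.
#'
#' @param t sample times (s), strictly increasing, length >= 4.
#' @param x signal values at `t`.
#' @param freqs frequency grid in Hz (default `feature_config()` grid).
#' @param center mean-center before evaluation.
#' @return object of class `periodogram`: list with `freqs` (Hz), `power`
#'   (same units as `x^2`), `n`.
#' @export
lomb_scargle <- function(t, x, freqs = NULL, center = TRUE) {
  stopifnot(length(t) == length(x), length(t) >= 4)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (is.null(freqs)) {
    g <- feature_config()$ls_grid
    freqs <- seq(g[1], g[2], length.out = g[3])
  }
  if (center) x <- x - mean(x)
  omega <- 2 * pi * freqs
  wt <- outer(t, omega)                      # n x nf
  tau_num <- colSums(sin(2 * wt))
  tau_den <- colSums(cos(2 * wt))
  tau <- atan2(tau_num, tau_den) / (2 * omega)
  arg <- wt - matrix(omega * tau, nrow = length(t), ncol = length(omega),
                     byrow = TRUE)
  ca <- cos(arg); sa <- sin(arg)
  xc <- colSums(x * ca); xs <- colSums(x * sa)
  cc <- colSums(ca^2); ss <- colSums(sa^2)
  power <- 0.5 * (ifelse(cc > 0, xc^2 / cc, 0) +
                    ifelse(ss > 0, xs^2 / ss, 0))
  structure(list(freqs = freqs, power = power, n = length(x)),
            class = "periodogram")
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Normalized LF/HF band powers
#'
#' Trapezoidal integration of the periodogram over the LF [0.04, 0.15] Hz
#' and HF [0.15, 0.40] Hz bands, expressed as percent of (LF + HF), plus
#' their ratio.
#'
#' @param pgram a [lomb_scargle()] periodogram covering [0.04, 0.40] Hz.
#' @param lf,hf band edges in Hz.
#' @return list with `lf_pct`, `hf_pct` (summing to 100), `ratio`, and
#'   `flagged` (TRUE when LF + HF has no power; values are `NA` then).
#' @export
band_powers <- function(pgram, lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  f <- pgram$freqs; p <- pgram$power
  if (min(f) > lf[1] || max(f) < hf[2])
    stop("grid must cover [", lf[1], ", ", hf[2], "] Hz")
  band <- function(b) {
    i <- f >= b[1] & f <= b[2]
    trapz(f[i], p[i])
  }
  LF <- band(lf); HF <- band(hf)
  if (LF + HF <= 0)
    return(list(lf_pct = NA_real_, hf_pct = NA_real_, ratio = NA_real_,
                flagged = TRUE))
  list(lf_pct = 100 * LF / (LF + HF), hf_pct = 100 * HF / (LF + HF),
       ratio = LF / HF, flagged = FALSE)
}

#' Sample entropy
#'
#' `-log(A/B)` where `B` counts template pairs of length `m` and `A` pairs
#' of length `m + 1` within Chebyshev tolerance `r * sd(x)`, self-matches
#' excluded, both counts over the `n - m` templates for which the extended
#' vector exists.
#'
#' @param x numeric series, length > m + 1.
#' @param m embedding length.
#' @param r tolerance as a fraction of `sd(x)`.
#' @return scalar entropy; `NA` (flagged undefined) when no matches exist.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2) {
  n <- length(x)
  stopifnot(n > m + 1)
  tol <- r * sd(x)
  if (tol == 0) tol <- .Machine$double.eps  # constant series: all match
  nt <- n - m
  # Chebyshev distances between length-(m+1) embeddings of the nt templates
  d <- matrix(0, nt, nt)
  for (j in 0:m) {
    seg <- x[(1 + j):(nt + j)]
    d_j <- abs(outer(seg, seg, "-"))
    if (j == m) dm <- d                     # distance at length m
    d <- pmax(d, d_j)
  }
  B <- sum(dm <= tol) - nt
  A <- sum(d <= tol) - nt
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

#' Higuchi curve lengths
#'
#' Mean curve length `L(k)` over the `k` decimation offsets, for
#' `k = 1..k_max`, with Higuchi's normalization.
#'
#' @param x numeric series, length >= 2 * k_max.
#' @param k_max maximum delay.
#' @return numeric vector `L(1..k_max)`.
#' @export
higuchi_lengths <- function(x, k_max = 10L) {
  n <- length(x)
  stopifnot(n >= 2 * k_max, all(is.finite(x)))
  vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      i <- seq(m, n, by = k)
      if (length(i) < 2) return(NA_real_)
      nm <- length(i) - 1
      sum(abs(diff(x[i]))) * (n - 1) / (nm * k) / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
}

#' Higuchi fractal dimension
#'
#' Least-squares slope of `log L(k)` against `log(1/k)`; ~1 for smooth
#' curves, ~2 for white noise.
#'
#' @inheritParams higuchi_lengths
#' @return scalar dimension estimate.
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  L <- higuchi_lengths(x, k_max)
  k <- seq_len(k_max)
  lx <- log(1 / k); ly <- log(L)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Multiscale morphological dilations and erosions
#'
#' Flat dilation/erosion of the signal graph by discrete half-width-`s`
#' windows, computed by iterating the elementary +/-1 window `s` times
#' (equivalent to running max/min over `[n - s, n + s]`, truncated at the
#' edges).
#'
#' @param x numeric signal.
#' @param max_scale largest half-width.
#' @return list with `dilation` and `erosion`, each a `max_scale` x
#'   `length(x)` matrix (row s = scale s).
#' @export
morph_covers <- function(x, max_scale) {
  n <- length(x)
  dil <- matrix(0, max_scale, n)
  ero <- matrix(0, max_scale, n)
  d <- x; e <- x
  for (s in seq_len(max_scale)) {
    d <- pmax(d, c(d[-1], d[n]), c(d[1], d[-n]))
    e <- pmin(e, c(e[-1], e[n]), c(e[1], e[-n]))
    dil[s, ] <- d
    ero[s, ] <- e
  }
  list(dilation = dil, erosion = ero)
}

#' Multiscale fractal dimension profile
#'
#' Short-time Minkowski-Bouligand dimensions from morphological graph
#' covers: per time frame and scale, the cover area (mean dilation-erosion
#' envelope over the samples with full +/-s support) follows
#' `A(s) ~ s^(2 - D)`, so the local dimension is 2 minus the least-squares
#' slope of `log A` against `log s` over a sliding window of scales.
#' Estimates are clipped into the theoretical [1, 2] range for
#' one-dimensional signals; constant frames have D = 1 at all scales.
#'
#' @param x numeric signal, length >= 2 * max scale.
#' @param config a [feature_config()].
#' @param summary_axis `"both"` summarizes min/max/mean/std over the full
#'   D(s, t) profile; `"time"` / `"scale"` first average over the other
#'   axis.
#' @return object of class `mfd_profile`: list with `scales` (regression
#'   window starts), `frames` (frame start indices), `D` (scales x frames
#'   matrix), and summaries `fd1` (mean smallest-scale dimension), `min`,
#'   `max`, `mean`, `std`.
#' @export
mfd_profile <- function(x, config = feature_config(),
                        summary_axis = c("both", "time", "scale")) {
  summary_axis <- match.arg(summary_axis)
  stopifnot(all(is.finite(x)))
  n <- length(x)
  S <- config$mfd_max_scale
  w <- config$mfd_reg_window
  stopifnot(n >= 2 * S)
  L <- min(config$mfd_frame_len, n)
  cov <- morph_covers(x, S)
  env <- cov$dilation - cov$erosion          # S x n

  starts <- seq(1, n - L + 1, by = L)
  n_win <- S - w + 1
  D <- matrix(NA_real_, n_win, length(starts))
  ls <- log(seq_len(S))
  for (fi in seq_along(starts)) {
    cols <- starts[fi]:(starts[fi] + L - 1)
    A <- vapply(seq_len(S), function(s) {
      full <- cols[cols > s & cols <= n - s]  # full-support samples
      if (!length(full)) full <- cols
      mean(env[s, full])
    }, numeric(1))
    logA <- ifelse(A > 0, log(A), NA_real_)
    for (s0 in seq_len(n_win)) {
      i <- s0:(s0 + w - 1)
      if (anyNA(logA[i])) { D[s0, fi] <- 1; next }  # flat cover: smooth
      lx <- ls[i]; ly <- logA[i]
      slope <- sum((lx - mean(lx)) * (ly - mean(ly))) /
        sum((lx - mean(lx))^2)
      D[s0, fi] <- clamp(2 - slope, 1, 2)
    }
  }
  vals <- switch(summary_axis, both = as.numeric(D),
                 time = rowMeans(D), scale = colMeans(D))
  structure(list(scales = seq_len(n_win), frames = starts, D = D,
                 fd1 = mean(D[1, ]), min = min(vals), max = max(vals),
                 mean = mean(vals), std = if (length(vals) > 1) sd(vals)
                 else 0),
            class = "mfd_profile")
}

#' Poincare plot descriptors
#'
#' SD1 is the dispersion perpendicular to the identity line of the lag-1
#' return map, computed as RMSSD / sqrt(2) (uncentered second moment of
#' the successive differences, the HRV convention); SD2 is the
#' mean-centered population SD of the rotated sum coordinate
#' `(rr[n+1] + rr[n]) / sqrt(2)`.
#'
#' @param rr RR series in ms, >= 3 beats.
#' @return list with `sd1`, `sd2` (ms).
#' @export
poincare_sd <- function(rr) {
  stopifnot(length(rr) >= 3)
  d <- diff(rr)
  s <- (rr[-1] + rr[-length(rr)]) / sqrt(2)
  list(sd1 = sqrt(mean(d^2) / 2),
       sd2 = sqrt(mean((s - mean(s))^2)))
}

#' Per-day steps and sleep/wake ratio
#'
#' Retains only days with at least `min_hours` recorded hours and joins
#' the diary-implied sleep/wake ratio.
#'
#' @param daily data frame with `subject_id`, `day`, `steps`,
#'   `recorded_hours`.
#' @param diary data frame with `day`, `sleep_start`, `sleep_end`
#'   (absolute seconds) for the same subject.
#' @param min_hours inclusion threshold (default 20).
#' @return data frame `subject_id`, `day`, `steps`, `sleep_hours`,
#'   `sleep_wake_ratio` (`NA`-flagged when no awake time).
#' @export
daily_activity <- function(daily, diary, min_hours = 20) {
  keep <- daily$recorded_hours >= min_hours
  out <- daily[keep, , drop = FALSE]
  sleep_h <- vapply(out$day, function(d) {
    lo <- d * DAY_S; hi <- lo + DAY_S
    sum(pmax(0, pmin(diary$sleep_end, hi) - pmax(diary$sleep_start, lo))) /
      3600
  }, numeric(1))
  awake_h <- 24 - sleep_h
  out$sleep_hours <- sleep_h
  out$sleep_wake_ratio <- ifelse(awake_h > 0, sleep_h / awake_h, NA_real_)
  out[, c("subject_id", "day", "steps", "sleep_hours", "sleep_wake_ratio")]
}

#' Full feature vector for one 5-minute slot
#'
#' Composes every descriptor from the cleaned windows of one slot: motion
#' energies, SampEn, Higuchi, MFD summaries, Poincare, Lomb-Scargle band
#' powers, mean HR and RR, watch-compliance fraction, the time-of-day
#' sine/cosine, and the sleep/awake state. Missing modalities yield `NA`
#' features.
#'
#' @param window_start slot start second (subject-local).
#' @param rr_win an `rr_window` from [clean_rr_window()] or `NULL`.
#' @param acc_win,gyr_win `motion_window`s or `NULL`.
#' @param diary sleep diary data frame.
#' @param config a [feature_config()].
#' @return one-row data frame.
#' @export
interval_features <- function(window_start, rr_win = NULL, acc_win = NULL,
                              gyr_win = NULL, diary = NULL,
                              config = feature_config()) {
  tod <- window_start %% DAY_S
  out <- data.frame(
    t_start = window_start,
    state = if (!is.null(diary)) label_state(window_start, diary)
            else NA_character_,
    sin_t = sin(2 * pi * tod / DAY_S),
    cos_t = cos(2 * pi * tod / DAY_S),
    stringsAsFactors = FALSE
  )
  out$ste_acc <- if (!is.null(acc_win) && !acc_win$rejected)
    short_time_energy(acc_win) else NA_real_
  out$ste_gyr <- if (!is.null(gyr_win) && !gyr_win$rejected)
    short_time_energy(gyr_win) else NA_real_

  hrv <- c(sampen = NA, higuchi = NA, mfd_fd1 = NA, mfd_min = NA,
           mfd_max = NA, mfd_mean = NA, mfd_std = NA, sd1 = NA, sd2 = NA,
           lf_pct = NA, hf_pct = NA, lfhf_ratio = NA, hr_mean = NA,
           rr_mean = NA, pct_valid = NA)
  if (!is.null(rr_win) && !rr_win$rejected) {
    rr <- rr_win$rr
    hrv["rr_mean"] <- mean(rr)
    hrv["hr_mean"] <- mean(60000 / rr)
    hrv["pct_valid"] <- rr_win$pct_valid
    if (length(rr) > config$sampen_m + 1)
      hrv["sampen"] <- sample_entropy(rr, config$sampen_m,
                                      config$sampen_r)
    if (length(rr) >= 2 * config$higuchi_kmax)
      hrv["higuchi"] <- higuchi_fd(rr, config$higuchi_kmax)
    if (length(rr) >= 2 * config$mfd_max_scale) {
      mp <- mfd_profile(rr, config)
      hrv["mfd_fd1"] <- mp$fd1; hrv["mfd_min"] <- mp$min
      hrv["mfd_max"] <- mp$max; hrv["mfd_mean"] <- mp$mean
      hrv["mfd_std"] <- mp$std
    }
    if (length(rr) >= 3) {
      ps <- poincare_sd(rr)
      hrv["sd1"] <- ps$sd1; hrv["sd2"] <- ps$sd2
    }
    if (length(rr) >= 4) {
      bt <- window_start + cumsum(rr) / 1000
      bp <- band_powers(lomb_scargle(bt, rr))
      hrv["lf_pct"] <- bp$lf_pct; hrv["hf_pct"] <- bp$hf_pct
      hrv["lfhf_ratio"] <- bp$ratio
    }
  }
  cbind(out, as.data.frame(as.list(hrv)))
}

#' Fixed-seed signal battery for fractal-dimension validation
#'
#' Four canonical one-dimensional test signals -- a line, a sinusoid,
#' white noise, and an fBm-like random walk -- used to exercise the
#' morphological fractal-dimension estimator across its [1, 2] range.
#'
#' @param seed RNG seed (default 0).
#' @param n signal length (default 1000).
#' @return named list of numeric signals.
#' @export
mfd_signal_battery <- function(seed = 0L, n = 1000L) {
  with_seed(seed, list(
    line = seq(0, 10, length.out = n),
    sinusoid = sin(2 * pi * seq_len(n) / 100),
    white_noise = rnorm(n),
    fbm_like = cumsum(rnorm(n))
  ))
}

#' Welch-periodogram band peaks of an RR series
#'
#' The fusion-branch HRV variant: the unevenly sampled RR series is
#' resampled to a uniform grid (linear interpolation), Hann-windowed
#' segments with 50% overlap are periodogram-averaged, and the peak power
#' within the LF [0.04, 0.15] Hz and HF [0.15, 0.40] Hz bands is
#' returned. Complements the Lomb-Scargle normalized band energies of
#' [band_powers()].
#'
#' @param t beat times in seconds, strictly increasing.
#' @param rr RR values (ms) at `t`.
#' @param resample_hz uniform resampling rate (default 4 Hz).
#' @param seg_len segment length in samples (default 256).
#' @param lf,hf band edges in Hz.
#' @return list with `lf_peak` and `hf_peak` (ms^2 per unit frequency).
#' @export
welch_band_peaks <- function(t, rr, resample_hz = 4, seg_len = 256L,
                             lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  stopifnot(length(t) == length(rr), length(t) >= 8)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  grid <- seq(t[1], t[length(t)], by = 1 / resample_hz)
  x <- approx(t, rr, xout = grid)$y
  x <- x - mean(x)
  n <- length(x)
  seg_len <- min(seg_len, n)
  hop <- max(seg_len %/% 2L, 1L)
  starts <- seq(1L, max(n - seg_len + 1L, 1L), by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1))
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * win
    acc <- acc + Mod(fft(seg))^2
  }
  pxx <- acc[seq_len(seg_len %/% 2L + 1L)] /
    (length(starts) * sum(win^2) * resample_hz)
  freqs <- (seq_len(seg_len %/% 2L + 1L) - 1L) * resample_hz / seg_len
  peak <- function(b) {
    i <- freqs >= b[1] & freqs <= b[2]
    if (!any(i)) return(NA_real_)
    max(pxx[i])
  }
  list(lf_peak = peak(lf), hf_peak = peak(hf))
}
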