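# Preprocessing of raw streams into cleaned 5-min analysis windows and
# per-day feature tensors. All window and day boundaries are half-open and
# midnight-anchored in subject-local seconds.

#' Collapse the 5 Hz RR readout to beat events
#'
#' The wrist device repeats the latest RR value at every 5 Hz readout until
#' the next beat; consecutive identical values are collapsed to their first
#' occurrence, whose readout time becomes the beat time.
#'
#' @param stream data frame with columns `t_sec` (sorted) and `rr_ms`.
#' @return data frame `t_sec`, `rr_ms` with one row per beat event.
#' @export
#' @examples
#' dedupe_rr(data.frame(t_sec = 0:4 / 5, rr_ms = c(800, 800, 800, 812, 812)))
dedupe_rr <- function(stream) {
  if (nrow(stream) == 0)
    return(data.frame(t_sec = numeric(), rr_ms = numeric()))
  if (is.unsorted(stream$t_sec)) stop("rr stream must be time-sorted")
  rr <- stream$rr_ms
  keep <- c(TRUE, rr[-1] != rr[-length(rr)])
  data.frame(t_sec = stream$t_sec[keep], rr_ms = rr[keep])
}

#' Clean one 5-minute RR window
#'
#' Removes RR values outside [300, 2000] ms, declares a missed-pulse run
#' wherever an inter-beat spacing exceeds `gap_factor` times the local
#' median RR (11-beat rolling window) and fills it by linear interpolation
#' between the flanking beats, then truncates the sequence to the beats
#' whose cumulative time lies within the first `trunc_s` seconds (90% of
#' the window) so that windows are comparable in length.
#'
#' @param events data frame `t_sec`, `rr_ms` of deduplicated beats inside
#'   the window, time-sorted.
#' @param window_start window start time in seconds (metadata only).
#' @param gap_factor missed-pulse gap threshold as a multiple of the local
#'   median RR (default 1.75).
#' @param trunc_s cumulative-time truncation point (default 270 s = 4.5 min).
#' @param min_beats windows with fewer cleaned beats are rejected with a
#'   `"sparse"` flag (default 10).
#' @return an object of class `rr_window`: list with `window_start`, `rr`
#'   (cleaned ms values), `n_raw`, `pct_valid` (in-range beats / raw
#'   beats), `flags` (character vector, possibly containing `"sparse"` or
#'   `"short"`), `rejected`.
#' @export
clean_rr_window <- function(events, window_start = 0, gap_factor = 1.75,
                            trunc_s = 270, min_beats = 10) {
  n_raw <- nrow(events)
  ok <- events$rr_ms >= 300 & events$rr_ms <= 2000
  rr <- events$rr_ms[ok]
  tt <- events$t_sec[ok]
  pct_valid <- if (n_raw > 0) sum(ok) / n_raw else 0
  flags <- character()

  if (length(rr) < min_beats)
    return(structure(list(window_start = window_start, rr = NULL,
                          n_raw = n_raw, pct_valid = pct_valid,
                          flags = c(flags, "sparse"), rejected = TRUE),
                     class = "rr_window"))

  # Missed-pulse runs: an inter-beat time gap larger than gap_factor x the
  # local median RR hides k missed beats, restored by linear interpolation
  # between the flanking values. When the oversized readout value itself
  # equals the gap (a merged interval) it is replaced along with the fill.
  med <- rolling_median(rr, 11)
  gap_ms <- c(med[1], diff(tt) * 1000)
  out <- rr[1]
  n <- length(rr)
  for (i in 2:n) {
    if (gap_ms[i] > gap_factor * med[i]) {
      k <- max(round(gap_ms[i] / med[i]) - 1, 1)
      merged <- abs(rr[i] - gap_ms[i]) < 0.25 * med[i]
      nxt <- if (merged) rr[min(i + 1, n)] else rr[i]
      fill <- seq(out[length(out)], nxt, length.out = k + 2)[-c(1, k + 2)]
      out <- c(out, fill, if (merged) fill[length(fill)] else rr[i])
    } else {
      out <- c(out, rr[i])
    }
  }
  rr <- out

  cum <- cumsum(rr) / 1000
  keep <- cum <= trunc_s
  if (all(keep)) flags <- c(flags, "short") else rr <- rr[keep]

  structure(list(window_start = window_start, rr = rr, n_raw = n_raw,
                 pct_valid = pct_valid, flags = flags, rejected = FALSE),
            class = "rr_window")
}

rolling_median <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  vapply(seq_len(n), function(i)
    median(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

# ---- periodized Daubechies-4 DWT ------------------------------------------

DB4_LO <- c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.18703481171888114,
            -0.02798376941698385, 0.6308807679295904,
            0.7148465705525415, 0.23037781330885523)
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1, 1, -1, 1, -1)

dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  n2 <- n %/% 2
  a <- numeric(n2); d <- numeric(n2)
  base <- 2 * (seq_len(n2) - 1)
  for (m in 0:7) {
    idx <- (base + m) %% n + 1
    a <- a + DB4_LO[m + 1] * x[idx]
    d <- d + DB4_HI[m + 1] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  n <- 2 * length(a)
  x <- numeric(n)
  base <- 2 * (seq_along(a) - 1)
  for (m in 0:7) {
    idx <- (base + m) %% n + 1
    x[idx] <- x[idx] + DB4_LO[m + 1] * a + DB4_HI[m + 1] * d
  }
  x
}

#' Wavelet high-frequency denoising of a motion axis
#'
#' Decomposes the signal with a periodized orthogonal db4 transform and
#' suppresses the `levels` finest detail bands. The default mode removes
#' those bands entirely: the IMU's intrinsic sensor noise and isolated
#' glitch spikes live in the top octaves, and robust shrinkage thresholds
#' treat large isolated spikes as signal and leave them intact. Classic
#' universal soft-thresholding is available via `mode = "soft"`.
#'
#' @param x numeric vector, length divisible by `2^levels`.
#' @param levels number of finest detail bands to attenuate (default 2).
#' @param mode `"suppress"` (zero the bands) or `"soft"` (universal soft
#'   threshold with MAD noise estimate).
#' @return denoised vector of the same length.
#' @export
denoise_wavelet <- function(x, levels = 2, mode = c("suppress", "soft")) {
  mode <- match.arg(mode)
  stopifnot(length(x) %% (2^levels) == 0)
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a)
    a <- s$a
    details[[l]] <- s$d
  }
  for (l in seq_len(levels)) {
    d <- details[[l]]
    if (mode == "suppress") {
      details[[l]] <- numeric(length(d))
    } else {
      sigma <- median(abs(d)) / 0.6745
      thr <- sigma * sqrt(2 * log(length(x)))
      details[[l]] <- sign(d) * pmax(abs(d) - thr, 0)
    }
  }
  for (l in rev(seq_len(levels))) a <- idwt_step(a, details[[l]])
  a
}

#' Clean one 5-minute motion window
#'
#' Rejects windows with more than `max_missing` missing samples, fills the
#' remaining gaps by nearest-neighbour interpolation, truncates to the
#' first 5940 samples (99% of the nominal 6000) and denoises each axis
#' with [denoise_wavelet()].
#'
#' @param samples numeric matrix of nominally 6000 x 3 samples; missing
#'   samples are `NA` rows.
#' @param modality `"acc"` or `"gyr"` (metadata).
#' @param window_start window start second (metadata).
#' @param max_missing rejection threshold on the missing-sample count
#'   (default 50).
#' @param denoise logical; apply wavelet denoising (default TRUE).
#' @return object of class `motion_window`: list with `samples` (5940 x
#'   3), `modality`, `window_start`, `n_missing`, `rejected` (FALSE), or a
#'   rejection record with `rejected = TRUE` and `reason`.
#' @export
clean_motion_window <- function(samples, modality = "acc",
                                window_start = 0, max_missing = 50,
                                denoise = TRUE) {
  samples <- as.matrix(samples)
  miss <- !complete.cases(samples)
  n_missing <- sum(miss)
  if (n_missing > max_missing)
    return(structure(list(samples = NULL, modality = modality,
                          window_start = window_start,
                          n_missing = n_missing, rejected = TRUE,
                          reason = "missing"),
                     class = "motion_window"))
  if (n_missing > 0) {
    idx <- which(!miss)
    nn <- idx[pmax(1, round(approx(idx, seq_along(idx),
                                   xout = which(miss), rule = 2)$y))]
    samples[miss, ] <- samples[nn, , drop = FALSE]
  }
  samples <- samples[seq_len(min(5940L, nrow(samples))), , drop = FALSE]
  if (denoise && nrow(samples) == 5940L)
    samples <- apply(samples, 2, denoise_wavelet)
  structure(list(samples = samples, modality = modality,
                 window_start = window_start, n_missing = n_missing,
                 rejected = FALSE),
            class = "motion_window")
}

#' Assemble a nominal 6000-sample motion window from a raw stream
#'
#' Maps samples onto the 20 Hz grid of the half-open window
#' `[window_start, window_start + 300)`; grid slots without a sample
#' become `NA` rows (missing).
#'
#' @param stream data frame `t_sec`, `x`, `y`, `z`.
#' @param window_start window start second.
#' @return 6000 x 3 matrix with `NA` rows where samples are missing.
#' @export
window_motion_stream <- function(stream, window_start) {
  sel <- stream$t_sec >= window_start & stream$t_sec < window_start + 300
  sub <- stream[sel, , drop = FALSE]
  out <- matrix(NA_real_, 6000L, 3L)
  if (nrow(sub)) {
    slot <- floor((sub$t_sec - window_start) * 20) + 1L
    slot <- clamp(slot, 1L, 6000L)
    out[slot, ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  out
}

#' Label a window as sleep or awake from the diary
#'
#' A window is `sleep` iff its midpoint falls inside a sleep episode
#' (half-open: a midpoint at the exact episode end is awake).
#'
#' @param window_start window start second.
#' @param diary data frame with `sleep_start`, `sleep_end` (seconds).
#' @param window_s window length (default 300).
#' @return `"sleep"` or `"awake"`.
#' @export
label_state <- function(window_start, diary, window_s = 300) {
  mid <- window_start + window_s / 2
  if (any(mid >= diary$sleep_start & mid < diary$sleep_end)) "sleep"
  else "awake"
}

#' Build the 288 x 10 day tensor from an interval feature table
#'
#' Stacks the 5-min detection features of one subject-day into a 288-slot
#' tensor. Runs of up to 120 consecutive missing slots (10 h) are filled
#' per feature with the median over the surrounding +/- `fill_halfwidth`
#' slots (day median when that window is empty; the deterministic
#' time-of-day sine/cosine are recomputed exactly). A longer run rejects
#' the day.
#'
#' @param day_features data frame for one subject-day with column `slot`
#'   (0-based) and the feature columns.
#' @param features character vector of tensor feature columns (default the
#'   documented 10-feature order).
#' @param max_gap_slots rejection threshold on consecutive missing slots
#'   (default 120 = 10 h).
#' @param fill_halfwidth half-width of the median fill window in slots
#'   (default 12 = 1 h).
#' @return object of class `day_tensor`: list with `tensor` (288 x 10
#'   matrix), `n_filled`, `rejected` (FALSE); or a rejection record with
#'   `rejected = TRUE` and `reason`.
#' @export
build_day_tensor <- function(day_features, features = TENSOR_FEATURES,
                             max_gap_slots = 120L, fill_halfwidth = 12L) {
  stopifnot(all(c("slot", setdiff(features, c("sin_t", "cos_t"))) %in%
                  names(day_features)))
  mat <- matrix(NA_real_, 288L, length(features),
                dimnames = list(NULL, features))
  rows <- day_features$slot + 1L
  for (f in features)
    if (f %in% names(day_features)) mat[rows, f] <- day_features[[f]]

  missing_slot <- !(0:287 %in% day_features$slot)
  if (any(missing_slot)) {
    r <- rle(missing_slot)
    if (any(r$lengths[r$values] > max_gap_slots))
      return(structure(list(tensor = NULL, n_filled = NA_integer_,
                            rejected = TRUE, reason = "gap_over_10h"),
                       class = "day_tensor"))
    tod <- (which(missing_slot) - 1L) * 300
    mat[missing_slot, "sin_t"] <- sin(2 * pi * tod / DAY_S)
    mat[missing_slot, "cos_t"] <- cos(2 * pi * tod / DAY_S)
    for (f in setdiff(features, c("sin_t", "cos_t"))) {
      col <- mat[, f]
      for (i in which(missing_slot)) {
        win <- col[max(1, i - fill_halfwidth):min(288, i + fill_halfwidth)]
        v <- median(win, na.rm = TRUE)
        if (is.na(v)) v <- median(col, na.rm = TRUE)
        mat[i, f] <- v
      }
    }
  }
  structure(list(tensor = mat, n_filled = sum(missing_slot),
                 rejected = FALSE),
            class = "day_tensor")
}
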