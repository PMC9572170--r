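# WAV ingestion and log-mel spectrogram slicing for the speech-based
# anomaly models: 16 kHz target rate, 512-sample frames with 256-sample
# hop, 128 Slaney-style mel bands, 64-frame slices (about one second of
# speech each).

#' Read a PCM WAV file
#'
#' Minimal RIFF reader for 16-bit PCM (mono or multichannel; channels are
#' averaged to mono).
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in [-1, 1]) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE")
    stop("not a WAVE file", call. = FALSE)
  rate <- NULL; n_chan <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      n_chan <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (fmt[1] != 1L || bits != 16L)
        stop("only 16-bit PCM WAV is supported", call. = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (id == "data") {
      raw <- readBin(con, "integer", size %/% 2, 2, signed = TRUE,
                     endian = "little")
      samples <- raw / 32768
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples) || !length(samples))
    stop("no audio data found", call. = FALSE)
  if (n_chan > 1)
    samples <- rowMeans(matrix(samples, ncol = n_chan, byrow = TRUE))
  list(samples = samples, rate = rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric in [-1, 1].
#' @param rate sample rate (Hz).
#' @param path output path.
#' @export
write_wav <- function(samples, rate, path) {
  pcm <- as.integer(clamp(round(samples * 32767), -32768, 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")      # PCM, mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

# Slaney-style mel scale.
hz_to_mel <- function(f)
  ifelse(f < 1000, f / (200 / 3), 15 + 27 * log(f / 1000) / log(6.4))
mel_to_hz <- function(m)
  ifelse(m < 15, m * 200 / 3, 1000 * 6.4^((m - 15) / 27))

mel_filterbank <- function(n_mels, n_fft, rate, fmin = 0,
                           fmax = rate / 2) {
  n_bins <- n_fft %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * rate / n_fft
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                       length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn)) * 2 / (hi - lo)  # area-normalized
  }
  fb
}

#' Slice audio into 128 x 64 log-mel spectrogram matrices
#'
#' Resamples to the target rate (linear interpolation), computes a
#' Hann-windowed STFT with `floor((N - frame) / hop) + 1` frames, maps
#' power spectra through a Slaney mel filterbank, takes dB
#' (`10 log10`), and cuts the spectrogram into non-overlapping
#' `slice_frames`-frame slices, dropping any incomplete trailing slice.
#'
#' @param samples numeric audio samples in [-1, 1], or a [read_wav()]
#'   result list.
#' @param rate input sample rate (ignored when `samples` is a list).
#' @param target_rate resampling target (default 16000 Hz).
#' @param frame,hop STFT frame and hop lengths in samples (512 / 256).
#' @param n_mels mel bands (128).
#' @param slice_frames frames per slice (64).
#' @return list of `n_mels` x `slice_frames` matrices (possibly empty).
#' @export
wav_to_slices <- function(samples, rate = NULL, target_rate = 16000L,
                          frame = 512L, hop = 256L, n_mels = 128L,
                          slice_frames = 64L) {
  if (is.list(samples)) { rate <- samples$rate; samples <- samples$samples }
  stopifnot(!is.null(rate), length(samples) > 0)
  if (rate != target_rate) {
    n_out <- floor(length(samples) * target_rate / rate)
    samples <- approx(seq_along(samples), samples,
                      xout = seq(1, length(samples),
                                 length.out = n_out))$y
    rate <- target_rate
  }
  n <- length(samples)
  if (n < frame) return(list())
  n_frames <- (n - frame) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(frame) - 1) / (frame - 1))
  fm <- matrix(samples[outer(seq_len(frame), starts, "+")], frame,
               n_frames) * win
  spec <- Mod(stats::mvfft(fm))^2
  spec <- spec[seq_len(frame %/% 2 + 1), , drop = FALSE]
  mel <- mel_filterbank(n_mels, frame, rate) %*% spec
  logmel <- 10 * log10(pmax(mel, 1e-10))
  n_slices <- n_frames %/% slice_frames
  lapply(seq_len(n_slices), function(s)
    logmel[, ((s - 1L) * slice_frames + 1L):(s * slice_frames),
           drop = FALSE])
}
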