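# Synthetic interview sessions: spectrogram-domain only. Clean slices come
# from a patient-specific rank-8 non-negative template model; anomalous
# states mix the templates and raise the noise floor proportionally to the
# anomaly magnitude.

#' Simulate spectrogram-slice interview sessions for one patient
#'
#' Each session carries a list of 128 x 64 non-negative log-mel-like
#' matrices (one per second of speech). Session states follow the 30-day
#' pre-relapse rule: `relapse` inside an annotated window, `pre_relapse`
#' within 30 days before onset, `clean` otherwise.
#'
#' @param patient_id patient identifier (also keys the template model).
#' @param annotations relapse annotation data frame (as in
#'   [simulate_cohort()]).
#' @param n_sessions number of sessions (>= 1).
#' @param anomaly_magnitude dimensionless perturbation strength; 0 makes
#'   anomalous sessions statistically identical to clean ones.
#' @param seed integer seed.
#' @param span_days calendar span over which session dates are spread.
#' @param mean_slices mean slices (seconds of speech) per session.
#' @return list of sessions, each with `patient_id`, `session_date` (day
#'   index), `state`, and `slices` (list of 128 x 64 matrices).
#' @export
simulate_sessions <- function(patient_id, annotations, n_sessions,
                              anomaly_magnitude = 1, seed = 1L,
                              span_days = 120L, mean_slices = 30) {
  stopifnot_scalar_count(n_sessions, "n_sessions", min = 1L)
  with_seed(derive_seed(seed, 606), {
    # patient-specific rank-8 spectral templates, smooth along the mel axis
    W <- abs(matrix(rnorm(128 * 8), 128, 8))
    W <- apply(W, 2, function(c) as.numeric(stats::filter(
      c, rep(1 / 7, 7), sides = 2, circular = TRUE)))
    W <- W / mean(W)

    dates <- sort(sample.int(span_days, n_sessions, replace = TRUE) - 1L)
    states <- session_state_labels(annotations, patient_id, dates)

    lapply(seq_len(n_sessions), function(k) {
      n_slices <- 1L + rpois(1, max(mean_slices - 1, 0))
      a <- switch(states[k], clean = 0,
                  pre_relapse = 0.15 * anomaly_magnitude,
                  relapse = 0.3 * anomaly_magnitude)
      Wk <- W
      if (a > 0) {
        P <- matrix(abs(rnorm(64)), 8, 8)
        P <- P / rowSums(P)
        Wk <- (1 - a) * W + a * (W %*% P)
      }
      slices <- lapply(seq_len(n_slices), function(j) {
        H <- abs(matrix(rnorm(8 * 64), 8, 64))
        H <- t(apply(H, 1, function(r) as.numeric(stats::filter(
          r, rep(1 / 5, 5), sides = 2, circular = TRUE))))
        S <- Wk %*% H + (0.1 + a * 0.2) * abs(matrix(rnorm(128 * 64),
                                                     128, 64))
        stopifnot(all(S >= 0))
        S
      })
      list(patient_id = patient_id, session_date = dates[k],
           state = states[k], slices = slices)
    })
  })
}
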