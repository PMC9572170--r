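# Cohort configuration and the population parameter table that the
# interval-level generator draws from. Population values are centred on the
# magnitudes a wrist-worn PPG/IMU cohort produces (RR ~ 800 ms, STE in
# (m/s^2)^2, LF share ~ 31% of LF+HF) so every downstream estimator is
# exercised on realistic scales.

# The 14 per-interval feature types whose per-subject mean/std make up the
# 28 aggregate statistics.
STAT_FEATURE_TYPES <- c(
  "ste_acc", "ste_gyr", "sampen", "higuchi", "sd1", "sd2",
  "lfhf_ratio", "lf_pct", "hf_pct",
  "mfd_mean", "mfd_std", "mfd_fd1", "mfd_max", "mfd_min"
)

# Column order of the detection-model day tensor (288 x 10).
TENSOR_FEATURES <- c(
  "ste_acc", "ste_gyr", "hr_mean", "rr_mean", "lf_pct", "hf_pct",
  "sd1", "sin_t", "cos_t", "pct_valid"
)

SEVERITY_LEVELS <- c("low", "moderate", "severe")
SEVERITY_MULT <- c(low = 0.5, moderate = 1.0, severe = 1.5)

# Population table: per feature type the awake/sleep population mean of the
# subject-level mean aggregate (m_a, m_s), the between-subject sd of that
# mean (bs), and the awake/sleep population within-subject interval sd
# (ws_a, ws_s) whose subject-level realization is the "std" aggregate.
POP_TABLE <- data.frame(
  type = STAT_FEATURE_TYPES,
  m_a  = c(6.5, 4045, 1.45, 1.97, 214, 237, 0.449, 30.86, 69.14,
           1.696, 0.035, 1.614, 1.734, 1.612),
  m_s  = c(0.7, 372, 1.44, 1.88, 79, 112, 0.445, 30.65, 69.35,
           1.529, 0.027, 1.506, 1.565, 1.481),
  bs   = c(1.0, 900, 0.16, 0.02, 20, 22, 0.002, 0.06, 0.06,
           0.03, 0.003, 0.03, 0.03, 0.03),
  ws_a = c(8.0, 5572, 0.41, 0.040, 56, 58, 0.066, 3.11, 3.11,
           0.093, 0.014, 0.071, 0.094, 0.076),
  ws_s = c(2.2, 1324, 0.37, 0.089, 60, 63, 0.066, 3.13, 3.13,
           0.085, 0.015, 0.070, 0.090, 0.075),
  stringsAsFactors = FALSE
)

# Direction in which a relapse pushes each tensor feature, in units of the
# subject's within-interval sd (autonomic arousal: heart rate up, vagal
# markers down, motor variability up, watch compliance down).
RELAPSE_DIRECTION <- c(
  ste_acc = 0.8, ste_gyr = 0.8, hr_mean = 0.8, rr_mean = -0.8,
  lf_pct = 0.8, hf_pct = -0.8, sd1 = -0.8, sin_t = 0, cos_t = 0,
  pct_valid = -0.3,
  sampen = -0.6, higuchi = -0.4, sd2 = -0.6, lfhf_ratio = 0.8,
  mfd_mean = -0.4, mfd_std = 0.4, mfd_fd1 = -0.4, mfd_max = -0.4,
  mfd_min = -0.4
)

#' Configure a synthetic smartwatch cohort
#'
#' Defines the study conditions for [simulate_cohort()]: group sizes,
#' monitoring duration, standardized patient-versus-control effect sizes,
#' the relapse calendar, artifact rates of the 5 Hz RR readout, and the
#' master seed from which every per-subject stream is derived.
#'
#' @param n_controls,n_patients number of control / patient subjects.
#' @param days_per_subject monitored days per subject (>= 1).
#' @param effect_sizes named numeric vector of standardized group shifts on
#'   the subject-level aggregates, e.g. `c(ste_acc_std = 1)` shifts the
#'   patient distribution of the within-subject STE standard deviation by
#'   one between-subject SD. Names are `<feature>_mean` / `<feature>_std`
#'   over the 14 interval feature types plus `steps_mean`, `steps_std`,
#'   `sleep_ratio_mean`, `sleep_ratio_std`.
#' @param relapse_spec `data.frame` with columns `patient` (1-based patient
#'   index), `start_day`, `duration` (days), `severity` (`"low"`,
#'   `"moderate"`, `"severe"`), `psychotic` (logical), `magnitude`
#'   (dimensionless anomaly magnitude; 0 disables the perturbation).
#' @param prodrome_days length of the pre-relapse ramp (default 21 days).
#' @param artifact_rates named vector with `rr_outlier_rate` (per-sample
#'   probability of an out-of-range RR readout), `gap_rate` (per 5-min
#'   block probability of a recording gap) and `repeat_rate` (per-sample
#'   probability of a stuck readout).
#' @param seed integer master seed.
#' @return an object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(2, 2, days_per_subject = 3, seed = 7)
cohort_config <- function(n_controls, n_patients, days_per_subject,
                          effect_sizes = numeric(),
                          relapse_spec = NULL,
                          prodrome_days = 21,
                          artifact_rates = c(rr_outlier_rate = 0.005,
                                             gap_rate = 0.01,
                                             repeat_rate = 0.002),
                          seed = 1L) {
  n_controls <- stopifnot_scalar_count(n_controls, "n_controls")
  n_patients <- stopifnot_scalar_count(n_patients, "n_patients")
  days_per_subject <- stopifnot_scalar_count(days_per_subject,
                                             "days_per_subject", min = 1L)
  prodrome_days <- stopifnot_scalar_count(prodrome_days, "prodrome_days")
  if (any(artifact_rates < 0) || any(is.na(artifact_rates)))
    stop("artifact rates must be non-negative", call. = FALSE)
  rates <- c(rr_outlier_rate = 0, gap_rate = 0, repeat_rate = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (length(effect_sizes) && is.null(names(effect_sizes)))
    stop("'effect_sizes' must be named", call. = FALSE)

  if (!is.null(relapse_spec)) {
    relapse_spec <- as.data.frame(relapse_spec)
    need <- c("patient", "start_day", "duration", "severity")
    if (!all(need %in% names(relapse_spec)))
      stop("relapse_spec needs columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    if (is.null(relapse_spec$psychotic)) relapse_spec$psychotic <- FALSE
    if (is.null(relapse_spec$magnitude)) relapse_spec$magnitude <- 1
    if (!all(relapse_spec$severity %in% SEVERITY_LEVELS))
      stop("severity must be one of: ",
           paste(SEVERITY_LEVELS, collapse = ", "), call. = FALSE)
    if (any(relapse_spec$patient < 1 | relapse_spec$patient > n_patients))
      stop("relapse_spec$patient out of range", call. = FALSE)
    bad <- relapse_spec$start_day < 0 |
      relapse_spec$start_day + relapse_spec$duration > days_per_subject
    if (any(bad))
      stop("relapse windows must lie within [0, days_per_subject)",
           call. = FALSE)
  }

  structure(list(
    n_controls = n_controls, n_patients = n_patients,
    days_per_subject = days_per_subject,
    effect_sizes = effect_sizes,
    relapse_spec = relapse_spec,
    prodrome_days = prodrome_days,
    artifact_rates = rates,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d controls + %d patients, %d days each, seed %d\n",
    x$n_controls, x$n_patients, x$days_per_subject, x$seed))
  if (length(x$effect_sizes))
    cat("  effect sizes:",
        paste(sprintf("%s=%.2g", names(x$effect_sizes), x$effect_sizes),
              collapse = ", "), "\n")
  if (!is.null(x$relapse_spec))
    cat(sprintf("  %d relapse episode(s)\n", nrow(x$relapse_spec)))
  invisible(x)
}
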