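# Interval-level feature generation. Cohort-scale statistics and the
# detection models consume 5-min interval features; drawing them directly
# from the subject parameterization (rather than synthesising 20 Hz raw
# streams for hundreds of subject-days and re-extracting) keeps cohort
# simulations tractable while preserving the group effects, circadian
# state structure and relapse perturbations of the raw model.

subject_level_params <- function(profile, type, state) {
  row <- POP_TABLE[POP_TABLE$type == type, ]
  m_pop <- if (state == "awake") row$m_a else row$m_s
  ws <- if (state == "awake") row$ws_a else row$ws_s
  list(mean = m_pop + row$bs * profile$z[[type]],
       sd = ws * exp(0.2 * profile$u[[type]]))
}

#' Simulate per-interval feature tables for a cohort
#'
#' Draws the 5-minute interval features (the 14 statistical feature types
#' plus heart rate, mean RR, watch-compliance fraction and the time-of-day
#' sine/cosine) for each subject-day from the cohort's subject profiles.
#' Relapse and prodrome windows perturb the interval distributions by the
#' annotated anomaly magnitude scaled by severity (low/moderate/severe =
#' 0.5/1/1.5). LF and HF percentages are complementary by construction and
#' the LF/HF ratio is derived from them.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param subject_ids subjects to include (default all).
#' @param days day indices (default all).
#' @return data frame with one row per retained 5-min interval; columns
#'   `subject_id`, `group`, `day`, `slot`, `t_start`, `state`
#'   (awake/sleep), `day_state` (normal/near_relapse/relapse), the feature
#'   columns, and `missing`-free rows only (recording gaps drop rows at the
#'   configured `gap_rate`).
#' @export
simulate_interval_features <- function(cohort, subject_ids = NULL,
                                       days = NULL) {
  stopifnot(inherits(cohort, "relapse_cohort"))
  if (is.null(subject_ids)) subject_ids <- cohort$subjects$subject_id
  if (is.null(days)) days <- seq_len(cohort$config$days_per_subject) - 1L
  out <- lapply(subject_ids, function(id)
    simulate_subject_intervals(cohort, id, days))
  do.call(rbind, out)
}

simulate_subject_intervals <- function(cohort, id, days) {
  profile <- cohort$profiles[[id]]
  config <- cohort$config
  diary <- cohort$diaries[[id]]
  ann <- cohort$annotations

  with_seed(derive_seed(profile$seed, 303), {
    slots <- 0:287
    grid <- expand.grid(slot = slots, day = days)
    n <- nrow(grid)
    t_start <- grid$day * DAY_S + grid$slot * 300
    mid <- t_start + 150
    asleep <- sleep_lookup(diary)(mid)
    state <- ifelse(asleep, "sleep", "awake")
    mag <- vapply(days, function(d)
      relapse_magnitude_at(ann, id, d, config$prodrome_days), numeric(1))
    mag <- mag[match(grid$day, days)]
    dstate <- day_state_labels(ann, id, days, config$prodrome_days)
    dstate <- dstate[match(grid$day, days)]

    df <- data.frame(subject_id = id, group = profile$group,
                     day = grid$day, slot = grid$slot, t_start = t_start,
                     state = state, day_state = dstate,
                     stringsAsFactors = FALSE)

    draw_type <- function(type) {
      v <- numeric(n)
      for (st in c("awake", "sleep")) {
        i <- state == st
        if (!any(i)) next
        p <- subject_level_params(profile, type, st)
        shift <- RELAPSE_DIRECTION[[type]] * mag[i] * p$sd
        v[i] <- rnorm(sum(i), p$mean + shift, p$sd)
      }
      v
    }

    for (type in setdiff(STAT_FEATURE_TYPES,
                         c("hf_pct", "lfhf_ratio")))
      df[[type]] <- draw_type(type)
    df$lf_pct <- clamp(df$lf_pct, 1, 99)
    df$hf_pct <- 100 - df$lf_pct
    df$lfhf_ratio <- df$lf_pct / df$hf_pct
    df$sampen <- pmax(df$sampen, 0)
    df$sd1 <- pmax(df$sd1, 1)
    df$sd2 <- pmax(df$sd2, 1)
    df$mfd_std <- pmax(df$mfd_std, 0)
    for (m in c("mfd_mean", "mfd_fd1", "mfd_max", "mfd_min"))
      df[[m]] <- clamp(df[[m]], 1, 2)
    df$ste_acc <- pmax(df$ste_acc, 0.01)
    df$ste_gyr <- pmax(df$ste_gyr, 0.1)

    base_rr <- profile$baseline_rr + 120 * asleep +
      RELAPSE_DIRECTION[["rr_mean"]] * mag * 30
    df$rr_mean <- clamp(rnorm(n, base_rr, 30), 400, 1800)
    df$hr_mean <- 60000 / df$rr_mean
    df$pct_valid <- clamp(
      rnorm(n, profile$pct_valid_level +
              RELAPSE_DIRECTION[["pct_valid"]] * mag * 0.05, 0.03), 0, 1)
    tod <- t_start %% DAY_S
    df$sin_t <- sin(2 * pi * tod / DAY_S)
    df$cos_t <- cos(2 * pi * tod / DAY_S)

    gap <- config$artifact_rates[["gap_rate"]]
    if (gap > 0) df <- df[runif(n) >= gap, , drop = FALSE]
    df
  })
}

#' Simulate the per-day activity ledger
#'
#' Steps per day and recorded hours for every subject-day, alongside the
#' slept/awake hours implied by the sleep diary; input to
#' [daily_activity()].
#'
#' @param cohort a [simulate_cohort()] object.
#' @return data frame with columns `subject_id`, `day`, `steps`,
#'   `recorded_hours`.
#' @export
simulate_daily_table <- function(cohort) {
  stopifnot(inherits(cohort, "relapse_cohort"))
  out <- lapply(cohort$subjects$subject_id, function(id) {
    p <- cohort$profiles[[id]]
    with_seed(derive_seed(p$seed, 404), {
      days <- seq_len(cohort$config$days_per_subject) - 1L
      steps <- pmax(rnorm(length(days), p$steps_level, p$steps_spread), 0)
      rec <- 24 - rexp(length(days), 2)
      low <- runif(length(days)) < 0.08   # occasional poorly-worn days
      rec[low] <- runif(sum(low), 10, 20)
      data.frame(subject_id = id, day = days, steps = round(steps),
                 recorded_hours = clamp(rec, 0, 24))
    })
  })
  do.call(rbind, out)
}

#' Simulate hourly 5 x 30 HRV tensors
#'
#' Emulates the fusion-branch physiological representation: five HRV
#' features (mean HR, mean RR, LF and HF band peaks, Poincare SD1)
#' averaged over 2-min slots and stacked into one-hour 5 x 30 tensors,
#' with relapse perturbations as in [simulate_interval_features()].
#'
#' @param cohort a [simulate_cohort()] object.
#' @param subject_id one subject id.
#' @param days day indices (default all).
#' @param hours hours-of-day to emit (default 9:20, waking hours).
#' @return list of entries with `tensor` (5 x 30 matrix), `day`, `hour`,
#'   `day_state` (30-day session rule).
#' @export
simulate_hour_tensors <- function(cohort, subject_id, days = NULL,
                                  hours = 9:20) {
  stopifnot(inherits(cohort, "relapse_cohort"))
  p <- cohort$profiles[[subject_id]]
  config <- cohort$config
  if (is.null(days)) days <- seq_len(config$days_per_subject) - 1L
  ann <- cohort$annotations
  states <- session_state_labels(ann, subject_id, days)
  with_seed(derive_seed(p$seed, 505), {
    out <- list()
    for (i in seq_along(days)) {
      d <- days[i]
      mag <- relapse_magnitude_at(ann, subject_id, d, 0)
      for (h in hours) {
        rr <- clamp(rnorm(30, p$baseline_rr - 24 * mag, 25), 400, 1800)
        hr <- 60000 / rr
        lf <- pmax(rnorm(30, p$lf_amp^2 * (1 + 0.2 * mag),
                         p$lf_amp^2 * 0.2), 1)
        hf <- pmax(rnorm(30, p$hf_amp^2 * (1 - 0.15 * mag),
                         p$hf_amp^2 * 0.2), 1)
        sd1 <- pmax(rnorm(30, 40 * (1 - 0.2 * mag), 8), 1)
        out[[length(out) + 1L]] <- list(
          tensor = rbind(hr_mean = hr, rr_mean = rr, lf_peak = lf,
                         hf_peak = hf, sd1 = sd1),
          day = d, hour = h, day_state = states[i])
      }
    }
    out
  })
}

# Session-rule (30-day) state labels for whole days.
session_state_labels <- function(annotations, subject_id, days) {
  ann <- annotations[annotations$subject_id == subject_id, , drop = FALSE]
  state <- rep("clean", length(days))
  for (k in seq_len(nrow(ann))) {
    pre <- days >= ann$start_day[k] - 30 & days < ann$start_day[k]
    state[pre & state == "clean"] <- "pre_relapse"
    inwin <- days >= ann$start_day[k] & days < ann$end_day[k]
    state[inwin] <- "relapse"
  }
  state
}
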