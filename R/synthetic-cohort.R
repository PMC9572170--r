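# Cohort-level simulation. Each subject's epoch is local midnight of day 0;
# all times are seconds since epoch, days are the half-open intervals
# [86400*k, 86400*(k+1)).

DAY_S <- 86400

#' Simulate a cohort of controls and patients
#'
#' Realizes subject profiles (baseline RR, LF/HF oscillation amplitudes,
#' activity level, sleep window, per-feature random effects and configured
#' group shifts), sleep diaries and the relapse calendar. Raw sensor streams
#' and interval-level feature tables are generated per subject from this
#' object by [simulate_subject()] and [simulate_interval_features()]; all
#' per-subject seeds derive deterministically from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `relapse_cohort` with elements `config`,
#'   `subjects` (data frame: `subject_id`, `group`, `seed`), `profiles`
#'   (named list), `diaries` (named list of data frames with absolute
#'   `sleep_start`/`sleep_end` seconds), `annotations` (data frame) and
#'   `manifest`.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(2, 2, days_per_subject = 3, seed = 1))
#' co$manifest$n_subject_days
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- c(sprintf("C%02d", seq_len(config$n_controls)),
           sprintf("P%02d", seq_len(config$n_patients)))
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  groups <- rep(c("control", "patient"),
                c(config$n_controls, config$n_patients))
  subjects <- data.frame(subject_id = ids, group = groups,
                         seed = vapply(seq_along(ids), function(i)
                           derive_seed(config$seed, i), integer(1)),
                         stringsAsFactors = FALSE)

  profiles <- lapply(seq_along(ids), function(i)
    make_profile(ids[i], groups[i], subjects$seed[i], config))
  names(profiles) <- ids

  diaries <- lapply(profiles, function(p) make_diary(p, config))
  annotations <- make_annotations(config, ids)

  manifest <- list(
    subjects = subjects[, c("subject_id", "group")],
    seeds = setNames(subjects$seed, ids),
    days_per_subject = config$days_per_subject,
    n_subject_days = nrow(subjects) * config$days_per_subject,
    relapse_calendar = annotations,
    master_seed = config$seed
  )
  structure(list(config = config, subjects = subjects, profiles = profiles,
                 diaries = diaries, annotations = annotations,
                 manifest = manifest),
            class = "relapse_cohort")
}

#' @export
print.relapse_cohort <- function(x, ...) {
  cat(sprintf("<relapse_cohort> %d subjects x %d days, %d relapse(s)\n",
              nrow(x$subjects), x$config$days_per_subject,
              nrow(x$annotations)))
  invisible(x)
}

# Subject profile: physiological baselines plus the per-feature random
# effects (z for the mean aggregate, u for the std aggregate) that the
# interval generator turns into subject-level means and scales.
make_profile <- function(id, group, seed, config) {
  with_seed(seed, {
    nt <- length(STAT_FEATURE_TYPES)
    p <- list(
      subject_id = id, group = group, seed = seed,
      baseline_rr = clamp(rnorm(1, 800, 60), 600, 1100),
      lf_amp = clamp(rnorm(1, 30, 5), 10, 60),
      hf_amp = clamp(rnorm(1, 20, 4), 5, 45),
      activity_level = rlnorm(1, log(1.2), 0.25),
      sleep_onset = rnorm(1, 23.0, 0.6),
      sleep_offset = rnorm(1, 7.0, 0.6),
      z = setNames(rnorm(nt), STAT_FEATURE_TYPES),
      u = setNames(rnorm(nt), STAT_FEATURE_TYPES),
      steps_level = rnorm(1, 7000, 1800),
      steps_spread = clamp(rnorm(1, 3200, 900), 500, Inf),
      pct_valid_level = clamp(rnorm(1, 0.96, 0.02), 0.7, 1)
    )
    if (p$sleep_offset <= 0.5) p$sleep_offset <- 0.5  # non-degenerate window
    if (group == "patient") {
      es <- config$effect_sizes
      shift <- function(key) if (key %in% names(es)) es[[key]] else 0
      p$z <- p$z + vapply(STAT_FEATURE_TYPES,
                          function(t) shift(paste0(t, "_mean")), numeric(1))
      p$u <- p$u + vapply(STAT_FEATURE_TYPES,
                          function(t) shift(paste0(t, "_std")), numeric(1))
      p$steps_level <- p$steps_level + shift("steps_mean") * 1800
      p$steps_spread <- p$steps_spread + shift("steps_std") * 900
      p$sleep_onset <- p$sleep_onset + shift("sleep_ratio_mean") * (-0.8)
      p$sleep_offset <- p$sleep_offset + shift("sleep_ratio_mean") * 0.8
    }
    p
  })
}

# One sleep episode per night, crossing midnight: onset on day k, offset on
# day k + 1. Episodes are ordered and non-overlapping by construction.
make_diary <- function(profile, config) {
  with_seed(derive_seed(profile$seed, 101), {
    days <- seq_len(config$days_per_subject) - 1L
    onset <- profile$sleep_onset + rnorm(length(days), 0, 0.3)
    offset <- profile$sleep_offset + rnorm(length(days), 0, 0.3)
    onset <- clamp(onset, 20.5, 25.5)
    offset <- clamp(offset, 4.5, 10.5)
    start <- days * DAY_S + onset * 3600
    end <- (days + 1) * DAY_S + offset * 3600
    data.frame(day = days, sleep_start = start, sleep_end = end)
  })
}

make_annotations <- function(config, ids) {
  rs <- config$relapse_spec
  if (is.null(rs) || nrow(rs) == 0)
    return(data.frame(subject_id = character(), start_day = numeric(),
                      end_day = numeric(), start_s = numeric(),
                      end_s = numeric(), severity = character(),
                      psychotic = logical(), magnitude = numeric(),
                      stringsAsFactors = FALSE))
  pid <- sprintf("P%02d", rs$patient)
  out <- data.frame(
    subject_id = pid,
    start_day = rs$start_day,
    end_day = rs$start_day + rs$duration,
    start_s = rs$start_day * DAY_S,
    end_s = (rs$start_day + rs$duration) * DAY_S,
    severity = as.character(rs$severity),
    psychotic = as.logical(rs$psychotic),
    magnitude = rs$magnitude,
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$end_s > out$start_s))
  out[order(out$subject_id, out$start_s), , drop = FALSE]
}

# Effective relapse magnitude for a subject at a day (prodrome ramps
# linearly from 0 to half magnitude over the `prodrome_days` before onset).
relapse_magnitude_at <- function(annotations, subject_id, day,
                                 prodrome_days) {
  ann <- annotations[annotations$subject_id == subject_id, , drop = FALSE]
  if (nrow(ann) == 0) return(0)
  mag <- 0
  for (k in seq_len(nrow(ann))) {
    m <- ann$magnitude[k] * SEVERITY_MULT[[ann$severity[k]]]
    if (day >= ann$start_day[k] && day < ann$end_day[k]) {
      mag <- max(mag, m)
    } else if (prodrome_days > 0 && day < ann$start_day[k] &&
               day >= ann$start_day[k] - prodrome_days) {
      frac <- 1 - (ann$start_day[k] - day) / prodrome_days
      mag <- max(mag, 0.5 * m * frac)
    }
  }
  mag
}

# Day-level state labels under the physiological (21-day) rule.
day_state_labels <- function(annotations, subject_id, days,
                             prodrome_days = 21) {
  ann <- annotations[annotations$subject_id == subject_id, , drop = FALSE]
  state <- rep("normal", length(days))
  for (k in seq_len(nrow(ann))) {
    pre <- days >= ann$start_day[k] - prodrome_days & days < ann$start_day[k]
    state[pre & state == "normal"] <- "near_relapse"
    inwin <- days >= ann$start_day[k] & days < ann$end_day[k]
    state[inwin] <- "relapse"
  }
  state
}
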