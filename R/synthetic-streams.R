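# Raw-stream simulation for one subject. The RR generator is a two-sinusoid
# (LF ~ 0.1 Hz, HF ~ 0.25 Hz) plus AR(1) beat model read out at 5 Hz with
# the latest beat value repeated until the next beat, reproducing the
# identical-consecutive-values artifact the preprocessor removes. Motion is
# a circadian-gated two-state bout process at 20 Hz.

#' Simulate raw sensor streams for one subject
#'
#' @param profile a subject profile from a [simulate_cohort()] object.
#' @param config the [cohort_config()] used to build the cohort.
#' @param annotations relapse annotation data frame (rows for this subject
#'   are honoured; default none).
#' @param diary optional precomputed sleep diary; regenerated from the
#'   profile when `NULL`.
#' @param days integer vector of day indices to simulate (default all).
#' @return list with `streams` (named list of data frames `acc`, `gyr`,
#'   `rr`, `steps`), `diary`, and `annotations` (rows for this subject).
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(1, 0, days_per_subject = 1, seed = 3))
#' s <- simulate_subject(co$profiles[[1]], co$config)
#' head(s$streams$rr)
simulate_subject <- function(profile, config, annotations = NULL,
                             diary = NULL, days = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$days_per_subject == 0)
    stop("days_per_subject must be positive", call. = FALSE)
  if (any(config$artifact_rates < 0))
    stop("artifact rates must be non-negative", call. = FALSE)
  if (is.null(days)) days <- seq_len(config$days_per_subject) - 1L
  if (is.null(diary)) diary <- make_diary(profile, config)
  if (is.null(annotations))
    annotations <- make_annotations(config, character())
  ann <- annotations[annotations$subject_id == profile$subject_id, ,
                     drop = FALSE]

  sleep_fun <- sleep_lookup(diary)
  out <- with_seed(derive_seed(profile$seed, 202), {
    parts <- lapply(days, function(d)
      simulate_day_streams(profile, config, ann, d, sleep_fun))
    rr <- do.call(rbind, lapply(parts, `[[`, "rr"))
    attr(rr, "beat_t") <- unlist(lapply(parts, function(p)
      attr(p$rr, "beat_t")), use.names = FALSE)
    list(
      acc = do.call(rbind, lapply(parts, `[[`, "acc")),
      gyr = do.call(rbind, lapply(parts, `[[`, "gyr")),
      rr = rr,
      steps = do.call(rbind, lapply(parts, `[[`, "steps"))
    )
  })
  list(streams = out, diary = diary, annotations = ann)
}

sleep_lookup <- function(diary) {
  starts <- diary$sleep_start
  ends <- diary$sleep_end
  function(t) {
    if (!length(starts)) return(rep(FALSE, length(t)))
    res <- rep(FALSE, length(t))
    for (k in seq_along(starts))
      res <- res | (t >= starts[k] & t < ends[k])
    res
  }
}

simulate_day_streams <- function(profile, config, ann, day, sleep_fun) {
  mag <- relapse_magnitude_at(ann, profile$subject_id, day,
                              config$prodrome_days)
  t0 <- day * DAY_S
  t1 <- t0 + DAY_S

  ## ---- RR beats ----------------------------------------------------------
  base <- profile$baseline_rr - 30 * mag
  n_max <- ceiling(DAY_S / (base / 1000) * 1.3)
  e <- rnorm(n_max, 0, 15)
  arn <- as.numeric(stats::filter(e, 0.9, method = "recursive"))
  t_approx <- t0 + cumsum(rep(base / 1000, n_max))
  asleep <- sleep_fun(t_approx)
  rr <- base + 120 * asleep +
    profile$lf_amp * sin(2 * pi * 0.1 * t_approx) +
    profile$hf_amp * sin(2 * pi * 0.25 * t_approx) + arn
  rr <- clamp(rr, 350, 1900)
  beat_t <- t0 + cumsum(rr) / 1000
  keep <- beat_t < t1
  rr <- rr[keep]; beat_t <- beat_t[keep]

  # 5 Hz readout: latest beat value repeated until the next beat
  grid <- seq(t0, t1 - 0.2, by = 0.2)
  idx <- findInterval(grid, beat_t)
  valid <- idx >= 1
  rr_read <- rr[pmax(idx, 1L)]
  grid <- grid[valid]; rr_read <- rr_read[valid]

  rates <- config$artifact_rates
  if (rates[["repeat_rate"]] > 0) {
    stuck <- which(runif(length(rr_read)) < rates[["repeat_rate"]])
    stuck <- stuck[stuck > 1]
    if (length(stuck)) rr_read[stuck] <- rr_read[stuck - 1]
  }
  if (rates[["rr_outlier_rate"]] > 0) {
    out_i <- which(runif(length(rr_read)) < rates[["rr_outlier_rate"]])
    if (length(out_i)) {
      lo <- runif(length(out_i)) < 0.5
      rr_read[out_i] <- ifelse(lo, runif(sum(lo) + sum(!lo), 80, 295),
                               runif(length(out_i), 2050, 3500))[
                                 seq_along(out_i)]
    }
  }

  ## ---- motion bouts (1 s states -> 20 Hz samples) ------------------------
  sec <- seq(t0, t1 - 1)
  asleep_s <- sleep_fun(sec + 0.5)
  p_on <- ifelse(asleep_s, 0.004, 0.05)
  p_off <- ifelse(asleep_s, 0.5, 0.1)
  u <- runif(length(sec))
  state <- integer(length(sec))
  s <- 0L
  for (i in seq_along(sec)) {           # two-state bout chain
    s <- if (s == 0L) as.integer(u[i] < p_on[i])
         else 1L - as.integer(u[i] < p_off[i])
    state[i] <- s
  }
  act <- profile$activity_level * (1 + 0.25 * mag)
  sd_sec <- ifelse(state == 1L, act, 0.05) * ifelse(asleep_s, 0.3, 1)
  sd20 <- rep(sd_sec, each = 20L)
  n20 <- length(sd20)
  tm <- t0 + (seq_len(n20) - 1) / 20
  acc <- data.frame(t_sec = tm,
                    x = rnorm(n20, 0, sd20),
                    y = rnorm(n20, 0, sd20),
                    z = 9.81 + rnorm(n20, 0, sd20))
  gsd <- sd20 * 40
  gyr <- data.frame(t_sec = tm,
                    x = rnorm(n20, 0, gsd),
                    y = rnorm(n20, 0, gsd),
                    z = rnorm(n20, 0, gsd))

  ## ---- recording gaps ----------------------------------------------------
  if (rates[["gap_rate"]] > 0) {
    blocks <- which(runif(288) < rates[["gap_rate"]]) - 1L
    for (b in blocks) {
      gs <- t0 + b * 300 + runif(1, 0, 240)
      ge <- gs + runif(1, 10, 60)
      acc <- acc[acc$t_sec < gs | acc$t_sec >= ge, , drop = FALSE]
      gyr <- gyr[gyr$t_sec < gs | gyr$t_sec >= ge, , drop = FALSE]
      kg <- grid < gs | grid >= ge
      grid <- grid[kg]; rr_read <- rr_read[kg]
    }
  }

  ## ---- steps per minute --------------------------------------------------
  mins <- seq(t0, t1 - 60, by = 60)
  active_s <- tapply(state, rep(seq_along(mins), each = 60)[seq_along(state)],
                     sum)
  steps <- rpois(length(mins), 1.8 * as.numeric(active_s))
  rr_df <- data.frame(t_sec = grid, rr_ms = rr_read,
                      hr_bpm = 60000 / rr_read)
  attr(rr_df, "beat_t") <- beat_t    # ground-truth beat times for audits
  list(acc = acc, gyr = gyr, rr = rr_df,
       steps = data.frame(t_sec = mins, steps = steps))
}
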