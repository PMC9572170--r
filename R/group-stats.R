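# Patient-versus-control statistics: per-subject aggregation into 28
# features per state, two-tailed Mann-Whitney U tests with
# Benjamini-Hochberg adjustment, and the recorded-data balance checks.

#' Aggregate interval features into per-subject summaries
#'
#' Mean and standard deviation over a subject's intervals, separately per
#' sleep/awake state, for each of the 14 feature types: 28 aggregate
#' values per state.
#'
#' @param intervals interval feature data frame (one subject), with
#'   columns `state` and the feature types.
#' @param feature_types character vector (default the 14 standard types).
#' @return data frame with one row per state: `subject_id`, `state`,
#'   `n_intervals`, `flagged` (TRUE when fewer than 2 intervals make the
#'   SD undefined), then `<type>_mean` and `<type>_std` columns.
#' @export
aggregate_subject <- function(intervals,
                              feature_types = STAT_FEATURE_TYPES) {
  stopifnot("state" %in% names(intervals))
  missing_cols <- setdiff(feature_types, names(intervals))
  if (length(missing_cols))
    stop("missing feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- lapply(c("awake", "sleep"), function(st) {
    sub <- intervals[intervals$state == st, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    row <- data.frame(
      subject_id = sub$subject_id[1] %||% NA_character_,
      state = st, n_intervals = nrow(sub),
      flagged = nrow(sub) < 2, stringsAsFactors = FALSE)
    for (f in feature_types) {
      row[[paste0(f, "_mean")]] <- mean(sub[[f]], na.rm = TRUE)
      row[[paste0(f, "_std")]] <- if (nrow(sub) >= 2)
        sd(sub[[f]], na.rm = TRUE) else NA_real_
    }
    row
  })
  do.call(rbind, out)
}

#' Two-tailed Mann-Whitney U test
#'
#' Midrank tie handling; the exact permutation distribution is used for
#' combined samples up to `exact_max` without ties, the tie-corrected
#' normal approximation otherwise (delegated to [stats::wilcox.test()]).
#'
#' @param a,b numeric samples (both non-empty).
#' @param exact_max switchover size for the exact null distribution.
#' @return list with `U` (statistic for `a`) and `p` (two-tailed).
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  same <- (length(a) == length(b) && all(sort(a) == sort(b))) ||
    length(unique(c(a, b))) == 1L
  if (same) return(list(U = length(a) * length(b) / 2, p = 1))
  exact <- (length(a) + length(b)) <= exact_max && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                     correct = !exact))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, elementwise >= `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Patient-versus-control comparison table
#'
#' For one state, compares every aggregate feature between groups with
#' two-tailed Mann-Whitney U tests, reports group medians and IQRs
#' (linear-interpolation quantiles), and adjusts p-values across all
#' features of the run with Benjamini-Hochberg.
#'
#' @param summaries per-subject summary data frame (rows from
#'   [aggregate_subject()] across subjects) with a `group` column.
#' @param state `"awake"` or `"sleep"`.
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @return data frame of class `group_comparison`, one row per feature:
#'   `feature`, `state`, `control_median`, `control_iqr`,
#'   `patient_median`, `patient_iqr`, `U`, `p`, `p_adj`, `significant`.
#' @export
group_comparison <- function(summaries, state = "awake", alpha = 0.05) {
  stopifnot(all(c("group", "state") %in% names(summaries)))
  sub <- summaries[summaries$state == state, , drop = FALSE]
  ctrl <- sub[sub$group == "control", , drop = FALSE]
  pat <- sub[sub$group == "patient", , drop = FALSE]
  if (nrow(ctrl) < 2 || nrow(pat) < 2)
    stop("need >= 2 subjects per group", call. = FALSE)
  feats <- grep("_(mean|std)$", names(sub), value = TRUE)
  if (!length(feats)) stop("no aggregate feature columns found")
  rows <- lapply(feats, function(f) {
    x <- na.omit(ctrl[[f]]); y <- na.omit(pat[[f]])
    mw <- mann_whitney_u(x, y)
    data.frame(feature = f, state = state,
               control_median = median(x), control_iqr = iqr7(x),
               patient_median = median(y), patient_iqr = iqr7(y),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Recorded-data balance check
#'
#' Tests whether per-subject recorded-interval counts differ between
#' groups: Student's t-test when both groups pass Shapiro-Wilk normality
#' at `alpha_norm`, otherwise the Mann-Whitney fallback.
#'
#' @param counts_control,counts_patient per-subject counts (>= 3 each).
#' @param alpha_norm normality screening level (default 0.05).
#' @return list with `shapiro_p` (per group), `method` (`"t"` or
#'   `"wilcox"`), and `p` for the group difference.
#' @export
recorded_balance_check <- function(counts_control, counts_patient,
                                   alpha_norm = 0.05) {
  stopifnot(length(counts_control) >= 3, length(counts_patient) >= 3)
  sw <- c(control = shapiro_p_safe(counts_control),
          patient = shapiro_p_safe(counts_patient))
  if (all(sw > alpha_norm)) {
    p <- t.test(counts_control, counts_patient)$p.value
    method <- "t"
  } else {
    p <- mann_whitney_u(counts_control, counts_patient)$p
    method <- "wilcox"
  }
  list(shapiro_p = sw, method = method, p = p)
}

shapiro_p_safe <- function(x) {
  if (length(unique(x)) < 3) return(0)   # degenerate: treat as non-normal
  shapiro.test(x)$p.value
}

#' Boxplot summary (median, quartiles, 1.5 IQR whiskers, outliers)
#'
#' @param x numeric vector.
#' @return list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
boxplot_stats <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  list(median = q[2], q1 = q[1], q3 = q[3], whisker_lo = lo,
       whisker_hi = hi, outliers = x[x < lo | x > hi])
}
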