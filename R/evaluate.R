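# Experiment protocol: grouped 5-fold 60/20/20 splits with a halved
# validation set, train-partition min-max normalization, temporal pooling,
# day averaging, ROC/PR evaluation with per-fold medians, the
# personalized/global runners, severity analysis and decision-level fusion.

#' Grouped k-fold split plans (60/20/20 with halved validation)
#'
#' Normal groups (days or interview sessions) rotate through the test
#' partition across folds; of the remaining normal groups, three quarters
#' train and one quarter validate, the validation groups being halved into
#' two equal subsets (sizes differ by at most one). Anomalous groups are
#' appended to every fold's test set (switchable) and never reach
#' training or validation.
#'
#' @param groups character vector of group keys, one per instance.
#' @param anomalous logical per instance (group-constant).
#' @param k folds (default 5).
#' @param seed shuffling seed.
#' @param anomalous_in_every_fold append anomalous groups to every fold's
#'   test set (default) rather than partitioning them across folds.
#' @return list of `split_plan`s: `fold`, `train`, `val1`, `val2`, `test`
#'   (instance indices).
#' @export
make_splits <- function(groups, anomalous, k = 5L, seed = 1L,
                        anomalous_in_every_fold = TRUE) {
  stopifnot(length(groups) == length(anomalous))
  g_anom <- tapply(anomalous, groups, any)
  normal_groups <- names(g_anom)[!g_anom]
  anom_groups <- names(g_anom)[g_anom]
  if (length(normal_groups) < k)
    stop("need at least k normal groups", call. = FALSE)
  ord <- with_seed(derive_seed(seed, 17), sample(normal_groups))
  part <- split(ord, rep_len(seq_len(k), length(ord)))
  anom_parts <- if (anomalous_in_every_fold) NULL else
    split(with_seed(derive_seed(seed, 18), sample(anom_groups)),
          rep_len(seq_len(k), max(length(anom_groups), 1L)))
  lapply(seq_len(k), function(i) {
    test_g <- part[[i]]
    val_g <- part[[if (i == k) 1L else i + 1L]]
    train_g <- setdiff(normal_groups, c(test_g, val_g))
    half <- ceiling(length(val_g) / 2)
    val1_g <- val_g[seq_len(half)]
    val2_g <- setdiff(val_g, val1_g)
    test_anom <- if (anomalous_in_every_fold) anom_groups
                 else anom_parts[[i]] %||% character()
    structure(list(
      fold = i,
      train = which(groups %in% train_g),
      val1 = which(groups %in% val1_g),
      val2 = which(groups %in% val2_g),
      test = which(groups %in% c(test_g, test_anom))),
      class = "split_plan")
  })
}

#' Min-max feature normalization fitted on the training partition
#'
#' Maps each feature to [0, 1] using training-partition minima and maxima
#' (per patient when `mode = "per_patient"`); the time-of-day sine/cosine
#' columns pass through unchanged; out-of-range test values are clipped;
#' constant features map to 0.5 with a warning.
#'
#' @param x numeric matrix (rows = instances or time points).
#' @param fit_idx rows to fit the transform on.
#' @param mode `"global"` or `"per_patient"`.
#' @param patient row patient ids (`per_patient` mode).
#' @param exempt columns passed through (default `sin_t`, `cos_t`).
#' @return list with `x` (normalized matrix) and `transform` (per-feature
#'   ranges).
#' @export
normalize_features <- function(x, fit_idx, mode = c("global",
                                                    "per_patient"),
                               patient = NULL,
                               exempt = c("sin_t", "cos_t")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  cols <- setdiff(colnames(x) %||% as.character(seq_len(ncol(x))), exempt)
  norm_block <- function(xb, fit_rows) {
    rng <- list()
    for (f in cols) {
      v <- xb[fit_rows, f]
      lo <- min(v); hi <- max(v)
      if (hi - lo < .Machine$double.eps) {
        warning("constant feature '", f, "' maps to 0.5", call. = FALSE)
        xb[, f] <- 0.5
      } else {
        xb[, f] <- clamp((xb[, f] - lo) / (hi - lo), 0, 1)
      }
      rng[[f]] <- c(lo, hi)
    }
    list(x = xb, rng = rng)
  }
  if (mode == "global") {
    res <- norm_block(x, fit_idx)
    return(list(x = res$x, transform = list(global = res$rng)))
  }
  stopifnot(!is.null(patient))
  tr <- list()
  for (p in unique(patient)) {
    rows <- which(patient == p)
    fit_p <- intersect(fit_idx, rows)
    if (!length(fit_p)) fit_p <- fit_idx    # fall back to global fit rows
    res <- norm_block(x[rows, , drop = FALSE],
                      match(fit_p, rows))
    x[rows, ] <- res$x
    tr[[p]] <- res$rng
  }
  list(x = x, transform = tr)
}

#' Temporal pooling of per-instance scores
#'
#' Average (`AP`), max (`MP`) or norm pooling (`NP`,
#' `(mean(s^p))^(1/p)`, default p = 10, requiring non-negative scores).
#'
#' @param scores numeric vector (non-empty).
#' @param method `"AP"`, `"MP"` or `"NP"`.
#' @param p norm-pooling exponent (>= 1).
#' @return pooled scalar.
#' @export
pool_scores <- function(scores, method = c("AP", "MP", "NP"), p = 10) {
  method <- match.arg(method)
  stopifnot(length(scores) > 0, p >= 1)
  switch(method,
         AP = mean(scores),
         MP = max(scores),
         NP = {
           if (any(scores < 0))
             stop("norm pooling requires non-negative scores",
                  call. = FALSE)
           mean(scores^p)^(1 / p)
         })
}

#' Average per-point scores over subject-local days
#'
#' @param scores numeric vector.
#' @param days day key per score (numeric day index or any grouping key;
#'   returned as character).
#' @return data frame `day`, `score` (mean), empty days dropped.
#' @export
day_average <- function(scores, days) {
  m <- tapply(scores, days, mean)
  data.frame(day = names(m), score = as.numeric(m),
             stringsAsFactors = FALSE)
}

#' ROC-AUC and PR-AUC of anomaly scores
#'
#' ROC-AUC through the Mann-Whitney identity on midranks; PR-AUC by
#' interpolation-free step integration with the anomalous class positive.
#' The base rate is reported alongside since PR-AUC is
#' prevalence-dependent.
#'
#' @param scores numeric anomaly scores.
#' @param labels logical (TRUE = anomalous) or 0/1.
#' @return list with `roc_auc`, `pr_auc`, `base_rate`, `n_pos`, `n_neg`;
#'   `NA` metrics when one class is absent.
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    return(list(roc_auc = NA_real_, pr_auc = NA_real_,
                base_rate = n_pos / length(labels), n_pos = n_pos,
                n_neg = n_neg))
  r <- rank(scores)
  roc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  # collapse tied thresholds: keep last entry of each tie block
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  pr <- sum(diff(c(0, rec)) * prec)
  list(roc_auc = roc, pr_auc = pr, base_rate = n_pos / length(labels),
       n_pos = n_pos, n_neg = n_neg)
}

## ---- day-tensor pipeline helpers ------------------------------------------

#' Day tensors with labels for one subject
#'
#' Generates the subject's interval features, stacks each day with
#' [build_day_tensor()] and attaches the day-level state under the
#' physiological 21-day rule (near-relapse days are labelled so the
#' protocol can discard them).
#'
#' @param cohort a [simulate_cohort()] object.
#' @param subject_id subject.
#' @return list with `tensors` (list of 288 x 10 matrices), `day`,
#'   `day_state` vectors, `n_rejected`.
#' @export
subject_day_tensors <- function(cohort, subject_id) {
  iv <- simulate_interval_features(cohort, subject_id)
  days <- sort(unique(iv$day))
  tensors <- list(); day_out <- numeric(); st_out <- character()
  n_rej <- 0L
  states <- day_state_labels(cohort$annotations, subject_id, days,
                             cohort$config$prodrome_days)
  for (i in seq_along(days)) {
    dt <- build_day_tensor(iv[iv$day == days[i], , drop = FALSE])
    if (dt$rejected) { n_rej <- n_rej + 1L; next }
    tensors[[length(tensors) + 1L]] <- dt$tensor
    day_out <- c(day_out, days[i])
    st_out <- c(st_out, states[i])
  }
  list(tensors = tensors, day = day_out, day_state = st_out,
       n_rejected = n_rej)
}

# Cut day tensors into (n, subseq, 10) instances.
tensor_instances <- function(tensors, days, subseq_len = 48L) {
  stopifnot(288L %% subseq_len == 0L)
  per_day <- 288L %/% subseq_len
  n <- length(tensors) * per_day
  D <- ncol(tensors[[1]])
  X <- array(0, c(n, subseq_len, D))
  inst_day <- numeric(n)
  at <- 0L
  for (i in seq_along(tensors)) {
    for (c_ in seq_len(per_day)) {
      rows <- ((c_ - 1L) * subseq_len + 1L):(c_ * subseq_len)
      X[at + c_, , ] <- tensors[[i]][rows, , drop = FALSE]
      inst_day[at + c_] <- days[i]
    }
    at <- at + per_day
  }
  dimnames(X)[[3]] <- colnames(tensors[[1]])
  list(X = X, day = inst_day)
}

## ---- experiment runners ----------------------------------------------------

#' Run the relapse detection experiment on a synthetic cohort
#'
#' Implements the full protocol: day tensors per patient (near-relapse
#' days discarded), grouped 5-fold splits of the normal days with
#' relapse days in every test set, train-partition normalization, model
#' training on normal data, expected-error fit on the second validation
#' subset, Mahalanobis (or KL) scoring, day averaging, and ROC/PR
#' evaluation with per-fold medians. A model-free Mahalanobis baseline
#' on the raw features is always reported.
#'
#' @param cohort a [simulate_cohort()] cohort with at least one relapsing
#'   patient.
#' @param scheme `"personalized"` (one model per patient, per-patient
#'   evaluation), `"global"` (one model, pooled evaluation) or
#'   `"global_eval_individual"` (one model, per-patient evaluation).
#' @param architecture sequence architecture (default `"cnn"`).
#' @param probe `"emd"` (Mahalanobis on error vectors) or `"kl"`
#'   (variational models only).
#' @param subseq_len sub-sequence length in 5-min slots (default 48 = 4 h).
#' @param k folds.
#' @param seed experiment seed.
#' @param normalization `"global"` or `"per_patient"` (global schemes).
#' @param epochs optional cap on training epochs.
#' @param config a [model_config()].
#' @return object of class `rk_experiment`: list with `folds` (per
#'   patient x fold metrics), `summary` (per-patient and pooled medians),
#'   `baseline` (same structure for the untrained baseline), `scheme`.
#' @export
run_experiment <- function(cohort,
                           scheme = c("personalized", "global",
                                      "global_eval_individual"),
                           architecture = "cnn", probe = c("emd", "kl"),
                           subseq_len = 48L, k = 5L, seed = 1L,
                           normalization = "global", epochs = NULL,
                           config = model_config()) {
  scheme <- match.arg(scheme)
  probe <- match.arg(probe)
  patients <- cohort$subjects$subject_id[cohort$subjects$group == "patient"]
  prep <- lapply(patients, function(p) {
    td <- subject_day_tensors(cohort, p)
    keep <- td$day_state != "near_relapse"
    ti <- tensor_instances(td$tensors[keep], td$day[keep], subseq_len)
    list(patient = p, X = ti$X, day = ti$day,
         state = td$day_state[keep][match(ti$day, td$day[keep])])
  })
  names(prep) <- patients

  if (scheme == "personalized") {
    res <- lapply(patients, function(p)
      run_patient_folds(prep[[p]], architecture, probe, k,
                        derive_seed(seed, match(p, patients)),
                        normalization = "global", epochs, config))
    folds <- do.call(rbind, lapply(res, `[[`, "folds"))
    base <- do.call(rbind, lapply(res, `[[`, "baseline"))
  } else {
    r <- run_global_folds(prep, architecture, probe, k, seed,
                          normalization,
                          per_patient_eval =
                            scheme == "global_eval_individual",
                          epochs, config)
    folds <- r$folds
    base <- r$baseline
  }
  summarize <- function(df) {
    per_pat <- stats::aggregate(cbind(roc_auc, pr_auc) ~ patient, df,
                                median, na.action = na.omit)
    list(per_patient = per_pat,
         median_roc_auc = median(per_pat$roc_auc, na.rm = TRUE),
         median_pr_auc = median(per_pat$pr_auc, na.rm = TRUE))
  }
  structure(list(scheme = scheme, architecture = architecture,
                 probe = probe, folds = folds, baseline = base,
                 summary = summarize(folds),
                 baseline_summary = summarize(base)),
            class = "rk_experiment")
}

#' @export
print.rk_experiment <- function(x, ...) {
  cat(sprintf("<rk_experiment> %s / %s: median ROC-AUC %.3f (baseline %.3f)\n",
              x$scheme, x$architecture, x$summary$median_roc_auc,
              x$baseline_summary$median_roc_auc))
  invisible(x)
}

score_fold_days <- function(model, dist, X, day, idx, probe) {
  if (probe == "kl") {
    s <- kl_score(model, take_batch(X, idx))
    data.frame(day = day[idx], score = s)
  } else {
    sc <- anomaly_score(model, dist, take_batch(X, idx))
    data.frame(day = day[idx][sc$instance], score = sc$score)
  }
}

run_patient_folds <- function(pd, architecture, probe, k, seed,
                              normalization, epochs, config) {
  anomalous <- pd$state == "relapse"
  splits <- make_splits(as.character(pd$day), anomalous, k = k,
                        seed = seed)
  rows <- list(); brows <- list()
  D <- dim(pd$X)[3]
  flat <- matrix(pd$X, prod(dim(pd$X)[1:2]), D)
  colnames(flat) <- dimnames(pd$X)[[3]]
  inst_of_row <- rep(seq_len(dim(pd$X)[1]), times = dim(pd$X)[2])
  day_of_inst <- pd$day
  for (sp in splits) {
    fit_rows <- which(inst_of_row %in% sp$train)
    nm <- normalize_features(flat, fit_rows, mode = "global")
    Xn <- array(nm$x, dim(pd$X))
    spec <- train_spec(architecture,
                       max_epochs = epochs %||% NULL,
                       seed = derive_seed(seed, 1000 + sp$fold))
    model <- build_model(spec, dim(Xn)[2:3], config)
    model <- train_model(model, take_batch(Xn, sp$train),
                         take_batch(Xn, sp$val1), spec)
    dist <- if (probe == "emd")
      fit_error_distribution(model, take_batch(Xn, sp$val2)) else NULL
    sc <- score_fold_days(model, dist, Xn, day_of_inst, sp$test, probe)
    da <- day_average(sc$score, sc$day)
    lab <- pd$state[match(da$day, pd$day)] == "relapse"
    ev <- evaluate_scores(da$score, lab)
    rows[[sp$fold]] <- data.frame(patient = pd$patient, fold = sp$fold,
                                  roc_auc = ev$roc_auc,
                                  pr_auc = ev$pr_auc,
                                  base_rate = ev$base_rate)
    # untrained baseline: Eq. 4 on the raw features of the validation rows
    val_rows <- which(inst_of_row %in% c(sp$val1, sp$val2))
    test_rows <- which(inst_of_row %in% sp$test)
    rb <- random_baseline(nm$x[val_rows, , drop = FALSE],
                          nm$x[test_rows, , drop = FALSE])
    dab <- day_average(rb$scores, day_of_inst[inst_of_row[test_rows]])
    labb <- pd$state[match(dab$day, pd$day)] == "relapse"
    evb <- evaluate_scores(dab$score, labb)
    brows[[sp$fold]] <- data.frame(patient = pd$patient, fold = sp$fold,
                                   roc_auc = evb$roc_auc,
                                   pr_auc = evb$pr_auc,
                                   base_rate = evb$base_rate)
  }
  list(folds = do.call(rbind, rows), baseline = do.call(rbind, brows))
}

run_global_folds <- function(prep, architecture, probe, k, seed,
                             normalization, per_patient_eval, epochs,
                             config) {
  # concatenate patients; groups are patient-qualified days
  Xs <- lapply(prep, `[[`, "X")
  n_inst <- vapply(Xs, function(x) dim(x)[1], numeric(1))
  X <- do.call(abind1, Xs)
  patient <- rep(names(prep), n_inst)
  day <- unlist(lapply(prep, `[[`, "day"), use.names = FALSE)
  state <- unlist(lapply(prep, `[[`, "state"), use.names = FALSE)
  gkey <- paste(patient, day, sep = "#")
  splits <- make_splits(gkey, state == "relapse", k = k, seed = seed)
  D <- dim(X)[3]
  flat <- matrix(X, prod(dim(X)[1:2]), D)
  colnames(flat) <- dimnames(X)[[3]]
  inst_of_row <- rep(seq_len(dim(X)[1]), times = dim(X)[2])
  rows <- list(); brows <- list()
  for (sp in splits) {
    fit_rows <- which(inst_of_row %in% sp$train)
    nm <- normalize_features(flat, fit_rows, mode = normalization,
                             patient = patient[inst_of_row])
    Xn <- array(nm$x, dim(X))
    spec <- train_spec(architecture, max_epochs = epochs %||% NULL,
                       seed = derive_seed(seed, 2000 + sp$fold))
    model <- build_model(spec, dim(Xn)[2:3], config)
    model <- train_model(model, take_batch(Xn, sp$train),
                         take_batch(Xn, sp$val1), spec)
    dist <- if (probe == "emd")
      fit_error_distribution(model, take_batch(Xn, sp$val2)) else NULL
    sc <- score_fold_days(model, dist, Xn, seq_len(dim(Xn)[1]),
                          sp$test, probe)   # day col = instance index
    sc$patient <- patient[sc$day]
    sc$pday <- gkey[sc$day]
    eval_groups <- if (per_patient_eval) unique(sc$patient) else "all"
    for (pg in eval_groups) {
      sub <- if (pg == "all") sc else sc[sc$patient == pg, , drop = FALSE]
      da <- day_average(sub$score, sub$pday)
      lab <- state[match(da$day, gkey)] == "relapse"
      ev <- evaluate_scores(da$score, lab)
      rows[[length(rows) + 1L]] <-
        data.frame(patient = pg, fold = sp$fold, roc_auc = ev$roc_auc,
                   pr_auc = ev$pr_auc, base_rate = ev$base_rate)
    }
    val_rows <- which(inst_of_row %in% c(sp$val1, sp$val2))
    test_rows <- which(inst_of_row %in% sp$test)
    rb <- random_baseline(nm$x[val_rows, , drop = FALSE],
                          nm$x[test_rows, , drop = FALSE])
    bsc <- data.frame(pday = gkey[inst_of_row[test_rows]],
                      patient = patient[inst_of_row[test_rows]],
                      score = rb$scores)
    for (pg in eval_groups) {
      sub <- if (pg == "all") bsc else bsc[bsc$patient == pg, ,
                                           drop = FALSE]
      da <- day_average(sub$score, sub$pday)
      lab <- state[match(da$day, gkey)] == "relapse"
      evb <- evaluate_scores(da$score, lab)
      brows[[length(brows) + 1L]] <-
        data.frame(patient = pg, fold = sp$fold, roc_auc = evb$roc_auc,
                   pr_auc = evb$pr_auc, base_rate = evb$base_rate)
    }
  }
  list(folds = do.call(rbind, rows), baseline = do.call(rbind, brows))
}

abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[(at + 1L):(at + dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  dimnames(out)[[3]] <- dimnames(arrs[[1]])[[3]]
  out
}

#' Mean anomaly score per relapse severity
#'
#' @param scores numeric day-level scores.
#' @param severity severity label per score (`"low"`, `"moderate"`,
#'   `"severe"`; relapse days only).
#' @param n_boot bootstrap replicates for the CI (default 200).
#' @param seed bootstrap seed.
#' @return data frame `severity`, `mean_score`, `ci_lo`, `ci_hi`, `n`,
#'   ordered low < moderate < severe.
#' @export
severity_analysis <- function(scores, severity, n_boot = 200L, seed = 1L) {
  stopifnot(length(scores) == length(severity))
  levs <- intersect(SEVERITY_LEVELS, unique(severity))
  with_seed(derive_seed(seed, 33), {
    rows <- lapply(levs, function(s) {
      v <- scores[severity == s]
      bs <- replicate(n_boot, mean(sample(v, replace = TRUE)))
      data.frame(severity = s, mean_score = mean(v),
                 ci_lo = quantile(bs, 0.025, names = FALSE),
                 ci_hi = quantile(bs, 0.975, names = FALSE), n = length(v))
    })
    do.call(rbind, rows)
  })
}

#' Decision-level fusion of audio and physiological scores
#'
#' Pairs each interview session with the physiological score of its
#' calendar day, min-max standardizes each modality over the evaluation
#' set (so both operate on commensurate scales) and combines them
#' additively or multiplicatively. Unpaired sessions are dropped and
#' counted.
#'
#' @param audio data frame `day`, `score` (one row per session).
#' @param physio data frame `day`, `score` (one row per day).
#' @param method `"additive"` or `"multiplicative"`.
#' @return data frame `day`, `audio`, `physio`, `fused`, with attribute
#'   `n_unpaired`.
#' @export
fuse_scores <- function(audio, physio,
                        method = c("additive", "multiplicative")) {
  method <- match.arg(method)
  j <- match(audio$day, physio$day)
  unpaired <- sum(is.na(j))
  keep <- !is.na(j)
  a <- audio$score[keep]
  p <- physio$score[j[keep]]
  mm <- function(v) if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v))
                    else rep(0.5, length(v))
  an <- mm(a); pn <- mm(p)
  fused <- if (method == "additive") an + pn else an * pn
  out <- data.frame(day = audio$day[keep], audio = an, physio = pn,
                    fused = fused)
  attr(out, "n_unpaired") <- unpaired
  out
}

#' Bonferroni-corrected pairwise comparison of model variants
#'
#' Mann-Whitney U tests between AUC samples (repetitions x folds) of
#' model variants, with Bonferroni correction over the number of pairs.
#'
#' @param auc_samples named list of numeric AUC vectors.
#' @return data frame `a`, `b`, `p`, `p_bonf`.
#' @export
compare_model_variants <- function(auc_samples) {
  nms <- names(auc_samples)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    p <- mann_whitney_u(auc_samples[[pr[1]]], auc_samples[[pr[2]]])$p
    data.frame(a = pr[1], b = pr[2], p = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(out$p * nrow(out), 1)
  out
}
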