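test_that("split plans rotate normal groups and quarantine anomalies", {
  groups <- rep(sprintf("d%02d", 1:12), each = 4)
  anomalous <- rep(c(rep(FALSE, 10), TRUE, TRUE), each = 4)
  sp <- make_splits(groups, anomalous, k = 5, seed = 3)
  expect_length(sp, 5L)
  tested_normal <- character()
  for (s in sp) {
    # group atomicity: every group sits wholly inside one role
    for (role in c("train", "val1", "val2", "test")) {
      g <- unique(groups[s[[role]]])
      other <- setdiff(c("train", "val1", "val2", "test"), role)
      for (o in other)
        expect_length(intersect(g, unique(groups[s[[o]]])), 0L)
    }
    # anomalous instances never reach train or validation
    expect_false(any(anomalous[c(s$train, s$val1, s$val2)]))
    expect_true(all(c("d11", "d12") %in% groups[s$test]))
    # val1/val2 sizes differ by at most one group
    expect_lte(abs(length(unique(groups[s$val1])) -
                     length(unique(groups[s$val2]))), 1L)
    tested_normal <- c(tested_normal,
                       setdiff(unique(groups[s$test]), c("d11", "d12")))
  }
  # each normal group tested exactly once across folds
  expect_equal(sort(tested_normal), sprintf("d%02d", 1:10))
  expect_error(make_splits(c("a", "b"), c(FALSE, FALSE), k = 5), "k normal")
})

test_that("min-max normalization is fit on training rows only", {
  x <- cbind(f1 = c(2, 3, 4, 10), sin_t = c(-1, 0, 1, 0.5))
  nm <- normalize_features(x, fit_idx = 1:3)
  expect_equal(unname(nm$x[2, "f1"]), 0.5)   # (3-2)/(4-2)
  expect_equal(unname(nm$x[4, "f1"]), 1)     # clipped test value
  expect_equal(nm$x[, "sin_t"], x[, "sin_t"])  # exempt passthrough
  expect_warning(normalize_features(cbind(f = rep(2, 4)), 1:3), "constant")

  # per-patient mode: adding a per-patient offset leaves each patient's
  # normalized data unchanged
  set.seed(4)
  xx <- cbind(f = rnorm(40))
  pat <- rep(c("a", "b"), each = 20)
  n1 <- normalize_features(xx, 1:40, mode = "per_patient", patient = pat)
  xx2 <- xx; xx2[pat == "b", ] <- xx2[pat == "b", ] + 100
  n2 <- normalize_features(xx2, 1:40, mode = "per_patient", patient = pat)
  expect_equal(n1$x, n2$x, tolerance = 1e-12)
})

test_that("pooling follows the power-mean family", {
  s <- c(0, 1)
  expect_equal(pool_scores(s, "AP"), 0.5)
  expect_equal(pool_scores(s, "MP"), 1)
  expect_equal(pool_scores(s, "NP", p = 10), 0.5^0.1, tolerance = 1e-12)
  expect_equal(pool_scores(s, "NP", p = 1), pool_scores(s, "AP"))
  set.seed(5)
  for (i in 1:10) {
    v <- runif(sample(3:30, 1))
    ap <- pool_scores(v, "AP"); np <- pool_scores(v, "NP")
    mp <- pool_scores(v, "MP")
    expect_lte(ap, np + 1e-12); expect_lte(np, mp + 1e-12)
  }
  expect_error(pool_scores(c(-1, 2), "NP"), "non-negative")
})

test_that("day averaging equals a group-by mean", {
  expect_equal(day_average(rep(3, 10), rep(1, 10))$score, 3)
  expect_equal(day_average(c(0, 1), c(7, 7))$score, 0.5)
  set.seed(6)
  sc <- rnorm(100); dy <- sample(1:9, 100, replace = TRUE)
  da <- day_average(sc, dy)
  bf <- sapply(split(sc, dy), mean)
  expect_equal(da$score, unname(bf), tolerance = 1e-12)
})

test_that("ROC follows the Mann-Whitney identity and PR integrates steps", {
  sep <- c(rnorm(10, 0), rnorm(10, 100))
  lab <- rep(c(FALSE, TRUE), each = 10)
  ev <- evaluate_scores(sep, lab)
  expect_equal(ev$roc_auc, 1)
  expect_equal(ev$pr_auc, 1)

  set.seed(7)
  for (i in 1:5) {
    sc <- rnorm(20); lb <- sample(c(TRUE, FALSE), 20, replace = TRUE,
                                  prob = c(0.4, 0.6))
    if (sum(lb) %in% c(0, 20)) next
    expect_equal(evaluate_scores(sc, lb)$roc_auc, oracle_roc_auc(sc, lb),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(evaluate_scores(exp(2 * sc), lb)$roc_auc,
                 evaluate_scores(sc, lb)$roc_auc, tolerance = 1e-12)
    expect_equal(evaluate_scores(exp(2 * sc), lb)$pr_auc,
                 evaluate_scores(sc, lb)$pr_auc, tolerance = 1e-12)
  }
  # labels independent of scores: mean ROC over seeds near 1/2
  aucs <- vapply(1:100, function(i) {
    set.seed(i)
    evaluate_scores(rnorm(50), sample(rep(c(TRUE, FALSE), 25)))$roc_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  # single-class test sets are flagged undefined
  expect_true(is.na(evaluate_scores(rnorm(5), rep(TRUE, 5))$roc_auc))
  # pROC cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(8)
    sc <- rnorm(40); lb <- rep(c(TRUE, FALSE), 20)
    expect_equal(evaluate_scores(sc, lb)$roc_auc,
                 as.numeric(suppressMessages(
                   pROC::auc(pROC::roc(lb, sc, direction = "<")))),
                 tolerance = 1e-10)
  }
})

test_that("fusion standardizes per modality and respects its identities", {
  audio <- data.frame(day = 1:10, score = c(5, 9, 1, 7, 3, 8, 2, 6, 4, 10))
  physio <- data.frame(day = 1:10, score = rep(2, 10))   # constant modality
  lab <- rep(c(FALSE, TRUE), 5)
  fz <- fuse_scores(audio, physio, "additive")
  expect_equal(evaluate_scores(fz$fused, lab)$roc_auc,
               evaluate_scores(audio$score, lab)$roc_auc)

  physio2 <- data.frame(day = 1:10, score = c(0, runif(9) + 1))
  fm <- fuse_scores(audio, physio2, "multiplicative")
  expect_equal(fm$fused[fm$physio == 0], 0)

  audio_un <- rbind(audio, data.frame(day = 99, score = 1))
  fu <- fuse_scores(audio_un, physio, "additive")
  expect_equal(attr(fu, "n_unpaired"), 1L)
  expect_false(99 %in% fu$day)
})

test_that("severity analysis summarizes and orders built-in effects", {
  set.seed(9)
  sc <- c(rnorm(30, 1), rnorm(30, 2), rnorm(30, 3))
  sev <- rep(c("low", "moderate", "severe"), each = 30)
  sa <- severity_analysis(sc, sev)
  expect_equal(sa$severity, c("low", "moderate", "severe"))
  expect_true(all(diff(sa$mean_score) > 0))
  expect_true(all(sa$ci_lo < sa$mean_score & sa$mean_score < sa$ci_hi))
  one <- severity_analysis(rnorm(10), rep("low", 10))
  expect_equal(nrow(one), 1L)
})

test_that("variant comparison applies the Bonferroni correction", {
  set.seed(10)
  cmp <- compare_model_variants(list(a = runif(25), b = runif(25),
                                     c = runif(25) + 0.5))
  expect_equal(nrow(cmp), 3L)
  expect_true(all(cmp$p_bonf >= cmp$p))
  expect_true(all(cmp$p_bonf <= 1))
})

test_that("subject day tensors and instances feed the experiment runner", {
  co <- tiny_cohort(0, 1, days = 3, seed = 51)
  td <- subject_day_tensors(co, "P01")
  expect_true(length(td$tensors) >= 2)
  expect_true(all(vapply(td$tensors, function(m)
    all(dim(m) == c(288, 10)), logical(1))))
  ti <- tensor_instances(td$tensors, td$day, subseq_len = 48L)
  expect_equal(dim(ti$X)[2:3], c(48L, 10L))
  expect_equal(dim(ti$X)[1], 6L * length(td$tensors))
  expect_error(tensor_instances(td$tensors, td$day, subseq_len = 50L))
})
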