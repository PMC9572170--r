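# Independent brute-force oracles used across the suite. These stay
# deliberately naive (double loops, direct formula evaluation) so they are
# independent of the implementation paths they check.

# Direct evaluation of the Lomb-Scargle definition at one frequency.
oracle_lomb_scargle <- function(t, x, f, center = TRUE) {
  if (center) x <- x - mean(x)
  w <- 2 * pi * f
  tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
  ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
  0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
}

# Exhaustive pair-count sample entropy.
oracle_sampen <- function(x, m, r) {
  tol <- r * sd(x)
  n <- length(x)
  count <- function(mm) {
    cnt <- 0L
    for (i in 1:(n - m)) for (j in 1:(n - m)) {
      if (i == j) next
      if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= tol)
        cnt <- cnt + 1L
    }
    cnt
  }
  A <- count(m + 1); B <- count(m)
  if (A == 0 || B == 0) return(NA_real_)   # undefined, flagged
  -log(A / B)
}

# Higuchi curve lengths by the per-offset definition.
oracle_higuchi_lengths <- function(x, k_max) {
  n <- length(x)
  sapply(1:k_max, function(k) {
    lm <- sapply(1:k, function(m) {
      i <- seq(m, n, by = k)
      nm <- length(i) - 1
      sum(abs(diff(x[i]))) * (n - 1) / (nm * k) / k
    })
    mean(lm)
  })
}

# Brute-force flat dilation/erosion over [n - s, n + s] neighborhoods.
oracle_morph <- function(x, s) {
  n <- length(x)
  dil <- sapply(seq_len(n), function(i) max(x[max(1, i - s):min(n, i + s)]))
  ero <- sapply(seq_len(n), function(i) min(x[max(1, i - s):min(n, i + s)]))
  list(dilation = dil, erosion = ero)
}

# ROC-AUC by pair enumeration (ties count one half).
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# BH adjustment by the definition: sort, p * m / i, cummin from the top.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

tiny_cohort <- function(n_c = 2, n_p = 2, days = 2, seed = 11, ...) {
  simulate_cohort(cohort_config(n_c, n_p, days_per_subject = days,
                                seed = seed, ...))
}

# A small structured instance set for the sequence models.
toy_sequences <- function(n, T_ = 48L, D = 10L, seed = 1) {
  set.seed(seed)
  X <- array(0, c(n, T_, D))
  t <- seq_len(T_)
  for (i in seq_len(n))
    X[i, , ] <- outer(sin(2 * pi * t / T_ + runif(1) * 2 * pi),
                      runif(D, 0.3, 0.7)) + 0.5 +
      array(rnorm(T_ * D, 0, 0.05), c(T_, D))
  X
}
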