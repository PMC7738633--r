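# Independent oracles used across test files. These deliberately avoid the
# code paths they check: crossing times by bisection on the growth curve,
# AUC by exhaustive pair counting, Welch statistics from the textbook formulas.

# time at which the Gompertz curve through (0, X0) reaches `target`,
# solved by bisection (negative times = backward projection)
oracle_crossing_time <- function(alpha, X0, K, target, lo = -1e5, hi = 1e5) {
  f <- function(t) K * exp(log(X0 / K) * exp(-alpha * t)) - target
  stopifnot(f(lo) < 0, f(hi) > 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_initiation_time <- function(alpha, X0, K, x_start = 1e-6, x_end = 10) {
  oracle_crossing_time(alpha, X0, K, x_end) -
    oracle_crossing_time(alpha, X0, K, x_start)
}

# Mann-Whitney concordance: fraction of (high, low) pairs ranked correctly,
# ties counted 1/2
oracle_auc <- function(alphas, labels) {
  hi <- alphas[labels == "high"]
  lo <- alphas[labels == "low"]
  tot <- 0
  for (h in hi) tot <- tot + sum(h > lo) + 0.5 * sum(h == lo)
  tot / (length(hi) * length(lo))
}

# best achievable accuracy over every candidate cut (both prediction
# directions are not needed: high = alpha above cut, by construction)
oracle_best_accuracy <- function(alphas, labels) {
  u <- sort(unique(alphas))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  max(vapply(cand, function(t) mean((alphas > t) == (labels == "high")),
             numeric(1)))
}

# textbook Welch statistics
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# noiseless observation table on a Gompertz trajectory
noiseless_obs <- function(alpha, X0, times, K = 180000) {
  d <- (6 * gompertz_volume(times, alpha, X0, K) / pi)^(1 / 3)
  data.frame(time = times, long_axis = d, short_axis = d)
}

# small hand-built cohort: 2 patients per class on exact trajectories
toy_cohort <- function(alphas = c(0.02, 0.03, 0.08, 0.1),
                       classes = c("low", "low", "high", "high")) {
  patients <- lapply(seq_along(alphas), function(i) {
    patient_record(sprintf("T%02d", i), classes[i],
                   noiseless_obs(alphas[i], 500 + 100 * i, c(0, 6, 14)))
  })
  pdac_cohort(patients, metadata = list(source = "toy"))
}
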