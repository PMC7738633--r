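test_that("Gompertz curve anchors at X0, saturates at K, and matches the closed form", {
  expect_equal(gompertz_volume(0, 0.05, 1000), 1000)
  expect_lt(abs(gompertz_volume(1e6, 0.05, 1000) - 180000), 1e-6 * 180000)
  # frozen from direct high-precision evaluation of K*exp(log(X0/K)*exp(-a*t))
  expect_equal(gompertz_volume(12, 0.088, 1000), 29565.73, tolerance = 1e-6)
  tt <- seq(0, 60, by = 0.5)
  v <- gompertz_volume(tt, 0.088, 1000)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 180000))
  expect_error(gompertz_volume(1, -0.1, 1000), "alpha")
  expect_error(gompertz_volume(1, 0.1, 2e5), "X0")
})

test_that("noiseless trajectories return the generating alpha to 1e-6 relative", {
  set.seed(21)
  for (i in 1:20) {
    alpha <- runif(1, 0.01, 0.3)
    X0 <- runif(1, 50, 2000)
    n <- sample(2:10, 1)
    times <- c(0, sort(runif(n - 1, 1, 48)))
    fit <- fit_gompertz(noiseless_obs(alpha, X0, times))
    expect_equal(fit$alpha, alpha, tolerance = 1e-6)
    expect_true(fit$converged)
  }
})

test_that("two noiseless points identify alpha exactly with perfect correlation", {
  fit <- fit_gompertz(noiseless_obs(0.07, 800, c(0, 9)))
  expect_equal(fit$alpha, 0.07, tolerance = 1e-8)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$X0, gompertz_volume(0, 0.07, 800))
})

test_that("median fitted alpha stays within 15% under 10% diameter noise", {
  set.seed(31)
  # 6 scans over 15 months: even 4-sigma diameter noise (cubed on the volume
  # scale) keeps observations below the carrying capacity
  times <- seq(0, 15, length.out = 6)
  alphas <- replicate(500, {
    d <- sphere_diameter(gompertz_volume(times, 0.088, 1000))
    s <- sqrt(log(1 + 0.1^2))
    v <- sphere_volume(d * rlnorm(6, -s^2 / 2, s))
    suppressWarnings(
      fit_gompertz(data.frame(time = times, volume = v))$alpha)
  })
  expect_lt(abs(median(alphas) - 0.088) / 0.088, 0.15)
})

test_that("degenerate trajectories are flagged, capacity violations refused", {
  shrinking <- data.frame(time = c(0, 6, 12), volume = c(2000, 1500, 1200))
  expect_warning(fit <- fit_gompertz(shrinking), "bound")
  expect_false(fit$converged)
  expect_error(
    fit_gompertz(data.frame(time = c(0, 6), volume = c(1000, 180000))),
    "carrying-capacity")
  expect_error(fit_gompertz(data.frame(time = 0, volume = 1000)),
               "at least 2")
})

test_that("log-scale fitting recovers noiseless alpha too", {
  fit <- fit_gompertz(noiseless_obs(0.12, 300, c(0, 5, 11, 20)),
                      log_scale = TRUE)
  expect_equal(fit$alpha, 0.12, tolerance = 1e-6)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  obs <- noiseless_obs(0.05, 800, c(0, 8, 16))
  fit <- fit_gompertz(obs)
  expect_named(coef(fit), c("alpha", "X0", "K"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, 0), fit$X0)
  expect_equal(residuals(fit), fit$fitted - fit$observed)
  expect_output(print(fit), "alpha")
})

test_that("pooled per-class fit quality behaves like a correlation", {
  cohort <- toy_cohort()
  fc <- fit_cohort(cohort)
  r <- cohort_fit_quality(fc$fits, delta_classes(cohort))
  expect_equal(unname(r[c("low", "high")]), c(1, 1), tolerance = 1e-9)

  # contrived anti-correlated "fits"
  fake <- list(A = list(observed = c(1, 2, 3), fitted = c(5, 4, 3)))
  expect_equal(unname(cohort_fit_quality(fake, c(A = "low"))), -1)
  one_point <- list(A = list(observed = 1, fitted = 1))
  expect_error(cohort_fit_quality(one_point, c(A = "low")),
               "undefined correlation")
})

test_that("characteristic growth time is the inverse rate", {
  expect_equal(characteristic_time(1), 1)
  expect_equal(characteristic_time(0.024), 1 / 0.024)
  expect_equal(round(characteristic_time(c(0.024, 0.088)), 1), c(41.7, 11.4))
  expect_error(characteristic_time(0), "positive")
})

test_that("initiation time matches the bisection crossing-time oracle", {
  for (alpha in c(0.005, 0.024, 0.088, 0.2, 0.5)) {
    for (K in c(90000, 180000, 360000)) {
      expect_lt(abs(initiation_time(alpha, X0 = 1000, K = K) -
                      oracle_initiation_time(alpha, 1000, K)), 1e-3)
    }
  }
  # frozen oracle values at the defaults for the two reported class means
  expect_equal(initiation_time(0.024), 40.53, tolerance = 3e-4)
  expect_equal(initiation_time(0.088), 11.05, tolerance = 3e-4)
})

test_that("initiation time is independent of X0 and scales as 1/alpha", {
  t1 <- initiation_time(0.05, X0 = 500)
  expect_equal(t1, initiation_time(0.05, X0 = 5000), tolerance = 1e-12)
  expect_equal(initiation_time(0.1, X0 = 500), t1 / 2)
  expect_equal(initiation_time(0.05 * 3.7), t1 / 3.7)
  expect_error(initiation_time(0.05, X_start = 10, X_end = 1e-6),
               "ordering")
})

test_that("growth and initiation are invariant to the global volume unit", {
  # mm^3 vs cm^3: scale every volume argument by 1/1000
  expect_equal(gompertz_volume(7, 0.05, 1000, 180000) / 1000,
               gompertz_volume(7, 0.05, 1, 180))
  expect_equal(initiation_time(0.05, X0 = 1000, K = 180000,
                               X_start = 1e-6, X_end = 10),
               initiation_time(0.05, X0 = 1, K = 180,
                               X_start = 1e-9, X_end = 0.01))
})

test_that("lognormal MLE uses log-moment estimates and recovers parameters", {
  x <- c(2, 2, 2)
  d <- fit_lognormal(x)
  expect_equal(d$mu, log(2))
  expect_equal(d$sigma, 0)
  expect_true(d$degenerate)

  set.seed(41)
  y <- rlnorm(1e4, meanlog = 2, sdlog = 0.5)
  d <- fit_lognormal(y)
  expect_equal(d$mu, mean(log(y)))
  expect_equal(d$sigma, sqrt(mean((log(y) - mean(log(y)))^2)))
  expect_equal(d$mu, 2, tolerance = 0.02)
  expect_equal(d$sigma, 0.5, tolerance = 0.02)
  du <- fit_lognormal(y, unbiased = TRUE)
  expect_equal(du$sigma, sd(log(y)))
  expect_error(fit_lognormal(c(1, -2)), "positive")
})

test_that("lognormal MLE agrees with an independent likelihood maximizer", {
  set.seed(42)
  y <- rlnorm(500, meanlog = 1.2, sdlog = 0.8)
  d <- fit_lognormal(y)
  ref <- fitdistrplus::fitdist(y, "lnorm")
  expect_equal(d$mu, unname(ref$estimate["meanlog"]), tolerance = 1e-4)
  expect_equal(d$sigma, unname(ref$estimate["sdlog"]), tolerance = 1e-4)
})

test_that("initiation distribution exposes mode, pdf, cdf and quantiles", {
  set.seed(43)
  d <- fit_lognormal(rlnorm(200, 3, 0.7))
  expect_equal(initiation_mode(d), exp(d$mu - d$sigma^2))
  expect_equal(cumulative_initiation_probability(d, exp(d$mu)), 0.5)
  expect_equal(cumulative_initiation_probability(d, -1), 0)
  expect_equal(cumulative_initiation_probability(d, 1e9), 1, tolerance = 1e-6)
  tt <- seq(0.1, 100, length.out = 50)
  expect_true(all(diff(cumulative_initiation_probability(d, tt)) >= 0))
  expect_equal(initiation_quantile(d, 0.9), qlnorm(0.9, d$mu, d$sigma))
  # pdf integrates to ~1
  expect_equal(integrate(function(t) initiation_pdf(d, t), 0, Inf)$value, 1,
               tolerance = 1e-4)
})
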