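#' Gompertz tumor volume
#'
#' Sigmoidal growth law `X(t) = K * exp(log(X0/K) * exp(-alpha * t))`:
#' growth is fastest early on and decelerates as the volume approaches the
#' carrying capacity `K`.
#'
#' @param t Time in months since the first observation. Vectorized.
#' @param alpha Growth-rate constant, month^-1 (> 0).
#' @param X0 Volume at the first observation, mm^3 (0 < X0 < K).
#' @param K Carrying capacity, mm^3; defaults to 180,000 mm^3 (180 cm^3,
#'   a 7-cm-diameter sphere).
#' @return Volume in mm^3, strictly increasing in `t`, bounded by (0, K).
#' @examples
#' gompertz_volume(0:24, alpha = 0.088, X0 = 1000)
#' @export
gompertz_volume <- function(t, alpha, X0, K = 180000) {
  check_gompertz_params(alpha, X0, K)
  K * exp(log(X0 / K) * exp(-alpha * t))
}

check_gompertz_params <- function(alpha, X0, K) {
  if (!is.finite(alpha) || alpha <= 0) {
    stop("alpha must be a positive growth-rate constant", call. = FALSE)
  }
  if (!is.finite(K) || K <= 0) stop("K must be positive", call. = FALSE)
  if (!is.finite(X0) || X0 <= 0 || X0 >= K) {
    stop("X0 must satisfy 0 < X0 < K", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit the Gompertz growth model to one patient's serial lesion volumes
#'
#' Nonlinear least squares by the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]), minimizing squared volume residuals. The volume
#' at the first observation anchors `X0` and the carrying capacity `K` is
#' fixed, so the growth-rate constant `alpha` is the only free parameter.
#'
#' @param observations data.frame with columns `time` (months, first row 0,
#'   strictly increasing) and either `volume` (mm^3) or `long_axis` +
#'   `short_axis` (mm, converted by [mean_diameter()] and [sphere_volume()]);
#'   or a [patient_record()].
#' @param K Carrying capacity in mm^3. All observed volumes must lie below it.
#' @param alpha_init Optimizer start, month^-1.
#' @param alpha_bounds Box constraint on alpha; fits ending on a bound are
#'   flagged non-converged.
#' @param log_scale If `TRUE`, residuals are computed on log-volume instead of
#'   volume.
#' @return Object of class `gompertz_fit`: estimated `alpha`, anchored `X0`,
#'   `K`, fitted volumes, residuals (fitted minus observed), Pearson
#'   correlation between observed and fitted volumes, and a convergence flag.
#' @examples
#' obs <- data.frame(time = c(0, 8, 16),
#'                   volume = gompertz_volume(c(0, 8, 16), 0.05, 800))
#' fit <- fit_gompertz(obs)
#' coef(fit)
#' @export
fit_gompertz <- function(observations, K = 180000, alpha_init = 0.05,
                         alpha_bounds = c(1e-4, 2), log_scale = FALSE) {
  pid <- NULL
  if (inherits(observations, "patient_record")) {
    pid <- observations$patient_id
    observations <- observations$observations
  }
  observations <- as.data.frame(observations)
  if (is.null(observations$volume)) {
    observations$volume <- sphere_volume(
      mean_diameter(observations$long_axis, observations$short_axis))
  }
  times <- observations$time
  volumes <- observations$volume
  n <- length(times)
  if (n < 2L) stop("at least 2 observations required", call. = FALSE)
  if (times[1] != 0) stop("first observation time must be 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("observation times must be strictly increasing", call. = FALSE)
  }
  if (any(volumes >= K)) {
    stop(sprintf("carrying-capacity violation: observed volume >= K (%g mm^3)", K),
         call. = FALSE)
  }
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)

  X0 <- volumes[1]
  resid_fun <- if (log_scale) {
    function(par) log(gompertz_volume(times, par[["alpha"]], X0, K)) - log(volumes)
  } else {
    function(par) gompertz_volume(times, par[["alpha"]], X0, K) - volumes
  }
  fit <- minpack.lm::nls.lm(
    par = c(alpha = alpha_init), lower = alpha_bounds[1], upper = alpha_bounds[2],
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  alpha <- unname(fit$par[["alpha"]])
  at_bound <- alpha <= alpha_bounds[1] * (1 + 1e-8) ||
    alpha >= alpha_bounds[2] * (1 - 1e-8)
  converged <- fit$info %in% 1:4 && !at_bound
  if (at_bound) {
    warning(sprintf("alpha at optimizer bound (%g); fit flagged non-converged",
                    alpha), call. = FALSE)
  }
  fitted_vol <- gompertz_volume(times, alpha, X0, K)
  pearson_r <- if (stats::sd(volumes) > 0 && stats::sd(fitted_vol) > 0) {
    stats::cor(volumes, fitted_vol)
  } else NA_real_

  structure(
    list(alpha = alpha, X0 = X0, K = K, times = times, observed = volumes,
         fitted = fitted_vol, residuals = fitted_vol - volumes,
         pearson_r = pearson_r, n_obs = n, converged = converged,
         log_scale = log_scale, patient_id = pid),
    class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz growth fit")
  if (!is.null(x$patient_id)) cat(" for patient", x$patient_id)
  cat("\n")
  cat(sprintf("  alpha = %.4f month^-1 (characteristic time %.1f months)%s\n",
              x$alpha, 1 / x$alpha,
              if (x$converged) "" else "  [non-converged]"))
  cat(sprintf("  X0 = %.1f mm^3 (anchored), K = %.0f mm^3 (fixed)\n",
              x$X0, x$K))
  cat(sprintf("  %d observations over %.1f months, Pearson R = %.4f\n",
              x$n_obs, max(x$times), x$pearson_r))
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  c(alpha = object$alpha, X0 = object$X0, K = object$K)
}

#' @export
residuals.gompertz_fit <- function(object, ...) object$residuals

#' @export
fitted.gompertz_fit <- function(object, ...) object$fitted

#' Predicted volumes from a Gompertz fit
#' @param object A `gompertz_fit`.
#' @param newdata Optional vector of times (months) or data.frame with a
#'   `time` column; defaults to the observed times.
#' @param ... Unused.
#' @return Predicted volumes in mm^3.
#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) {
    object$times
  } else if (is.data.frame(newdata)) {
    newdata$time
  } else {
    as.numeric(newdata)
  }
  gompertz_volume(t, object$alpha, object$X0, object$K)
}

#' @export
plot.gompertz_fit <- function(x, ...) {
  tt <- seq(0, max(x$times) * 1.1, length.out = 200)
  graphics::plot(tt, predict(x, tt) / 1000, type = "l",
                 xlab = "Months since first observation",
                 ylab = expression(Tumor ~ volume ~ (cm^3)),
                 main = if (!is.null(x$patient_id)) x$patient_id else
                   "Gompertz fit", ...)
  graphics::points(x$times, x$observed / 1000, pch = 19)
  invisible(x)
}

#' Fit the Gompertz model to every patient in a cohort
#'
#' Patients whose fit fails (for example, an observed volume at or above the
#' carrying capacity) are excluded with the error message recorded, so that
#' fitted plus excluded patients always account for the whole cohort.
#'
#' @param cohort A [pdac_cohort()].
#' @inheritParams fit_gompertz
#' @return List with `fits` (named list of `gompertz_fit`) and `exclusions`
#'   (data.frame of patient_id, reason).
#' @export
fit_cohort <- function(cohort, K = 180000, alpha_init = 0.05,
                       alpha_bounds = c(1e-4, 2), log_scale = FALSE) {
  stopifnot(inherits(cohort, "pdac_cohort"))
  fits <- list()
  excl <- list()
  for (p in cohort$patients) {
    f <- tryCatch(
      fit_gompertz(p, K = K, alpha_init = alpha_init,
                   alpha_bounds = alpha_bounds, log_scale = log_scale),
      error = function(e) conditionMessage(e))
    if (inherits(f, "gompertz_fit")) {
      fits[[p$patient_id]] <- f
    } else {
      excl[[p$patient_id]] <- f
    }
  }
  exclusions <- if (length(excl)) {
    data.frame(patient_id = names(excl), reason = unlist(excl),
               row.names = NULL)
  } else {
    data.frame(patient_id = character(), reason = character())
  }
  list(fits = fits, exclusions = exclusions)
}

#' Pooled goodness of fit per delta class
#'
#' Pools every (observed, fitted) volume pair of a delta class across patients
#' and returns the Pearson correlation per class, the cohort-level fit-quality
#' summary used for the growth model.
#'
#' @param fits Named list of [fit_gompertz()] results (names = patient ids).
#' @param classes Named character vector mapping patient id to delta class,
#'   e.g. [delta_classes()].
#' @return Named numeric vector of Pearson R, one entry per class present.
#' @export
cohort_fit_quality <- function(fits, classes) {
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  cls <- classes[names(fits)]
  out <- vapply(unique(cls), function(cl) {
    obs <- unlist(lapply(fits[cls == cl], `[[`, "observed"))
    fit <- unlist(lapply(fits[cls == cl], `[[`, "fitted"))
    if (length(obs) < 2 || stats::sd(obs) == 0 || stats::sd(fit) == 0) {
      stop("undefined correlation: need >= 2 pooled pairs with variation",
           call. = FALSE)
    }
    stats::cor(obs, fit)
  }, numeric(1))
  out
}

#' Characteristic tumor growth time
#'
#' The inverse growth-rate constant `1/alpha`, the time scale of Gompertz
#' growth. The reported class means 0.024 and 0.088 month^-1 correspond to
#' roughly 41 and 11 months.
#'
#' @param alpha Growth-rate constant, month^-1 (> 0). Vectorized.
#' @return Characteristic time in months.
#' @export
characteristic_time <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("alpha must be positive", call. = FALSE)
  }
  1 / alpha
}

#' Tumor initiation time by backward projection
#'
#' Projects the fitted Gompertz curve backward to estimate the time to grow
#' from a single cancerous cell (1e-6 mm^3) to a detectable 10 mm^3 mass
#' (10 million cells):
#' `T = |-(1/alpha) log(log(X_start/K)/log(X0/K))| -
#'      |-(1/alpha) log(log(X_end/K)/log(X0/K))|`.
#' When `X_start < X_end <= X0 < K` this reduces to
#' `(1/alpha) * log(log(X_start/K) / log(X_end/K))`, independent of `X0`;
#' the reduced form is used as an internal consistency check.
#'
#' @param alpha Growth-rate constant, month^-1 (> 0). Vectorized.
#' @param X0 Anchor volume of the fitted curve, mm^3 (0 < X0 < K). The result
#'   does not depend on it.
#' @param K Carrying capacity, mm^3.
#' @param X_start Single-cell volume, mm^3 (default 1e-6).
#' @param X_end Detectable mass, mm^3 (default 10).
#' @return Initiation time in months (positive).
#' @examples
#' initiation_time(c(0.024, 0.088)) # ~40.5 and ~11.1 months
#' @export
initiation_time <- function(alpha, X0 = 1000, K = 180000,
                            X_start = 1e-6, X_end = 10) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("alpha must be positive", call. = FALSE)
  }
  if (!(X_start > 0 && X_start < X_end && X_end < K)) {
    stop("volume ordering violated: need 0 < X_start < X_end < K",
         call. = FALSE)
  }
  if (!(X0 > 0 && X0 < K)) stop("X0 must satisfy 0 < X0 < K", call. = FALSE)
  t_start <- abs(-(1 / alpha) * log(log(X_start / K) / log(X0 / K)))
  t_end <- abs(-(1 / alpha) * log(log(X_end / K) / log(X0 / K)))
  T_lit <- t_start - t_end
  if (X0 >= X_end) {
    T_red <- (1 / alpha) * log(log(X_start / K) / log(X_end / K))
    if (any(abs(T_lit - T_red) > 1e-8 * pmax(1, abs(T_red)))) {
      stop("internal inconsistency between initiation-time forms",
           call. = FALSE)
    }
  }
  T_lit
}

#' Lognormal characterization of cohort initiation times
#'
#' Maximum-likelihood fit of a lognormal distribution: `mu` is the mean and
#' `sigma` the (population, 1/n) standard deviation of the log samples. The
#' MLE variance can be replaced by the unbiased 1/(n-1) form via `unbiased`.
#'
#' @param samples Positive values (months), n >= 2.
#' @param unbiased Use the 1/(n-1) variance of logs instead of the MLE 1/n.
#' @return Object of class `initiation_dist` with `mu`, `sigma`, `n`, and a
#'   `degenerate` flag (all samples identical, sigma = 0).
#' @export
fit_lognormal <- function(samples, unbiased = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(samples)) || any(samples <= 0)) {
    stop("all samples must be positive", call. = FALSE)
  }
  logs <- log(samples)
  n <- length(logs)
  mu <- mean(logs)
  ss <- sum((logs - mu)^2)
  sigma <- sqrt(ss / if (unbiased) n - 1 else n)
  structure(list(mu = mu, sigma = sigma, n = n, degenerate = sigma == 0),
            class = "initiation_dist")
}

#' @export
print.initiation_dist <- function(x, ...) {
  cat(sprintf("Lognormal initiation-time distribution (n = %d)\n", x$n))
  cat(sprintf("  mu = %.4f, sigma = %.4f%s\n", x$mu, x$sigma,
              if (x$degenerate) "  [degenerate: all samples identical]" else ""))
  if (!x$degenerate) {
    cat(sprintf("  mode = %.1f months, median = %.1f months, 90%% quantile = %.1f months\n",
                initiation_mode(x), exp(x$mu), initiation_quantile(x, 0.9)))
  }
  invisible(x)
}

#' Mode of the fitted initiation-time distribution
#' @param dist An `initiation_dist`.
#' @return `exp(mu - sigma^2)`, months.
#' @export
initiation_mode <- function(dist) {
  stopifnot(inherits(dist, "initiation_dist"))
  exp(dist$mu - dist$sigma^2)
}

#' Initiation-time density
#' @param dist An `initiation_dist`.
#' @param t Times in months.
#' @return Lognormal density at `t`.
#' @export
initiation_pdf <- function(dist, t) {
  stopifnot(inherits(dist, "initiation_dist"))
  stats::dlnorm(t, meanlog = dist$mu, sdlog = dist$sigma)
}

#' Cumulative probability that initiation occurred within `t` months
#'
#' Lognormal CDF of the fitted initiation-time distribution; returns 0 for
#' `t <= 0`, is non-decreasing, and tends to 1.
#'
#' @param dist An `initiation_dist`.
#' @param t Times in months. Vectorized.
#' @return Probabilities in `[0, 1]`.
#' @export
cumulative_initiation_probability <- function(dist, t) {
  stopifnot(inherits(dist, "initiation_dist"))
  ifelse(t <= 0, 0,
         stats::plnorm(t, meanlog = dist$mu, sdlog = dist$sigma))
}

#' Initiation-time quantile
#' @param dist An `initiation_dist`.
#' @param p Probabilities.
#' @return Quantiles in months.
#' @export
initiation_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "initiation_dist"))
  stats::qlnorm(p, meanlog = dist$mu, sdlog = dist$sigma)
}

#' @export
plot.initiation_dist <- function(x, ...) {
  tt <- seq(1e-3, initiation_quantile(x, 0.995), length.out = 400)
  graphics::plot(tt, initiation_pdf(x, tt), type = "l",
                 xlab = "Initiation time (months)", ylab = "Density",
                 main = "Initiation-time distribution", ...)
  invisible(x)
}
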