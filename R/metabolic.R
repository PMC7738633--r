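#' Tissue volume from a single-slice CT area
#'
#' Body composition (subcutaneous fat, visceral fat, muscle) is quantified as
#' the contoured area on one axial slice at the L2-L3 level; the volume is
#' area times slice thickness.
#'
#' @param area_cm2 Contoured area, cm^2 (>= 0). Vectorized.
#' @param slice_thickness_mm Slice thickness, mm (> 0).
#' @return Volume in cm^3 (`area * thickness / 10`).
#' @examples
#' tissue_volume(100, 3) # 30 cm^3
#' @export
tissue_volume <- function(area_cm2, slice_thickness_mm) {
  if (any(!is.finite(area_cm2)) || any(area_cm2 < 0)) {
    stop("area must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(slice_thickness_mm)) || any(slice_thickness_mm <= 0)) {
    stop("slice thickness must be positive", call. = FALSE)
  }
  area_cm2 * slice_thickness_mm / 10
}

#' Soft-tissue wasting rate
#'
#' Percent change per month of a tissue volume over the pre-diagnostic
#' interval, `100 * (V_last - V_first) / (V_first * (t_last - t_first))`,
#' taking the earliest pre-diagnostic and the diagnostic scans as endpoints.
#' A regression alternative (OLS slope over all points, normalized to the
#' baseline volume) is available via `method`.
#'
#' @param series data.frame with columns `time` (months relative to diagnosis,
#'   strictly increasing) and `value` (volume, cm^3; baseline > 0), >= 2 rows.
#' @param method `"endpoints"` (default) or `"regression"`.
#' @return Signed rate in % change per month.
#' @examples
#' wasting_rate(data.frame(time = c(-10, 0), value = c(100, 50))) # -5
#' @export
wasting_rate <- function(series, method = c("endpoints", "regression")) {
  method <- match.arg(method)
  series <- as.data.frame(series)
  stopifnot(all(c("time", "value") %in% names(series)))
  if (nrow(series) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (any(diff(series$time) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  v0 <- series$value[1]
  if (v0 <= 0) stop("baseline volume must be positive", call. = FALSE)
  span <- series$time[nrow(series)] - series$time[1]
  if (span == 0) stop("zero time span", call. = FALSE)
  if (method == "endpoints") {
    100 * (series$value[nrow(series)] - v0) / (v0 * span)
  } else {
    100 * unname(stats::coef(stats::lm(value ~ time, data = series))[2]) / v0
  }
}

#' Pre-diagnostic blood-glucose trend
#'
#' Ordinary least-squares slope of glucose on time over the pre-diagnostic
#' window (by default the 24 months before diagnosis). Patients with fewer
#' than 2 in-window readings are flagged by returning `NA` with a warning, so
#' callers can exclude them.
#'
#' @param series data.frame with columns `time` (months relative to diagnosis)
#'   and `value` (glucose, mg/dL).
#' @param window Inclusive window in months relative to diagnosis.
#' @return Slope in mg/dL per month, or `NA` if insufficient data.
#' @export
bg_trend <- function(series, window = c(-24, 0)) {
  series <- as.data.frame(series)
  stopifnot(all(c("time", "value") %in% names(series)))
  keep <- series$time >= window[1] & series$time <= window[2]
  s <- series[keep, , drop = FALSE]
  if (nrow(s) < 2L || length(unique(s$time)) < 2L) {
    warning("fewer than 2 in-window blood-glucose readings; patient excluded",
            call. = FALSE)
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(value ~ time, data = s))[2])
}

#' Two-group comparison by Welch's t-test
#'
#' Two-sided Welch (unequal-variance) two-sample t-test, the comparison used
#' for wasting rates and glucose slopes between delta classes. If both groups
#' are degenerate (zero variance), the p-value is 1 when the means are equal
#' and 0 otherwise, with a flag.
#'
#' @param values_a,values_b Numeric vectors, >= 2 values each.
#' @return Object of class `group_comparison`: `group_means`, `t_statistic`,
#'   `df`, `p_value`, `n_per_group`, `degenerate` flag.
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need at least 2 finite values per group", call. = FALSE)
  }
  means <- c(mean(values_a), mean(values_b))
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    equal <- means[1] == means[2]
    out <- list(group_means = means, t_statistic = if (equal) 0 else Inf,
                df = NA_real_, p_value = if (equal) 1 else 0,
                n_per_group = c(length(values_a), length(values_b)),
                degenerate = TRUE)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    out <- list(group_means = means, t_statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                n_per_group = c(length(values_a), length(values_b)),
                degenerate = FALSE)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch two-sample comparison: means %.3f vs %.3f (n = %d/%d)\n",
              x$group_means[1], x$group_means[2], x$n_per_group[1],
              x$n_per_group[2]))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3g%s\n", x$t_statistic, x$df,
              x$p_value, if (x$degenerate) "  [degenerate groups]" else ""))
  invisible(x)
}

#' Per-patient wasting rates for a cohort
#'
#' @param cohort A [pdac_cohort()] whose patients carry tissue series.
#' @param method Passed to [wasting_rate()].
#' @return data.frame: patient_id, delta_class, tissue, rate_pct_per_month.
#'   Patients without a series for a tissue are simply absent for it.
#' @export
wasting_rates <- function(cohort, method = "endpoints") {
  stopifnot(inherits(cohort, "pdac_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    if (is.null(p$tissue_series)) return(NULL)
    do.call(rbind, lapply(names(p$tissue_series), function(tn) {
      s <- p$tissue_series[[tn]]
      if (nrow(s) < 2L) return(NULL)
      data.frame(patient_id = p$patient_id, delta_class = p$delta_class,
                 tissue = tn,
                 rate_pct_per_month = wasting_rate(s, method = method))
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), delta_class = character(),
                      tissue = character(), rate_pct_per_month = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Per-patient blood-glucose slopes for a cohort
#'
#' @param cohort A [pdac_cohort()].
#' @param window Passed to [bg_trend()].
#' @return data.frame: patient_id, delta_class, bg_slope_mg_dl_per_month
#'   (`NA` where in-window data were insufficient).
#' @export
bg_trends <- function(cohort, window = c(-24, 0)) {
  stopifnot(inherits(cohort, "pdac_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    if (is.null(p$bg_series)) return(NULL)
    data.frame(patient_id = p$patient_id, delta_class = p$delta_class,
               bg_slope_mg_dl_per_month = bg_trend(p$bg_series, window))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), delta_class = character(),
                      bg_slope_mg_dl_per_month = numeric())
  }
  rownames(out) <- NULL
  out
}
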