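#' Run the full pre-diagnostic growth-kinetics analysis
#'
#' Executes the pipeline stages in order: per-patient Gompertz fits,
#' initiation-time backward projection, lognormal characterization of the
#' per-class initiation times, growth-rate classification of the delta class
#' with LOOCV, and the metabolic comparisons (per-tissue wasting rates and
#' blood-glucose slopes between classes). If only one delta class is present,
#' the classification stage is skipped with a warning; fits and the metabolic
#' stage are still produced where possible. Re-running with identical inputs
#' yields identical numeric results.
#'
#' @param cohort A [pdac_cohort()], e.g. from [read_cohort()] or
#'   [generate_cohort()].
#' @param K Carrying capacity, mm^3.
#' @param X_start,X_end Single-cell and detectable volumes for the
#'   initiation-time projection, mm^3.
#' @param bg_window Blood-glucose window passed to [bg_trends()].
#' @param out_dir Optional directory; when given, writes `fits.csv`,
#'   `wasting_rates.csv`, `classifier.json` and `report.json`.
#' @param ... Further arguments to [fit_cohort()] (`alpha_init`,
#'   `alpha_bounds`, `log_scale`).
#' @return Object of class `pdac_report`; see Details.
#' @details The report contains: `fits` (per-patient table with alpha,
#'   Pearson R, convergence, characteristic and initiation times),
#'   `exclusions`, `fit_quality` (pooled per-class Pearson R), `initiation`
#'   (per-class `initiation_dist` plus mode and 90% quantile, over converged
#'   fits only — a bound-pinned alpha has no usable backward projection),
#'   `classifier`
#'   (model, training report, LOOCV), `metabolic` (per-tissue class means and
#'   Welch comparisons, BG slopes and comparison), and `provenance`.
#' @export
run_pipeline <- function(cohort, K = 180000, X_start = 1e-6, X_end = 10,
                         bg_window = c(-24, 0), out_dir = NULL, ...) {
  stopifnot(inherits(cohort, "pdac_cohort"))
  classes <- delta_classes(cohort)

  ## stage: Gompertz fits
  fc <- fit_cohort(cohort, K = K, ...)
  if (length(fc$fits) == 0) {
    stop("pipeline stage 'fit': no patient could be fitted", call. = FALSE)
  }
  fits_table <- do.call(rbind, lapply(fc$fits, function(f) {
    data.frame(patient_id = f$patient_id,
               delta_class = classes[[f$patient_id]],
               alpha = f$alpha, pearson_r = f$pearson_r,
               converged = f$converged, n_obs = f$n_obs,
               characteristic_time_months = characteristic_time(f$alpha),
               initiation_time_months = initiation_time(
                 f$alpha, X0 = f$X0, K = K, X_start = X_start, X_end = X_end))
  }))
  rownames(fits_table) <- NULL
  fit_quality <- tryCatch(
    cohort_fit_quality(fc$fits, classes),
    error = function(e) {
      warning("pipeline stage 'fit quality': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })

  ## stage: lognormal initiation-time distributions per class.
  ## Bound-pinned (non-converged) fits carry no usable rate estimate, so their
  ## backward projections are left out of the cohort distribution.
  conv <- fits_table[fits_table$converged, , drop = FALSE]
  initiation <- lapply(split(conv, conv$delta_class), function(d) {
    if (nrow(d) < 2) return(NULL)
    dist <- fit_lognormal(d$initiation_time_months)
    list(dist = dist, mu = dist$mu, sigma = dist$sigma, n = dist$n,
         mode_months = initiation_mode(dist),
         q90_months = initiation_quantile(dist, 0.9))
  })

  ## stage: classification + LOOCV
  classifier <- NULL
  if (length(unique(fits_table$delta_class)) < 2) {
    warning("pipeline stage 'classify' skipped: only one delta class present",
            call. = FALSE)
  } else if (nrow(fits_table) < 5) {
    warning("pipeline stage 'classify' skipped: fewer than 5 fitted patients",
            call. = FALSE)
  } else {
    model <- fit_classifier(fits_table$alpha, fits_table$delta_class)
    training <- classification_report(fits_table$alpha,
                                      fits_table$delta_class, model$threshold)
    cv <- loocv(fits_table$alpha, fits_table$delta_class)
    classifier <- list(model = model, training = training, loocv = cv)
  }

  ## stage: metabolic comparisons
  metabolic <- NULL
  rates <- wasting_rates(cohort)
  bg <- bg_trends(cohort, window = bg_window)
  if (nrow(rates) || nrow(bg)) {
    tissue_cmp <- lapply(split(rates, rates$tissue), function(d) {
      hi <- d$rate_pct_per_month[d$delta_class == "high"]
      lo <- d$rate_pct_per_month[d$delta_class == "low"]
      cmp <- if (length(hi) >= 2 && length(lo) >= 2) compare_groups(hi, lo)
      list(mean_high = if (length(hi)) mean(hi) else NA_real_,
           mean_low = if (length(lo)) mean(lo) else NA_real_,
           comparison = cmp)
    })
    bg_cmp <- NULL
    if (nrow(bg)) {
      ok <- is.finite(bg$bg_slope_mg_dl_per_month)
      hi <- bg$bg_slope_mg_dl_per_month[ok & bg$delta_class == "high"]
      lo <- bg$bg_slope_mg_dl_per_month[ok & bg$delta_class == "low"]
      bg_cmp <- list(
        mean_high = if (length(hi)) mean(hi) else NA_real_,
        mean_low = if (length(lo)) mean(lo) else NA_real_,
        n_excluded = sum(!ok),
        comparison = if (length(hi) >= 2 && length(lo) >= 2)
          compare_groups(hi, lo))
    }
    metabolic <- list(rates = rates, tissue = tissue_cmp,
                      bg_slopes = bg, bg = bg_cmp)
  }

  report <- structure(
    list(fits = fits_table, exclusions = fc$exclusions,
         fit_quality = fit_quality, initiation = initiation,
         classifier = classifier, metabolic = metabolic,
         provenance = list(
           n_patients = length(cohort$patients),
           n_fitted = nrow(fits_table), n_excluded = nrow(fc$exclusions),
           K = K, X_start = X_start, X_end = X_end,
           seed = cohort$metadata$seed, source = cohort$metadata$source,
           package_version = as.character(utils::packageVersion("pdacgrowth")))),
    class = "pdac_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pdac_report <- function(x, ...) {
  cat("Pre-diagnostic PDAC growth-kinetics report\n")
  cat(sprintf("  %d patients fitted, %d excluded\n",
              x$provenance$n_fitted, x$provenance$n_excluded))
  for (cl in c("low", "high")) {
    d <- x$fits[x$fits$delta_class == cl, ]
    if (!nrow(d)) next
    cat(sprintf("  %s delta (n = %d): mean alpha %.4f month^-1, characteristic time %.1f months\n",
                cl, nrow(d), mean(d$alpha), 1 / mean(d$alpha)))
    ini <- x$initiation[[cl]]
    if (!is.null(ini)) {
      cat(sprintf("    initiation time: mode %.1f months, 90%% quantile %.1f years\n",
                  ini$mode_months, ini$q90_months / 12))
    }
  }
  if (!is.null(x$fit_quality)) {
    cat("  pooled fit quality (Pearson R):",
        paste(sprintf("%s %.3f", names(x$fit_quality), x$fit_quality),
              collapse = ", "), "\n")
  }
  if (!is.null(x$classifier)) {
    cat(sprintf("  classifier: AUC %.3f, threshold %.4f month^-1, accuracy %.1f%%, MCC %+.2f\n",
                x$classifier$model$auc, x$classifier$model$threshold,
                100 * x$classifier$training$accuracy,
                x$classifier$training$mcc))
    cat(sprintf("  LOOCV: pooled accuracy %.1f%%, training AUC %.3f +/- %.3f\n",
                100 * x$classifier$loocv$report$accuracy,
                x$classifier$loocv$auc_mean, x$classifier$loocv$auc_sd))
  }
  if (!is.null(x$metabolic)) {
    for (tn in names(x$metabolic$tissue)) {
      tc <- x$metabolic$tissue[[tn]]
      cat(sprintf("  %s wasting: %.1f (high) vs %.1f (low) %%/month%s\n", tn,
                  tc$mean_high, tc$mean_low,
                  if (!is.null(tc$comparison))
                    sprintf(", p = %.2g", tc$comparison$p_value) else ""))
    }
    if (!is.null(x$metabolic$bg)) {
      cat(sprintf("  BG slope: %.2f (high) vs %.2f (low) mg/dL/month%s\n",
                  x$metabolic$bg$mean_high, x$metabolic$bg$mean_low,
                  if (!is.null(x$metabolic$bg$comparison))
                    sprintf(", p = %.2g", x$metabolic$bg$comparison$p_value)
                  else ""))
    }
  }
  invisible(x)
}

report_to_list <- function(report) {
  x <- report
  cls_block <- NULL
  if (!is.null(x$classifier)) {
    tr <- x$classifier$training
    cv <- x$classifier$loocv
    cls_block <- list(
      auc = x$classifier$model$auc,
      threshold = x$classifier$model$threshold,
      coefficients = as.list(x$classifier$model$coefficients),
      confusion = as.list(tr$confusion),
      accuracy = tr$accuracy, sensitivity = tr$sensitivity,
      specificity = tr$specificity, ppv = tr$ppv, npv = tr$npv, mcc = tr$mcc,
      loocv = list(
        confusion = as.list(cv$report$confusion),
        accuracy = cv$report$accuracy, sensitivity = cv$report$sensitivity,
        specificity = cv$report$specificity, ppv = cv$report$ppv,
        npv = cv$report$npv, mcc = cv$report$mcc,
        auc_mean = cv$auc_mean, auc_sd = cv$auc_sd,
        n_excluded_iterations = cv$n_excluded))
  }
  ini_block <- lapply(x$initiation, function(ini) {
    if (is.null(ini)) return(NULL)
    list(mu = ini$mu, sigma = ini$sigma, n = ini$n,
         mode_months = ini$mode_months, q90_months = ini$q90_months)
  })
  met_block <- NULL
  if (!is.null(x$metabolic)) {
    met_block <- list(
      tissue = lapply(x$metabolic$tissue, function(tc) {
        list(mean_high = tc$mean_high, mean_low = tc$mean_low,
             p_value = if (!is.null(tc$comparison)) tc$comparison$p_value)
      }),
      bg = if (!is.null(x$metabolic$bg)) list(
        mean_high = x$metabolic$bg$mean_high,
        mean_low = x$metabolic$bg$mean_low,
        n_excluded = x$metabolic$bg$n_excluded,
        p_value = if (!is.null(x$metabolic$bg$comparison))
          x$metabolic$bg$comparison$p_value))
  }
  list(fits = x$fits, exclusions = x$exclusions,
       fit_quality = as.list(x$fit_quality), initiation = ini_block,
       classifier = cls_block, metabolic = met_block,
       provenance = x$provenance)
}

#' Write a pipeline report to disk
#'
#' Writes the per-patient fit table (`fits.csv`), per-patient wasting rates
#' (`wasting_rates.csv`), classifier summary (`classifier.json`) and the full
#' report (`report.json`).
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pdac_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, "fits.csv")
  utils::write.csv(report$fits, paths, row.names = FALSE)
  if (!is.null(report$metabolic)) {
    p <- file.path(out_dir, "wasting_rates.csv")
    utils::write.csv(report$metabolic$rates, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  lst <- report_to_list(report)
  if (!is.null(lst$classifier)) {
    p <- file.path(out_dir, "classifier.json")
    jsonlite::write_json(lst$classifier, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(lst, p, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, dataframe = "rows")
  invisible(c(paths, p))
}
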