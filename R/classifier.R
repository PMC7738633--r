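#' Binary delta-class classifier on the growth-rate constant
#'
#' Fits a univariate logistic regression of the imaging subtype (high vs low
#' delta) on the Gompertz growth-rate constant alpha and computes the ROC
#' curve. Because the logistic link is monotone in alpha, the ROC over
#' predicted probabilities is identical to the ROC over alpha itself, so the
#' curve is built directly from alpha. Candidate discrimination thresholds are
#' the midpoints between consecutive distinct sorted alpha values plus
#' sentinels below and above the observed range; a point is classified high
#' delta when its alpha exceeds the threshold. AUC is the trapezoid area under
#' the ROC staircase. Perfect separation is permitted: the logistic
#' coefficients may diverge (a warning is raised) but the ranking, ROC and
#' threshold remain well defined.
#'
#' @param alphas Growth-rate constants, month^-1.
#' @param labels Delta classes, `"high"`/`"low"` (character or factor).
#' @return Object of class `delta_classifier`: logistic `coefficients`, `roc`
#'   data.frame (threshold, fpr, tpr), `auc`, accuracy-maximizing `threshold`
#'   (see [select_threshold()]), and the training data.
#' @examples
#' cl <- fit_classifier(c(0.01, 0.02, 0.05, 0.06),
#'                      c("low", "low", "high", "high"))
#' cl$auc
#' @export
fit_classifier <- function(alphas, labels) {
  labels <- check_labels(alphas, labels)
  if (length(alphas) < 4L) stop("need at least 4 points", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: both classes must be present", call. = FALSE)
  }
  y <- as.integer(labels == "high")
  glm_fit <- withCallingHandlers(
    stats::glm(y ~ alphas, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warning("perfect or quasi-perfect separation: logistic coefficients may diverge",
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  roc <- roc_curve(alphas, labels)
  model <- structure(
    list(coefficients = stats::coef(glm_fit), roc = roc,
         auc = roc_auc(roc), threshold = NA_real_,
         alphas = alphas, labels = labels, positive_class = "high"),
    class = "delta_classifier")
  model$threshold <- select_threshold(model)
  model
}

check_labels <- function(alphas, labels) {
  stopifnot(length(alphas) == length(labels))
  if (any(!is.finite(alphas))) stop("alphas must be finite", call. = FALSE)
  labels <- tolower(as.character(labels))
  if (!all(labels %in% c("high", "low"))) {
    stop("labels must be 'high' or 'low'", call. = FALSE)
  }
  labels
}

# candidate cuts: midpoints of consecutive distinct sorted alphas + sentinels
threshold_candidates <- function(alphas) {
  u <- sort(unique(alphas))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(u[1] - 1, mids, u[length(u)] + 1)
}

roc_curve <- function(alphas, labels) {
  cand <- threshold_candidates(alphas)
  pos <- labels == "high"
  fpr <- vapply(cand, function(t) mean(alphas[!pos] > t), numeric(1))
  tpr <- vapply(cand, function(t) mean(alphas[pos] > t), numeric(1))
  d <- data.frame(threshold = cand, fpr = fpr, tpr = tpr)
  d[order(d$fpr, d$tpr), , drop = FALSE]
}

roc_auc <- function(roc) {
  # trapezoid over the staircase; ties in alpha across classes give diagonal
  # segments, so this equals the Mann-Whitney statistic with the 1/2 tie rule
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Accuracy-maximizing discrimination threshold
#'
#' Exhaustively evaluates classification accuracy at every candidate threshold
#' (midpoints of distinct sorted alphas plus sentinels) and returns the
#' maximizer. Ties are broken by the larger Youden's J (sensitivity +
#' specificity - 1), then by the smallest threshold.
#'
#' @param model A [fit_classifier()] result, or `NULL` when `alphas` and
#'   `labels` are given directly.
#' @param alphas,labels Data to evaluate on; default to the model's training
#'   data.
#' @return The threshold on alpha, month^-1.
#' @export
select_threshold <- function(model = NULL, alphas = model$alphas,
                             labels = model$labels) {
  labels <- check_labels(alphas, labels)
  cand <- threshold_candidates(alphas)
  pos <- labels == "high"
  acc <- j <- numeric(length(cand))
  for (i in seq_along(cand)) {
    pred <- alphas > cand[i]
    acc[i] <- mean(pred == pos)
    sens <- if (any(pos)) mean(pred[pos]) else 0
    spec <- if (any(!pos)) mean(!pred[!pos]) else 0
    j[i] <- sens + spec - 1
  }
  best <- which(acc == max(acc))
  best <- best[j[best] == max(j[best])]
  cand[min(best)]
}

#' Confusion matrix and derived classification metrics
#'
#' Predicts high delta when alpha exceeds the threshold and tabulates the
#' confusion counts with the usual derived proportions. The Matthews
#' correlation coefficient is
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0 when
#' any factor of the denominator is 0.
#'
#' @param alphas Growth-rate constants.
#' @param labels True delta classes.
#' @param threshold Discrimination threshold on alpha.
#' @param predictions Optional explicit predicted classes (overrides
#'   `threshold`), used by [loocv()] to pool held-out predictions.
#' @return Object of class `classification_report`: `confusion` (TP, FP, TN,
#'   FN), `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `mcc`, `n`.
#' @export
classification_report <- function(alphas, labels, threshold,
                                  predictions = NULL) {
  labels <- check_labels(alphas, labels)
  pos <- labels == "high"
  pred <- if (is.null(predictions)) {
    alphas > threshold
  } else {
    check_labels(alphas, predictions) == "high"
  }
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  prop <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
         accuracy = (tp + tn) / length(labels),
         sensitivity = prop(tp, tp + fn), specificity = prop(tn, tn + fp),
         ppv = prop(tp, tp + fp), npv = prop(tn, tn + fn),
         mcc = mcc, threshold = if (is.null(predictions)) threshold else NA_real_,
         n = length(labels)),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (positive class: high delta)\n")
  cat(sprintf("  n = %d; TP = %d, FP = %d, TN = %d, FN = %d\n", x$n,
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  PPV %.3f, NPV %.3f, MCC %+.3f\n", x$ppv, x$npv, x$mcc))
  invisible(x)
}

#' @export
print.delta_classifier <- function(x, ...) {
  cat("Delta-class classifier on the growth-rate constant\n")
  cat(sprintf("  n = %d (%d high, %d low); AUC = %.3f\n", length(x$alphas),
              sum(x$labels == "high"), sum(x$labels == "low"), x$auc))
  cat(sprintf("  discrimination threshold = %.4f month^-1 (alpha above -> high delta)\n",
              x$threshold))
  invisible(x)
}

#' @export
summary.delta_classifier <- function(object, ...) {
  rep <- classification_report(object$alphas, object$labels, object$threshold)
  out <- list(model = object, report = rep)
  class(out) <- "summary.delta_classifier"
  out
}

#' @export
print.summary.delta_classifier <- function(x, ...) {
  print(x$model)
  print(x$report)
  invisible(x)
}

#' Predict delta class for new growth-rate constants
#' @param object A `delta_classifier`.
#' @param newdata Alphas to classify (defaults to training alphas).
#' @param ... Unused.
#' @return Character vector of `"high"`/`"low"`.
#' @export
predict.delta_classifier <- function(object, newdata = object$alphas, ...) {
  ifelse(newdata > object$threshold, "high", "low")
}

#' @export
plot.delta_classifier <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Complementary cumulative distribution of growth-rate constants
#'
#' Returns the right-continuous step function `t -> P(alpha > t)` used to
#' visualize the binary classification at the chosen threshold; evaluate it
#' per delta class for plotting.
#'
#' @param alphas Non-empty numeric vector.
#' @return A vectorized function of `t`.
#' @examples
#' f <- ccd(c(1, 2, 3)); f(2) # 1/3
#' @export
ccd <- function(alphas) {
  stopifnot(length(alphas) > 0, all(is.finite(alphas)))
  force(alphas)
  function(t) vapply(t, function(ti) mean(alphas > ti), numeric(1))
}

#' Leave-one-out cross-validation of the delta classifier
#'
#' Runs n iterations, each removing one point, refitting the classifier and
#' its accuracy-maximizing threshold on the remaining n-1 points, and
#' classifying the held-out point. Held-out predictions are pooled into a
#' cross-validated [classification_report()]; the per-iteration training-fold
#' AUCs are summarized as mean and sd. An iteration whose training fold loses
#' one class entirely is excluded with a warning.
#'
#' @param alphas Growth-rate constants (n >= 5).
#' @param labels Delta classes, both present.
#' @return Object of class `loocv_result`: `report` (pooled), `auc_mean`,
#'   `auc_sd`, `n_excluded`, and the per-point held-out `predictions`.
#' @export
loocv <- function(alphas, labels) {
  labels <- check_labels(alphas, labels)
  n <- length(alphas)
  if (n < 5L) stop("need at least 5 points for LOOCV", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: both classes must be present", call. = FALSE)
  }
  predictions <- rep(NA_character_, n)
  aucs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr_a <- alphas[-i]; tr_l <- labels[-i]
    if (length(unique(tr_l)) < 2L) {
      warning(sprintf("LOOCV iteration %d excluded: training fold lost a class", i),
              call. = FALSE)
      next
    }
    roc <- roc_curve(tr_a, tr_l)
    aucs[i] <- roc_auc(roc)
    thr <- select_threshold(alphas = tr_a, labels = tr_l)
    predictions[i] <- if (alphas[i] > thr) "high" else "low"
  }
  kept <- !is.na(predictions)
  report <- classification_report(alphas[kept], labels[kept], NA_real_,
                                  predictions = predictions[kept])
  structure(
    list(report = report, auc_mean = mean(aucs[kept]),
         auc_sd = stats::sd(aucs[kept]), n_excluded = sum(!kept),
         predictions = predictions),
    class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("Leave-one-out cross-validation\n")
  cat(sprintf("  training-fold AUC: %.3f +/- %.3f; excluded iterations: %d\n",
              x$auc_mean, x$auc_sd, x$n_excluded))
  print(x$report)
  invisible(x)
}
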