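test_that("perfectly separated classes give AUC 1 and the midpoint threshold", {
  cl <- suppressWarnings(fit_classifier(c(0.01, 0.02, 0.05, 0.06),
                                        c("low", "low", "high", "high")))
  expect_equal(cl$auc, 1)
  expect_equal(cl$threshold, 0.035)
  rep <- classification_report(cl$alphas, cl$labels, cl$threshold)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$mcc, 1)
})

test_that("staircase AUC equals exhaustive concordant-pair counting", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    # rounding forces ties both within and across classes
    a <- round(rlnorm(n, -3, 1), sample(1:3, 1))
    l <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c("high", "low")
    roc <- suppressWarnings(fit_classifier(c(a, 10, 1e-9), c(l, "high", "low")))
    expect_equal(oracle_auc(c(a, 10, 1e-9), c(l, "high", "low")), roc$auc,
                 tolerance = 1e-12)
  }
})

test_that("ROC is a monotone staircase from (0,0) to (1,1)", {
  set.seed(52)
  cl <- fit_classifier(rlnorm(30, -3, 1),
                       sample(c("high", "low"), 30, replace = TRUE,
                              prob = c(0.5, 0.5)))
  expect_equal(cl$roc$fpr[1], 0)
  expect_equal(cl$roc$tpr[1], 0)
  expect_equal(cl$roc$fpr[nrow(cl$roc)], 1)
  expect_equal(cl$roc$tpr[nrow(cl$roc)], 1)
  expect_true(all(diff(cl$roc$fpr) >= 0))
  expect_true(all(diff(cl$roc$tpr) >= 0))
  expect_gte(cl$auc, 0)
  expect_lte(cl$auc, 1)
})

test_that("random label permutations average to AUC one half", {
  set.seed(53)
  a <- rlnorm(20, -3, 1)
  l <- rep(c("high", "low"), each = 10)
  aucs <- replicate(1e4, oracle_auc(a, sample(l)))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
  # and our staircase matches the oracle on a permuted instance
  lp <- sample(l)
  expect_equal(fit_classifier(a, lp)$auc, oracle_auc(a, lp))
})

test_that("hand-computable mixed instance matches the pair-counting oracle", {
  a <- c(0.01, 0.02, 0.03, 0.05, 0.005)
  l <- c("high", "low", "high", "high", "low")
  expect_equal(oracle_auc(a, l), 5 / 6)
  expect_equal(fit_classifier(a, l)$auc, 5 / 6)
})

test_that("selected threshold attains the brute-force maximum accuracy", {
  set.seed(54)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    a <- round(rlnorm(n, -3, 1), 2)
    l <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c("high", "low")
    thr <- select_threshold(alphas = a, labels = l)
    expect_equal(mean((a > thr) == (l == "high")), oracle_best_accuracy(a, l))
  }
})

test_that("threshold ties break by Youden's J then smallest cut", {
  # accuracy 2/3 at both the all-high sentinel and the 0.025 midpoint;
  # the midpoint wins on Youden's J
  thr <- select_threshold(alphas = c(0.01, 0.02, 0.03),
                          labels = c("high", "low", "high"))
  expect_equal(thr, 0.025)
})

test_that("classification report computes the closed-form metrics", {
  # TP=8, FP=2, TN=8, FN=2
  a <- c(rep(1, 8), rep(0, 2), rep(0, 8), rep(1, 2))
  l <- c(rep("high", 10), rep("low", 10))
  rep <- classification_report(a, l, 0.5)
  expect_equal(unname(rep$confusion), c(8, 2, 8, 2))
  expect_equal(rep$sensitivity, 0.8)
  expect_equal(rep$specificity, 0.8)
  expect_equal(rep$mcc, 0.6)
  expect_equal(rep$accuracy, 0.8)
  # sensitivity*P + specificity*N = TP + TN
  expect_equal(rep$sensitivity * 10 + rep$specificity * 10,
               sum(rep$confusion[c("TP", "TN")]))
})

test_that("MCC is zero by convention when a denominator factor vanishes", {
  a <- c(1, 2, 3, 4)
  l <- c("high", "low", "high", "low")
  rep <- classification_report(a, l, 0) # everything predicted high
  expect_equal(rep$mcc, 0)
  expect_true(is.na(rep$npv))
})

test_that("single-class input is refused", {
  expect_error(fit_classifier(1:4 / 100, rep("high", 4)), "degenerate")
  expect_error(loocv(1:5 / 100, rep("low", 5)), "degenerate")
})

test_that("perfect separation warns but leaves ROC and threshold intact", {
  expect_warning(
    cl <- fit_classifier(c(0.01, 0.015, 0.02, 0.06, 0.07, 0.08),
                         rep(c("low", "high"), each = 3)),
    "separation")
  expect_equal(cl$auc, 1)
  expect_equal(cl$threshold, 0.04)
})

test_that("complementary cumulative distribution matches 1 - ECDF", {
  f <- ccd(c(1, 2, 3))
  expect_equal(f(2), 1 / 3)
  expect_equal(f(0.5), 1)
  expect_equal(f(3.5), 0)
  set.seed(55)
  x <- rlnorm(100, -3, 1)
  g <- ccd(x)
  emp <- ecdf(x)
  tt <- c(x, runif(50, 0, 0.5))
  expect_equal(g(tt), 1 - emp(tt))
})

test_that("LOOCV produces one held-out prediction per point and is order-invariant", {
  set.seed(56)
  a <- rlnorm(20, -3, 0.8)
  l <- rep(c("high", "low"), 10)
  cv <- loocv(a, l)
  expect_length(cv$predictions, 20)
  expect_equal(cv$report$n, 20)
  expect_equal(cv$n_excluded, 0)
  perm <- sample(20)
  cv2 <- loocv(a[perm], l[perm])
  expect_equal(cv2$report$accuracy, cv$report$accuracy)
  expect_equal(cv2$auc_mean, cv$auc_mean)
})

test_that("LOOCV separates the two reported class means at sigma_log 0.3", {
  set.seed(57)
  a <- c(rlnorm(50, log(0.024) - 0.3^2 / 2, 0.3),
         rlnorm(50, log(0.088) - 0.3^2 / 2, 0.3))
  l <- rep(c("low", "high"), each = 50)
  cv <- loocv(a, l)
  expect_gte(cv$report$accuracy, 0.9)
})

test_that("LOOCV on labels independent of alpha hovers near chance", {
  set.seed(58)
  a <- rlnorm(100, -3, 0.8)
  l <- rep(c("high", "low"), 50)
  cv <- loocv(a, l)
  expect_lt(abs(cv$report$accuracy - 0.5), 0.1)
})

test_that("training folds that lose a class are excluded with a warning", {
  a <- c(0.1, 0.01, 0.02, 0.03, 0.04, 0.05)
  l <- c("high", rep("low", 5))
  expect_warning(cv <- loocv(a, l), "lost a class")
  expect_equal(cv$n_excluded, 1)
  expect_equal(cv$report$n, 5)
})

test_that("staircase AUC agrees with an independent ROC implementation", {
  set.seed(59)
  a <- rlnorm(40, -3, 1)
  l <- sample(c("high", "low"), 40, replace = TRUE)
  l[1:2] <- c("high", "low")
  ours <- fit_classifier(a, l)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(l, levels = c("low", "high")), predictor = a,
    direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref))
})

test_that("predict labels new growth rates by the fitted threshold", {
  cl <- suppressWarnings(fit_classifier(c(0.01, 0.02, 0.05, 0.06),
                                        c("low", "low", "high", "high")))
  expect_equal(predict(cl, c(0.001, 0.1)), c("low", "high"))
  expect_output(print(summary(cl)), "MCC")
})
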