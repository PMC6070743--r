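logistic_table <- function(n, beta0, beta, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(beta)), n)
  eta <- beta0 + x %*% beta
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  tab <- data.frame(subject_id = sprintf("S%04d", 1:n), label = y)
  for (k in seq_along(beta)) tab[[paste0("f", k)]] <- x[, k]
  tab
}

test_that("maximum-likelihood fit recovers known coefficients", {
  tab <- logistic_table(2000, -0.5, 1.2, seed = 21)
  model <- fit_logistic(tab)
  expect_false(model$separation)
  expect_lt(abs(model$intercept - (-0.5)), 0.15)
  expect_lt(abs(model$coefficients[["f1"]] - 1.2), 0.15)
})

test_that("a perfectly separating feature raises the separation flag", {
  tab <- data.frame(subject_id = letters[1:10],
                    label = rep(c(1L, 0L), each = 5),
                    f1 = c(1:5, -(1:5)))
  model <- fit_logistic(tab)
  expect_true(model$separation)
  expect_true(all(is.finite(c(model$intercept, model$coefficients))))
  # the ridge fallback still ranks the classes correctly
  sc <- radiomics_score(model, tab)
  expect_equal(roc_auc(sc, tab$label)$auc, 1)
})

test_that("a constant zero feature fits to a null model", {
  tab <- data.frame(subject_id = sprintf("S%02d", 1:40),
                    label = rep(c(1L, 0L), 20), f1 = 0)
  model <- fit_logistic(tab)
  expect_lt(abs(model$intercept), 1e-6)
  expect_lt(abs(model$coefficients[["f1"]]), 1e-6)
})

test_that("radiomics scores are the linear predictor through the sigmoid", {
  model <- structure(list(intercept = 0.7,
                          coefficients = c(f1 = 2, f2 = -1),
                          converged = TRUE, separation = FALSE),
                     class = "cc_logistic")
  tab <- data.frame(subject_id = c("a", "b"), label = c(1L, 0L),
                    f1 = c(0, 1), f2 = c(0, 2))
  sc <- radiomics_score(model, tab)
  expect_equal(sc, c(0.7, 0.7 + 2 - 2))
  expect_equal(ccradiomics:::.sigmoid(0), 0.5)
  # monotone in a positively weighted feature
  tab2 <- tab; tab2$f1 <- tab2$f1 + 1
  expect_true(all(radiomics_score(model, tab2) > sc))
  expect_error(radiomics_score(model, tab[, 1:3]), "missing feature")
})

test_that("AUC follows the Mann-Whitney identity with half ties", {
  expect_equal(roc_auc(c(3, 2, 1, 2), c(1, 1, 0, 0))$auc, 0.875)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals the trapezoidal area of the constructed ROC", {
  set.seed(22)
  for (rep in 1:5) {
    sc <- rnorm(60)
    lab <- rbinom(60, 1, 0.4)
    if (length(unique(lab)) < 2) next
    ra <- roc_auc(sc, lab)
    o <- order(ra$roc$fpr, ra$roc$tpr)
    fpr <- ra$roc$fpr[o]; tpr <- ra$roc$tpr[o]
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(ra$auc, trap, tolerance = 1e-12)
    # independent oracle: pROC
    expect_equal(ra$auc,
                 as.numeric(pROC::auc(pROC::roc(
                   lab, sc, quiet = TRUE, direction = "<",
                   levels = c(0, 1)))))
    # invariance under strictly monotone transform
    expect_equal(roc_auc(exp(sc), lab)$auc, ra$auc)
  }
})

test_that("the published metric panel follows from counts 19/5/7/7", {
  cm <- confusion_metrics(TP = 19, FP = 7, TN = 7, FN = 5)
  expect_equal(unname(cm$reported[c("sensitivity", "specificity",
                                    "accuracy", "precision", "npv")]),
               c(0.792, 0.500, 0.684, 0.731, 0.583))
  expect_equal(cm$metrics[["precision"]], cm$metrics[["ppv"]])
  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_true(all(perfect$metrics == 1))
  # zero denominator is flagged, not silently zero
  none_pred <- confusion_metrics(0, 0, 10, 5)
  expect_true(is.na(none_pred$metrics[["precision"]]))
  expect_equal(none_pred$metrics[["specificity"]], 1)
})

test_that("reported metrics round half-up at the third decimal", {
  expect_equal(ccradiomics:::.round_half_up(0.0005, 3), 0.001)
  expect_equal(ccradiomics:::.round_half_up(19 / 24, 3), 0.792)
  expect_equal(ccradiomics:::.round_half_up(7 / 12, 3), 0.583)
})

test_that("evaluation reports are self-consistent", {
  tab <- logistic_table(200, 0, c(1.5, -1), seed = 23)
  model <- fit_logistic(tab)
  rep <- evaluate(model, tab)
  cnt <- rep$counts
  expect_equal(cnt[["TP"]] + cnt[["FN"]], sum(tab$label == 1))
  expect_equal(cnt[["TN"]] + cnt[["FP"]], sum(tab$label == 0))
  m <- rep$metrics
  expect_equal(m[["sensitivity"]], cnt[["TP"]] / (cnt[["TP"]] + cnt[["FN"]]))
  expect_equal(m[["accuracy"]],
               (cnt[["TP"]] + cnt[["TN"]]) / nrow(tab))
  expect_gte(m[["auc"]], 0); expect_lte(m[["auc"]], 1)
  # probability exactly 0.5 classifies as positive
  model0 <- structure(list(intercept = 0, coefficients = c(f1 = 0),
                           converged = TRUE, separation = FALSE),
                      class = "cc_logistic")
  tab0 <- data.frame(subject_id = c("a", "b"), label = c(1L, 0L),
                     f1 = c(1, 2))
  rep0 <- evaluate(model0, tab0)
  expect_equal(unname(rep0$counts), c(TP = 1, FP = 1, TN = 0, FN = 0),
               ignore_attr = TRUE)
})
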