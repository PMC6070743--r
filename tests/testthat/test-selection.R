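# Random labelled feature table for selection tests.
random_table <- function(n1 = 20, n0 = 20, p = 10, seed = 1,
                         prefix = "f") {
  set.seed(seed)
  n <- n1 + n0
  tab <- data.frame(subject_id = sprintf("S%03d", 1:n),
                    label = c(rep(1L, n1), rep(0L, n0)))
  for (k in seq_len(p)) tab[[paste0(prefix, k)]] <- rnorm(n)
  tab
}

test_that("abnormal values are imputed by the mean of the remainder", {
  tab <- data.frame(subject_id = c("a", "b", "c", "d"),
                    label = c(1L, 1L, 0L, 0L),
                    f1 = c(1, 2, 3, NaN),
                    f2 = c(1, 1, 1, 1000),
                    f3 = c(1, 2, 3, 4))
  out <- impute_abnormal(tab)
  expect_equal(out$f1, c(1, 2, 3, 2))
  expect_equal(out$f2, c(1, 1, 1, 1))     # 1000 flagged by the IQR rule
  expect_equal(out$f3, c(1, 2, 3, 4))
  expect_equal(attr(out, "n_imputed"), 2L)
  clean <- random_table(5, 5, p = 3, seed = 2)
  out2 <- impute_abnormal(clean)
  expect_equal(attr(out2, "n_imputed"), 0L)
  attributes(out2)[c("n_imputed", "anchor")] <- NULL
  expect_identical(out2, clean)
})

test_that("anchored imputation applies training statistics to new rows", {
  tr <- data.frame(subject_id = letters[1:4], label = c(1L, 1L, 0L, 0L),
                   f1 = c(1, 2, 3, 4))
  tr_imp <- impute_abnormal(tr)
  te <- data.frame(subject_id = "e", label = 0L, f1 = 1000)
  te_imp <- impute_abnormal(te, anchor = attr(tr_imp, "anchor"))
  expect_equal(te_imp$f1, 2.5)   # training mean, not a test statistic
})

test_that("stratified split uses the floor rule per class", {
  labels <- c(rep(1, 78), rep(0, 44))
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_equal(sum(labels[sp$train] == 1), 54)
  expect_equal(sum(labels[sp$train] == 0), 30)
  expect_equal(sum(labels[sp$test] == 1), 24)
  expect_equal(sum(labels[sp$test] == 0), 14)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_identical(sp, stratified_split(labels, 0.7, seed = 1))
  expect_false(identical(sp, stratified_split(labels, 0.7, seed = 2)))
  sp2 <- stratified_split(c(rep(1, 10), rep(0, 10)), 0.7, seed = 3)
  expect_equal(length(sp2$train), 14)
  expect_equal(length(sp2$test), 6)
})

test_that("standardization is anchored on the training partition", {
  tr <- data.frame(subject_id = c("a", "b", "c"), label = c(1L, 1L, 0L),
                   f1 = c(1, 2, 3))
  te <- data.frame(subject_id = "d", label = 0L, f1 = 4)
  std <- standardize(tr, te)
  expect_equal(std$train$f1, c(-1, 0, 1))
  expect_equal(std$test$f1, 2)
  big <- random_table(15, 15, p = 5, seed = 4)
  sp <- stratified_split(big$label, 0.7, seed = 4)
  std2 <- standardize(big[sp$train, ], big[sp$test, ])
  for (f in paste0("f", 1:5)) {
    expect_lt(abs(mean(std2$train[[f]])), 1e-12)
    expect_equal(sd(std2$train[[f]]), 1, tolerance = 1e-12)
  }
  # zero-variance training column is dropped with a warning
  big$f6 <- 1
  expect_warning(std3 <- standardize(big[sp$train, ], big[sp$test, ]),
                 "zero-variance")
  expect_false("f6" %in% colnames(std3$train))
})

test_that("univariate filter drops null features and keeps real effects", {
  tab <- random_table(40, 40, p = 4, seed = 5)
  tab$f1 <- tab$f1 + 2 * tab$label          # strong effect, power ~ 1
  tab$f4 <- 0.5                             # constant
  tab$f4[1] <- 0.5                          # still constant
  res <- univariate_filter(tab, alpha = 0.05)
  expect_true(res$selected[res$feature == "f1"])
  expect_equal(res$p[res$feature == "f4"], 1)
  expect_equal(res$test[res$feature == "f4"], "constant")
  # identical distribution in both classes: not selected
  same <- random_table(30, 30, p = 1, seed = 6)
  same$f1 <- rep(c(1, 2, 3), 20)
  expect_false(univariate_filter(same)$selected[1])
})

test_that("clearly non-normal features route to the rank-sum test", {
  tab <- random_table(30, 30, p = 1, seed = 7)
  tab$f1 <- exp(4 * tab$f1)                 # heavy lognormal
  res <- univariate_filter(tab)
  expect_equal(res$test[1], "wilcox")
  tabn <- random_table(30, 30, p = 1, seed = 8)
  expect_equal(univariate_filter(tabn)$test[1], "t")
})

test_that("univariate type-I error is calibrated at alpha", {
  tab <- random_table(60, 60, p = 200, seed = 9)
  res <- univariate_filter(tab, alpha = 0.05)
  k <- sum(res$selected)
  # binomial 99% bounds around 200 x 0.05
  bounds <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("spearman filter keeps the more significant of a collinear pair", {
  tab <- random_table(25, 25, p = 2, seed = 10)
  tab$f2 <- 2 * tab$f1                      # rho = 1
  pv <- c(f1 = 0.001, f2 = 0.002)
  expect_equal(spearman_filter(tab, pv, 0.9), "f1")
  pv2 <- c(f1 = 0.02, f2 = 0.001)
  expect_equal(spearman_filter(tab, pv2, 0.9), "f2")
  expect_equal(spearman_filter(tab, pv, 1.0), c("f1", "f2"))
  # independent features all survive
  ind <- random_table(100, 100, p = 6, seed = 11)
  pvs <- setNames(runif(6, 0, 0.05), paste0("f", 1:6))
  expect_equal(spearman_filter(ind, pvs, 0.9), paste0("f", 1:6))
})

test_that("lasso path converges to the unpenalised fit as lambda -> 0", {
  tab <- random_table(60, 60, p = 3, seed = 12)
  tab$f1 <- tab$f1 + 1.0 * tab$label
  sel <- lasso_select(tab, n_folds = 10, seed = 12)
  expect_true("f1" %in% sel$selected)
  x <- as.matrix(tab[, paste0("f", 1:3)])
  unpen <- glm(tab$label ~ x, family = binomial())
  fit_small <- glmnet::glmnet(x, tab$label, family = "binomial",
                              lambda = min(sel$cv$lambda))
  expect_lt(max(abs(as.numeric(coef(fit_small)) - coef(unpen))), 1e-3)
  expect_error(lasso_select(tab[1:8, ], n_folds = 10), "fewer subjects")
})

test_that("the cascade records non-increasing stage counts and is
           deterministic", {
  tab <- random_table(30, 25, p = 40, seed = 13)
  tab$f1 <- tab$f1 + 2 * tab$label
  tab$f2 <- tab$f1 + rnorm(55, sd = 0.01)   # redundant copy
  sel <- run_selection(tab, seed = 13)
  expect_true(all(diff(sel$trace$counts) <= 0))
  expect_equal(sel$trace$counts[["initial"]], 40)
  expect_true(all(sel$trace$survivors$lasso %in%
                    sel$trace$survivors$correlation))
  expect_true(all(sel$trace$survivors$correlation %in%
                    sel$trace$survivors$univariate))
  sel2 <- run_selection(tab, seed = 13)
  expect_identical(sel$trace$counts, sel2$trace$counts)
  expect_identical(sel$train, sel2$train)
})

test_that("test subjects never influence the selection", {
  tab <- random_table(30, 25, p = 30, seed = 14)
  tab$f1 <- tab$f1 + 2 * tab$label
  sel <- run_selection(tab, seed = 14)
  # mutate the test rows' features wildly and re-run
  tab2 <- tab
  mut <- sel$split$test
  for (f in paste0("f", 1:30))
    tab2[[f]][mut] <- tab2[[f]][mut] * 3 + 7
  sel2 <- run_selection(tab2, seed = 14)
  expect_identical(sel$trace$counts, sel2$trace$counts)
  expect_identical(sel$trace$survivors, sel2$trace$survivors)
  expect_identical(sel$scaler, sel2$scaler)
  expect_identical(sel$trace$lasso_lambda, sel2$trace$lasso_lambda)
})
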