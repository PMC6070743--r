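# Three-stage feature selection with its preprocessing: abnormal-value
# imputation, stratified 70/30 split, train-anchored standardization,
# normality-routed univariate filtering, Spearman redundancy pruning, and
# L1-penalised logistic selection with stratified cross-validation.
#
# A feature table is a data.frame with columns subject_id, label (1 = case,
# 0 = control) and one numeric column per feature.

.feature_cols <- function(table) {
  setdiff(colnames(table), c("subject_id", "label"))
}

.check_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "label") %in% colnames(table)))
  if (!all(table$label %in% c(0, 1))) stop("labels must be 0/1")
  invisible(table)
}

#' Replace abnormal feature values by the column mean
#'
#' Per feature column, values that are non-finite or farther than
#' 3 x IQR from the column median are flagged abnormal and replaced by the
#' mean of the remaining values. Columns with fewer than two usable values
#' are an error.
#'
#' @param table feature table.
#' @param anchor optional anchor statistics from a previous call (the
#'   `anchor` attribute of an imputed training table); when given, the
#'   abnormality rule and replacement means are taken from the anchor
#'   rather than from `table` itself, so held-out subjects can be imputed
#'   without influencing any statistic.
#' @return the table with abnormal entries imputed; attribute `n_imputed`
#'   counts the replaced cells and `anchor` carries the per-column
#'   median/IQR/mean used.
#' @export
impute_abnormal <- function(table, anchor = NULL) {
  .check_table(table)
  if (is.null(anchor) && nrow(table) < 2) stop("need at least 2 subjects")
  n_imp <- 0L
  out_anchor <- list()
  for (f in .feature_cols(table)) {
    x <- table[[f]]
    fin <- is.finite(x)
    if (is.null(anchor)) {
      if (sum(fin) < 2) stop("column ", f, " has fewer than 2 finite values")
      med <- median(x[fin])
      iqr <- quantile(x[fin], 0.75, names = FALSE) -
             quantile(x[fin], 0.25, names = FALSE)
      bad <- !fin | abs(x - med) > 3 * iqr
      bad[is.na(bad)] <- TRUE
      if (all(bad)) stop("column ", f, " is entirely abnormal")
      repl <- mean(x[!bad])
    } else {
      a <- anchor[[f]]
      med <- a$median; iqr <- a$iqr; repl <- a$mean
      bad <- !fin | abs(x - med) > 3 * iqr
      bad[is.na(bad)] <- TRUE
    }
    if (any(bad)) {
      x[bad] <- repl
      table[[f]] <- x
      n_imp <- n_imp + sum(bad)
    }
    out_anchor[[f]] <- list(median = med, iqr = iqr, mean = repl)
  }
  attr(table, "n_imputed") <- n_imp
  attr(table, "anchor") <- if (is.null(anchor)) out_anchor else anchor
  table
}

#' Stratified train/test split
#'
#' Per class, a seeded uniform shuffle assigns the first
#' `floor(train_fraction x n_class)` subjects to the training partition and
#' the rest to testing. With the study's 78/44 class sizes and fraction 0.7
#' this yields a 54 + 30 training and 24 + 14 testing composition.
#'
#' @param labels 0/1 vector, one per subject.
#' @param train_fraction target training proportion (default 0.7).
#' @param seed RNG seed for the shuffle.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)))
  train <- integer(0)
  set.seed(seed)
  for (cl in c(1, 0)) {
    idx <- which(labels == cl)
    if (length(idx) < 2) stop("class ", cl, " has fewer than 2 subjects")
    n_tr <- floor(train_fraction * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stop("class ", cl, " too small to appear in both partitions")
    train <- c(train, sample(idx)[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = sort(setdiff(seq_along(labels), train)))
}

#' Train-anchored standardization
#'
#' Z-scores every feature column using the training partition's means and
#' SDs (n-1 denominator) and applies the identical transform to the test
#' partition. Zero-variance training columns are dropped from both tables
#' with a warning.
#'
#' @param train,test feature tables with identical feature columns.
#' @return list with `train`, `test`, and `scaler` (means/SDs used).
#' @export
standardize <- function(train, test) {
  .check_table(train)
  feats <- .feature_cols(train)
  mu <- vapply(feats, function(f) mean(train[[f]]), numeric(1))
  sg <- vapply(feats, function(f) sd(train[[f]]), numeric(1))
  drop <- sg == 0 | !is.finite(sg)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance training column(s)")
    keep <- feats[!drop]
    train <- train[, c("subject_id", "label", keep)]
    test <- test[, c("subject_id", "label", keep)]
    mu <- mu[!drop]; sg <- sg[!drop]
    feats <- keep
  }
  for (f in feats) {
    train[[f]] <- (train[[f]] - mu[[f]]) / sg[[f]]
    test[[f]] <- (test[[f]] - mu[[f]]) / sg[[f]]
  }
  list(train = train, test = test, scaler = list(mean = mu, sd = sg))
}

#' Normality-routed univariate filter
#'
#' Per feature: Shapiro-Wilk normality is tested in each class at the 0.05
#' level; if both classes look normal the feature is compared with a
#' two-sample t test (pooled or Welch per the variance gate), otherwise
#' with the Mann-Whitney rank-sum test (normal approximation with tie
#' correction). Features with p < `alpha` survive; the union of the two
#' routes forms the surviving set. Constant features get p = 1.
#'
#' @param train standardized training feature table.
#' @param alpha significance level (default 0.05).
#' @return data frame with `feature`, `test` ("t", "wilcox" or "constant"),
#'   `p`, `selected`, in catalogue order.
#' @export
univariate_filter <- function(train, alpha = 0.05) {
  .check_table(train)
  g1 <- train$label == 1
  g0 <- train$label == 0
  if (sum(g1) < 3 || sum(g0) < 3) stop("both classes need >= 3 subjects")
  feats <- .feature_cols(train)
  rows <- lapply(feats, function(f) {
    x1 <- train[[f]][g1]; x0 <- train[[f]][g0]
    if (sd(c(x1, x0)) == 0)
      return(data.frame(feature = f, test = "constant", p = 1))
    normal <- function(x) {
      if (sd(x) == 0) return(FALSE)
      shapiro.test(x)$p.value >= 0.05
    }
    if (normal(x1) && normal(x0)) {
      eq <- sd(x1) > 0 && sd(x0) > 0 &&
        variance_gate(group_summary(length(x1), mean(x1), sd(x1)),
                      group_summary(length(x0), mean(x0), sd(x0)))$choice ==
          "pooled"
      p <- t.test(x1, x0, var.equal = eq)$p.value
      data.frame(feature = f, test = "t", p = p)
    } else {
      p <- suppressWarnings(
        wilcox.test(x1, x0, exact = FALSE, correct = FALSE)$p.value)
      data.frame(feature = f, test = "wilcox", p = p)
    }
  })
  res <- do.call(rbind, rows)
  res$selected <- res$p < alpha
  res
}

#' Spearman redundancy filter
#'
#' Orders the surviving features by ascending univariate p (ties break to
#' catalogue order) and greedily keeps a feature iff its absolute Spearman
#' rank correlation with every already-kept feature does not exceed
#' `threshold`: of any highly correlated pair the more discriminative
#' member is retained.
#'
#' @param train standardized training feature table (restricted to the
#'   univariate survivors).
#' @param pvalues named numeric vector of univariate p-values for the
#'   features in `train`.
#' @param threshold absolute correlation cut-off (default 0.9).
#' @return character vector of surviving feature names, in catalogue order.
#' @export
spearman_filter <- function(train, pvalues, threshold = 0.9) {
  feats <- .feature_cols(train)
  stopifnot(all(feats %in% names(pvalues)))
  if (length(feats) < 2) return(feats)
  ord <- feats[order(pvalues[feats], seq_along(feats))]
  rho <- cor(as.matrix(train[, ord, drop = FALSE]), method = "spearman")
  kept <- character(0)
  for (f in ord) {
    if (length(kept) == 0 || all(abs(rho[f, kept]) <= threshold))
      kept <- c(kept, f)
  }
  feats[feats %in% kept]
}

# Stratified fold assignment: within each class, seeded shuffle then
# round-robin over folds.
.stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  foldid <- integer(length(labels))
  for (cl in c(1, 0)) {
    idx <- sample(which(labels == cl))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' L1-penalised logistic feature selection
#'
#' Fits a binomial LASSO path over a log-spaced grid of 100 penalties
#' spanning four decades below the smallest all-zero penalty, picks the
#' penalty minimising the mean 10-fold cross-validated deviance
#' (stratified, seeded folds), and returns the features with nonzero
#' coefficients there.
#'
#' @param train standardized training feature table.
#' @param n_folds cross-validation folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return list with `selected` (feature names, catalogue order),
#'   `lambda` (chosen penalty), `cv` (data frame lambda/mean/sd deviance),
#'   `path` (coefficient matrix, features x lambda), `fit` (the glmnet
#'   path object).
#' @export
lasso_select <- function(train, n_folds = 10L, seed = 1L) {
  .check_table(train)
  feats <- .feature_cols(train)
  if (length(feats) < 2) stop("need >= 2 candidate features")
  if (nrow(train) < n_folds) stop("fewer subjects than folds")
  x <- as.matrix(train[, feats, drop = FALSE])
  y <- train$label
  lmax <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", nlambda = 3)$lambda[1])
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
  foldid <- .stratified_folds(y, n_folds, seed)
  cvfit <- withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "binomial",
                      type.measure = "deviance",
                      lambda = grid, foldid = foldid),
    warning = function(w) {
      # routine small-cohort advisories from the CV engine
      # the 4-decade grid intentionally reaches the overfit regime, where
      # the path solver may stop early and return the converged prefix
      if (grepl("dangerous ground|grouped=FALSE enforced|lambda value not reached",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  lam <- cvfit$lambda.min
  beta <- coef(cvfit$glmnet.fit, s = lam)[-1, 1]
  selected <- feats[feats %in% names(beta)[beta != 0]]
  list(
    selected = selected,
    lambda = lam,
    cv = data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                    cvsd = cvfit$cvsd),
    path = as.matrix(cvfit$glmnet.fit$beta),
    fit = cvfit$glmnet.fit
  )
}

#' Run the full selection cascade
#'
#' stratified split -> train-anchored abnormal-value imputation ->
#' train-anchored standardization -> univariate filter -> Spearman
#' redundancy filter -> LASSO, recording the surviving-feature count at
#' every stage. All anchoring statistics (imputation medians/IQRs/means,
#' scaler means/SDs) come from the training partition only, so test
#' subjects never influence any selection statistic.
#'
#' @param table full feature table (all subjects).
#' @param train_fraction training proportion (default 0.7).
#' @param alpha univariate significance level (default 0.05).
#' @param spearman_threshold redundancy cut-off (default 0.9).
#' @param n_folds LASSO cross-validation folds (default 10).
#' @param seed RNG seed (split and folds).
#' @return list with `trace` (stage counts and surviving names, the chosen
#'   lambda and CV path), `train`, `test` (standardized tables restricted
#'   to the selected features), and `split`.
#' @export
run_selection <- function(table, train_fraction = 0.7, alpha = 0.05,
                          spearman_threshold = 0.9, n_folds = 10L,
                          seed = 1L) {
  .check_table(table)
  split <- stratified_split(table$label, train_fraction, seed)
  tr <- impute_abnormal(table[split$train, , drop = FALSE])
  te <- impute_abnormal(table[split$test, , drop = FALSE],
                        anchor = attr(tr, "anchor"))
  std <- standardize(tr, te)
  n0 <- length(.feature_cols(std$train))
  uni <- univariate_filter(std$train, alpha)
  surv1 <- uni$feature[uni$selected]
  pvals <- setNames(uni$p, uni$feature)
  keep_cols <- function(tab, feats) tab[, c("subject_id", "label", feats),
                                        drop = FALSE]
  surv2 <- if (length(surv1) >= 2) {
    spearman_filter(keep_cols(std$train, surv1), pvals, spearman_threshold)
  } else surv1
  if (length(surv2) >= 2) {
    las <- lasso_select(keep_cols(std$train, surv2), n_folds, seed)
    surv3 <- las$selected
  } else {
    las <- list(lambda = NA_real_, cv = NULL, path = NULL)
    surv3 <- surv2
  }
  trace <- list(
    counts = c(initial = n0, after_univariate = length(surv1),
               after_correlation = length(surv2),
               after_lasso = length(surv3)),
    survivors = list(univariate = surv1, correlation = surv2,
                     lasso = surv3),
    univariate = uni,
    lasso_lambda = las$lambda,
    lasso_cv = las$cv,
    lasso_path = las$path
  )
  list(trace = trace,
       train = keep_cols(std$train, surv3),
       test = keep_cols(std$test, surv3),
       split = split,
       scaler = std$scaler)
}
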