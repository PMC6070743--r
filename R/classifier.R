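# Logistic diagnostic model, radiomics scores, ROC/AUC and the
# confusion-matrix metric panel.

#' Fit the logistic diagnostic model
#'
#' Unpenalised maximum-likelihood logistic regression of the binary label
#' on the selected (standardized) features. If the fit shows complete or
#' quasi-complete separation (fitted probabilities numerically 0/1 or
#' non-convergence), the model falls back to a lightly ridge-penalised fit
#' and raises the `separation` flag.
#'
#' @param train feature table restricted to the selected features.
#' @param ridge_lambda penalty used only by the separation fallback.
#' @return a `cc_logistic` model: `intercept`, `coefficients` (named),
#'   `converged`, `separation`.
#' @export
fit_logistic <- function(train, ridge_lambda = 1e-4) {
  .check_table(train)
  feats <- .feature_cols(train)
  if (sum(train$label == 1) < 2 || sum(train$label == 0) < 2)
    stop("need >= 2 subjects per class")
  df <- train[, c("label", feats), drop = FALSE]
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(label ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  b[is.na(b)] <- 0   # aliased or constant columns carry no weight
  separated <- sep_warn || !fit$converged || any(!is.finite(b))
  if (separated && length(feats) >= 1) {
    x <- as.matrix(train[, feats, drop = FALSE])
    if (ncol(x) == 1) x <- cbind(x, 0)   # glmnet needs >= 2 columns
    rfit <- glmnet::glmnet(x, train$label, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
    b <- as.numeric(coef(rfit))
    co <- setNames(b[seq_along(feats) + 1L], feats)
    return(structure(list(intercept = b[1], coefficients = co,
                          converged = TRUE, separation = TRUE),
                     class = "cc_logistic"))
  }
  structure(list(intercept = unname(b[1]),
                 coefficients = setNames(unname(b[-1]), feats),
                 converged = fit$converged, separation = separated),
            class = "cc_logistic")
}

#' Per-subject radiomics score
#'
#' The model's linear predictor: intercept + sum of coefficient x feature
#' value. The sigmoid of the score is the predicted case probability;
#' score 0 corresponds to probability 0.5.
#'
#' @param model a `cc_logistic`.
#' @param table feature table containing the model's feature columns.
#' @return numeric vector of scores, one per subject.
#' @export
radiomics_score <- function(model, table) {
  feats <- names(model$coefficients)
  missing <- setdiff(feats, colnames(table))
  if (length(missing) > 0)
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  if (length(feats) == 0) return(rep(model$intercept, nrow(table)))
  x <- as.matrix(table[, feats, drop = FALSE])
  as.numeric(model$intercept + x %*% model$coefficients)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' ROC curve and AUC
#'
#' AUC via the Mann-Whitney identity (ties between a case and a control
#' score count 1/2); ROC points are generated from every distinct score
#' threshold.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels 0/1 labels.
#' @return list with `auc` and `roc` (data frame threshold/fpr/tpr).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present")
  cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  auc <- mean(cmp)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  roc <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(pos >= t), numeric(1))
  )
  list(auc = auc, roc = roc)
}

# Half-up rounding (R's round() is round-half-even); used only for the
# reported 3-decimal panel.
.round_half_up <- function(x, digits = 3) floor(x * 10^digits + 0.5) / 10^digits

#' Confusion-matrix metric panel
#'
#' Sensitivity, specificity, accuracy, precision (= PPV) and NPV from the
#' four confusion counts; reported values are additionally given rounded
#' half-up to 3 decimals. A zero denominator flags the affected metric as
#' undefined (NA) rather than silently reporting 0.
#'
#' @param TP,FP,TN,FN confusion counts at the classification threshold.
#' @return list with `counts`, `metrics` (exact), `reported` (3 dp).
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FN >= 1, TN + FP >= 1)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  m <- c(
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    accuracy = (TP + TN) / (TP + FP + TN + FN),
    precision = ratio(TP, TP + FP),
    ppv = ratio(TP, TP + FP),
    npv = ratio(TN, TN + FN)
  )
  list(counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
       metrics = m,
       reported = .round_half_up(m, 3))
}

#' Evaluate the diagnostic model on a partition
#'
#' Scores every subject, classifies at predicted probability >= `threshold`
#' (ties at the threshold count as positive), and assembles the full
#' evaluation report: confusion counts, the metric panel, ROC points, AUC
#' and per-subject radiomics scores.
#'
#' @param model a `cc_logistic`.
#' @param table feature table of the partition to evaluate.
#' @param threshold probability cut-off (default 0.5).
#' @return an `eval_report` list.
#' @export
evaluate <- function(model, table, threshold = 0.5) {
  .check_table(table)
  scores <- radiomics_score(model, table)
  probs <- .sigmoid(scores)
  pred <- as.integer(probs >= threshold)
  lab <- table$label
  TP <- sum(pred == 1 & lab == 1); FP <- sum(pred == 1 & lab == 0)
  TN <- sum(pred == 0 & lab == 0); FN <- sum(pred == 0 & lab == 1)
  cm <- confusion_metrics(TP, FP, TN, FN)
  ra <- roc_auc(scores, lab)
  structure(
    list(counts = cm$counts,
         metrics = c(auc = ra$auc, cm$metrics),
         reported = .round_half_up(c(auc = ra$auc, cm$metrics), 3),
         roc = ra$roc,
         scores = data.frame(subject_id = table$subject_id, label = lab,
                             score = scores, probability = probs,
                             predicted = pred)),
    class = "eval_report"
  )
}
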