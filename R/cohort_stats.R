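# Group-comparison statistics computable from published summary data:
# pooled and Welch two-sample t statistics with a variance-equality gate,
# and the uncorrected Pearson chi-square for a 2x2 sex table.

#' Group summary (n, mean, SD)
#'
#' @param n subject count (>= 2).
#' @param mean variable mean.
#' @param sd variable standard deviation (>= 0).
#' @return a `group_summary` list.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Pooled-variance two-sample t statistic from summaries
#'
#' Student's t assuming equal variances, in the (b - a) sign convention:
#' with a = patients and b = controls the statistic is negative when
#' patients score higher.
#'
#' @param a,b `group_summary` objects.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
pooled_t <- function(a, b) {
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = a$n + b$n - 2, p = 1))
    stop("zero pooled variance with unequal means")
  }
  t <- (b$mean - a$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  df <- a$n + b$n - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Welch two-sample t statistic from summaries
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, same
#' (b - a) sign convention as [pooled_t()].
#'
#' @param a,b `group_summary` objects.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) stop("both groups have zero variance")
  t <- (b$mean - a$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Variance-equality gate between pooled and Welch t
#'
#' Two-sided F test on the larger-to-smaller variance ratio with
#' (n - 1, n - 1) degrees of freedom; a significant ratio routes to the
#' Welch statistic, otherwise to the pooled one.
#'
#' @param a,b `group_summary` objects with positive SDs.
#' @param alpha significance level of the gate (default 0.05).
#' @return list with `choice` ("pooled" or "welch"), `F`, `p`.
#' @export
variance_gate <- function(a, b, alpha = 0.05) {
  if (a$sd <= 0 || b$sd <= 0) stop("variance gate needs positive SDs")
  if (a$sd^2 >= b$sd^2) {
    Fstat <- a$sd^2 / b$sd^2; df1 <- a$n - 1; df2 <- b$n - 1
  } else {
    Fstat <- b$sd^2 / a$sd^2; df1 <- b$n - 1; df2 <- a$n - 1
  }
  p <- 2 * pf(Fstat, df1, df2, lower.tail = FALSE)
  p <- min(p, 1)
  list(choice = if (p < alpha) "welch" else "pooled", F = Fstat, p = p)
}

#' Gated two-sample t statistic from summaries
#'
#' Applies [variance_gate()] and then the chosen statistic.
#'
#' @inheritParams variance_gate
#' @return list with `t`, `df`, `p`, `variant`.
#' @export
gated_t <- function(a, b, alpha = 0.05) {
  g <- variance_gate(a, b, alpha)
  res <- if (g$choice == "welch") welch_t(a, b) else pooled_t(a, b)
  res$variant <- g$choice
  res
}

#' Uncorrected Pearson chi-square for a 2x2 table
#'
#' Sum of (O - E)^2 / E over the four cells with expectations from the
#' marginals; no Yates continuity correction.
#'
#' @param counts 2x2 matrix (or coercible) of non-negative integer counts.
#' @return list with `chi2`, `df` (= 1), `p`.
#' @export
pearson_chi2 <- function(counts) {
  m <- matrix(as.numeric(counts), 2, 2)
  if (any(m < 0)) stop("counts must be non-negative")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in 2x2 table")
  E <- outer(rs, cs) / n
  chi2 <- sum((m - E)^2 / E)
  list(chi2 = chi2, df = 1, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Group-comparison table from a summaries data frame
#'
#' Convenience wrapper reproducing a demographics table: one gated t row
#' per continuous variable and one chi-square row per 2x2 count variable.
#'
#' @param summaries data frame with columns `variable`, `n_a`, `mean_a`,
#'   `sd_a`, `n_b`, `mean_b`, `sd_b`.
#' @param alpha gate significance level.
#' @return data frame with `variable`, `statistic`, `variant`, `p`.
#' @export
cohort_comparison <- function(summaries, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    r <- summaries[i, ]
    a <- group_summary(r$n_a, r$mean_a, r$sd_a)
    b <- group_summary(r$n_b, r$mean_b, r$sd_b)
    res <- gated_t(a, b, alpha)
    data.frame(variable = r$variable, statistic = res$t,
               variant = res$variant, p = res$p)
  })
  do.call(rbind, rows)
}
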