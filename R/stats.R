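stat_result <- function(name, estimate, test_stat, df, p, q = NA_real_) {
  data.frame(name = name, estimate = estimate, test_stat = test_stat,
             df = df, p = p, q = q, stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample t test
#'
#' Student (equal-variance) form with `df = n_A + n_B - 2`, matching the
#' df arithmetic of a 37 + 26 two-group comparison (df = 61). Estimate is
#' `mean(x) - mean(y)`; two-sided p.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param name Label for the result row.
#' @return One-row data.frame: `name, estimate, test_stat, df, p, q`.
#' @export
two_sample_t <- function(x, y, name = "t") {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  tt <- t.test(x, y, var.equal = TRUE)
  stat_result(name, mean(x) - mean(y), unname(tt$statistic),
              unname(tt$parameter), tt$p.value)
}

#' Covariate-adjusted group effect (ANCOVA)
#'
#' OLS of `outcome ~ group + covariates`; reports the group effect as the
#' mean of the first factor level minus the second (so a covariate-free
#' call reproduces [two_sample_t()] exactly), its t and two-sided p.
#'
#' @param outcome Numeric outcome.
#' @param group Two-level factor (or coercible).
#' @param covariates Optional data.frame of covariates (numeric or factor;
#'   factors enter treatment-coded).
#' @param name Label for the result row.
#' @return One-row StatResult data.frame.
#' @export
ancova_group_effect <- function(outcome, group, covariates = NULL,
                                name = "group") {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  dat <- data.frame(.y = outcome, .g = group)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  row <- grep("^\\.g", rownames(sm))
  if (length(row) != 1) stop("rank-deficient design: group effect inestimable")
  # lm reports level2 - level1; flip to level1 - level2.
  stat_result(name, -sm[row, 1], -sm[row, 3], fit$df.residual, sm[row, 4])
}

#' Simple/multiple linear regression slope
#'
#' OLS of `y` on `x` (plus optional covariates); reports the slope `b` of
#' `x`, its t, residual df and two-sided p. With n = 36 ADHD subjects and a
#' simple regression this yields df = 34.
#'
#' @param y Outcome (e.g. percent symptom change).
#' @param x Predictor (e.g. a graph-metric AUC).
#' @param covariates Optional data.frame.
#' @param name Label.
#' @return One-row StatResult data.frame.
#' @export
linear_regression <- function(y, x, covariates = NULL, name = "slope") {
  if (sd(x) == 0) stop("constant predictor")
  dat <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  if (nrow(dat) < 3 + (ncol(dat) - 2)) stop("too few observations")
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  stat_result(name, sm[".x", 1], sm[".x", 3], fit$df.residual, sm[".x", 4])
}

#' Correlation with t-based p value
#'
#' Pearson by default (the paper-era convention for graph-symptom
#' associations); Spearman available.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @param name Label.
#' @return One-row StatResult data.frame (`estimate` is r).
#' @export
pearson_correlation <- function(x, y, method = c("pearson", "spearman"),
                                name = "r") {
  method <- match.arg(method)
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  stat_result(name, unname(ct$estimate),
              if (method == "pearson") unname(ct$statistic) else NA_real_,
              if (method == "pearson") unname(ct$parameter) else length(x) - 2,
              ct$p.value)
}

#' Benjamini-Hochberg step-up q values
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1, returned in input
#' order. `m` may exceed the number of observed p values (a declared family
#' size); it can never be smaller.
#'
#' @param pvals Numeric p values in \[0, 1\].
#' @param m Family size (default `length(pvals)`).
#' @return q values, same order as `pvals`.
#' @export
bh_fdr <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  if (m < length(pvals)) stop("family size m must be >= length(pvals)")
  n <- length(pvals)
  o <- order(pvals)
  q_sorted <- rev(cummin(rev(pvals[o] * m / seq_len(n))))
  pmin(1, q_sorted)[order(o)]
}

#' No-information rate
#'
#' Accuracy of always predicting the majority class, as a percentage:
#' `100 * max(counts) / sum(counts)`. For a 37/26 split this is 58.7%.
#'
#' @param group_counts Non-negative integer counts per class (>= 2 classes).
#' @return Percentage.
#' @export
nir <- function(group_counts) {
  if (length(group_counts) < 2 || any(group_counts < 0) ||
      sum(group_counts) == 0)
    stop("need >= 2 non-negative counts with positive sum")
  100 * max(group_counts) / sum(group_counts)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact two-sided interval, returned in percent.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @return `c(lower, upper)` in percent.
#' @examples
#' round(clopper_pearson_ci(48, 63), 1)  # 63.8 86.0
#' @export
clopper_pearson_ci <- function(successes, n, level = 0.95) {
  if (n <= 0 || successes < 0 || successes > n) stop("invalid counts")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a, successes + 1, n - successes)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' One-sided exact binomial test against the no-information rate
#'
#' Upper-tail probability `P(X >= successes | n, p0)` under the binomial
#' null that the classifier guesses at the NIR `p0`.
#'
#' @param successes,n Counts.
#' @param p0 Null proportion in (0, 1).
#' @return p value.
#' @export
binomial_test_vs_nir <- function(successes, n, p0) {
  if (n <= 0 || successes < 0 || successes > n) stop("invalid counts")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  pbinom(successes - 1, n, p0, lower.tail = FALSE)
}

#' Classification accuracy statistics
#'
#' The full Table-1-style statistic set from held-out predictions: accuracy
#' with its exact binomial CI, NIR with the one-sided binomial p against it,
#' and sensitivity/specificity/PPV/NPV from the 2x2 table.
#'
#' @param predicted,actual Equal-length label vectors (two classes).
#' @param positive The positive class label.
#' @return An `accuracy_stats` list.
#' @export
confusion_stats <- function(predicted, actual, positive) {
  predicted <- as.character(predicted); actual <- as.character(actual)
  if (length(predicted) != length(actual)) stop("length mismatch")
  classes <- unique(c(actual, predicted))
  if (length(classes) > 2) stop("more than 2 classes")
  if (!positive %in% classes) stop("positive class absent")
  tp <- sum(predicted == positive & actual == positive)
  fn <- sum(predicted != positive & actual == positive)
  fp <- sum(predicted == positive & actual != positive)
  tn <- sum(predicted != positive & actual != positive)
  n <- length(actual)
  n_correct <- tp + tn
  counts <- table(actual)
  nir_pct <- nir(as.integer(counts))
  structure(list(
    n_correct = n_correct, n_total = n,
    accuracy_pct = 100 * n_correct / n,
    ci95_pct = clopper_pearson_ci(n_correct, n),
    nir_pct = nir_pct,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    p_vs_nir = binomial_test_vs_nir(n_correct, n, nir_pct / 100),
    table = c(TP = tp, FN = fn, FP = fp, TN = tn)),
    class = "accuracy_stats")
}

#' @export
print.accuracy_stats <- function(x, ...) {
  cat(sprintf(
    "Accuracy %.1f%% (%d/%d), CI95 (%.1f, %.1f), NIR %.1f%%, p vs NIR %.4g\n",
    x$accuracy_pct, x$n_correct, x$n_total, x$ci95_pct[1], x$ci95_pct[2],
    x$nir_pct, x$p_vs_nir))
  cat(sprintf("Sens %.3f  Spec %.3f  PPV %.3f  NPV %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Percent symptom change (negative = improvement)
#'
#' @param w0 Baseline score(s), > 0.
#' @param w6 Post-treatment score(s).
#' @return `100 * (w6 - w0) / w0`.
#' @export
percent_change <- function(w0, w6) {
  if (any(w0 <= 0)) stop("baseline score must be > 0")
  100 * (w6 - w0) / w0
}

#' Treatment responder rule
#'
#' Responder iff symptom reduction exceeds 25%, i.e. percent change is
#' strictly below -25 (a change of exactly -25% is a non-responder).
#'
#' @param pct_change Percent change value(s).
#' @return Logical.
#' @export
responder_flag <- function(pct_change) {
  if (any(!is.finite(pct_change))) stop("non-finite percent change")
  pct_change < -25
}
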