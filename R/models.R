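#' Default SVM cost grid
#'
#' Powers of 2 from 2^-10 to 2^5 plus 0.218 and 10.9 (the selected costs
#' reported for the reference models, so they are always reachable).
#'
#' @return Sorted numeric vector of candidate costs.
#' @export
default_c_grid <- function() sort(unique(c(2 ^ seq(-10, 5), 0.218, 10.9)))

# Treatment-coded numeric encoding of a covariate data.frame (factors and
# logicals become dummies; the spec'd covariate sets keep this to one column
# per covariate for the bundled cohort).
encode_covariates <- function(df) {
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      out <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else if (is.logical(v)) {
      out <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- droplevels(as.factor(v))
      if (nlevels(f) < 2) {
        # degenerate in this subsample: constant column keeps the contract
        out <- matrix(0, length(v), 1, dimnames = list(NULL, nm))
      } else {
        mm <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, "_", levels(f)[-1])
        out <- mm
      }
    }
    out
  })
  do.call(cbind, cols)
}

#' Assemble an SVM feature table
#'
#' Builds the subjects x features matrix of the 82 `leff_<region>_auc`
#' local-efficiency features (plus task-appropriate covariates when
#' requested) and the task outcome:
#' * `diagnosis` — all subjects; outcome is the ADHD/TDC label; covariates
#'   are age and gender only (dose and medication history do not exist for
#'   controls).
#' * `response` — ADHD subjects with week-6 scores; outcome is percent
#'   change in total symptom score; covariates are age, gender, dose,
#'   subtype, prior stimulant use and its duration.
#' * `severity` — ADHD subjects; outcome is the baseline total score.
#'
#' Values are stored raw; standardization happens inside each LOOCV
#' training fold only.
#'
#' @param metrics Metric table from [compute_cohort_metrics()].
#' @param cohort A `cohort_table`.
#' @param task `"diagnosis"`, `"response"` or `"severity"`.
#' @param include_covariates Append covariate columns (default FALSE).
#' @return A `feature_table`: list with `subject_ids`, `feature_names`,
#'   `x`, `outcome`, `task`.
#' @export
assemble_features <- function(metrics, cohort,
                              task = c("diagnosis", "response", "severity"),
                              include_covariates = FALSE) {
  task <- match.arg(task)
  subj <- cohort$subjects
  keep <- switch(task,
    diagnosis = rep(TRUE, nrow(subj)),
    response = subj$group == "ADHD" & subj$has_week6,
    severity = subj$group == "ADHD")
  subj <- subj[keep, , drop = FALSE]
  if (nrow(subj) == 0) stop("no subjects available for task ", task)
  mrow <- match(subj$subject_id, metrics$subject_id)
  if (any(is.na(mrow)))
    stop("missing metrics for subject(s): ",
         paste(subj$subject_id[is.na(mrow)], collapse = ", "))
  leff_cols <- grep("^leff_.*_auc$", names(metrics), value = TRUE)
  x <- as.matrix(metrics[mrow, leff_cols, drop = FALSE])
  rownames(x) <- subj$subject_id
  if (include_covariates) {
    cov_df <- if (task == "diagnosis") {
      subj[, c("age", "gender")]
    } else {
      subj[, c("age", "gender", "mph_dose_mg_per_kg", "adhd_subtype",
               "prior_stimulant_6mo", "prior_stimulant_duration")]
    }
    if (anyNA(cov_df))
      stop("covariate undefined for some subject in task ", task)
    x <- cbind(x, encode_covariates(cov_df))
  }
  if (anyNA(x)) stop("missing values in feature table")
  outcome <- switch(task,
    diagnosis = factor(subj$group, levels = c("ADHD", "TDC")),
    response = percent_change(subj$adhdrs_total_w0, subj$adhdrs_total_w6),
    severity = as.numeric(subj$adhdrs_total_w0))
  structure(list(subject_ids = subj$subject_id,
                 feature_names = colnames(x),
                 x = x, outcome = outcome, task = task),
            class = "feature_table")
}

fold_standardize <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = scale(xtr, center = mu, scale = sdv),
       test = scale(xte, center = mu, scale = sdv))
}

# Full LOOCV over every candidate cost in one pass: folds outer,
# warm-started ascending cost path inner (the dual solution at one cost
# seeds the next, so the whole grid costs little more than one fit).
# Standardization happens inside each training fold only (no leakage).
# Returns an n x nC prediction matrix.
loocv_predictions_all_C <- function(x, y, C_grid, epsilon, tol) {
  n <- nrow(x)
  is_class <- is.factor(y)
  pred <- matrix(if (is_class) NA_character_ else NA_real_, n,
                 length(C_grid))
  for (i in seq_len(n)) {
    std <- fold_standardize(x[-i, , drop = FALSE], x[i, , drop = FALSE])
    xa <- cbind(std$train, 1)
    Wm <- if (is_class) {
      ynum <- ifelse(y[-i] == levels(y)[1], 1, -1)
      cpp_svc_path(xa, ynum, C_grid, tol, 20000L)
    } else {
      cpp_svr_path(xa, as.numeric(y[-i]), C_grid, epsilon, tol, 20000L)
    }
    dec <- drop(Wm %*% c(std$test[1, ], 1))
    pred[i, ] <- if (is_class) {
      ifelse(dec >= 0, levels(y)[1], levels(y)[2])
    } else dec
  }
  pred
}

loocv_metric <- function(preds, y, tuning_metric) {
  if (is.factor(y)) {
    if (tuning_metric == "rmse") {
      # Paper-literal reading: RMSE on a +/-1 class coding.
      code <- function(v) ifelse(v == levels(y)[1], 1, -1)
      sqrt(mean((code(preds) - code(y)) ^ 2))
    } else {
      mean(preds == y)
    }
  } else {
    sqrt(mean((preds - y) ^ 2))
  }
}

#' Leave-one-out cross-validated SVM evaluation with cost tuning
#'
#' For every candidate cost, runs a full LOOCV (standardization and fitting
#' inside each training fold) and scores the held-out predictions; selects
#' the cost maximizing accuracy (classification) or minimizing RMSE
#' (regression), breaking ties toward the smallest cost. Tuning and
#' evaluation share this single resampling loop, mirroring the reference
#' procedure; `tuning_metric = "rmse"` applies the RMSE rule to
#' classification too (on a +/-1 coding), the paper-literal reading.
#'
#' @param table A `feature_table`.
#' @param C_grid Candidate costs (default [default_c_grid()]).
#' @param tuning_metric `"auto"` (task-appropriate; default), `"accuracy"`,
#'   or `"rmse"`.
#' @param epsilon SVR insensitivity (default 0.1).
#' @param tol Solver tolerance.
#' @param compute_importance Attach ranked variable importance
#'   (default TRUE).
#' @return A `model_evaluation`: tuned cost, per-subject held-out
#'   predictions, `accuracy_stats` (classification) or `obs_pred`
#'   (r, p, RMSE; regression), importance table, `permutation_p` (NA until
#'   [permutation_test()] is run).
#' @export
loocv_evaluate <- function(table, C_grid = default_c_grid(),
                           tuning_metric = c("auto", "accuracy", "rmse"),
                           epsilon = 0.1, tol = 1e-6,
                           compute_importance = TRUE) {
  tuning_metric <- match.arg(tuning_metric)
  x <- table$x; y <- table$outcome
  if (nrow(x) < 5) stop("need n >= 5 for LOOCV evaluation")
  is_class <- is.factor(y)
  tm <- if (tuning_metric == "auto") {
    if (is_class) "accuracy" else "rmse"
  } else tuning_metric
  C_grid <- sort(C_grid)
  pred_mat <- loocv_predictions_all_C(x, y, C_grid, epsilon, tol)
  preds_by_C <- lapply(seq_along(C_grid), function(ci) {
    if (is_class) factor(pred_mat[, ci], levels = levels(y))
    else as.numeric(pred_mat[, ci])
  })
  scores <- vapply(preds_by_C, loocv_metric, numeric(1), y = y,
                   tuning_metric = tm)
  best <- if (is_class && tm == "accuracy") which.max(scores)
          else which.min(scores)
  preds <- preds_by_C[[best]]
  out <- list(task = if (is_class) "classification" else "regression",
              tuned_cost = C_grid[best],
              tuning_metric = tm,
              tuning_trace = data.frame(C = C_grid, score = scores),
              loocv_predictions = data.frame(
                subject_id = table$subject_ids,
                observed = if (is_class) as.character(y) else y,
                predicted = if (is_class) as.character(preds) else preds,
                stringsAsFactors = FALSE),
              permutation_p = NA_real_)
  if (is_class) {
    out$accuracy_stats <- confusion_stats(preds, y, positive = levels(y)[1])
    out$statistic <- out$accuracy_stats$accuracy_pct / 100
  } else {
    ct <- if (sd(preds) > 0) pearson_correlation(y, preds, name = "obs_pred")
          else stat_result("obs_pred", NA_real_, NA_real_, NA, NA_real_)
    out$obs_pred <- list(r = ct$estimate, p = ct$p,
                         rmse = sqrt(mean((preds - y) ^ 2)))
    out$statistic <- ct$estimate
  }
  if (compute_importance) {
    out$importance <- if (is_class) importance_classification(table)
                      else importance_regression(table)
  }
  structure(out, class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat("<model_evaluation>", x$task, "| tuned C =", x$tuned_cost, "\n")
  if (x$task == "classification") print(x$accuracy_stats)
  else cat(sprintf("obs-pred r = %.3f (p = %.4g), RMSE = %.2f\n",
                   x$obs_pred$r, x$obs_pred$p, x$obs_pred$rmse))
  if (!is.na(x$permutation_p))
    cat("permutation p =", format(x$permutation_p), "\n")
  invisible(x)
}

#' Permutation test of an SVM evaluation
#'
#' Permutes the outcome `B` times under a fixed seed, reruns the full
#' tuning + LOOCV pipeline on each permuted outcome, and reports
#' `p = (1 + #\{permuted >= observed\}) / (B + 1)` where the statistic is
#' LOOCV accuracy (classification) or the observed-predicted correlation
#' (regression; degenerate constant predictions count as -Inf).
#'
#' @param table A `feature_table`.
#' @param B Number of permutations (default 1000; scaled runs use less).
#' @param seed RNG seed for the permutation stream.
#' @inheritParams loocv_evaluate
#' @param observed Optional precomputed `model_evaluation` to reuse.
#' @return List: `p`, `observed` statistic, `permuted` statistics vector.
#' @export
permutation_test <- function(table, B = 1000, seed = 1,
                             C_grid = default_c_grid(),
                             tuning_metric = "auto", epsilon = 0.1,
                             tol = 1e-6, observed = NULL) {
  if (B < 1) stop("B must be >= 1")
  if (is.null(observed))
    observed <- loocv_evaluate(table, C_grid, tuning_metric, epsilon, tol,
                               compute_importance = FALSE)
  obs_stat <- observed$statistic
  set.seed(seed)
  perm <- numeric(B)
  for (b in seq_len(B)) {
    tb <- table
    tb$outcome <- sample(table$outcome)
    ev <- loocv_evaluate(tb, C_grid, tuning_metric, epsilon, tol,
                         compute_importance = FALSE)
    perm[b] <- ev$statistic
  }
  perm[is.na(perm)] <- -Inf
  p <- (1 + sum(perm >= obs_stat - 1e-12)) / (B + 1)
  list(p = p, observed = obs_stat, permuted = perm)
}

#' ROC-based variable importance (classification)
#'
#' Treats each feature as a univariate score and computes the ROC AUC via
#' the rank-sum (Mann-Whitney) identity, tie-aware; reports
#' `max(AUC, 1 - AUC)` with the direction (which class has higher values)
#' retained, sorted descending.
#'
#' @param table A classification `feature_table`.
#' @return data.frame: `feature`, `score`, `auc_positive` (AUC for the
#'   positive/first class), `higher_in`.
#' @export
importance_classification <- function(table) {
  y <- table$outcome
  if (!is.factor(y) || nlevels(y) != 2) stop("need a two-class outcome")
  pos <- y == levels(y)[1]
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop("single class")
  aucs <- apply(table$x, 2, function(f) {
    r <- rank(f)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
  out <- data.frame(feature = colnames(table$x),
                    score = pmax(aucs, 1 - aucs),
                    auc_positive = aucs,
                    higher_in = ifelse(aucs >= 0.5, levels(y)[1],
                                       levels(y)[2]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Loess-r2 variable importance (regression)
#'
#' Fits a local polynomial smoother (span 0.75, degree 2) of the outcome on
#' each feature and scores `1 - RSS_smooth / RSS_intercept-only`, floored
#' at 0; constant features score 0 and are flagged. Sorted descending.
#'
#' @param table A regression `feature_table`.
#' @return data.frame: `feature`, `score`, `direction` (sign of the linear
#'   association), `constant` flag.
#' @export
importance_regression <- function(table) {
  y <- table$outcome
  if (is.factor(y)) stop("need a numeric outcome")
  if (length(y) < 10) stop("need n >= 10 per smoother fit")
  rss0 <- sum((y - mean(y)) ^ 2)
  res <- lapply(seq_len(ncol(table$x)), function(j) {
    f <- table$x[, j]
    if (sd(f) == 0)
      return(list(score = 0, dir = 0, constant = TRUE))
    fit <- tryCatch(
      suppressWarnings(loess(y ~ f, span = 0.75, degree = 2,
                             family = "gaussian")),
      error = function(e) NULL)
    score <- if (is.null(fit)) 0
             else max(0, 1 - sum(residuals(fit) ^ 2) / rss0)
    list(score = score, dir = sign(stats::cov(f, y)), constant = FALSE)
  })
  out <- data.frame(feature = colnames(table$x),
                    score = vapply(res, `[[`, numeric(1), "score"),
                    direction = vapply(res, `[[`, numeric(1), "dir"),
                    constant = vapply(res, `[[`, logical(1), "constant"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Top-k regions of a ranked importance table
#'
#' Maps `leff_<region>_auc` features back to atlas regions and reports the
#' top k with hemisphere, network label and effect direction, plus a
#' network census (fraction of the top k per network).
#'
#' @param importance Output of an importance function.
#' @param atlas A `parcellation_atlas`.
#' @param k Number of top features (default 10).
#' @return List: `top` (data.frame) and `census` (named fractions).
#' @export
summarize_top_regions <- function(importance, atlas, k = 10) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(importance)) stop("k exceeds number of features")
  top <- importance[seq_len(k), , drop = FALSE]
  region <- sub("^leff_(.*)_auc$", "\\1", top$feature)
  region[!grepl("^leff_.*_auc$", top$feature)] <- NA
  idx <- match(region, atlas$name)
  top$region <- region
  top$hemisphere <- atlas$hemisphere[idx]
  top$network <- atlas$network[idx]
  if ("higher_in" %in% names(top)) {
    top$direction_label <- paste("higher in", top$higher_in)
  } else if ("direction" %in% names(top)) {
    top$direction_label <- ifelse(top$direction < 0,
                                  "higher value, better response",
                                  "higher value, worse response")
  }
  census <- table(factor(top$network, levels = NETWORK_LABELS)) / k
  list(top = top, census = census)
}
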