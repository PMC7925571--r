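# A full-size (82-region) but small-n cohort for feature-assembly contracts.
cohort82 <- NULL
get_cohort82 <- function() {
  if (is.null(cohort82)) {
    sim <- simulate_cohort(simulation_config(n_adhd = 7, n_tdc = 5,
                                             seed = 77))
    met <- compute_cohort_metrics(sim$cohort,
                                  thresholds = seq(0.1, 0.3, by = 0.05))
    cohort82 <<- list(sim = sim, met = met)
  }
  cohort82
}

test_that("assemble_features builds the contracted column sets", {
  cs <- get_cohort82()
  ft0 <- assemble_features(cs$met, cs$sim$cohort, "diagnosis", FALSE)
  expect_equal(ncol(ft0$x), 82)
  expect_true(all(grepl("^leff_.*_auc$", ft0$feature_names)))
  expect_s3_class(ft0$outcome, "factor")
  ft1 <- assemble_features(cs$met, cs$sim$cohort, "diagnosis", TRUE)
  expect_equal(ncol(ft1$x), 84)   # + age, gender (dose etc. absent for TDC)
  ft2 <- assemble_features(cs$met, cs$sim$cohort, "response", TRUE)
  expect_equal(ncol(ft2$x), 88)   # + age, gender, dose, subtype, prior x2
  expect_equal(nrow(ft2$x), 7)    # ADHD with week-6 only
  expect_true(is.numeric(ft2$outcome))
  # missing metrics for a subject is an error
  expect_error(assemble_features(cs$met[-1, ], cs$sim$cohort, "diagnosis"),
               "missing metrics")
})

test_that("LOOCV separates a planted strong effect and tracks a signal", {
  set.seed(11)
  n <- 40
  x <- matrix(rnorm(n * 5), n, 5)
  y <- factor(rep(c("A", "B"), each = n / 2))
  x[, 1] <- x[, 1] + ifelse(y == "A", 3, -3)     # d = 6 on feature 1
  ev <- loocv_evaluate(make_feature_table(x, y), C_grid = c(0.1, 1))
  expect_equal(ev$accuracy_stats$accuracy_pct, 100)
  expect_equal(nrow(ev$loocv_predictions), n)
  # regression: y ~= first feature
  yr <- x[, 2] + rnorm(n, 0, 0.01)
  evr <- loocv_evaluate(make_feature_table(x, yr), C_grid = c(0.1, 1, 10))
  expect_gt(evr$obs_pred$r, 0.95)
  expect_error(loocv_evaluate(make_feature_table(x[1:3, ], y[1:3])),
               "n >= 5")
})

test_that("null features give chance-level held-out accuracy (no leakage)", {
  set.seed(12)
  n <- 40
  x <- matrix(rnorm(n * 10), n, 10)
  y <- factor(rep(c("A", "B"), n / 2))
  ev <- loocv_evaluate(make_feature_table(x, y), C_grid = c(0.01, 0.1, 1))
  acc <- ev$accuracy_stats$n_correct
  # central 95% binomial band around 0.5 for n = 40: [14, 26]
  expect_gte(acc, qbinom(0.025, n, 0.5))
  expect_lte(acc, qbinom(0.975, n, 0.5))
})

test_that("fold standardization uses training statistics only", {
  x_tr <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  x_te <- matrix(c(100, 100), 1, 2)
  std <- connectopath:::fold_standardize(x_tr, x_te)
  expect_equal(drop(std$test), (c(100, 100) - colMeans(x_tr)) /
                 apply(x_tr, 2, sd), ignore_attr = TRUE)
  expect_equal(unname(colMeans(std$train)), c(0, 0))
})

test_that("permutation p is exact at the floor, reproducible and invariant
           to feature order", {
  set.seed(13)
  n <- 16
  x <- matrix(rnorm(n * 3), n, 3)
  y <- factor(rep(c("A", "B"), each = n / 2))
  x[, 1] <- x[, 1] + ifelse(y == "A", 4, -4)
  ft <- make_feature_table(x, y)
  pt <- permutation_test(ft, B = 200, seed = 9, C_grid = c(0.1, 1))
  expect_equal(pt$p, 1 / 201)    # observed beats every permutation
  pt2 <- permutation_test(ft, B = 200, seed = 9, C_grid = c(0.1, 1))
  expect_identical(pt$p, pt2$p)
  ft_shuf <- make_feature_table(x[, c(3, 1, 2)], y)
  pt3 <- permutation_test(ft_shuf, B = 200, seed = 9, C_grid = c(0.1, 1))
  expect_equal(pt3$p, pt$p)
  expect_error(permutation_test(ft, B = 0), "B must be")
})

test_that("ROC importance equals brute-force Mann-Whitney and ranks
           planted effects first", {
  set.seed(14)
  y <- factor(c(rep("A", 12), rep("B", 18)))
  x <- matrix(rnorm(30 * 6), 30, 6)
  x[, 3] <- round(x[, 3], 1)    # induce ties
  ft <- make_feature_table(x, y)
  imp <- importance_classification(ft)
  for (j in 1:6) {
    u <- 0
    for (a in which(y == "A")) for (b in which(y == "B"))
      u <- u + (x[a, j] > x[b, j]) + 0.5 * (x[a, j] == x[b, j])
    auc <- u / (12 * 18)
    row <- imp[imp$feature == sprintf("f%02d", j), ]
    expect_equal(row$auc_positive, auc, tolerance = 1e-12)
    expect_equal(row$score, max(auc, 1 - auc))
  }
  # spec toys
  ind <- make_feature_table(matrix(c(0, 0, 0, 1, 1, 1), 6, 1),
                            factor(c("B", "B", "B", "A", "A", "A")))
  expect_equal(importance_classification(ind)$score, 1)
  const <- make_feature_table(matrix(1, 6, 1),
                              factor(rep(c("A", "B"), 3)))
  expect_equal(importance_classification(const)$score, 0.5)
  sep <- make_feature_table(matrix(c(1, 2, 3, 4, 5, 6), 6, 1),
                            factor(c("A", "A", "A", "B", "B", "B")))
  expect_equal(importance_classification(sep)$score, 1)
})

test_that("planted d = 1.5 effects land in the top decile of importance", {
  set.seed(15)
  hits <- 0
  for (rep in 1:10) {
    n <- 63
    x <- matrix(rnorm(n * 82), n, 82)
    y <- factor(c(rep("ADHD", 37), rep("TDC", 26)))
    planted <- 1:8
    x[y == "ADHD", planted] <- x[y == "ADHD", planted] - 1.5
    imp <- importance_classification(make_feature_table(x, y))
    top8 <- imp$feature[1:8]
    if (all(sprintf("f%02d", planted) %in% top8)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("loess importance scores signal, noise and curvature correctly", {
  set.seed(16)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3)
  y <- x[, 1]
  ft <- make_feature_table(x, y)
  imp <- importance_regression(ft)
  expect_equal(imp$feature[1], "f01")
  expect_gt(imp$score[1], 0.95)
  expect_lt(max(imp$score[imp$feature != "f01"]), 0.1)
  # quadratic signal: loess r2 far above the linear r2
  yq <- x[, 2] ^ 2
  impq <- importance_regression(make_feature_table(x, yq))
  lin_r2 <- summary(lm(yq ~ x[, 2]))$r.squared
  expect_gt(impq$score[impq$feature == "f02"], lin_r2 + 0.3)
  # constant feature flagged with score 0
  xc <- cbind(x, f_const = 1)
  impc <- importance_regression(make_feature_table(xc, y))
  expect_true(impc$constant[impc$feature == "f_const"])
  expect_equal(impc$score[impc$feature == "f_const"], 0)
  expect_error(importance_regression(make_feature_table(x[1:5, ], y[1:5])),
               "n >= 10")
})

test_that("summarize_top_regions maps features to atlas networks", {
  atlas <- default_atlas()
  sc <- atlas$name[atlas$network == "subcortical"][1:5]
  other <- atlas$name[atlas$network != "subcortical"][1:5]
  imp <- data.frame(feature = paste0("leff_", c(sc, other), "_auc"),
                    score = seq(1, 0.1, length.out = 10),
                    higher_in = "TDC", stringsAsFactors = FALSE)
  s <- summarize_top_regions(imp, atlas, k = 10)
  expect_equal(unname(s$census[["subcortical"]]), 0.5)
  expect_equal(nrow(s$top), 10)
  expect_equal(s$top$region[1], sc[1])
  s1 <- summarize_top_regions(imp, atlas, k = 1)
  expect_equal(nrow(s1$top), 1)
  expect_error(summarize_top_regions(imp, atlas, k = 11), "exceeds")
  expect_error(summarize_top_regions(imp, atlas, k = 0), "positive")
})
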