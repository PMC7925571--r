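#' Resolved run configuration
#'
#' Collects every knob of the three-question pipeline with validated
#' defaults. The resolved configuration is embedded in each report so a run
#' can be reproduced exactly.
#'
#' @param thresholds Sparsity grid (default [default_thresholds()]).
#' @param normalize `"max"` or `"none"`.
#' @param path_length `"weighted"` or `"hops"`.
#' @param C_grid SVM cost grid.
#' @param tuning_metric `"auto"`, `"accuracy"` or `"rmse"`.
#' @param permutations Permutation count for SVM significance (default 200
#'   for desk-scale runs; the reference analysis used 1000).
#' @param fdr_family Optional fixed FDR family size `m`; `NULL` (default)
#'   uses the number of tests in each research-question family.
#' @param responder_cut Percent-reduction cutoff for responder status
#'   (default 25; strict inequality).
#' @param seed Seed for permutation streams.
#' @return A `run_config` list.
#' @export
run_config <- function(thresholds = default_thresholds(),
                       normalize = "max", path_length = "weighted",
                       C_grid = default_c_grid(),
                       tuning_metric = "auto",
                       permutations = 200, fdr_family = NULL,
                       responder_cut = 25, seed = 1) {
  structure(list(thresholds = thresholds, normalize = normalize,
                 path_length = path_length, C_grid = C_grid,
                 tuning_metric = tuning_metric,
                 permutations = permutations, fdr_family = fdr_family,
                 responder_cut = responder_cut, seed = as.integer(seed)),
            class = "run_config")
}

fdr_m <- function(config, n_tests) {
  m <- config$fdr_family
  if (is.null(m)) n_tests else max(m, n_tests)
}

# Degenerate measures (e.g. a nodal AUC constant across subjects at a toy
# scale) carry no test: they get an NA row instead of aborting the family.
safe_stat <- function(expr, name) {
  tryCatch(expr, error = function(e)
    stat_result(name, NA_real_, NA_real_, NA_integer_, NA_real_))
}

add_q <- function(tab, config) {
  tab$q <- NA_real_
  ok <- !is.na(tab$p)
  if (any(ok)) tab$q[ok] <- bh_fdr(tab$p[ok], m = fdr_m(config, sum(ok)))
  tab
}

metric_columns <- function(metrics) {
  c("global_efficiency_auc", "char_path_length_auc", "mean_clustering_auc",
    grep("^leff_.*_auc$", names(metrics), value = TRUE))
}

#' Research question 1: diagnostic group differences
#'
#' Pooled-variance t tests (ADHD vs TDC) on the 3 global AUCs and every
#' nodal local-efficiency AUC with BH-FDR across the family, then linear
#' SVM classification of group from the 82 local-efficiency features, with
#' and without the age/gender covariates, with the Table-1 statistic set
#' and the top-10 importance summary (network census).
#'
#' @param cohort A `cohort_table` with both groups.
#' @param metrics Metric table from [compute_cohort_metrics()]; computed
#'   here if `NULL`.
#' @param config A `run_config`.
#' @return Report section (list).
#' @export
run_question1 <- function(cohort, metrics = NULL, config = run_config()) {
  grp <- cohort$subjects$group
  if (length(unique(grp)) < 2) stop("need both ADHD and TDC groups")
  if (is.null(metrics))
    metrics <- compute_cohort_metrics(cohort, config$thresholds,
                                      config$normalize, config$path_length)
  cols <- metric_columns(metrics)
  adhd_ids <- cohort$subjects$subject_id[grp == "ADHD"]
  tdc_ids <- cohort$subjects$subject_id[grp == "TDC"]
  a <- metrics[match(adhd_ids, metrics$subject_id), ]
  t_ <- metrics[match(tdc_ids, metrics$subject_id), ]
  uni <- do.call(rbind, lapply(cols, function(cl)
    safe_stat(two_sample_t(a[[cl]], t_[[cl]], name = cl), cl)))
  uni <- add_q(uni, config)

  ft <- assemble_features(metrics, cohort, "diagnosis", FALSE)
  ev <- loocv_evaluate(ft, config$C_grid, config$tuning_metric)
  if (config$permutations > 0)
    ev$permutation_p <- permutation_test(ft, B = config$permutations,
                                         seed = config$seed,
                                         C_grid = config$C_grid,
                                         tuning_metric = config$tuning_metric,
                                         observed = ev)$p
  ft_cov <- assemble_features(metrics, cohort, "diagnosis", TRUE)
  ev_cov <- loocv_evaluate(ft_cov, config$C_grid, config$tuning_metric)
  top10 <- summarize_top_regions(ev$importance, cohort$atlas,
                                 k = min(10, nrow(ev$importance)))
  list(question = "diagnostic_group",
       univariate = uni, svm = ev, svm_covariates = ev_cov,
       top_regions = top10)
}

#' Research question 2: methylphenidate treatment response
#'
#' Among ADHD subjects with week-6 scores: linear regressions of percent
#' change (total, inattention, hyperactivity) on the global-efficiency AUC
#' and each nodal local-efficiency AUC, with and without the six
#' covariates, BH-FDR within each outcome family; a regression SVM over the
#' 82 features with permutation significance and loess importance; and
#' responder vs non-responder vs TDC three-way comparisons on global
#' efficiency plus any FDR-significant nodal measure.
#'
#' @inheritParams run_question1
#' @return Report section (list).
#' @export
run_question2 <- function(cohort, metrics = NULL, config = run_config()) {
  subj <- cohort$subjects
  tr <- subj$group == "ADHD" & subj$has_week6
  if (!any(tr)) stop("no ADHD subjects with post-treatment scores")
  if (is.null(metrics))
    metrics <- compute_cohort_metrics(cohort, config$thresholds,
                                      config$normalize, config$path_length)
  ad <- subj[tr, ]
  m_ad <- metrics[match(ad$subject_id, metrics$subject_id), ]
  pct <- list(
    total = percent_change(ad$adhdrs_total_w0, ad$adhdrs_total_w6),
    inattention = percent_change(pmax(ad$adhdrs_inatt_w0, 1),
                                 ad$adhdrs_inatt_w6),
    hyperactivity = percent_change(pmax(ad$adhdrs_hyper_w0, 1),
                                   ad$adhdrs_hyper_w6))
  cov_df <- ad[, c("age", "gender", "mph_dose_mg_per_kg", "adhd_subtype",
                   "prior_stimulant_6mo", "prior_stimulant_duration")]
  pred_cols <- c("global_efficiency_auc",
                 grep("^leff_.*_auc$", names(metrics), value = TRUE))
  regressions <- lapply(names(pct), function(oc) {
    tab <- do.call(rbind, lapply(pred_cols, function(cl)
      safe_stat(linear_regression(pct[[oc]], m_ad[[cl]], name = cl), cl)))
    tab_cov <- do.call(rbind, lapply(pred_cols, function(cl)
      safe_stat(linear_regression(pct[[oc]], m_ad[[cl]],
                                  covariates = cov_df, name = cl), cl)))
    list(outcome = oc, unadjusted = add_q(tab, config),
         adjusted = add_q(tab_cov, config))
  })
  names(regressions) <- names(pct)

  ft <- assemble_features(metrics, cohort, "response", FALSE)
  ev <- loocv_evaluate(ft, config$C_grid, config$tuning_metric)
  if (config$permutations > 0)
    ev$permutation_p <- permutation_test(ft, B = config$permutations,
                                         seed = config$seed,
                                         C_grid = config$C_grid,
                                         tuning_metric = config$tuning_metric,
                                         observed = ev)$p
  top10 <- summarize_top_regions(ev$importance, cohort$atlas,
                                 k = min(10, nrow(ev$importance)))

  # Responder / non-responder / TDC three-way contrasts.
  resp <- if (config$responder_cut == 25) responder_flag(pct$total)
          else pct$total < -config$responder_cut
  sig_nodal <- regressions$total$unadjusted
  sig_nodal <- sig_nodal$name[!is.na(sig_nodal$q) & sig_nodal$q < 0.05 &
                                grepl("^leff_", sig_nodal$name)]
  contrast_cols <- unique(c("global_efficiency_auc", sig_nodal))
  tdc_ids <- subj$subject_id[subj$group == "TDC"]
  m_tdc <- metrics[match(tdc_ids, metrics$subject_id), ]
  three_way <- do.call(rbind, lapply(contrast_cols, function(cl) {
    r <- m_ad[[cl]][resp]; nr <- m_ad[[cl]][!resp]; td <- m_tdc[[cl]]
    rbind(
      if (length(r) >= 2 && length(td) >= 2)
        two_sample_t(r, td, paste0(cl, ":responder_vs_tdc")),
      if (length(nr) >= 2 && length(td) >= 2)
        two_sample_t(nr, td, paste0(cl, ":nonresponder_vs_tdc")),
      if (length(r) >= 2 && length(nr) >= 2)
        two_sample_t(r, nr, paste0(cl, ":responder_vs_nonresponder")))
  }))
  list(question = "treatment_response",
       n_treated = sum(tr), regressions = regressions,
       svm = ev, top_regions = top10,
       responder_counts = c(responder = sum(resp),
                            nonresponder = sum(!resp)),
       three_way = three_way)
}

#' Research question 3: baseline severity associations
#'
#' Correlations of baseline total/inattention/hyperactivity scores with all
#' 85 graph-measure AUCs among ADHD subjects, BH-FDR within each family.
#'
#' @inheritParams run_question1
#' @param method Correlation method (default Pearson).
#' @return Report section (list).
#' @export
run_question3 <- function(cohort, metrics = NULL, config = run_config(),
                          method = "pearson") {
  subj <- cohort$subjects
  ad <- subj[subj$group == "ADHD", ]
  if (nrow(ad) < 3) stop("need at least 3 ADHD subjects with baseline scores")
  if (is.null(metrics))
    metrics <- compute_cohort_metrics(cohort, config$thresholds,
                                      config$normalize, config$path_length)
  m_ad <- metrics[match(ad$subject_id, metrics$subject_id), ]
  cols <- metric_columns(metrics)
  outcomes <- list(total = ad$adhdrs_total_w0,
                   inattention = ad$adhdrs_inatt_w0,
                   hyperactivity = ad$adhdrs_hyper_w0)
  correlations <- lapply(names(outcomes), function(oc) {
    tab <- do.call(rbind, lapply(cols, function(cl)
      safe_stat(pearson_correlation(m_ad[[cl]], outcomes[[oc]],
                                    method = method, name = cl), cl)))
    add_q(tab, config)
  })
  names(correlations) <- names(outcomes)
  list(question = "symptom_severity", correlations = correlations)
}

svm_table_rows <- function(ev) {
  if (ev$task == "classification") {
    s <- ev$accuracy_stats
    list(cost = ev$tuned_cost,
         accuracy_pct = s$accuracy_pct,
         ci95_pct = unname(s$ci95_pct),
         accuracy_null_pct = s$nir_pct,
         sensitivity = s$sensitivity, specificity = s$specificity,
         ppv = s$ppv, npv = s$npv,
         p_value = s$p_vs_nir, permutation_p = ev$permutation_p)
  } else {
    list(cost = ev$tuned_cost, obs_pred_r = ev$obs_pred$r,
         p_value = ev$obs_pred$p, rmse = ev$obs_pred$rmse,
         permutation_p = ev$permutation_p)
  }
}

#' Render an analysis report
#'
#' Writes `report.json` (machine-readable; round-trips the section
#' structures) and `report.md` (tables mirroring the reference Table-1 row
#' layout: Cost, Accuracy %, CI 95%, Accuracy null %, Sensitivity,
#' Specificity, PPV, NPV, p value, Permutation p value), plus a provenance
#' block (seed, package version, resolved config).
#'
#' @param sections Named list of completed report sections.
#' @param dir Output directory.
#' @param config The `run_config` used.
#' @return Paths of the written files, invisibly.
#' @export
render_report <- function(sections, dir, config = run_config()) {
  if (length(sections) == 0) stop("need at least one completed section")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(
    package = "connectopath",
    version = as.character(utils::packageVersion("connectopath")),
    seed = config$seed, config = unclass(config))
  payload <- list(provenance = provenance, sections = sections)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")

  md <- c("# Structural connectome analysis report", "")
  fmt <- function(x, d = 3) ifelse(is.na(x), "NA", format(round(x, d)))
  for (sec in sections) {
    md <- c(md, paste("##", sec$question), "")
    if (!is.null(sec$svm)) {
      r <- svm_table_rows(sec$svm)
      md <- c(md, "| Performance measure | Value |", "|---|---|",
              paste0("| Cost | ", fmt(r$cost, 4), " |"))
      if (sec$svm$task == "classification") {
        md <- c(md,
          paste0("| Accuracy % | ", fmt(r$accuracy_pct, 1), " |"),
          paste0("| CI 95% (lower, upper) | (", fmt(r$ci95_pct[1], 1), ", ",
                 fmt(r$ci95_pct[2], 1), ") |"),
          paste0("| Accuracy null % | ", fmt(r$accuracy_null_pct, 1), " |"),
          paste0("| Sensitivity | ", fmt(100 * r$sensitivity, 1), " |"),
          paste0("| Specificity | ", fmt(100 * r$specificity, 1), " |"),
          paste0("| PPV | ", fmt(100 * r$ppv, 1), " |"),
          paste0("| NPV | ", fmt(100 * r$npv, 1), " |"))
      } else {
        md <- c(md, paste0("| Observed-predicted r | ", fmt(r$obs_pred_r),
                           " |"),
                paste0("| RMSE | ", fmt(r$rmse, 2), " |"))
      }
      md <- c(md, paste0("| p value | ", fmt(r$p_value, 4), " |"),
              paste0("| Permutation p value | ", fmt(r$permutation_p, 4),
                     " |"), "")
    }
    if (!is.null(sec$top_regions)) {
      md <- c(md, "Top contributing regions:",
              paste0("- ", sec$top_regions$top$region, " (",
                     sec$top_regions$top$network, "), score ",
                     fmt(sec$top_regions$top$score)), "")
    }
  }
  md <- c(md, "---",
          paste0("Seed ", provenance$seed, "; connectopath ",
                 provenance$version, "."))
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(json = json_path, markdown = md_path))
}
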