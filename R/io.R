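#' Construct a connectivity matrix
#'
#' Validates and canonicalizes one subject's weighted structural connectome:
#' a symmetric, non-negative, zero-diagonal region-by-region matrix of
#' streamline counts (or normalized weights). Asymmetry up to `1e-9` in
#' absolute value is symmetrized by averaging; anything larger is an error,
#' since tractography pipelines emit symmetric counts and silently averaging
#' truly asymmetric data would hide upstream bugs. The diagonal (self
#' connections are meaningless here) is forced to exactly zero.
#'
#' @param weights n x n numeric matrix, finite and non-negative.
#' @param regions Character vector of n region names, in matrix order.
#' @param subject_id Subject identifier.
#' @return A `connectivity_matrix`: list with `subject_id`, `regions`,
#'   `weights` (dimnames set to `regions`).
#' @export
connectivity_matrix <- function(weights, regions, subject_id = "") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("matrix is not square")
  if (length(regions) != nrow(weights))
    stop("region list length (", length(regions),
         ") does not match matrix dimension (", nrow(weights), ")")
  if (any(!is.finite(weights))) stop("non-finite weight")
  if (any(weights < 0)) stop("negative weight")
  asym <- max(abs(weights - t(weights)))
  if (asym > SYMMETRY_TOL)
    stop("matrix asymmetric beyond tolerance (max |A - t(A)| = ",
         format(asym), ")")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(regions, regions)
  structure(list(subject_id = subject_id,
                 regions = as.character(regions),
                 weights = weights),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix>", x$subject_id, ":", length(x$regions),
      "regions,", sum(x$weights[upper.tri(x$weights)] > 0), "edges\n")
  invisible(x)
}

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

#' Load a subject's connectivity matrix from delimited text
#'
#' Accepts comma- or tab-delimited n x n numeric text (auto-detected), with
#' an optional header row of region names. When a header is present its
#' order must match the atlas exactly; n must equal the atlas length.
#'
#' @param path File path (`<subject_id>.csv` / `.tsv`).
#' @param atlas A `parcellation_atlas` giving the expected region order.
#' @param subject_id Optional subject id; defaults to the file stem.
#' @return A validated `connectivity_matrix`.
#' @export
load_matrix <- function(path, atlas, subject_id = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  sep <- detect_sep(first)
  tokens <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(tokens))))
  raw <- read.table(path, sep = sep, header = has_header,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (has_header) {
    hdr <- names(raw)
    if (!identical(hdr, atlas$name))
      stop("matrix header does not match atlas region order")
  }
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("non-numeric entries in matrix file")
  if (nrow(m) != ncol(m)) stop("matrix is not square")
  if (nrow(m) != nrow(atlas))
    stop("matrix dimension ", nrow(m), " does not match atlas length ",
         nrow(atlas))
  connectivity_matrix(unname(m), atlas$name, subject_id)
}

#' Write a connectivity matrix as delimited text
#'
#' Serializes at 15 significant digits with a header row of region names so
#' that a write/load round trip reproduces weights to within 1e-9 in
#' absolute terms even for streamline counts in the thousands. Delimiter
#' follows the file extension (`.tsv` tab, otherwise comma).
#'
#' @param m A `connectivity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  txt <- apply(m$weights, 1, function(r)
    paste(formatC(r, digits = 15, format = "g"), collapse = sep))
  writeLines(c(paste(m$regions, collapse = sep), txt), path)
  invisible(path)
}

# ---- phenotype / cohort ----------------------------------------------------

PHENO_COLS <- c("subject_id", "group", "age", "gender", "adhd_subtype",
                "mph_dose_mg_per_kg", "prior_stimulant_6mo",
                "prior_stimulant_duration",
                "adhdrs_total_w0", "adhdrs_inatt_w0", "adhdrs_hyper_w0",
                "adhdrs_total_w6", "adhdrs_inatt_w6", "adhdrs_hyper_w6")

validate_subjects <- function(df) {
  missing_cols <- setdiff(PHENO_COLS, names(df))
  if (length(missing_cols))
    stop("phenotype table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id")
  if (!all(df$group %in% c("ADHD", "TDC")))
    stop("group must be ADHD or TDC")
  rng_ok <- function(x, lo, hi) is.na(x) | (x >= lo & x <= hi)
  for (col in c("adhdrs_total_w0", "adhdrs_total_w6"))
    if (!all(rng_ok(df[[col]], 0, 54)))
      stop("score out of range in ", col, " (ADHD-RS total is 0-54)")
  for (col in c("adhdrs_inatt_w0", "adhdrs_hyper_w0",
                "adhdrs_inatt_w6", "adhdrs_hyper_w6"))
    if (!all(rng_ok(df[[col]], 0, 27)))
      stop("score out of range in ", col, " (subscale is 0-27)")
  if (any(is.na(df$adhdrs_total_w0)))
    stop("baseline ADHD-RS total missing")
  tdc <- df$group == "TDC"
  if (any(tdc & (!is.na(df$adhdrs_total_w6) | !is.na(df$adhdrs_inatt_w6) |
                   !is.na(df$adhdrs_hyper_w6))))
    stop("week-6 scores present for TDC subject")
  df
}

#' Load a full cohort (phenotypes + one matrix per subject)
#'
#' @param pheno_path CSV with one row per subject (see `PHENO_COLS` in the
#'   package source for the column contract).
#' @param matrix_dir Directory holding `<subject_id>.csv` or `.tsv` files.
#' @param atlas A `parcellation_atlas`.
#' @return A `cohort_table`: list with `subjects` (data.frame), `matrices`
#'   (named list of `connectivity_matrix`), `atlas`. ADHD subjects lacking
#'   week-6 scores are retained but flagged (`has_week6 = FALSE`) and a
#'   warning is raised; they are excluded from treatment-response analyses.
#' @export
load_cohort <- function(pheno_path, matrix_dir, atlas) {
  df <- read.csv(pheno_path, stringsAsFactors = FALSE)
  df <- validate_subjects(df)
  mats <- list()
  for (id in df$subject_id) {
    f <- file.path(matrix_dir, paste0(id, ".csv"))
    if (!file.exists(f)) f <- file.path(matrix_dir, paste0(id, ".tsv"))
    if (!file.exists(f)) stop("missing matrix file for subject ", id)
    mats[[id]] <- load_matrix(f, atlas, subject_id = id)
  }
  cohort_table(df, mats, atlas)
}

#' Assemble a cohort table from in-memory pieces
#'
#' @param subjects Phenotype data.frame (validated).
#' @param matrices Named list of `connectivity_matrix`, one per subject.
#' @param atlas A `parcellation_atlas`.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(subjects, matrices, atlas) {
  subjects <- validate_subjects(subjects)
  if (!setequal(names(matrices), subjects$subject_id) ||
      length(matrices) != nrow(subjects))
    stop("every subject must have exactly one matrix")
  matrices <- matrices[subjects$subject_id]
  subjects$has_week6 <- !is.na(subjects$adhdrs_total_w6)
  n_flag <- sum(subjects$group == "ADHD" & !subjects$has_week6)
  if (n_flag > 0)
    warning(n_flag, " ADHD subject(s) lack week-6 scores; excluded from ",
            "treatment-response analyses")
  structure(list(subjects = subjects, matrices = matrices, atlas = atlas),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("<cohort_table>", nrow(x$subjects), "subjects (",
      paste(names(tab), as.integer(tab), collapse = ", "), "),",
      nrow(x$atlas), "regions\n")
  invisible(x)
}
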