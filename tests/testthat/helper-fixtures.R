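# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

toy_atlas3 <- function() {
  as_parcellation_atlas(data.frame(
    name = c("r1", "r2", "r3"),
    hemisphere = c("left", "right", "left"),
    network = c("visual", "subcortical", "default_mode"),
    stringsAsFactors = FALSE))
}

# connectivity_matrix from a bare weight matrix with autogenerated regions
cm <- function(W, id = "s1") {
  connectivity_matrix(W, sprintf("n%02d", seq_len(nrow(W))), id)
}

# symmetric zero-diagonal matrix from upper-triangle values (row-major by
# upper.tri order, i.e. column-major (i<j))
sym_from_upper <- function(n, vals) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- vals
  W + t(W)
}

# Independent Floyd-Warshall oracle (vectorized over the middle index),
# lengths 1/w -- the brute-force reference for shortest_distances().
fw_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# random symmetric weighted graph
rand_graph <- function(n, density = 0.4) {
  m <- n * (n - 1) / 2
  w <- ifelse(runif(m) < density, runif(m, 0.1, 1), 0)
  sym_from_upper(n, w)
}

# small synthetic cohort for structural tests (fast: few regions/subjects)
small_cohort <- function(seed = 42, n_regions = 16, n_adhd = 6, n_tdc = 5,
                         ...) {
  simulate_cohort(simulation_config(n_adhd = n_adhd, n_tdc = n_tdc,
                                    n_regions = n_regions, seed = seed, ...))
}

# build a feature_table directly (bypassing cohort plumbing)
make_feature_table <- function(x, outcome, task = "diagnosis") {
  colnames(x) <- colnames(x) %||% sprintf("f%02d", seq_len(ncol(x)))
  structure(list(subject_ids = sprintf("s%03d", seq_len(nrow(x))),
                 feature_names = colnames(x), x = x, outcome = outcome,
                 task = task),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# distance matrices may contain Inf for unreachable pairs; Inf - Inf is NaN,
# so compare reachability pattern and finite entries separately
expect_dist_equal <- function(D1, D2, tol = 1e-10) {
  expect_identical(unname(is.finite(D1)), unname(is.finite(D2)))
  fin <- is.finite(D1) & is.finite(D2)
  expect_lt(max(abs(D1[fin] - D2[fin])), tol)
}

validate_subjects_wrap <- function(df)
  connectopath:::validate_subjects(df[, setdiff(names(df), "has_week6")])
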