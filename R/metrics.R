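#' Max-normalize connectome weights
#'
#' Divides every weight by the matrix maximum so weights lie in \[0, 1\],
#' the scale assumed by the weighted (Onnela) clustering coefficient and by
#' the \[0, 1\] bounds on efficiency metrics.
#'
#' @param m A `connectivity_matrix`.
#' @return A `connectivity_matrix` with maximum weight 1.
#' @export
normalize_weights <- function(m) {
  mx <- max(m$weights)
  if (mx <= 0) stop("all-zero matrix cannot be normalized")
  m$weights <- m$weights / mx
  m
}

#' Proportional (density) threshold
#'
#' Retains the `floor(S * n(n-1)/2)` strongest undirected edges with their
#' original weights and zeroes the rest. Ties at the cut weight are broken
#' deterministically by ascending (row, column) upper-triangle index so
#' results are identical across platforms.
#'
#' @param m A `connectivity_matrix` (or `thresholded_graph`).
#' @param S Sparsity in (0, 1]: fraction of possible edges retained.
#' @return A `thresholded_graph`: list with `weights`, `sparsity`, `regions`.
#' @export
proportional_threshold <- function(m, S) {
  if (!is.numeric(S) || length(S) != 1 || S <= 0 || S > 1)
    stop("S must be in (0, 1]")
  W <- m$weights
  n <- nrow(W)
  k <- floor(S * n * (n - 1) / 2)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  # Strongest first; among equal weights the smaller (row, col) wins.
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(k, length(ord)))]
  keep <- keep[w[keep] > 0]            # zero weights are not edges
  Wt <- matrix(0, n, n, dimnames = dimnames(W))
  Wt[ut[keep, , drop = FALSE]] <- w[keep]
  Wt <- Wt + t(Wt)
  structure(list(weights = Wt, sparsity = S, regions = m$regions),
            class = "thresholded_graph")
}

as_weights <- function(g) {
  if (is.matrix(g)) g else g$weights
}

#' Weighted shortest-path distance matrix
#'
#' Maps each weight to a length `1/w` (stronger connections are shorter) and
#' runs single-source shortest paths from every node. Unreachable pairs get
#' `+Inf`; the diagonal is 0.
#'
#' @param g A `thresholded_graph`, `connectivity_matrix`, or plain matrix.
#' @return n x n numeric distance matrix.
#' @export
shortest_distances <- function(g) {
  W <- as_weights(g)
  D <- cpp_shortest_distances(W)
  dimnames(D) <- dimnames(W)
  D
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered pairs i != j with finite
#' distance. Infinite (unreachable) pairs are excluded from the mean and
#' their count is attached as `attr(, "n_infinite_pairs")`; if no finite
#' pair exists the value is `+Inf`.
#'
#' @param d Distance matrix from [shortest_distances()].
#' @return Scalar path length with the exclusion count as an attribute.
#' @export
characteristic_path_length <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  val <- if (any(fin)) mean(off[fin]) else Inf
  structure(val, n_infinite_pairs = sum(!fin))
}

#' Global efficiency
#'
#' Harmonic-mean form `E_glob = (1/(n(n-1))) * sum_{i != j} 1/d_ij` with
#' `1/Inf = 0`, so disconnected pairs contribute zero rather than being
#' dropped.
#'
#' @param d Distance matrix from [shortest_distances()].
#' @return Scalar in \[0, 1\] when weights are max-normalized.
#' @export
global_efficiency <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  off <- d[row(d) != col(d)]
  inv <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  sum(inv) / (n * (n - 1))
}

#' Weighted (Onnela) clustering coefficient
#'
#' `C_i = (1/(k_i (k_i - 1))) * [W^(1/3)]^3_ii` over node triangles, with
#' `k_i` the binary degree and `C_i = 0` when `k_i < 2`. Weights should be
#' max-normalized so each `C_i` lies in \[0, 1\].
#'
#' @param g A `thresholded_graph` (or matrix).
#' @return List with `per_node` (named vector) and `mean` over all nodes.
#' @export
weighted_clustering <- function(g) {
  W <- as_weights(g)
  res <- cpp_graph_metrics(W)
  per_node <- as.numeric(res$clustering)
  names(per_node) <- rownames(W)
  list(per_node = per_node, mean = res$mean_clustering)
}

#' Nodal local efficiency
#'
#' Global efficiency of the subgraph induced by the neighbours of node `i`
#' (node `i` removed, original weights retained); 0 when the node has fewer
#' than 2 neighbours. Indexes fault tolerance of information flow around
#' the node.
#'
#' @param g A `thresholded_graph` (or matrix).
#' @param i Node index (1-based) or region name.
#' @return Scalar local efficiency.
#' @export
local_efficiency <- function(g, i) {
  W <- as_weights(g)
  if (is.character(i)) i <- match(i, rownames(W))
  if (is.na(i) || i < 1 || i > nrow(W)) stop("node index out of range")
  nb <- which(W[i, ] > 0)
  if (length(nb) < 2) return(0)
  cpp_subgraph_geff(W, as.integer(nb - 1L))
}

#' Default proportional-threshold grid
#'
#' The sweep covers sparsities from 5% to 30% in 1% steps. The inclusive
#' reading (26 levels, endpoints in) is the default; `inclusive = FALSE`
#' gives the strict reading (6%..29%, 24 levels).
#'
#' @param inclusive Include the 5% and 30% endpoints (default TRUE).
#' @return Numeric vector of sparsity values.
#' @export
default_thresholds <- function(inclusive = TRUE) {
  if (inclusive) seq(0.05, 0.30, by = 0.01) else seq(0.06, 0.29, by = 0.01)
}

# Trapezoidal integral of y over x, using only runs where both endpoints are
# finite; attaches the number of excluded segment endpoints.
auc_trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(y)
  both <- ok[-length(ok)] & ok[-1]
  if (!any(both)) return(structure(NA_real_, n_nonfinite = sum(!ok)))
  dx <- diff(x)[both]
  ym <- (y[-length(y)][both] + y[-1][both]) / 2
  structure(sum(dx * ym), n_nonfinite = sum(!ok))
}

metric_curve <- function(thresholds, values) {
  list(thresholds = thresholds, values = values,
       auc = as.numeric(auc_trapezoid(thresholds, values)),
       n_nonfinite = attr(auc_trapezoid(thresholds, values), "n_nonfinite"))
}

#' Sparsity sweep of graph metrics with AUC aggregation
#'
#' Thresholds the (optionally max-normalized) matrix at each sparsity level,
#' computes global efficiency, characteristic path length, mean weighted
#' clustering and the 82 nodal local efficiencies, and aggregates each
#' metric curve into a single trapezoidal area-under-the-curve scalar over
#' the raw threshold axis (width 0.25 for the default grid). Infinite path
#' lengths at a sparse threshold propagate as missing and the AUC uses only
#' finite segments (count recorded on the curve).
#'
#' @param m A `connectivity_matrix`.
#' @param thresholds Strictly increasing sparsities, length >= 2.
#' @param normalize `"max"` (default) or `"none"`.
#' @param path_length `"weighted"` (lengths `1/w`; default) or `"hops"`
#'   (binary hop count, the paper-literal reading of path length).
#' @return A `graph_metrics` object: `subject_id`, `thresholds`, metric
#'   curves `global_efficiency`, `char_path_length`, `mean_clustering`, and
#'   `local_efficiency` (list with a regions x thresholds `values` matrix
#'   and named `auc` vector).
#' @export
sweep_metrics <- function(m, thresholds = default_thresholds(),
                          normalize = c("max", "none"),
                          path_length = c("weighted", "hops")) {
  normalize <- match.arg(normalize)
  path_length <- match.arg(path_length)
  if (length(thresholds) < 2) stop("need at least 2 thresholds")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (normalize == "max") m <- normalize_weights(m)
  # One C++ call does the whole ascending sweep (edges sorted once and added
  # incrementally); equivalence with composing proportional_threshold() and
  # the per-metric operations is asserted in the test suite.
  res <- cpp_sweep_subject(m$weights, thresholds,
                           hop_cpl = (path_length == "hops"))
  ge <- res$global_efficiency
  cpl <- res$char_path_length
  cl <- res$mean_clustering
  le <- res$local_efficiency
  dimnames(le) <- list(m$regions, NULL)
  leff_auc <- apply(le, 1, function(v) as.numeric(auc_trapezoid(thresholds, v)))
  structure(list(
    subject_id = m$subject_id,
    thresholds = thresholds,
    global_efficiency = metric_curve(thresholds, ge),
    char_path_length = metric_curve(thresholds, cpl),
    mean_clustering = metric_curve(thresholds, cl),
    local_efficiency = list(values = le, auc = leff_auc)),
    class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat("<graph_metrics>", x$subject_id, ":", length(x$thresholds),
      "thresholds; gE AUC =", signif(x$global_efficiency$auc, 4),
      "; CPL AUC =", signif(x$char_path_length$auc, 4), "\n")
  invisible(x)
}

#' Per-subject AUC metric table for a cohort
#'
#' Runs [sweep_metrics()] for every subject and returns one row per subject
#' with columns `global_efficiency_auc`, `char_path_length_auc`,
#' `mean_clustering_auc` and `leff_<region>_auc` for each region.
#'
#' @param cohort A `cohort_table`.
#' @inheritParams sweep_metrics
#' @return data.frame keyed by `subject_id`.
#' @export
compute_cohort_metrics <- function(cohort,
                                   thresholds = default_thresholds(),
                                   normalize = "max",
                                   path_length = "weighted") {
  rows <- lapply(cohort$matrices, function(m) {
    gm <- sweep_metrics(m, thresholds, normalize, path_length)
    c(global_efficiency_auc = gm$global_efficiency$auc,
      char_path_length_auc = gm$char_path_length$auc,
      mean_clustering_auc = gm$mean_clustering$auc,
      stats::setNames(gm$local_efficiency$auc,
                      paste0("leff_", names(gm$local_efficiency$auc), "_auc")))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(subject_id = names(cohort$matrices), out)
  rownames(out) <- NULL
  out
}
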