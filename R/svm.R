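#' Linear support-vector machine (classification or regression)
#'
#' Soft-margin linear maximum-margin classifier (L1 hinge loss) when `y` is
#' a two-level factor, or epsilon-insensitive linear support-vector
#' regression when `y` is numeric. Solved by deterministic cyclic dual
#' coordinate descent to convergence tolerance 1e-6; the bias term uses an
#' augmented constant feature. Features are used as given — standardize
#' before fitting (the LOOCV driver does this inside each training fold).
#'
#' @param x Numeric matrix (subjects x features).
#' @param y Two-level factor (classification) or numeric (regression).
#' @param C Cost parameter, > 0.
#' @param epsilon Insensitivity half-width for regression (default 0.1).
#' @param tol Convergence tolerance (default 1e-6).
#' @param kernel Only `"linear"` is implemented; `"rbf"` (sigma) is accepted
#'   in configuration for completeness but routes to an explicit error.
#' @return An `svm_linear` model with weights `w`, bias `b`, and for
#'   classification the class levels (first level is coded +1).
#' @export
svm_linear <- function(x, y, C = 1, epsilon = 0.1, tol = 1e-6,
                       kernel = "linear") {
  if (kernel != "linear")
    stop("non-linear (sigma/RBF) kernels are not implemented")
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  x <- as.matrix(x)
  xa <- cbind(x, `(bias)` = 1)
  if (is.factor(y) || is.character(y)) {
    y <- droplevels(as.factor(y))
    if (nlevels(y) < 2) stop("single-class training set")
    if (nlevels(y) > 2) stop("only two-class problems supported")
    if (nrow(x) < 4 || min(table(y)) < 2)
      stop("need >= 2 subjects per class")
    ynum <- ifelse(y == levels(y)[1], 1, -1)
    fit <- cpp_svc_train(xa, ynum, C, tol, 20000L)
    type <- "classification"
    levels_ <- levels(y)
  } else {
    if (nrow(x) < 3) stop("need >= 3 subjects for regression")
    fit <- cpp_svr_train(xa, as.numeric(y), C, epsilon, tol, 20000L)
    type <- "regression"
    levels_ <- NULL
  }
  d <- ncol(x)
  structure(list(type = type, w = fit$w[seq_len(d)], b = fit$w[d + 1],
                 C = C, epsilon = epsilon, levels = levels_,
                 converged = fit$converged, epochs = fit$epochs,
                 feature_names = colnames(x)),
            class = "svm_linear")
}

#' Predict from a linear SVM
#'
#' @param object An `svm_linear` model.
#' @param newdata Numeric matrix with the training feature columns.
#' @param type `"response"` (class label / fitted value) or `"decision"`
#'   (raw decision value).
#' @param ... Unused.
#' @return Factor of class labels, or numeric vector.
#' @export
predict.svm_linear <- function(object, newdata, type = "response", ...) {
  newdata <- as.matrix(newdata)
  dec <- drop(newdata %*% object$w) + object$b
  if (object$type == "regression" || type == "decision") return(dec)
  factor(ifelse(dec >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' @export
print.svm_linear <- function(x, ...) {
  cat("<svm_linear>", x$type, "| C =", x$C,
      "|", length(x$w), "features | converged:", x$converged, "\n")
  invisible(x)
}
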