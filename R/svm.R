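#' Default SVM box constraint (SVM-light heuristic)
#'
#' The regularization weight used when no parameter search is performed:
#' the reciprocal of the mean squared feature-vector norm,
#' `C = n / sum_i(x_i . x_i)`. With unit-norm rows this gives exactly 1.
#'
#' @param features Numeric n-by-d feature matrix with at least one row and
#'   nonzero total squared norm.
#' @return Positive scalar `C`.
#' @export
#' @examples
#' svm_default_C(diag(3))  # unit-norm rows -> 1
svm_default_C <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 1) abort("empty feature matrix")
  total <- sum(features^2)
  if (total == 0) abort("all-zero feature matrix: default C undefined")
  nrow(features) / total
}

#' Train a one-vs-rest linear SVM
#'
#' Fits one soft-margin linear binary SVM per class (class against the
#' rest). The box constraint defaults to [svm_default_C()]; no feature
#' scaling is applied beyond preprocessing and no parameter search is
#' performed. The underlying convex problems are solved to `tolerance`, so
#' the fit is deterministic given the data.
#'
#' @param features n-by-d numeric matrix, one row per trial.
#' @param labels Character/factor vector of class labels (>= 2 classes).
#' @param C Box constraint; `NULL` means [svm_default_C()].
#' @param classes Class order used for tie-breaking and output columns;
#'   default the sorted unique labels.
#' @param tolerance Solver termination tolerance.
#' @return An `ovr_svm` model: per-class weight vectors and intercepts, the
#'   class order, `C`, and feature dimension.
#' @export
train_ovr_svm <- function(features, labels, C = NULL, classes = NULL,
                          tolerance = 1e-6) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(unique(labels)) < 2) abort("need at least 2 classes to train")
  if (is.null(C)) C <- svm_default_C(features)

  W <- matrix(0, nrow = length(classes), ncol = ncol(features),
              dimnames = list(classes, NULL))
  b <- numeric(length(classes))
  for (k in seq_along(classes)) {
    y <- factor(ifelse(labels == classes[k], "pos", "neg"),
                levels = c("pos", "neg"))
    fit <- e1071::svm(features, y, type = "C-classification",
                      kernel = "linear", cost = C, scale = FALSE,
                      tolerance = tolerance)
    w <- crossprod(fit$SV, fit$coefs)[, 1]
    rho <- fit$rho
    # orient the decision function so the target class scores positive
    dec <- features %*% w - rho
    if (mean(dec[y == "pos"]) < mean(dec[y == "neg"])) {
      w <- -w
      rho <- -rho
    }
    W[k, ] <- w
    b[k] <- -rho
  }
  structure(list(weights = W, bias = b, classes = classes, C = C,
                 d = ncol(features), tolerance = tolerance),
            class = "ovr_svm")
}

#' Predict with a one-vs-rest linear SVM
#'
#' Computes the per-class linear decision values `x . w_k + b_k` and labels
#' each row with the class of maximal decision value; exact ties break by
#' the model's fixed class order.
#'
#' @param object An `ovr_svm` model.
#' @param features n-by-d matrix with `d` matching the training dimension.
#' @param ... Unused.
#' @return Tibble with `label` and one `decision_<class>` column per class.
#' @export
predict.ovr_svm <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$d) {
    abort(paste0("feature dimension ", ncol(features),
                 " does not match training dimension ", object$d))
  }
  dec <- features %*% t(object$weights)
  dec <- sweep(dec, 2, object$bias, `+`)
  colnames(dec) <- object$classes
  lab <- object$classes[max.col(dec, ties.method = "first")]
  out <- tibble::as_tibble(as.data.frame(dec))
  names(out) <- paste0("decision_", object$classes)
  dplyr::bind_cols(tibble::tibble(label = lab), out)
}

#' @export
print.ovr_svm <- function(x, ...) {
  cat("<ovr_svm> one-vs-rest linear SVM\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  features:", x$d, " C:", format(x$C, digits = 6), "\n")
  invisible(x)
}

#' @rdname tidy.grip_cv
#' @method tidy ovr_svm
#' @export
tidy.ovr_svm <- function(x, ...) {
  tibble::tibble(
    class = x$classes,
    bias = x$bias,
    weight_norm = sqrt(rowSums(x$weights^2))
  )
}

#' @rdname tidy.grip_cv
#' @method glance ovr_svm
#' @export
glance.ovr_svm <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), d = x$d, C = x$C)
}
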