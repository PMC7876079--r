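#' Train an SVM on a precomputed kernel matrix
#'
#' Fits a support vector machine (C-classification or epsilon-regression)
#' directly on an N x N kernel matrix, so any of the package's kernels — or a
#' user-supplied one — can drive prediction. Binary and multi-class
#' classification (one-vs-one) and regression are supported; the fit is
#' deterministic given its inputs.
#'
#' @param K a `kernel_matrix` over the training samples.
#' @param y labels (factor / character / logical) or numeric targets, aligned
#'   with the rows of `K`.
#' @param task `"classification"` or `"regression"`.
#' @param cost SVM cost parameter C (> 0).
#' @param epsilon epsilon of the regression tube (regression only).
#' @return An object of class `kernel_svm` with the dual coefficients,
#'   support indices, intercept, training sample ids and kernel provenance.
#' @export
svm_train <- function(K, y, task = c("classification", "regression"),
                      cost = 1, epsilon = 0.1) {
  task <- match.arg(task)
  if (!is.numeric(cost) || length(cost) != 1 || cost <= 0)
    stop("cost must be a single positive number")
  M <- kmat(K)
  if (nrow(M) != length(y))
    stop("y (length ", length(y), ") not aligned with kernel (",
         nrow(M), " samples)")
  if (task == "classification") {
    y <- factor(y)
    if (nlevels(y) < 2)
      stop("classification needs at least two classes, got only '",
           levels(y), "'")
    # shrinking is disabled: the shrinking heuristic can stall far from the
    # optimum on precomputed (rank-deficient) kernel matrices
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(M), y,
                         type = "C-svc", C = cost, shrinking = FALSE)
  } else {
    y <- as.numeric(y)
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(M), y,
                         type = "eps-svr", C = cost, epsilon = epsilon,
                         shrinking = FALSE)
  }
  sv <- unlist(kernlab::alphaindex(fit))
  structure(list(fit = fit,
                 task = task,
                 cost = cost,
                 epsilon = if (task == "regression") epsilon else NULL,
                 n_classes = if (task == "classification") nlevels(y) else NULL,
                 levels = if (task == "classification") levels(y) else NULL,
                 coefficients = unlist(kernlab::coef(fit)),
                 support = sv,
                 intercept = kernlab::b(fit),
                 sample_ids = rownames(M),
                 kernel_meta = attr(K, "kernel_meta")),
            class = "kernel_svm")
}

#' @export
print.kernel_svm <- function(x, ...) {
  cat(sprintf("Kernel SVM (%s), cost = %g\n", x$task, x$cost))
  km <- x$kernel_meta
  if (!is.null(km$kernel)) cat("  kernel:", km$kernel, "\n")
  cat(sprintf("  training samples: %d   support vectors: %d\n",
              length(x$sample_ids), length(unique(x$support))))
  invisible(x)
}

#' Predict from a kernel SVM
#'
#' Evaluates the fitted decision function on new samples, given the
#' rectangular kernel block between the new samples (rows) and the model's
#' training samples (columns, in training order).
#'
#' @param model a `kernel_svm`.
#' @param K_test_train numeric matrix, n_new x n_train; if it has column
#'   names, they must match the training sample ids in order.
#' @param type `"response"` (labels / numeric predictions) or `"decision"`.
#' @return predictions: factor (classification) or numeric (regression).
#' @export
svm_predict <- function(model, K_test_train, type = c("response", "decision")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "kernel_svm"))
  B <- as.matrix(K_test_train)
  if (ncol(B) != length(model$sample_ids))
    stop("kernel block has ", ncol(B), " columns but the model was trained ",
         "on ", length(model$sample_ids), " samples")
  if (!is.null(colnames(B)) &&
      !identical(colnames(B), model$sample_ids))
    stop("kernel block columns are not aligned with the training samples")
  sv <- sort(unique(unlist(kernlab::alphaindex(model$fit))))
  Kb <- kernlab::as.kernelMatrix(B[, sv, drop = FALSE])
  out <- kernlab::predict(model$fit, Kb,
                          type = if (type == "decision") "decision"
                          else "response")
  if (type == "response" && model$task == "classification")
    out <- factor(as.character(out), levels = model$levels)
  if (type == "response" && model$task == "regression") out <- as.numeric(out)
  out
}

#' @export
predict.kernel_svm <- function(object, K_test_train, ...) {
  svm_predict(object, K_test_train, ...)
}

#' Fitted values on the training kernel
#' @param object a `kernel_svm`.
#' @param K the training `kernel_matrix` used to fit the model.
#' @param ... unused.
#' @return predictions for the training samples.
#' @export
fitted_values <- function(object, K, ...) {
  svm_predict(object, kmat(K))
}
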