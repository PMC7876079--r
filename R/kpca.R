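#' Kernel principal components analysis
#'
#' Performs PCA in the feature space implied by a kernel: the kernel matrix
#' is double-centered and eigendecomposed, and the sample projections are the
#' eigenvectors scaled by the square roots of their eigenvalues, sorted by
#' decreasing eigenvalue. With the compositional linear kernel this
#' reproduces ordinary PCA scores of the clr matrix. Signs are fixed so that
#' the largest-magnitude entry of every component is positive.
#'
#' @param K a `kernel_matrix` (positive semi-definite).
#' @param n_components number of components to return (<= N - 1).
#' @return An object of class `kernel_pca` with elements `projections`
#'   (N x n_components), `eigenvalues` (all positive eigenvalues of the
#'   centered kernel, decreasing) and `explained` (their proportions).
#' @export
kpca <- function(K, n_components = 2) {
  M <- kmat(K)
  n <- nrow(M)
  if (n_components > n - 1)
    stop("n_components must be at most N - 1 = ", n - 1)
  Kc <- kmat(center_kernel(M))
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  lambda <- e$values[pos]
  V <- e$vectors[, pos, drop = FALSE]
  if (n_components > length(lambda)) {
    warning("only ", length(lambda), " positive eigenvalues; truncating ",
            "from ", n_components, " components")
    n_components <- length(lambda)
  }
  P <- V[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(n_components)]), n_components)
  for (j in seq_len(ncol(P))) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) P[, j] <- -P[, j]
  }
  rownames(P) <- rownames(M)
  colnames(P) <- paste0("PC", seq_len(ncol(P)))
  structure(list(projections = P,
                 eigenvalues = lambda,
                 explained = lambda / sum(lambda),
                 n_components = n_components,
                 kernel_meta = attr(K, "kernel_meta")),
            class = "kernel_pca")
}

#' @export
print.kernel_pca <- function(x, ...) {
  cat(sprintf("Kernel PCA: %d components over %d samples\n",
              x$n_components, nrow(x$projections)))
  k <- min(5, length(x$explained))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.kernel_pca <- function(x, components = c(1, 2), col = 1, pch = 19, ...) {
  P <- x$projections
  if (max(components) > ncol(P))
    stop("requested components not available")
  i <- components[1]; j <- components[2]
  plot(P[, i], P[, j], col = col, pch = pch,
       xlab = sprintf("PC%d (%.1f%%)", i, 100 * x$explained[i]),
       ylab = sprintf("PC%d (%.1f%%)", j, 100 * x$explained[j]), ...)
  invisible(x)
}
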