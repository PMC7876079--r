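#' Construct a kernel matrix object
#'
#' A kernel matrix is an N x N symmetric positive semi-definite similarity
#' matrix over samples. The object is a plain numeric matrix with sample ids
#' as dimnames, a `kernel_meta` attribute recording provenance (kernel name,
#' hyperparameters, preprocessing) and class `kernel_matrix`.
#'
#' @param values N x N numeric matrix.
#' @param sample_ids N sample identifiers aligned to rows and columns.
#' @param meta named list of provenance entries (e.g. `kernel`, `gamma`).
#' @param validate check symmetry (1e-10) and approximate PSD-ness.
#' @return A `kernel_matrix`.
#' @export
kernel_matrix <- function(values, sample_ids = NULL, meta = list(),
                          validate = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values))
    stop("kernel matrix must be square, got ",
         nrow(values), " x ", ncol(values))
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids in kernel matrix")
  dimnames(values) <- list(sample_ids, sample_ids)
  if (validate) {
    rep <- check_psd(values, tol = 1e-8)
    if (rep$symmetry_deviation > 1e-10)
      stop(sprintf("kernel matrix not symmetric (max |K - t(K)| = %.3g)",
                   rep$symmetry_deviation))
  }
  structure(values, kernel_meta = meta, class = c("kernel_matrix", "matrix"))
}

# strip class/attributes to a plain matrix
kmat <- function(K) {
  m <- unclass(K)
  attr(m, "kernel_meta") <- NULL
  m
}

#' Provenance metadata of a kernel matrix
#'
#' @param K a `kernel_matrix`.
#' @return named list (kernel name, hyperparameters, preprocessing record).
#' @export
kernel_meta <- function(K) attr(K, "kernel_meta")

#' @export
print.kernel_matrix <- function(x, ...) {
  meta <- attr(x, "kernel_meta")
  nm <- if (!is.null(meta$kernel)) meta$kernel else "unnamed"
  cat(sprintf("Kernel matrix '%s': %d x %d\n", nm, nrow(x), ncol(x)))
  hp <- meta[setdiff(names(meta), c("kernel", "preprocessing"))]
  if (length(hp))
    cat("  hyperparameters:",
        paste(names(hp), unlist(lapply(hp, format)), sep = "=", collapse = ", "),
        "\n")
  if (!is.null(meta$preprocessing))
    cat("  preprocessing:", paste(meta$preprocessing, collapse = " -> "), "\n")
  cat(sprintf("  value range: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Positive semi-definiteness check
#'
#' Reports the maximum symmetry deviation and the extreme eigenvalues of a
#' square matrix. The matrix passes if it is symmetric within `tol` and its
#' minimum eigenvalue is not below `-tol` times the maximum eigenvalue
#' (relative criterion, so kernels of any scale are judged alike).
#'
#' @param K square numeric matrix.
#' @param tol tolerance (default 1e-8).
#' @return A list of class `psd_report` with elements `pass`, `symmetric`,
#'   `symmetry_deviation`, `min_eigenvalue`, `max_eigenvalue`.
#' @export
check_psd <- function(K, tol = 1e-8) {
  K <- kmat(K)
  if (nrow(K) != ncol(K))
    stop("check_psd expects a square matrix, got ", nrow(K), " x ", ncol(K))
  sym_dev <- max(abs(K - t(K)))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  max_ev <- max(ev)
  min_ev <- min(ev)
  pass <- (sym_dev <= tol) && (min_ev >= -tol * max(max_ev, tol))
  structure(list(pass = pass,
                 symmetric = sym_dev <= tol,
                 symmetry_deviation = sym_dev,
                 min_eigenvalue = min_ev,
                 max_eigenvalue = max_ev,
                 tol = tol),
            class = "psd_report")
}

#' @export
print.psd_report <- function(x, ...) {
  cat(sprintf("PSD check: %s (sym dev %.3g, eigenvalues [%.3g, %.3g], tol %g)\n",
              if (x$pass) "PASS" else "FAIL",
              x$symmetry_deviation, x$min_eigenvalue, x$max_eigenvalue, x$tol))
  invisible(x)
}

#' Double-center a kernel matrix
#'
#' Centers the implicit feature map at its mean: K_c = K - row means -
#' column means + grand mean, i.e. `J K J` with `J = I - 11'/N`. Required
#' before eigendecomposition in kernel PCA. Idempotent.
#'
#' @param K a `kernel_matrix` or plain square matrix.
#' @return A centered `kernel_matrix` (row and column sums are 0).
#' @export
center_kernel <- function(K) {
  meta <- attr(K, "kernel_meta")
  M <- kmat(K)
  rm <- rowMeans(M)
  cm <- colMeans(M)
  g <- mean(M)
  C <- M - outer(rm, rep(1, ncol(M))) - outer(rep(1, nrow(M)), cm) + g
  meta$preprocessing <- c(meta$preprocessing, "centered")
  kernel_matrix(C, rownames(M), meta = meta, validate = FALSE)
}

#' Cosine-normalize a kernel matrix
#'
#' Rescales so that every sample has unit self-similarity:
#' K'(i,j) = K(i,j) / sqrt(K(i,i) K(j,j)). Puts kernels of different scales
#' on a comparable footing, e.g. before multiple kernel learning.
#'
#' @param K a `kernel_matrix` with strictly positive diagonal.
#' @return A `kernel_matrix` with unit diagonal.
#' @export
cosine_normalize_kernel <- function(K) {
  meta <- attr(K, "kernel_meta")
  M <- kmat(K)
  d <- diag(M)
  if (any(d <= 0))
    stop("non-positive diagonal entries for sample(s): ",
         paste(rownames(M)[d <= 0], collapse = ", "))
  s <- 1 / sqrt(d)
  M <- M * tcrossprod(s)
  diag(M) <- 1
  meta$preprocessing <- c(meta$preprocessing, "cosine-normalized")
  kernel_matrix(M, rownames(M), meta = meta, validate = FALSE)
}

#' Similarity between kernel matrices
#'
#' Pairwise Frobenius cosine between double-centered kernel matrices over the
#' same samples. Used to compare the views different kernels or different
#' body sites give of the same individuals; values lie in [-1, 1] with 1 on
#' the diagonal.
#'
#' @param Ks list of `kernel_matrix` objects sharing identical, identically
#'   ordered sample ids.
#' @return M x M numeric similarity matrix (names from list names).
#' @export
kernel_matrix_similarity <- function(Ks) {
  stopifnot(is.list(Ks), length(Ks) >= 1)
  ids <- rownames(Ks[[1]])
  for (a in seq_along(Ks)) {
    if (!identical(rownames(Ks[[a]]), ids))
      stop("kernel matrix ", a, " has sample_ids not aligned with matrix 1")
  }
  Cs <- lapply(Ks, function(K) kmat(center_kernel(K)))
  nrm <- vapply(Cs, function(M) sqrt(sum(M * M)), numeric(1))
  M <- length(Cs)
  S <- diag(1, M)
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      if (b <= a) next
      S[a, b] <- S[b, a] <- sum(Cs[[a]] * Cs[[b]]) / (nrm[a] * nrm[b])
    }
  }
  nm <- names(Ks)
  if (is.null(nm)) nm <- paste0("K", seq_len(M))
  dimnames(S) <- list(nm, nm)
  S
}
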