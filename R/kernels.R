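#' Compositional linear kernel (cLin)
#'
#' The linear kernel evaluated in clr coordinates:
#' cLin(x_i, x_j) = sum_k clr(x_i)_k clr(x_j)_k. Being a plain inner product
#' of clr-transformed samples it is positive semi-definite, invariant to
#' per-sample rescaling of the raw abundances, and supports retrieval of
#' taxa importances from the separating hyperplane of a linear SVM.
#'
#' @param table an `abundance_table` (or matrix) with strictly positive
#'   entries; apply [replace_zeros()] first when zeros are present.
#' @return A `kernel_matrix`.
#' @export
clin_kernel <- function(table) {
  table <- as_abundance(table)
  Z <- clr_transform(table)
  K <- tcrossprod(Z)
  kernel_matrix(K, rownames(Z),
                meta = list(kernel = "clin",
                            preprocessing = c(table$provenance, "clr")),
                validate = FALSE)
}

#' Aitchison-RBF kernel (cRBF)
#'
#' Gaussian kernel on the Aitchison geometry of the simplex:
#' cRBF(x_i, x_j) = exp(-gamma * ||clr(x_i) - clr(x_j)||^2), i.e. an RBF
#' kernel whose squared distance is the squared Aitchison distance between
#' compositions. `gamma` is a bandwidth hyperparameter to be tuned
#' (see [gamma_median_heuristic()] for a data-driven starting point).
#'
#' @inheritParams clin_kernel
#' @param gamma positive bandwidth.
#' @return A `kernel_matrix` with unit diagonal.
#' @export
crbf_kernel <- function(table, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a single positive number")
  table <- as_abundance(table)
  Z <- clr_transform(table)
  D2 <- squared_distances(Z)
  K <- exp(-gamma * D2)
  kernel_matrix(K, rownames(Z),
                meta = list(kernel = "crbf", gamma = gamma,
                            preprocessing = c(table$provenance, "clr")),
                validate = FALSE)
}

# pairwise squared Euclidean distances between rows, clipped at 0
squared_distances <- function(X) {
  sq <- rowSums(X * X)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  (D2 + t(D2)) / 2
}

#' Median-heuristic RBF bandwidth
#'
#' Returns 1 / median of the nonzero pairwise squared Euclidean distances
#' between rows of a feature matrix — a standard starting value for the
#' gamma of RBF-type kernels.
#'
#' @param features numeric matrix (e.g. clr coordinates).
#' @return positive scalar.
#' @export
gamma_median_heuristic <- function(features) {
  D2 <- squared_distances(as.matrix(features))
  m <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(m) || m <= 0) return(1)
  1 / m
}

#' Jensen-Shannon kernel (JSK)
#'
#' One minus the Jensen-Shannon divergence between samples viewed as
#' probability distributions over taxa (natural logarithm). Defined for
#' relative frequencies; count tables are closed to row proportions with a
#' warning. Zeros are handled with the convention 0*log(0/a) = 0. Values lie
#' in [1 - log(2), 1] with unit diagonal.
#'
#' @param table an `abundance_table` (or matrix) of relative abundances
#'   (counts are auto-normalized with a warning).
#' @return A `kernel_matrix`.
#' @export
jsk_kernel <- function(table) {
  table <- as_abundance(table)
  if (any(table$values < 0)) stop("negative entries are not permitted")
  if (table$scale != "relative") {
    warning("jsk_kernel expects relative frequencies; ",
            "normalizing rows to proportions")
    table <- relative_abundance(table)
  }
  P <- table$values
  n <- nrow(P)
  # JSD(p, q) = H((p+q)/2) - (H(p) + H(q))/2 with H the Shannon entropy (nats)
  ent <- function(M) {
    L <- M * log(M)
    L[M == 0] <- 0
    -rowSums(L)
  }
  h <- ent(P)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Mi <- (P[rep(i, n - i + 1), , drop = FALSE] +
             P[i:n, , drop = FALSE]) / 2
    hm <- ent(Mi)
    jsd <- hm - (h[i] + h[i:n]) / 2
    K[i, i:n] <- 1 - jsd
    K[i:n, i] <- K[i, i:n]
  }
  diag(K) <- 1
  K[K > 1] <- 1
  lo <- 1 - log(2)
  K[K < lo] <- lo
  kernel_matrix(K, rownames(P),
                meta = list(kernel = "jsk",
                            preprocessing = table$provenance),
                validate = FALSE)
}

#' Quantitative Jaccard (Ruzicka) kernel
#'
#' The Ruzicka similarity between abundance vectors:
#' qJac(x_i, x_j) = sum_k min(x_ik, x_jk) / sum_k max(x_ik, x_jk),
#' the quantitative extension of the Jaccard index. Zeros need no special
#' treatment; values lie in [0, 1] with unit diagonal for nonzero samples.
#' A pair of all-zero samples is assigned similarity 1 (identical samples)
#' with a warning.
#'
#' @param table an `abundance_table` (or matrix) of non-negative abundances.
#' @return A `kernel_matrix`.
#' @export
qjac_kernel <- function(table) {
  table <- as_abundance(table)
  X <- table$values
  if (any(X < 0)) stop("negative entries are not permitted")
  n <- nrow(X)
  rs <- rowSums(X)
  K <- matrix(0, n, n)
  warned <- FALSE
  for (i in seq_len(n)) {
    # sum(min) = (S_i + S_j - sum|x_i - x_j|)/2 ; sum(max) = (S_i + S_j + ...)/2
    A <- abs(X[i:n, , drop = FALSE] -
               X[rep(i, n - i + 1), , drop = FALSE])
    sad <- rowSums(A)
    tot <- rs[i] + rs[i:n]
    smin <- (tot - sad) / 2
    smax <- (tot + sad) / 2
    v <- ifelse(smax == 0, 1, smin / smax)
    if (any(smax == 0)) warned <- TRUE
    K[i, i:n] <- v
    K[i:n, i] <- v
  }
  if (warned)
    warning("pair(s) of all-zero samples assigned similarity 1 by convention")
  diag(K)[rs > 0] <- 1
  kernel_matrix(K, rownames(X),
                meta = list(kernel = "qjac",
                            preprocessing = table$provenance),
                validate = FALSE)
}

#' Compute a sample kernel by name
#'
#' Convenience dispatcher over the four sample-level kernels with the
#' preprocessing each expects: `clin`/`crbf` add a pseudocount to all entries
#' (zero handling for the log-ratio transform); `jsk`/`qjac` optionally apply
#' cumulative sum scaling first.
#'
#' @param table an `abundance_table` or matrix.
#' @param kernel one of `"clin"`, `"crbf"`, `"jsk"`, `"qjac"`.
#' @param gamma bandwidth for `"crbf"` (default: median heuristic on the clr
#'   coordinates).
#' @param pseudocount pseudocount for the compositional kernels.
#' @param css_quantile if non-NULL, CSS-normalize before `jsk`/`qjac`.
#' @return A `kernel_matrix`.
#' @export
compute_kernel <- function(table, kernel = c("clin", "crbf", "jsk", "qjac"),
                           gamma = NULL, pseudocount = 0.5,
                           css_quantile = NULL) {
  kernel <- match.arg(kernel)
  table <- as_abundance(table)
  if (kernel %in% c("clin", "crbf")) {
    tab <- replace_zeros(table, pseudocount)
    if (kernel == "clin") return(clin_kernel(tab))
    if (is.null(gamma)) gamma <- gamma_median_heuristic(clr_transform(tab))
    return(crbf_kernel(tab, gamma))
  }
  if (!is.null(css_quantile)) table <- css_normalize(table, css_quantile)
  if (kernel == "jsk") {
    return(suppressWarnings(jsk_kernel(relative_abundance(table))))
  }
  qjac_kernel(table)
}
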