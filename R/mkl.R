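#' Bundle kernel matrices over the same individuals
#'
#' @param matrices list of `kernel_matrix` objects with identical,
#'   identically ordered sample ids (e.g. one per body site or data source).
#' @param labels optional character names for the sources.
#' @return An object of class `kernel_bank`.
#' @export
kernel_bank <- function(matrices, labels = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  ids <- rownames(matrices[[1]])
  for (z in seq_along(matrices)) {
    if (!identical(rownames(matrices[[z]]), ids))
      stop("kernel matrix ", z, " is not aligned with matrix 1 ",
           "(sample ids differ or are reordered)")
  }
  if (is.null(labels)) {
    labels <- names(matrices)
    if (is.null(labels)) labels <- paste0("K", seq_along(matrices))
  }
  names(matrices) <- labels
  structure(list(matrices = matrices, labels = labels, sample_ids = ids),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("Kernel bank: %d matrices over %d samples\n",
              length(x$matrices), length(x$sample_ids)))
  cat("  sources:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' MKL weight vector
#'
#' Non-negative coefficients beta_1..beta_M over the matrices of a kernel
#' bank. When `normalized`, the betas are rescaled to sum to 1 (the scale of
#' the consensus kernel is otherwise redundant with the SVM cost).
#'
#' @param betas non-negative numeric vector.
#' @param labels optional source names.
#' @param normalized rescale to the unit simplex (default TRUE).
#' @return An object of class `mkl_weights`.
#' @export
mkl_weights <- function(betas, labels = NULL, normalized = TRUE) {
  betas <- as.numeric(betas)
  if (any(betas < 0)) stop("all betas must be non-negative")
  if (all(betas == 0)) stop("at least one beta must be positive")
  if (normalized) betas <- betas / sum(betas)
  if (!is.null(labels)) names(betas) <- labels
  structure(list(betas = betas, normalized = normalized),
            class = "mkl_weights")
}

#' @export
print.mkl_weights <- function(x, ...) {
  cat("MKL weights:", paste(signif(x$betas, 4), collapse = ", "), "\n")
  if (!is.null(names(x$betas)))
    cat("  sources:", paste(names(x$betas), collapse = ", "), "\n")
  invisible(x)
}

#' Consensus kernel by weighted combination
#'
#' K* = sum_z beta_z K_z. A non-negative combination of positive
#' semi-definite matrices, so the consensus kernel is itself a valid kernel.
#'
#' @param bank a `kernel_bank`.
#' @param w an `mkl_weights` (or bare non-negative numeric vector) of length
#'   equal to the number of matrices.
#' @return A `kernel_matrix`.
#' @export
mkl_combine <- function(bank, w) {
  stopifnot(inherits(bank, "kernel_bank"))
  if (!inherits(w, "mkl_weights")) w <- mkl_weights(w, normalized = FALSE)
  betas <- w$betas
  M <- length(bank$matrices)
  if (length(betas) != M)
    stop("length of betas (", length(betas),
         ") does not match number of kernels (", M, ")")
  K <- betas[1] * kmat(bank$matrices[[1]])
  if (M > 1) for (z in 2:M) K <- K + betas[z] * kmat(bank$matrices[[z]])
  kernel_matrix(K, bank$sample_ids,
                meta = list(kernel = "mkl-consensus",
                            betas = stats::setNames(betas, bank$labels),
                            sources = bank$labels),
                validate = FALSE)
}

# cosine-normalize every matrix of a bank
normalize_bank <- function(bank) {
  kernel_bank(lapply(bank$matrices, cosine_normalize_kernel), bank$labels)
}

#' Unsupervised consensus weights
#'
#' Chooses the beta coefficients that maximize the average similarity of the
#' consensus kernel K* with all the individual matrices: beta is proportional
#' to the leading eigenvector of the M x M Frobenius-cosine similarity matrix
#' of the centered, cosine-normalized kernels (non-negative by
#' Perron-Frobenius when the similarity matrix is non-negative), normalized
#' to sum to 1.
#'
#' @param bank a `kernel_bank` with M >= 2 matrices.
#' @return An `mkl_weights` with an attribute `similarity` holding the M x M
#'   matrix.
#' @export
consensus_unsupervised <- function(bank) {
  stopifnot(inherits(bank, "kernel_bank"))
  M <- length(bank$matrices)
  if (M < 2) stop("consensus weights need at least 2 kernel matrices")
  nb <- normalize_bank(bank)
  S <- kernel_matrix_similarity(nb$matrices)
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  if (any(v < 0)) {
    if (any(v < -1e-8))
      warning("leading eigenvector has negative entries; clipping at 0")
    v[v < 0] <- 0
  }
  w <- mkl_weights(v, labels = bank$labels, normalized = TRUE)
  attr(w, "similarity") <- S
  w
}

# all M-part compositions of `parts` units, as rows summing to 1
simplex_grid <- function(M, step) {
  parts <- round(1 / step)
  if (abs(parts * step - 1) > 1e-8)
    stop("grid step must divide 1")
  if (M == 1) return(matrix(1, 1, 1))
  rec <- function(m, left) {
    if (m == 1) return(matrix(left, 1, 1))
    do.call(rbind, lapply(0:left, function(i) {
      cbind(i, rec(m - 1, left - i))
    }))
  }
  rec(M, parts) / parts
}

#' Supervised MKL by simplex grid search
#'
#' Optimizes the kernel weights beta on the unit simplex, jointly with the
#' SVM cost, by cross-validated performance of the SVM trained on the
#' consensus kernel K*(beta): accuracy for classification, negative
#' normalized mean squared error for regression. The bank is cosine-
#' normalized first so the betas are comparable across kernels of different
#' scales. Ties are broken toward the most uniform beta, then toward the
#' smaller cost (stronger regularization).
#'
#' @param bank a `kernel_bank` over the training samples.
#' @param y labels (factor / character) or numeric targets aligned with the
#'   bank's samples.
#' @param task `"classification"` or `"regression"`.
#' @param grid_resolution simplex step; default 0.1 for M <= 3, 0.25
#'   otherwise.
#' @param cost_grid SVM cost candidates.
#' @param folds,repeats inner cross-validation design (default 5 x 5).
#' @param seed integer seed controlling the fold assignments.
#' @param normalize cosine-normalize the bank before combining.
#' @return A list of class `mkl_fit`: `weights` (`mkl_weights`), `cost`,
#'   `score` (mean CV score of the winner) and `grid` (all candidates with
#'   their scores).
#' @export
mkl_optimize_supervised <- function(bank, y,
                                    task = c("classification", "regression"),
                                    grid_resolution = NULL,
                                    cost_grid = c(0.1, 1, 10),
                                    folds = 5, repeats = 5, seed = 1,
                                    normalize = TRUE) {
  stopifnot(inherits(bank, "kernel_bank"))
  task <- match.arg(task)
  M <- length(bank$matrices)
  n <- length(bank$sample_ids)
  if (length(y) != n) stop("y must be aligned with the bank's samples")
  if (n < folds) stop("fewer samples (", n, ") than folds (", folds, ")")
  if (M == 1) {
    return(structure(list(weights = mkl_weights(1, bank$labels),
                          cost = cost_grid[1], score = NA_real_,
                          grid = NULL),
                     class = "mkl_fit"))
  }
  if (is.null(grid_resolution)) grid_resolution <- if (M <= 3) 0.1 else 0.25
  nb <- if (normalize) normalize_bank(bank) else bank
  B <- simplex_grid(M, grid_resolution)
  fold_sets <- make_folds(y, task, folds, repeats, seed)
  res <- vector("list", nrow(B))
  for (b in seq_len(nrow(B))) {
    beta <- B[b, ]
    Kb <- kmat(mkl_combine(nb, mkl_weights(beta, normalized = FALSE)))
    sc <- vapply(cost_grid, function(cost)
      cv_score(Kb, y, task, cost, fold_sets), numeric(1))
    res[[b]] <- data.frame(candidate = b, cost = cost_grid, score = sc)
  }
  grid <- do.call(rbind, res)
  best_score <- max(grid$score)
  tied <- grid[grid$score >= best_score - 1e-10 * max(1, abs(best_score)), ]
  # most uniform beta first, then smaller cost
  unif <- apply(B[tied$candidate, , drop = FALSE], 1,
                function(v) sum((v - 1 / M)^2))
  tied <- tied[order(unif, tied$cost), ]
  pick <- tied[1, ]
  structure(list(weights = mkl_weights(B[pick$candidate, ], bank$labels),
                 cost = pick$cost, score = pick$score,
                 grid = cbind(grid,
                              as.data.frame(B[grid$candidate, , drop = FALSE],
                                            col.names = bank$labels))),
            class = "mkl_fit")
}

#' @export
print.mkl_fit <- function(x, ...) {
  cat("Supervised MKL fit\n")
  print(x$weights)
  cat(sprintf("  cost: %g   CV score: %s\n", x$cost,
              if (is.na(x$score)) "NA" else signif(x$score, 4)))
  invisible(x)
}

#' Spatio-temporal consensus kernel
#'
#' Handles the temporal dimension first — one multivariate functional kernel
#' (fLin' or fRBF') per site over the individuals' time series — and then
#' integrates the spatial dimension by multiple kernel learning over the
#' per-site matrices.
#'
#' @param series_by_site named list mapping site -> `time_series_table`,
#'   all covering the same individuals.
#' @param kernel `"flin"` or `"frbf"`.
#' @param gamma bandwidth for `"frbf"` (single value shared across sites;
#'   default median heuristic per site).
#' @param weights an `mkl_weights`, `"consensus"` (unsupervised, default) or
#'   `"supervised"` (requires `y`).
#' @param y,task labels and task for supervised weighting.
#' @param ... passed to [mkl_optimize_supervised()].
#' @return A `kernel_matrix` with the betas recorded in its metadata.
#' @export
spatiotemporal_kernel <- function(series_by_site, kernel = c("flin", "frbf"),
                                  gamma = NULL, weights = "consensus",
                                  y = NULL,
                                  task = c("classification", "regression"),
                                  ...) {
  kernel <- match.arg(kernel)
  stopifnot(is.list(series_by_site), length(series_by_site) >= 1)
  ids <- dimnames(series_by_site[[1]]$values)[[1]]
  for (s in names(series_by_site)) {
    sids <- dimnames(series_by_site[[s]]$values)[[1]]
    missing <- setdiff(ids, sids)
    extra <- setdiff(sids, ids)
    if (length(missing) || length(extra))
      stop("site '", s, "' does not cover the same individuals: ",
           if (length(missing)) paste("missing", paste(missing, collapse = ", "))
           else paste("extra", paste(extra, collapse = ", ")))
  }
  mats <- lapply(series_by_site, function(tst) {
    if (kernel == "flin") flin_multivariate(tst)
    else frbf_multivariate(tst, gamma = gamma)
  })
  bank <- kernel_bank(mats, names(series_by_site))
  if (length(mats) == 1) return(mats[[1]])
  if (inherits(weights, "mkl_weights")) {
    w <- weights
    K <- mkl_combine(bank, w)
  } else if (identical(weights, "consensus")) {
    w <- consensus_unsupervised(bank)
    K <- mkl_combine(normalize_bank(bank), w)
  } else if (identical(weights, "supervised")) {
    if (is.null(y)) stop("supervised weighting requires y")
    fit <- mkl_optimize_supervised(bank, y, task = match.arg(task), ...)
    w <- fit$weights
    K <- mkl_combine(normalize_bank(bank), w)
  } else stop("weights must be an mkl_weights, 'consensus' or 'supervised'")
  K
}
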