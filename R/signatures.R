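#' Microbial signature from a linear-kernel SVM
#'
#' Recovers the hyperplane normal w of an SVM trained with the compositional
#' linear kernel (or the functional linear kernel) from its dual expansion,
#' w = sum over support samples of coef_i * features_i (the kernlab dual
#' coefficients already carry the label factor for classification, and are
#' alpha - alpha* for regression), and reports the taxa importances
#' (w_k)^2 converted to relative values summing to 1. Importances are to be
#' read on the clr scale, i.e. after the log-ratio transform.
#'
#' Signatures are only defined for linear kernels; models trained with
#' non-linear kernels (cRBF, fRBF, JSK, qJac) are rejected.
#'
#' @param model a `kernel_svm` trained on a cLin (or fLin) kernel; binary
#'   classification or regression.
#' @param features the exact N x D feature matrix whose row inner products
#'   built the training kernel (the clr matrix for cLin; see
#'   [functional_features()] for fLin).
#' @return An object of class `microbial_signature`: a data frame with
#'   columns `taxon_id`, `importance`, `rank`, plus attributes `w` (the
#'   hyperplane normal), `w2` (unnormalized squared weights), and `mode`.
#' @export
signature_from_clin_svm <- function(model, features) {
  stopifnot(inherits(model, "kernel_svm"))
  kname <- model$kernel_meta$kernel
  if (is.null(kname) || !kname %in% c("clin", "flin", "linear"))
    stop("signatures require a linear kernel (cLin or fLin); model was ",
         "trained with '", if (is.null(kname)) "unknown" else kname, "'")
  if (model$task == "classification" && model$n_classes != 2)
    stop("signatures are defined for binary classification or regression")
  features <- as.matrix(features)
  if (nrow(features) != length(model$sample_ids))
    stop("features (", nrow(features), " rows) not aligned with the ",
         length(model$sample_ids), " training samples")
  if (!is.null(rownames(features)) &&
      !identical(rownames(features), model$sample_ids))
    stop("feature rows are not in training-sample order")
  w <- drop(crossprod(features[model$support, , drop = FALSE],
                      model$coefficients))
  new_signature(w, colnames(features), mode = "single",
                provenance = list(kernel = kname, cost = model$cost,
                                  task = model$task))
}

# build a microbial_signature from a weight vector
new_signature <- function(w, taxon_ids, mode, provenance = list(),
                          w2 = NULL) {
  if (is.null(w2)) w2 <- w^2
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_along(w2))
  imp <- w2 / sum(w2)
  df <- data.frame(taxon_id = taxon_ids, importance = imp,
                   rank = rank(-imp, ties.method = "min"),
                   stringsAsFactors = FALSE)
  structure(df, w = w, w2 = w2, mode = mode, provenance = provenance,
            class = c("microbial_signature", "data.frame"))
}

#' @export
print.microbial_signature <- function(x, n = 10, ...) {
  cat(sprintf("Microbial signature (%s): %d taxa\n",
              attr(x, "mode"), nrow(x)))
  o <- order(-x$importance, x$taxon_id)
  top <- x[o[seq_len(min(n, nrow(x)))], , drop = FALSE]
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Aggregate signatures across sites
#'
#' Global importance of taxon k across M sampled sites: the beta-weighted sum
#' of its unnormalized partial importances (w_k)^2 per site, using the MKL
#' coefficients, then converted to relative values. Sites must have been
#' modeled with the linear kernel.
#'
#' @param site_signatures list of `microbial_signature` objects (one per
#'   site) or of raw unnormalized w^2 vectors named by taxon.
#' @param betas an `mkl_weights` (or numeric vector) aligned with the sites.
#' @return A `microbial_signature` with `mode = "spatial"`.
#' @export
signature_spatial_aggregate <- function(site_signatures, betas) {
  stopifnot(is.list(site_signatures), length(site_signatures) >= 1)
  if (inherits(betas, "mkl_weights")) betas <- betas$betas
  if (length(betas) != length(site_signatures))
    stop("betas (", length(betas), ") not aligned with ",
         length(site_signatures), " site signatures")
  parts <- lapply(site_signatures, function(s) {
    if (inherits(s, "microbial_signature"))
      stats::setNames(attr(s, "w2"), s$taxon_id)
    else if (is.numeric(s)) s
    else stop("site signatures must be microbial_signature objects or ",
              "named numeric vectors")
  })
  taxa <- unique(unlist(lapply(parts, names)))
  same <- all(vapply(parts, function(p) identical(sort(names(p)), sort(taxa)),
                     logical(1)))
  if (!same)
    warning("taxon sets differ across sites; missing taxa filled with 0")
  g <- stats::setNames(numeric(length(taxa)), taxa)
  for (z in seq_along(parts)) {
    p <- parts[[z]]
    g[names(p)] <- g[names(p)] + betas[z] * p
  }
  new_signature(w = sqrt(g), taxon_ids = taxa, mode = "spatial",
                provenance = list(betas = betas), w2 = g)
}

#' Longitudinal signature from a functional linear SVM
#'
#' For a model trained with the multivariate discrete functional linear
#' kernel, the hyperplane normal lives in the flattened (taxon, time) space;
#' the global importance of taxon k is the sum over the T time points of its
#' partial squared weights, converted to relative values.
#'
#' @param model a `kernel_svm` trained with an fLin kernel.
#' @param features the flattened feature matrix that built the kernel
#'   (see [functional_features()]); columns taxon-major, T consecutive
#'   columns per taxon.
#' @param D,T number of taxa and of time points (default: from the model's
#'   kernel metadata).
#' @param taxon_ids optional D taxon names.
#' @return A `microbial_signature` with `mode = "longitudinal"`.
#' @export
signature_longitudinal <- function(model, features, D = NULL, T = NULL,
                                   taxon_ids = NULL) {
  lay <- model$kernel_meta$layout
  if (is.null(D)) D <- lay$D
  if (is.null(T)) T <- lay$T
  if (is.null(D) || is.null(T))
    stop("D and T must be supplied or present in the kernel metadata")
  base <- signature_from_clin_svm(model, features)
  w <- attr(base, "w")
  if (length(w) != D * T)
    stop("feature layout mismatch: ", length(w), " weights but D*T = ", D * T)
  w2 <- colSums(matrix(w^2, nrow = T))
  if (is.null(taxon_ids)) {
    cn <- colnames(as.matrix(features))
    taxon_ids <- if (!is.null(cn)) unique(sub("@t.*$", "", cn)) else NULL
    if (length(taxon_ids) != D) taxon_ids <- NULL
  }
  new_signature(w = sqrt(w2), taxon_ids = taxon_ids, mode = "longitudinal",
                provenance = list(kernel = "flin", D = D, T = T), w2 = w2)
}

#' Keep the top fraction of a signature
#'
#' Retains the ceiling(fraction * D) most important taxa and reports their
#' cumulative share of total importance. Ties at the cutoff are broken by
#' taxon id in lexical order, so the selection is deterministic.
#'
#' @param sig a `microbial_signature`.
#' @param fraction fraction of taxa to keep, in (0, 1].
#' @return list with `signature` (the subset, in decreasing importance) and
#'   `cumulative_importance` (their total relative importance).
#' @export
select_top_fraction <- function(sig, fraction = 0.05) {
  stopifnot(inherits(sig, "microbial_signature"))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  m <- ceiling(fraction * nrow(sig))
  o <- order(-sig$importance, sig$taxon_id)
  top <- sig[o[seq_len(m)], , drop = FALSE]
  rownames(top) <- NULL
  list(signature = top,
       cumulative_importance = sum(top$importance))
}

#' Average signatures across evaluation replicates
#'
#' Mean per-taxon relative importance over a list of replicate signatures,
#' with the standard error across replicates.
#'
#' @param sigs list of `microbial_signature` objects over the same taxa.
#' @return data frame with columns `taxon_id`, `importance` (mean), `se` and
#'   `rank`.
#' @export
average_signatures <- function(sigs) {
  stopifnot(is.list(sigs), length(sigs) >= 1)
  taxa <- sigs[[1]]$taxon_id
  M <- vapply(sigs, function(s) {
    if (!identical(s$taxon_id, taxa))
      stop("signatures are not over the same taxa in the same order")
    s$importance
  }, numeric(length(taxa)))
  M <- matrix(M, nrow = length(taxa))
  mean_imp <- rowMeans(M)
  se <- apply(M, 1, stats::sd) / sqrt(ncol(M))
  data.frame(taxon_id = taxa, importance = mean_imp, se = se,
             rank = rank(-mean_imp, ties.method = "min"),
             stringsAsFactors = FALSE)
}
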