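#' Cross-validation / replication configuration
#'
#' Describes the evaluation protocol: an outer random 80/20 train/test split
#' repeated `n_replicates` times to obtain an error distribution, with
#' hyperparameters tuned on each training set by `inner_folds`-fold
#' cross-validation repeated `inner_repeats` times. When `group_ids` are
#' given (e.g. litters of full sibs), no group is ever split across train
#' and test.
#'
#' @param outer_test_fraction fraction of samples held out (default 0.2).
#' @param n_replicates number of outer replicates (default 40).
#' @param inner_folds,inner_repeats inner CV design (default 5 x 5).
#' @param group_ids optional vector of group labels, one per sample.
#' @param seed integer master seed; every replicate derives its own seed
#'   deterministically from it.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_test_fraction = 0.2, n_replicates = 40,
                      inner_folds = 5, inner_repeats = 5,
                      group_ids = NULL, seed = 1) {
  if (outer_test_fraction <= 0 || outer_test_fraction >= 1)
    stop("outer_test_fraction must lie strictly inside (0, 1)")
  if (inner_folds < 2) stop("inner_folds must be at least 2")
  structure(list(outer_test_fraction = outer_test_fraction,
                 n_replicates = n_replicates,
                 inner_folds = inner_folds,
                 inner_repeats = inner_repeats,
                 group_ids = group_ids,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Train/test split, optionally grouped
#'
#' Draws a random test set of approximately `test_fraction` of the samples.
#' With `groups`, whole groups are assigned to one side or the other, so no
#' group ever spans both.
#'
#' @param n number of samples.
#' @param test_fraction fraction in (0, 1).
#' @param groups optional length-n group labels.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
split_train_test <- function(n, test_fraction = 0.2, groups = NULL, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly inside (0, 1)")
  set.seed(seed)
  target <- max(1, round(test_fraction * n))
  if (is.null(groups)) {
    test <- sort(sample.int(n, target))
  } else {
    if (length(groups) != n) stop("groups must have length n")
    gs <- sample(unique(as.character(groups)))
    sizes <- cumsum(vapply(gs, function(g) sum(groups == g), numeric(1)))
    k <- which(sizes >= target)[1]
    if (is.na(k)) k <- length(gs)
    if (k == length(gs)) k <- length(gs) - 1  # keep at least one train group
    if (k < 1)
      stop("group structure incompatible with test fraction: ",
           "cannot form non-empty train and test sets")
    test <- sort(which(as.character(groups) %in% gs[seq_len(k)]))
  }
  if (length(test) == 0 || length(test) == n)
    stop("degenerate split: empty train or test set")
  list(train = setdiff(seq_len(n), test), test = test)
}

# stratified (classification) or plain (regression) repeated folds;
# returns a list over repeats, each an integer fold-id vector of length n
make_folds <- function(y, task, folds, repeats, seed) {
  n <- length(y)
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    fid <- integer(n)
    if (task == "classification") {
      for (lv in unique(as.character(y))) {
        idx <- which(as.character(y) == lv)
        fid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    } else {
      fid <- sample(rep_len(seq_len(folds), n))
    }
    fid
  })
}

# mean cross-validated score (higher is better: accuracy, or -NMSE) of an
# SVM with the given cost on a plain kernel matrix
cv_score <- function(K, y, task, cost, fold_sets) {
  scores <- c()
  for (fid in fold_sets) {
    for (f in sort(unique(fid))) {
      tr <- which(fid != f)
      va <- which(fid == f)
      if (length(va) == 0 || length(tr) == 0) next
      s <- tryCatch({
        m <- svm_train(kernel_matrix(K[tr, tr, drop = FALSE],
                                     validate = FALSE),
                       y[tr], task = task, cost = cost)
        p <- svm_predict(m, K[va, tr, drop = FALSE])
        if (task == "classification") accuracy(y[va], p)
        else -nmse(y[va], as.numeric(p))
      }, error = function(e) NA_real_)
      scores <- c(scores, s)
    }
  }
  mean(scores, na.rm = TRUE)
}

#' Tune the SVM cost (and kernel bandwidth) by inner cross-validation
#'
#' Scores every candidate by repeated k-fold cross-validation on the given
#' kernel(s) and returns the winner; ties are broken toward the smaller cost
#' (stronger regularization), then the smaller gamma.
#'
#' @param K plain kernel matrix over the tuning samples (ignored when
#'   `kernels` is given).
#' @param y labels or targets.
#' @param task `"classification"` or `"regression"`.
#' @param cost_grid candidate costs.
#' @param kernels optional named list `gamma value (as character) -> kernel
#'   matrix` for joint (gamma, cost) tuning.
#' @param folds,repeats,seed inner CV design.
#' @return list with `cost`, `gamma` (NA when not tuned) and `score`.
#' @export
tune_svm <- function(K = NULL, y, task = c("classification", "regression"),
                     cost_grid = c(0.01, 0.1, 1, 10, 100),
                     kernels = NULL, folds = 5, repeats = 5, seed = 1) {
  task <- match.arg(task)
  if (length(cost_grid) == 0) stop("cost_grid must be non-empty")
  fold_sets <- make_folds(y, task, folds, repeats, seed)
  if (is.null(kernels)) kernels <- list(`NA` = K)
  cand <- expand.grid(gamma = names(kernels), cost = cost_grid,
                      stringsAsFactors = FALSE)
  cand$score <- mapply(function(g, cost)
    cv_score(kmat(kernels[[g]]), y, task, cost, fold_sets),
    cand$gamma, cand$cost)
  best <- max(cand$score, na.rm = TRUE)
  tied <- cand[!is.na(cand$score) &
                 cand$score >= best - 1e-10 * max(1, abs(best)), ]
  tied <- tied[order(tied$cost, suppressWarnings(as.numeric(tied$gamma))), ]
  list(cost = tied$cost[1],
       gamma = suppressWarnings(as.numeric(tied$gamma[1])),
       score = tied$score[1],
       grid = cand)
}

#' Replicated train/test evaluation with nested tuning
#'
#' The package's evaluation harness. For each replicate it (i) draws a fresh
#' train/test partition (grouped when `cv$group_ids` is set), (ii) tunes the
#' SVM cost — and the kernel bandwidth gamma when `kernel_fun` is supplied —
#' by repeated k-fold cross-validation using only the training block of the
#' kernel matrix, (iii) refits on the whole training set with the winning
#' hyperparameters, and (iv) scores the held-out test samples (accuracy, or
#' NMSE for regression). The test block of the kernel is touched only at
#' scoring time.
#'
#' For comparing longitudinal models against per-time-point models, pass
#' `time_ids`: rows are then individual-by-time samples, splits are grouped
#' by `cv$group_ids` (the individuals), and each test individual is scored on
#' a single randomly chosen time point.
#'
#' @param K a `kernel_matrix` over all samples (ignored when `kernel_fun`
#'   is given).
#' @param y labels or targets.
#' @param cv a [cv_config()].
#' @param task `"classification"` or `"regression"`.
#' @param cost_grid candidate SVM costs.
#' @param gamma_grid candidate bandwidths, used with `kernel_fun`.
#' @param kernel_fun optional function(gamma) returning the full N x N kernel
#'   matrix; computed once per gamma and cached across replicates (cache
#'   expensive features inside the closure).
#' @param time_ids optional per-row time labels enabling the
#'   one-random-time-point test protocol (requires `cv$group_ids`).
#' @return An object of class `eval_report`: per-replicate metric values and
#'   chosen hyperparameters, their median and dispersion, and the splits.
#' @export
replicate_evaluation <- function(K = NULL, y, cv = cv_config(),
                                 task = c("classification", "regression"),
                                 cost_grid = c(0.01, 0.1, 1, 10, 100),
                                 gamma_grid = NULL, kernel_fun = NULL,
                                 time_ids = NULL) {
  task <- match.arg(task)
  n <- length(y)
  if (!is.null(time_ids) && is.null(cv$group_ids))
    stop("the one-time-point test protocol requires cv$group_ids ",
         "(the individual of each row)")
  if (!is.null(cv$group_ids) && length(cv$group_ids) != n)
    stop("cv$group_ids must have one entry per sample")
  kernels <- NULL
  if (!is.null(kernel_fun)) {
    if (is.null(gamma_grid) || !length(gamma_grid))
      stop("kernel_fun requires a non-empty gamma_grid")
    kernels <- lapply(gamma_grid, function(g) kmat(kernel_fun(g)))
    names(kernels) <- as.character(gamma_grid)
  } else {
    if (is.null(K)) stop("either K or kernel_fun must be supplied")
    kernels <- list(`NA` = kmat(K))
    if (nrow(kernels[[1]]) != n) stop("K not aligned with y")
  }
  results <- vector("list", cv$n_replicates)
  splits <- vector("list", cv$n_replicates)
  for (r in seq_len(cv$n_replicates)) {
    seed_r <- cv$seed + 7919L * r
    sp <- split_train_test(n, cv$outer_test_fraction, cv$group_ids, seed_r)
    if (!is.null(cv$group_ids) &&
        length(intersect(cv$group_ids[sp$train], cv$group_ids[sp$test])))
      stop("internal error: a group spans train and test")
    tr <- sp$train
    te <- sp$test
    if (!is.null(time_ids)) {
      set.seed(seed_r + 1L)
      pick <- unlist(lapply(split(te, as.character(cv$group_ids[te])),
                            function(rows) rows[sample.int(length(rows), 1)]),
                     use.names = FALSE)
      te <- sort(pick)
    }
    sub <- lapply(kernels, function(M)
      kernel_matrix(M[tr, tr, drop = FALSE], validate = FALSE))
    tn <- tune_svm(y = y[tr], task = task, cost_grid = cost_grid,
                   kernels = sub, folds = cv$inner_folds,
                   repeats = cv$inner_repeats, seed = seed_r + 2L)
    gkey <- if (is.na(tn$gamma)) "NA" else as.character(tn$gamma)
    M <- kernels[[gkey]]
    model <- svm_train(kernel_matrix(M[tr, tr, drop = FALSE],
                                     validate = FALSE),
                       y[tr], task = task, cost = tn$cost)
    pred <- svm_predict(model, M[te, tr, drop = FALSE])
    metric <- if (task == "classification") accuracy(y[te], pred)
    else nmse(y[te], as.numeric(pred))
    results[[r]] <- data.frame(replicate = r, metric = metric,
                               cost = tn$cost, gamma = tn$gamma,
                               n_test = length(te))
    splits[[r]] <- list(train = tr, test = sp$test, test_scored = te)
  }
  res <- do.call(rbind, results)
  structure(list(results = res,
                 splits = splits,
                 metric = if (task == "classification") "accuracy" else "nmse",
                 median = stats::median(res$metric),
                 se = stats::sd(res$metric) / sqrt(nrow(res)),
                 task = task,
                 config = cv),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report: %d replicates, %s\n",
              nrow(x$results), x$task))
  cat(sprintf("  median %s: %.4f  (se %.4f)\n",
              x$metric, x$median, x$se))
  invisible(x)
}

#' Serialize an evaluation report to JSON-ready structure
#'
#' @param x an `eval_report`.
#' @return a list of plain vectors suitable for `jsonlite::write_json()`.
#' @export
eval_report_as_list <- function(x) {
  stopifnot(inherits(x, "eval_report"))
  list(metric = x$metric,
       median = x$median,
       se = x$se,
       replicates = x$results)
}
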