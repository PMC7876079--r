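test_that("svm on a separable clin kernel fits the training data perfectly", {
  toy <- toy_separated(30, 8, shift = 4, seed = 51)
  K <- clin_kernel(toy$table)
  m <- svm_train(K, toy$y, cost = 10)
  expect_equal(accuracy(toy$y, fitted_values(m, K)), 1)

  expect_error(svm_train(K, rep("a", 30)), "two classes")
  expect_error(svm_train(K, toy$y, cost = 0), "cost")
})

test_that("kernel regression recovers an exact linear function of clr features", {
  set.seed(52)
  tab <- rand_positive_table(40, 15, seed = 52)
  Z <- clr_transform(tab)
  y <- drop(Z %*% stats::rnorm(15))
  K <- clin_kernel(tab)
  m <- svm_train(K, y, task = "regression", cost = 1000, epsilon = 0.001)
  expect_lt(nmse(y, as.numeric(fitted_values(m, K))), 0.01)
})

test_that("prediction on kernel blocks reproduces fitted values and duplicates", {
  toy <- toy_separated(24, 6, shift = 3, seed = 53)
  K <- clin_kernel(toy$table)
  m <- svm_train(K, toy$y, cost = 1)
  expect_equal(svm_predict(m, kernbiome:::kmat(K)), fitted_values(m, K))

  # a duplicated training row predicts that row's fitted value
  block <- kernbiome:::kmat(K)[c(3, 3), , drop = FALSE]
  p <- svm_predict(m, block)
  expect_equal(p[1], p[2])
  expect_equal(as.character(p[1]), as.character(fitted_values(m, K)[3]))

  expect_error(svm_predict(m, kernbiome:::kmat(K)[, 1:5]), "columns")
  wrong <- kernbiome:::kmat(K)
  colnames(wrong) <- rev(colnames(wrong))
  expect_error(svm_predict(m, wrong), "aligned")
})

test_that("held-out prediction succeeds on strongly separated classes", {
  toy <- toy_separated(60, 10, shift = 4, seed = 54)
  K <- kernbiome:::kmat(clin_kernel(toy$table))
  sp <- split_train_test(60, 0.25, seed = 7)
  m <- svm_train(kernel_matrix(K[sp$train, sp$train], validate = FALSE),
                 toy$y[sp$train], cost = 1)
  p <- svm_predict(m, K[sp$test, sp$train])
  expect_gt(accuracy(toy$y[sp$test], p), 0.9)
})

test_that("kpca on the clin kernel equals PCA of the clr matrix up to sign", {
  for (s in 1:5) {
    tab <- rand_positive_table(18, 12, seed = 500 + s)
    K <- clin_kernel(tab)
    p <- kpca(K, 4)
    pc <- stats::prcomp(clr_transform(tab), center = TRUE, scale. = FALSE)
    expect_equal(abs(p$projections), abs(pc$x[, 1:4]),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("kpca projections have variance eigenvalue/N and fixed signs", {
  tab <- rand_positive_table(25, 10, seed = 55)
  K <- clin_kernel(tab)
  p <- kpca(K, 3)
  n <- 25
  for (j in 1:3) {
    expect_equal(mean(p$projections[, j]^2), p$eigenvalues[j] / n,
                 tolerance = 1e-10)
    i <- which.max(abs(p$projections[, j]))
    expect_gt(p$projections[i, j], 0)
  }
  expect_error(kpca(K, 25), "N - 1")
  # rank-deficient kernel: requesting more components than positive
  # eigenvalues warns and truncates
  A <- matrix(stats::rnorm(20 * 2), 20)
  Klow <- kernel_matrix(tcrossprod(A))
  expect_warning(plow <- kpca(Klow, 10), "positive eigenvalues")
  expect_lte(plow$n_components, 2)
})

test_that("accuracy and nmse match their definitions", {
  expect_equal(accuracy(c("a", "b", "a"), c("a", "b", "a")), 1)
  expect_equal(nmse(c(1, 2, 3), c(1, 2, 3)), 0)
  # the mean predictor scores 1 under the population-variance convention
  y <- c(2, 4, 9, 1)
  expect_equal(nmse(y, rep(mean(y), 4)), 1)
  expect_equal(nmse(c(0, 1, 2), c(0, 1, 5)), 4.5)
  expect_error(nmse(c(1, 1), c(1, 2)), "constant")
  expect_error(accuracy(1:3, 1:4), "length")
})

test_that("grouped splits never separate a group's members", {
  groups <- rep(paste0("g", 1:12), each = 5)
  for (s in 1:40) {
    sp <- split_train_test(60, 0.2, groups, seed = s)
    expect_length(intersect(groups[sp$train], groups[sp$test]), 0)
    expect_gt(length(sp$test), 0)
    expect_gt(length(sp$train), 0)
  }
  expect_error(split_train_test(10, 0.2, groups = rep("g1", 10)),
               "incompatible")
})

test_that("replicate evaluation is bit-reproducible and seed-sensitive", {
  toy <- toy_separated(40, 8, shift = 2, seed = 56)
  K <- clin_kernel(toy$table)
  cv <- cv_config(n_replicates = 3, inner_folds = 4, inner_repeats = 1,
                  seed = 9)
  r1 <- replicate_evaluation(K, toy$y, cv, cost_grid = c(0.1, 1))
  r2 <- replicate_evaluation(K, toy$y, cv, cost_grid = c(0.1, 1))
  expect_identical(r1$results, r2$results)

  cv2 <- cv_config(n_replicates = 3, inner_folds = 4, inner_repeats = 1,
                   seed = 10)
  r3 <- replicate_evaluation(K, toy$y, cv2, cost_grid = c(0.1, 1))
  expect_false(identical(r1$splits[[1]]$test, r3$splits[[1]]$test))
})

test_that("tuning never reads the test block of the kernel matrix", {
  toy <- toy_separated(40, 8, shift = 3, seed = 57)
  K <- kernbiome:::kmat(clin_kernel(toy$table))
  cv1 <- cv_config(n_replicates = 1, inner_folds = 4, inner_repeats = 1,
                   seed = 11)
  ref <- replicate_evaluation(kernel_matrix(K), toy$y, cv1,
                              cost_grid = c(0.1, 1))
  # poison the replicate's off-diagonal test x test block; an identical
  # result proves those entries are never consulted during tuning/refit
  te <- ref$splits[[1]]$test
  Kp <- K
  for (i in te) for (j in te) if (i != j) Kp[i, j] <- NA_real_
  poisoned <- replicate_evaluation(kernel_matrix(Kp, validate = FALSE),
                                   toy$y, cv1, cost_grid = c(0.1, 1))
  expect_equal(poisoned$results, ref$results)
})

test_that("gamma is tuned by recomputing the kernel per candidate", {
  toy <- toy_separated(36, 8, shift = 3, seed = 58)
  Z <- clr_transform(replace_zeros(toy$table, 0.5))
  kfun <- function(g) crbf_kernel(replace_zeros(toy$table, 0.5), g)
  cv <- cv_config(n_replicates = 2, inner_folds = 3, inner_repeats = 1,
                  seed = 12)
  rep <- replicate_evaluation(y = toy$y, cv = cv, cost_grid = c(1, 10),
                              gamma_grid = c(0.01, 0.1),
                              kernel_fun = kfun)
  expect_true(all(rep$results$gamma %in% c(0.01, 0.1)))
  expect_equal(nrow(rep$results), 2)
})

test_that("the one-time-point protocol scores one row per test individual", {
  set.seed(59)
  n_ind <- 20; Tt <- 3
  ind <- rep(paste0("I", 1:n_ind), times = Tt)
  y <- factor(rep(rep(c("a", "b"), length.out = n_ind), times = Tt))
  A <- matrix(stats::rnorm(n_ind * Tt * 5), n_ind * Tt)
  A[y == "b", 1] <- A[y == "b", 1] + 3
  K <- kernel_matrix(tcrossprod(A))
  cv <- cv_config(n_replicates = 2, inner_folds = 3, inner_repeats = 1,
                  group_ids = ind, seed = 13)
  rep <- replicate_evaluation(K, y, cv, cost_grid = 1,
                              time_ids = rep(1:Tt, each = n_ind))
  for (r in 1:2) {
    scored <- rep$splits[[r]]$test_scored
    expect_equal(length(scored), length(unique(ind[scored])))
    expect_true(all(scored %in% rep$splits[[r]]$test))
    # every test individual contributes exactly one row
    expect_setequal(unique(ind[rep$splits[[r]]$test]), ind[scored])
  }
})
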