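test_that("signature concentrates on a single differing taxon", {
  # clr feature 1 separates the classes; all other columns identical
  set.seed(61)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  Z <- matrix(stats::rnorm(n * 12, sd = 0.01), n, 12)
  base <- matrix(stats::rnorm(12), n, 12, byrow = TRUE)
  Z <- base + Z * 0  # identical columns
  Z[, 1] <- ifelse(y == "a", -2, 2) + stats::rnorm(n, sd = 0.1)
  Z <- Z - rowMeans(Z)
  K <- kernel_matrix(tcrossprod(Z), meta = list(kernel = "clin"))
  m <- svm_train(K, y, cost = 10)
  sig <- signature_from_clin_svm(m, Z)
  expect_equal(sum(sig$importance), 1, tolerance = 1e-10)
  expect_gt(sig$importance[1], 0.9)
  expect_equal(sig$rank[1], 1)
})

test_that("dual-expansion w matches a linear SVM fit on explicit features", {
  for (s in 1:4) {
    toy <- toy_separated(30, 8, shift = 2.5, seed = 600 + s)
    Z <- clr_transform(toy$table)
    for (cost in c(0.1, 1, 10)) {
      m <- svm_train(clin_kernel(toy$table), toy$y, cost = cost)
      w_dual <- attr(signature_from_clin_svm(m, Z), "w")
      m2 <- kernlab::ksvm(Z, toy$y, type = "C-svc", C = cost,
                          kernel = "vanilladot", kpar = list(),
                          scaled = FALSE)
      w_feat <- colSums(unlist(kernlab::coef(m2)) *
                          Z[unlist(kernlab::alphaindex(m2)), , drop = FALSE])
      expect_equal(w_dual, w_feat, tolerance = 1e-5, ignore_attr = TRUE)
    }
  }
})

test_that("regression signatures use the dual coefficients directly", {
  set.seed(62)
  tab <- rand_positive_table(30, 10, seed = 62)
  Z <- clr_transform(tab)
  y <- drop(Z %*% c(3, rep(0, 9))) + stats::rnorm(30, sd = 0.05)
  m <- svm_train(clin_kernel(tab), y, task = "regression", cost = 100)
  sig <- signature_from_clin_svm(m, Z)
  expect_equal(which.max(sig$importance), 1)
  expect_equal(sum(sig$importance), 1, tolerance = 1e-10)
})

test_that("non-linear kernels are rejected for signature extraction", {
  toy <- toy_separated(20, 6, seed = 63)
  K <- crbf_kernel(toy$table, 0.5)
  m <- svm_train(K, toy$y)
  expect_error(signature_from_clin_svm(m, clr_transform(toy$table)),
               "linear")
})

test_that("spatial aggregation weights partial importances by beta", {
  toy1 <- toy_separated(30, 8, shift = 3, seed = 64)
  toy2 <- toy_separated(30, 8, shift = 3, seed = 65)
  s1 <- signature_from_clin_svm(svm_train(clin_kernel(toy1$table), toy1$y),
                                clr_transform(toy1$table))
  s2 <- signature_from_clin_svm(svm_train(clin_kernel(toy2$table), toy2$y),
                                clr_transform(toy2$table))

  # single site, beta = 1: unchanged
  g1 <- signature_spatial_aggregate(list(s1), mkl_weights(1))
  expect_equal(g1$importance, s1$importance, tolerance = 1e-12)

  # identical sites with equal weights: unchanged
  g2 <- signature_spatial_aggregate(list(s1, s1), mkl_weights(c(0.5, 0.5)))
  expect_equal(g2$importance, s1$importance, tolerance = 1e-12)

  # degenerate weighting ignores the second site entirely
  g3 <- signature_spatial_aggregate(list(s1, s2),
                                    mkl_weights(c(1, 0), normalized = FALSE))
  expect_equal(g3$importance, s1$importance, tolerance = 1e-12)
  expect_equal(sum(g3$importance), 1, tolerance = 1e-10)

  # differing taxon sets: union with zero fill, warned
  v1 <- c(A = 1, B = 2)
  v2 <- c(B = 1, C = 4)
  expect_warning(g4 <- signature_spatial_aggregate(list(v1, v2), c(0.5, 0.5)),
                 "differ")
  expect_setequal(g4$taxon_id, c("A", "B", "C"))
})

test_that("longitudinal signatures sum partial importances over time", {
  set.seed(66)
  n <- 40; D <- 6; Tt <- 3
  arr <- array(stats::rlnorm(n * D * Tt), dim = c(n, D, Tt))
  y <- factor(rep(c("a", "b"), each = n / 2))
  # plant signal on taxon 3 at the last time point only
  arr[y == "b", 3, Tt] <- arr[y == "b", 3, Tt] * 50
  tst <- time_series_table(arr, times = 0:2)
  ct <- clr_timeseries(tst, 0.5)
  K <- flin_multivariate(ct)
  F <- functional_features(ct)
  m <- svm_train(K, y, cost = 1)
  sig <- signature_longitudinal(m, F)
  expect_equal(sum(sig$importance), 1, tolerance = 1e-10)
  expect_equal(which.max(sig$importance), 3)

  # T = 1 reduces to the single-point signature
  one <- time_series_table(arr[, , 1, drop = FALSE], times = 0)
  co <- clr_timeseries(one, 0.5)
  K1 <- flin_multivariate(co, dt = 1)
  F1 <- functional_features(co, dt = 1)
  m1 <- svm_train(K1, y, cost = 1)
  expect_equal(signature_longitudinal(m1, F1)$importance,
               signature_from_clin_svm(m1, F1)$importance,
               tolerance = 1e-12)

  expect_error(signature_longitudinal(m, F[, 1:10], D = 6, T = 3),
               "mismatch|aligned|columns")
})

test_that("select_top_fraction is deterministic with reported share", {
  sig <- kernbiome:::new_signature(w = sqrt(c(rep(10, 10), rep(0.01, 190))),
                                   taxon_ids = sprintf("T%03d", 1:200),
                                   mode = "single")
  all_taxa <- select_top_fraction(sig, 1)
  expect_equal(nrow(all_taxa$signature), 200)
  expect_equal(all_taxa$cumulative_importance, 1, tolerance = 1e-10)

  top5 <- select_top_fraction(sig, 0.05)
  expect_equal(nrow(top5$signature), 10)
  expect_gt(top5$cumulative_importance, 0.9)
  expect_setequal(top5$signature$taxon_id, sprintf("T%03d", 1:10))

  unif <- kernbiome:::new_signature(w = rep(1, 100),
                                    taxon_ids = sprintf("U%03d", 1:100),
                                    mode = "single")
  u5 <- select_top_fraction(unif, 0.05)
  expect_equal(nrow(u5$signature), 5)
  expect_equal(u5$cumulative_importance, 0.05, tolerance = 1e-12)
  # lexical tie-break on uniform importances
  expect_equal(u5$signature$taxon_id, sprintf("U%03d", 1:5))

  expect_error(select_top_fraction(sig, 0), "fraction")
})

test_that("replicate-averaged signatures carry standard errors", {
  toy <- toy_separated(30, 8, shift = 3, seed = 67)
  Z <- clr_transform(toy$table)
  sigs <- lapply(c(0.5, 1, 2), function(cost)
    signature_from_clin_svm(svm_train(clin_kernel(toy$table), toy$y,
                                      cost = cost), Z))
  avg <- average_signatures(sigs)
  expect_equal(sum(avg$importance), 1, tolerance = 1e-10)
  expect_true(all(avg$se >= 0))
  expect_equal(nrow(avg), 8)
})
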