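test_that("clin kernel matches hand values and the clr cross-product oracle", {
  tab <- abundance_table(rbind(c(1, 2, 4), c(4, 2, 1), c(1, 1, 1)))
  K <- clin_kernel(tab)
  expect_equal(K[1, 2], -2 * log(2)^2, tolerance = 1e-10)
  # uniform composition has the zero clr vector
  expect_equal(unname(K[3, ]), c(0, 0, 0), tolerance = 1e-12)
  expect_true(all(diag(K) >= 0))

  big <- rand_positive_table(25, 40, seed = 11)
  Z <- clr_transform(big)
  expect_equal(kernbiome:::kmat(clin_kernel(big)), tcrossprod(Z),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("crbf kernel equals exp(-gamma * squared Aitchison distance)", {
  tab <- abundance_table(rbind(c(1, 2, 4), c(4, 2, 1)))
  K <- crbf_kernel(tab, gamma = 1)
  expect_equal(K[1, 2], exp(-8 * log(2)^2), tolerance = 1e-12)
  expect_equal(unname(diag(K)), c(1, 1))

  big <- rand_positive_table(20, 30, seed = 12)
  Z <- clr_transform(big)
  D2 <- as.matrix(stats::dist(Z))^2
  expect_equal(kernbiome:::kmat(crbf_kernel(big, 0.3)), exp(-0.3 * D2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # K(x, c*x) = 1 by clr scale invariance
  two <- abundance_table(rbind(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(crbf_kernel(two, 2)[1, 2], 1, tolerance = 1e-12)

  expect_error(crbf_kernel(tab, 0), "gamma")
  expect_error(crbf_kernel(tab, -1), "gamma")
})

test_that("compositional kernels are invariant to per-sample rescaling", {
  tab <- rand_positive_table(15, 25, seed = 13)
  c_scale <- stats::runif(15, 0.2, 8)
  scaled <- abundance_table(tab$values * c_scale)
  expect_equal(kernbiome:::kmat(clin_kernel(scaled)),
               kernbiome:::kmat(clin_kernel(tab)), tolerance = 1e-10)
  expect_equal(kernbiome:::kmat(crbf_kernel(scaled, 0.5)),
               kernbiome:::kmat(crbf_kernel(tab, 0.5)), tolerance = 1e-10)
})

test_that("jsk kernel matches hand examples and stays in its range", {
  P <- abundance_table(rbind(c(1, 0), c(0, 1), c(0.5, 0.5)),
                       scale = "relative")
  K <- jsk_kernel(P)
  expect_equal(K[1, 2], 1 - log(2), tolerance = 1e-12)
  expect_equal(K[1, 3], 0.7842384, tolerance = 1e-6)
  expect_equal(unname(diag(K)), rep(1, 3))

  counts <- rand_count_table(12, 20, seed = 14)
  expect_warning(Kc <- jsk_kernel(counts), "relative")
  expect_true(all(Kc >= 1 - log(2) - 1e-12 & Kc <= 1 + 1e-12))

  expect_error(jsk_kernel(abundance_table(matrix(c(0.5, 0.5), 1),
                                          scale = "relative")$values * -1),
               "negative|non-negative")
})

test_that("quantitative Jaccard is the ratio of sums with unit diagonal", {
  K <- qjac_kernel(rbind(c(1, 2), c(2, 1)))
  expect_equal(K[1, 2], 0.5)
  expect_equal(unname(diag(K)), c(1, 1))

  disj <- qjac_kernel(rbind(c(1, 0), c(0, 1)))
  expect_equal(disj[1, 2], 0)

  # straight-line oracle on a random sparse table
  tab <- rand_count_table(10, 15, seed = 15)
  X <- tab$values
  K2 <- kernbiome:::kmat(qjac_kernel(tab))
  for (i in 1:10) for (j in 1:10) {
    expect_equal(K2[i, j],
                 sum(pmin(X[i, ], X[j, ])) / sum(pmax(X[i, ], X[j, ])),
                 tolerance = 1e-12)
  }
  expect_true(all(K2 >= 0 & K2 <= 1))

  zz <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_warning(Kz <- qjac_kernel(zz), "all-zero")
  expect_equal(Kz[1, 2], 1)
})

test_that("all four sample kernels generate PSD matrices on random tables", {
  for (s in 1:6) {
    counts <- rand_count_table(15 + 5 * s, 40, seed = 100 + s)
    pos <- replace_zeros(counts, 0.5)
    rel <- relative_abundance(counts)
    Ks <- list(clin_kernel(pos), crbf_kernel(pos, 0.2),
               jsk_kernel(rel), qjac_kernel(counts))
    for (K in Ks) expect_true(check_psd(K, tol = 1e-8)$pass)
  }
})

test_that("check_psd reports symmetry and eigenvalue failures", {
  expect_true(check_psd(diag(3))$pass)
  rep <- check_psd(rbind(c(1, 2), c(2, 1)))
  expect_false(rep$pass)
  expect_equal(sort(c(rep$min_eigenvalue, rep$max_eigenvalue)), c(-1, 3))
  expect_error(check_psd(matrix(1, 2, 3)), "square")
})

test_that("center_kernel is the double-centering projector, idempotent", {
  expect_equal(kernbiome:::kmat(center_kernel(matrix(7, 4, 4))),
               matrix(0, 4, 4), ignore_attr = TRUE)

  set.seed(16)
  A <- matrix(stats::rnorm(100), 10)
  K <- tcrossprod(A)
  J <- diag(10) - matrix(1 / 10, 10, 10)
  expect_equal(kernbiome:::kmat(center_kernel(K)), J %*% K %*% J,
               ignore_attr = TRUE, tolerance = 1e-10)
  Kc <- center_kernel(K)
  expect_lt(max(abs(rowSums(kernbiome:::kmat(Kc)))), 1e-8)
  expect_equal(kernbiome:::kmat(center_kernel(Kc)), kernbiome:::kmat(Kc),
               tolerance = 1e-10)
})

test_that("cosine normalization yields unit diagonal and Cauchy-Schwarz bounds", {
  K <- rbind(c(4, 3), c(3, 9))
  Kn <- cosine_normalize_kernel(kernel_matrix(K))
  expect_equal(Kn[1, 2], 0.5)
  expect_equal(unname(diag(Kn)), c(1, 1))

  set.seed(17)
  A <- matrix(stats::rnorm(60), 12)
  KL <- kernel_matrix(tcrossprod(A))
  Kn2 <- cosine_normalize_kernel(KL)
  expect_true(all(abs(kernbiome:::kmat(Kn2)) <= 1 + 1e-12))
  # matches explicit normalized dot products
  U <- A / sqrt(rowSums(A^2))
  expect_equal(kernbiome:::kmat(Kn2), tcrossprod(U),
               ignore_attr = TRUE, tolerance = 1e-12)

  bad <- kernel_matrix(diag(c(0, 1)), sample_ids = c("z", "p"))
  expect_error(cosine_normalize_kernel(bad), "z")
})

test_that("kernel matrix similarity is a centered Frobenius cosine", {
  tab <- rand_positive_table(20, 15, seed = 18)
  K <- clin_kernel(tab)
  S <- kernel_matrix_similarity(list(a = K, b = K))
  expect_equal(S[1, 2], 1, tolerance = 1e-12)

  K5 <- kernel_matrix(kernbiome:::kmat(K) * 5, rownames(K))
  expect_equal(kernel_matrix_similarity(list(K, K5))[1, 2], 1,
               tolerance = 1e-12)

  # kernels from independent data are weakly similar
  for (s in 1:3) {
    t1 <- rand_positive_table(100, 30, seed = 200 + s)
    t2 <- rand_positive_table(100, 30, seed = 300 + s)
    S2 <- kernel_matrix_similarity(list(clin_kernel(t1), clin_kernel(t2)))
    expect_lt(S2[1, 2], 0.5)
  }

  K_wrong <- kernel_matrix(kernbiome:::kmat(K),
                           sample_ids = paste0("X", 1:20))
  expect_error(kernel_matrix_similarity(list(K, K_wrong)), "aligned")
})

test_that("compute_kernel dispatches with the expected preprocessing", {
  counts <- rand_count_table(10, 12, seed = 19)
  expect_equal(kernel_meta(compute_kernel(counts, "clin"))$kernel, "clin")
  expect_equal(kernel_meta(compute_kernel(counts, "crbf", gamma = 1))$gamma, 1)
  expect_equal(kernel_meta(compute_kernel(counts, "jsk",
                                          css_quantile = 0.5))$kernel, "jsk")
  expect_true(check_psd(compute_kernel(counts, "qjac"))$pass)
})
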