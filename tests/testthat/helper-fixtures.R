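# Shared fixture builders: everything generated in code, seeded.

# random count table with natural zeros (negative-binomial-ish counts)
rand_count_table <- function(n = 20, D = 30, seed = 1, zero_prob = 0.3) {
  set.seed(seed)
  lambda <- exp(stats::rnorm(D, 2, 1))
  X <- t(vapply(seq_len(n), function(i)
    stats::rpois(D, lambda) * (stats::runif(D) > zero_prob),
    numeric(D)))
  abundance_table(X)
}

# strictly positive table (compositional-kernel ready)
rand_positive_table <- function(n = 20, D = 30, seed = 1) {
  set.seed(seed)
  abundance_table(matrix(stats::rlnorm(n * D), n, D))
}

# two-cluster clr-separable data for toy SVM fits
toy_separated <- function(n = 30, D = 10, shift = 3, seed = 1) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * D), n, D)
  y <- factor(rep(c("a", "b"), length.out = n))
  Z[y == "b", 1] <- Z[y == "b", 1] + shift
  X <- exp(Z)  # positive table whose clr recovers Z up to row-centering
  list(table = abundance_table(X), y = y, Z = Z)
}
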