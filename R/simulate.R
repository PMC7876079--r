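#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Samples are drawn from a
#' logistic-normal compositional model: a latent multivariate normal vector
#' per sample is pushed through the softmax to a composition, then counts are
#' drawn multinomially at a log-normally distributed library size. Because
#' clr(softmax(z)) = z - mean(z), effects planted on the latent scale are
#' (up to the shared row-mean) exactly clr-scale effects, which makes
#' signature recovery well-posed.
#'
#' @param n_individuals number of individuals (samples at a single point).
#' @param n_taxa number of taxa D.
#' @param n_informative number of taxa carrying signal.
#' @param informative_taxa optional fixed indices of the informative taxa;
#'   by default `n_informative` taxa are sampled at random per seed. Fixing
#'   them lets replicated simulations share the same planted ground truth.
#' @param effect_size clr-scale mean separation between the two classes on
#'   each informative taxon (each class is shifted by +/- effect_size / 2).
#' @param library_size_meanlog,library_size_sdlog log-normal library-size
#'   distribution; the default sdlog of 1 spreads sizes over roughly an
#'   order of magnitude.
#' @param zero_fraction overall fraction of zero entries to reach by random
#'   thinning (zeros also arise naturally from multinomial sampling; if the
#'   natural fraction already exceeds the target, no thinning happens).
#' @param n_sites number of sites for the multi-site generator.
#' @param site_correlation correlation of the latent individual effect across
#'   sites, in [0, 1].
#' @param informative_sites indices of the sites carrying signal (default:
#'   all).
#' @param n_timepoints number of time points for the longitudinal generator.
#' @param times numeric time values (default `0:(n_timepoints-1) * 3.5`,
#'   i.e. roughly a week over three points).
#' @param informative_timepoints indices of time points where the classes
#'   diverge (default: the last).
#' @param task `"classification"` or `"regression"`.
#' @param seed integer; fully determines the generated data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 150, n_taxa = 200,
                       n_informative = 10, informative_taxa = NULL,
                       effect_size = 2,
                       library_size_meanlog = log(1e4),
                       library_size_sdlog = 1,
                       zero_fraction = 0,
                       n_sites = 4, site_correlation = 0.5,
                       informative_sites = NULL,
                       n_timepoints = 3, times = NULL,
                       informative_timepoints = NULL,
                       task = c("classification", "regression"),
                       seed = 1) {
  task <- match.arg(task)
  if (!is.null(informative_taxa)) {
    if (!all(informative_taxa %in% seq_len(n_taxa)))
      stop("informative_taxa must be indices in 1..n_taxa")
    n_informative <- length(informative_taxa)
  }
  if (n_informative > n_taxa)
    stop("n_informative must not exceed n_taxa")
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop("zero_fraction must lie in [0, 1)")
  if (site_correlation < 0 || site_correlation > 1)
    stop("site_correlation must lie in [0, 1]")
  if (is.null(times)) times <- (seq_len(n_timepoints) - 1) * 3.5
  if (length(times) != n_timepoints)
    stop("times must have length n_timepoints")
  if (is.null(informative_timepoints)) informative_timepoints <- n_timepoints
  if (length(informative_timepoints) &&
      !all(informative_timepoints %in% seq_len(n_timepoints)))
    stop("informative_timepoints must be indices in 1..n_timepoints")
  if (is.null(informative_sites)) informative_sites <- seq_len(n_sites)
  structure(list(n_individuals = n_individuals, n_taxa = n_taxa,
                 n_informative = n_informative,
                 informative_taxa = informative_taxa,
                 effect_size = effect_size,
                 library_size_meanlog = library_size_meanlog,
                 library_size_sdlog = library_size_sdlog,
                 zero_fraction = zero_fraction,
                 n_sites = n_sites, site_correlation = site_correlation,
                 informative_sites = informative_sites,
                 n_timepoints = n_timepoints, times = times,
                 informative_timepoints = informative_timepoints,
                 task = task, seed = as.integer(seed)),
            class = "sim_config")
}

# softmax rows
softmax <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

# multinomial counts at log-normal library sizes from latent rows
latent_to_counts <- function(Z, cfg) {
  P <- softmax(Z)
  L <- pmax(200, round(stats::rlnorm(nrow(Z), cfg$library_size_meanlog,
                                     cfg$library_size_sdlog)))
  t(vapply(seq_len(nrow(Z)),
           function(i) stats::rmultinom(1, L[i], P[i, ])[, 1],
           numeric(ncol(Z))))
}

# thin random positive entries to reach the target zero fraction, never
# emptying a sample
thin_to_zero_fraction <- function(X, target) {
  if (target <= 0) return(X)
  cur <- mean(X == 0)
  if (cur >= target) return(X)
  need <- round((target - cur) * length(X))
  pos <- which(X > 0)
  keep_one <- vapply(seq_len(nrow(X)),
                     function(i) (i - 1) + nrow(X) * (which(X[i, ] > 0)[1] - 1) + 1,
                     numeric(1))
  pos <- setdiff(pos, keep_one)
  if (need > length(pos))
    stop("infeasible zero_fraction: not enough removable entries")
  X[sample(pos, need)] <- 0
  X
}

# class labels and latent class shifts on the informative taxa
plant_signal <- function(Z, cfg, informative, y_class) {
  shift <- ifelse(y_class == levels(y_class)[1],
                  -cfg$effect_size / 2, cfg$effect_size / 2)
  Z[, informative] <- Z[, informative] + shift
  Z
}

#' Simulate a single-time-point abundance dataset
#'
#' Draws latent logistic-normal compositions with per-taxon baseline means,
#' plants a clr-scale class shift (classification) or a linear contribution
#' to a continuous target (regression) on `n_informative` randomly chosen
#' taxa, and emits multinomial counts. The ground truth (informative taxa,
#' true signature) is returned alongside the data so recovery can be tested.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (an `abundance_table` of counts), `y` (factor or
#'   numeric), `informative` (taxon ids carrying signal), `true_signature`
#'   (normalized planted importances) and `config`.
#' @export
simulate_single_point <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals; D <- cfg$n_taxa
  mu <- stats::rnorm(D, 0, 1)
  informative <- if (!is.null(cfg$informative_taxa))
    sort(cfg$informative_taxa) else sort(sample.int(D, cfg$n_informative))
  Z <- matrix(stats::rnorm(n * D), n, D, byrow = TRUE) +
    matrix(mu, n, D, byrow = TRUE)
  if (cfg$task == "classification") {
    y <- factor(rep(c("case", "control"), length.out = n))
    Z <- plant_signal(Z, cfg, informative, y)
    b <- rep(1, cfg$n_informative)
  } else {
    b <- rep(c(1, -1), length.out = cfg$n_informative)
    signal <- drop(Z[, informative, drop = FALSE] %*% b) /
      sqrt(cfg$n_informative) * (cfg$effect_size / 2)
    y <- signal + stats::rnorm(n, 0, 0.5)
  }
  X <- latent_to_counts(Z, cfg)
  X <- thin_to_zero_fraction(X, cfg$zero_fraction)
  taxa <- sprintf("T%03d", seq_len(D))
  tab <- abundance_table(X, sample_ids = sprintf("S%03d", seq_len(n)),
                         taxon_ids = taxa, scale = "counts")
  w2 <- numeric(D)
  w2[informative] <- b^2
  list(table = tab, y = y, informative = taxa[informative],
       true_signature = w2 / sum(w2), config = cfg)
}

#' Simulate spatially structured abundance data
#'
#' The same individuals measured at `n_sites` sites: each site's latent field
#' mixes a shared per-individual effect (weight `sqrt(site_correlation)`)
#' with site-specific noise, and the class signal is planted only at the
#' `informative_sites`. Emulates multi-body-site designs where some sites are
#' informative for the phenotype and others are not.
#'
#' @param cfg a [sim_config()] (classification task).
#' @return list with `tables` (named list site -> `abundance_table`), `y`,
#'   `informative` taxa, `informative_sites` and `config`.
#' @export
simulate_multisite <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_sites < 2) stop("n_sites must be at least 2")
  set.seed(cfg$seed)
  n <- cfg$n_individuals; D <- cfg$n_taxa
  mu <- stats::rnorm(D, 0, 1)
  informative <- if (!is.null(cfg$informative_taxa))
    sort(cfg$informative_taxa) else sort(sample.int(D, cfg$n_informative))
  y <- factor(rep(c("case", "control"), length.out = n))
  U <- matrix(stats::rnorm(n * D), n, D)
  rho <- cfg$site_correlation
  taxa <- sprintf("T%03d", seq_len(D))
  ids <- sprintf("S%03d", seq_len(n))
  tables <- list()
  for (s in seq_len(cfg$n_sites)) {
    E <- matrix(stats::rnorm(n * D), n, D)
    Z <- matrix(mu, n, D, byrow = TRUE) + sqrt(rho) * U + sqrt(1 - rho) * E
    if (s %in% cfg$informative_sites)
      Z <- plant_signal(Z, cfg, informative, y)
    X <- thin_to_zero_fraction(latent_to_counts(Z, cfg), cfg$zero_fraction)
    tables[[paste0("site", s)]] <-
      abundance_table(X, sample_ids = ids, taxon_ids = taxa)
  }
  list(tables = tables, y = y, informative = taxa[informative],
       informative_sites = cfg$informative_sites, config = cfg)
}

#' Simulate longitudinal abundance data
#'
#' Per-individual latent trajectories over a common time grid: a stable
#' individual baseline plus independent per-time fluctuation, with the
#' class-dependent divergence applied only at the `informative_timepoints`.
#' Non-informative time points are exchangeable between the classes, which
#' makes "no signal before day X" designs testable.
#'
#' @param cfg a [sim_config()] (classification task).
#' @return list with `series` (a `time_series_table` of counts), `y`,
#'   `informative` taxa, `informative_timepoints` and `config`.
#' @export
simulate_longitudinal <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_timepoints < 2) stop("n_timepoints must be at least 2")
  set.seed(cfg$seed)
  n <- cfg$n_individuals; D <- cfg$n_taxa; Tt <- cfg$n_timepoints
  mu <- stats::rnorm(D, 0, 1)
  informative <- if (!is.null(cfg$informative_taxa))
    sort(cfg$informative_taxa) else sort(sample.int(D, cfg$n_informative))
  y <- factor(rep(c("case", "control"), length.out = n))
  A <- matrix(stats::rnorm(n * D), n, D)  # individual baseline
  taxa <- sprintf("T%03d", seq_len(D))
  ids <- sprintf("I%03d", seq_len(n))
  arr <- array(0, dim = c(n, D, Tt),
               dimnames = list(ids, taxa, as.character(cfg$times)))
  shift <- ifelse(y == levels(y)[1], -cfg$effect_size / 2, cfg$effect_size / 2)
  for (t in seq_len(Tt)) {
    E <- matrix(stats::rnorm(n * D), n, D)
    Z <- matrix(mu, n, D, byrow = TRUE) + sqrt(0.5) * A + sqrt(0.5) * E
    if (t %in% cfg$informative_timepoints)
      Z[, informative] <- Z[, informative] + shift
    X <- thin_to_zero_fraction(latent_to_counts(Z, cfg), cfg$zero_fraction)
    arr[, , t] <- X
  }
  list(series = time_series_table(arr, ids, taxa, cfg$times),
       y = y, informative = taxa[informative],
       informative_timepoints = cfg$informative_timepoints, config = cfg)
}
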