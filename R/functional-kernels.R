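#' Discrete functional linear kernel (univariate)
#'
#' For two series sampled on the same regular grid of T points with
#' increment dt: fLin(f, g) = dt * sum_i f(t_i) g(t_i) — a rectangle-rule
#' inner product of the two trajectories.
#'
#' @param f,g numeric vectors of equal length T >= 1.
#' @param dt positive time increment.
#' @return scalar.
#' @export
flin_discrete <- function(f, g, dt = 1) {
  if (length(f) != length(g))
    stop("f and g must have the same length (", length(f), " vs ",
         length(g), ")")
  if (dt <= 0) stop("dt must be positive")
  dt * sum(f * g)
}

#' Discrete functional RBF kernel (univariate)
#'
#' exp(-gamma * sum_i (f(t_i) - g(t_i))^2) for two series on the same grid;
#' values in (0, 1], equal to 1 iff the trajectories coincide.
#'
#' @param f,g numeric vectors of equal length.
#' @param gamma positive bandwidth.
#' @return scalar in (0, 1].
#' @export
frbf_discrete <- function(f, g, gamma) {
  if (length(f) != length(g))
    stop("f and g must have the same length (", length(f), " vs ",
         length(g), ")")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a single positive number")
  exp(-gamma * sum((f - g)^2))
}

# coerce a sampled series to list(t, y), sorted by t
as_series <- function(s, arg = "series") {
  if (is.list(s) && !is.data.frame(s) && all(c("t", "y") %in% names(s))) {
    t <- s$t; y <- s$y
  } else if (is.data.frame(s)) {
    t <- s[[1]]; y <- s[[2]]
  } else if (is.matrix(s) && ncol(s) == 2) {
    t <- s[, 1]; y <- s[, 2]
  } else stop(arg, " must be a list(t=, y=), two-column matrix or data frame")
  if (length(t) != length(y)) stop(arg, ": t and y lengths differ")
  keep <- !is.na(y)
  t <- t[keep]; y <- y[keep]
  o <- order(t)
  list(t = t[o], y = y[o])
}

# evaluate both series on the union grid restricted to [a, b]
union_grid_eval <- function(f, g, interval) {
  a <- interval[1]; b <- interval[2]
  if (b <= a) stop("interval must satisfy t_a < t_b")
  for (s in list(f, g)) {
    if (length(s$t) < 2)
      stop("each series needs at least 2 observed points")
    if (a < min(s$t) - 1e-12 || b > max(s$t) + 1e-12)
      stop(sprintf(
        "interval [%g, %g] extends beyond a series' support [%g, %g]; %s",
        a, b, min(s$t), max(s$t), "extrapolation is not performed"))
  }
  u <- sort(unique(c(a, b, f$t[f$t > a & f$t < b], g$t[g$t > a & g$t < b])))
  list(u = u,
       fu = stats::approx(f$t, f$y, xout = u)$y,
       gu = stats::approx(g$t, g$y, xout = u)$y)
}

# integrate h(f, g) over the union grid by per-segment Simpson's rule.
# With piecewise-linear f and g, both f*g and (f-g)^2 are piecewise
# quadratic, for which Simpson is exact.
simpson_pairwise <- function(u, fu, gu, h) {
  n <- length(u)
  i <- seq_len(n - 1)
  w <- u[i + 1] - u[i]
  fm <- (fu[i] + fu[i + 1]) / 2
  gm <- (gu[i] + gu[i + 1]) / 2
  sum(w / 6 * (h(fu[i], gu[i]) + 4 * h(fm, gm) + h(fu[i + 1], gu[i + 1])))
}

#' Continuous functional linear kernel (univariate)
#'
#' fLin(f, g) = integral of f(t) g(t) dt over [t_a, t_b], with the two
#' trajectories reconstructed by piecewise-linear interpolation of their
#' sampled points. Sampling may be irregular and points may be missing (NA);
#' the integral is evaluated exactly on the union grid (the product of two
#' piecewise-linear functions is piecewise quadratic, integrated by Simpson's
#' rule segment by segment).
#'
#' @param f,g sampled series: `list(t =, y =)`, a two-column matrix, or a
#'   data frame with time in the first column.
#' @param interval numeric length-2 vector c(t_a, t_b); defaults to the
#'   intersection of the two observed supports.
#' @return scalar.
#' @export
flin_continuous <- function(f, g, interval = NULL) {
  f <- as_series(f, "f"); g <- as_series(g, "g")
  if (is.null(interval))
    interval <- c(max(min(f$t), min(g$t)), min(max(f$t), max(g$t)))
  e <- union_grid_eval(f, g, interval)
  simpson_pairwise(e$u, e$fu, e$gu, function(a, b) a * b)
}

#' Continuous functional RBF kernel (univariate)
#'
#' exp(-gamma * integral of (f(t) - g(t))^2 dt) over [t_a, t_b], with the
#' same piecewise-linear reconstruction and exact quadrature as
#' [flin_continuous()]. Values in (0, 1].
#'
#' @inheritParams flin_continuous
#' @param gamma positive bandwidth.
#' @return scalar in (0, 1].
#' @export
frbf_continuous <- function(f, g, interval = NULL, gamma = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a single positive number")
  f <- as_series(f, "f"); g <- as_series(g, "g")
  if (is.null(interval))
    interval <- c(max(min(f$t), min(g$t)), min(max(f$t), max(g$t)))
  e <- union_grid_eval(f, g, interval)
  exp(-gamma * simpson_pairwise(e$u, e$fu, e$gu, function(a, b) (a - b)^2))
}

#' Multivariate discrete functional linear kernel (fLin')
#'
#' For individuals measured on D taxa over a common regular time grid, the
#' per-taxon discrete linear kernels are summed:
#' fLin'(i, j) = sum_k fLin(f_k^i, f_k^j) = dt * <flat_i, flat_j>,
#' i.e. dt times the linear kernel on the flattened N x (D*T) matrix.
#'
#' @param tst a `time_series_table` on a regular grid without missing
#'   values (typically clr-transformed via [clr_timeseries()]).
#' @param dt time increment; derived from the grid when NULL.
#' @return A `kernel_matrix` over individuals.
#' @export
flin_multivariate <- function(tst, dt = NULL) {
  dt <- resolve_dt(tst, dt)
  F <- flatten_timeseries(tst)
  K <- dt * tcrossprod(F)
  kernel_matrix(K, rownames(F),
                meta = list(kernel = "flin", dt = dt,
                            layout = list(D = dim(tst$values)[2],
                                          T = dim(tst$values)[3]),
                            preprocessing = tst$provenance),
                validate = FALSE)
}

#' Multivariate discrete functional RBF kernel (fRBF')
#'
#' Per-taxon discrete RBF kernels multiplied across taxa, which by the
#' exponential-sum identity equals the RBF kernel on the flattened matrix:
#' fRBF'(i, j) = exp(-gamma * sum_k sum_t (f_k^i(t) - f_k^j(t))^2).
#' One bandwidth gamma is shared across all taxa. Unit diagonal.
#'
#' @inheritParams flin_multivariate
#' @param gamma positive bandwidth (default: median heuristic on the
#'   flattened trajectories).
#' @return A `kernel_matrix` over individuals.
#' @export
frbf_multivariate <- function(tst, gamma = NULL) {
  F <- flatten_timeseries(tst)
  if (is.null(gamma)) gamma <- gamma_median_heuristic(F)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a single positive number")
  K <- exp(-gamma * squared_distances(F))
  kernel_matrix(K, rownames(F),
                meta = list(kernel = "frbf", gamma = gamma,
                            layout = list(D = dim(tst$values)[2],
                                          T = dim(tst$values)[3]),
                            preprocessing = tst$provenance),
                validate = FALSE)
}
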