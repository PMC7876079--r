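#' Construct a longitudinal abundance array
#'
#' Container for repeated abundance measurements of the same individuals:
#' an N x D x T array (individuals x taxa x time points) with the numeric
#' time values of the T points. Missing measurements may be encoded as NA
#' only for use with the continuous functional kernels; the discrete kernels
#' require a complete common grid.
#'
#' @param values N x D x T non-negative numeric array.
#' @param individual_ids N identifiers (default from dimnames or `"I1"..`).
#' @param taxon_ids D identifiers.
#' @param times strictly increasing numeric vector of length T.
#' @param provenance character vector of preprocessing steps.
#' @return An object of class `time_series_table`.
#' @export
time_series_table <- function(values, individual_ids = NULL, taxon_ids = NULL,
                              times = NULL, provenance = character()) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  dn <- dimnames(values)
  if (is.null(individual_ids))
    individual_ids <- if (!is.null(dn[[1]])) dn[[1]] else
      paste0("I", seq_len(dim(values)[1]))
  if (is.null(taxon_ids))
    taxon_ids <- if (!is.null(dn[[2]])) dn[[2]] else
      paste0("T", seq_len(dim(values)[2]))
  if (is.null(times)) {
    times <- if (!is.null(dn[[3]])) as.numeric(dn[[3]]) else
      seq_len(dim(values)[3])
  }
  if (length(times) != dim(values)[3])
    stop("length(times) must equal dim(values)[3]")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (anyDuplicated(individual_ids)) stop("duplicate individual_ids")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon_ids")
  if (any(values < 0, na.rm = TRUE)) stop("values must be non-negative")
  dimnames(values) <- list(individual_ids, taxon_ids, as.character(times))
  structure(list(values = values, times = times, provenance = provenance),
            class = "time_series_table")
}

#' @export
print.time_series_table <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Time series table: %d individuals x %d taxa x %d time points\n",
              d[1], d[2], d[3]))
  cat("  times:", paste(x$times, collapse = ", "), "\n")
  if (anyNA(x$values))
    cat(sprintf("  missing entries: %d\n", sum(is.na(x$values))))
  if (length(x$provenance))
    cat("  preprocessing:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' clr-transform a longitudinal array per sample
#'
#' Applies the pseudocount and the centered log-ratio transform to each
#' (individual, time point) composition independently, the recommended
#' preprocessing for compositional longitudinal data before the functional
#' kernels.
#'
#' @param tst a `time_series_table` of counts or abundances.
#' @param pseudocount constant added to every entry before the log-ratio.
#' @return A `time_series_table` of clr coordinates (entries may be
#'   negative; the non-negativity invariant applies to abundances only, so
#'   the result is returned as a plain structure of the same class with
#'   provenance noting the transform).
#' @export
clr_timeseries <- function(tst, pseudocount = 0.5) {
  stopifnot(inherits(tst, "time_series_table"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  v <- tst$values + pseudocount
  lv <- log(v)
  # center over taxa within each (individual, time) slice
  m <- apply(lv, c(1, 3), mean)
  out <- tst
  out$values <- sweep_taxa_mean(lv, m)
  out$provenance <- c(tst$provenance,
                      sprintf("pseudocount=%g", pseudocount), "clr")
  class(out) <- class(tst)
  out
}

# subtract the (individual, time) mean from every taxon slice of an N x D x T
# array
sweep_taxa_mean <- function(lv, m) {
  d <- dim(lv)
  arr <- lv
  for (t in seq_len(d[3])) arr[, , t] <- lv[, , t] - m[, t]
  arr
}

#' Flatten a longitudinal array to individuals x (taxa * time)
#'
#' Columns are laid out taxon-major: for taxon k the T consecutive columns
#' (k-1)*T + 1 .. k*T hold its trajectory. This is the layout assumed by
#' [signature_longitudinal()].
#'
#' @param tst a `time_series_table` without missing values.
#' @return N x (D*T) matrix with column names `<taxon>@t<time>`.
#' @export
flatten_timeseries <- function(tst) {
  stopifnot(inherits(tst, "time_series_table"))
  v <- tst$values
  if (anyNA(v))
    stop("missing time points present; use the continuous kernels instead")
  d <- dim(v)
  # aperm to N x T x D then flatten so taxa vary slowest
  F <- matrix(aperm(v, c(1, 3, 2)), nrow = d[1])
  rownames(F) <- dimnames(v)[[1]]
  colnames(F) <- as.vector(outer(paste0("@t", dimnames(v)[[3]]),
                                 dimnames(v)[[2]],
                                 function(t, k) paste0(k, t)))
  F
}

#' Feature map of the discrete functional linear kernel
#'
#' Returns sqrt(dt) times the flattened array, so that the multivariate
#' functional linear kernel equals the matrix of row inner products exactly.
#' Use these features when retrieving longitudinal signatures.
#'
#' @param tst a `time_series_table` on a regular grid.
#' @param dt time increment; by default derived from the grid.
#' @return N x (D*T) matrix.
#' @export
functional_features <- function(tst, dt = NULL) {
  dt <- resolve_dt(tst, dt)
  sqrt(dt) * flatten_timeseries(tst)
}

# common time increment of a regular grid; errors on irregular grids
resolve_dt <- function(tst, dt = NULL) {
  if (!is.null(dt)) {
    if (dt <= 0) stop("dt must be positive")
    return(dt)
  }
  tt <- tst$times
  if (length(tt) == 1) return(1)
  dts <- diff(tt)
  if (max(dts) - min(dts) > 1e-8 * max(dts))
    stop("irregular time grid (increments ",
         paste(signif(dts, 4), collapse = ", "),
         "); the discrete functional kernels require a common increment - ",
         "supply dt explicitly or use the continuous kernels")
  dts[1]
}
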