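#' Construct an abundance table
#'
#' Container for a samples-by-taxa abundance matrix, either raw sequencing
#' counts or relative abundances (per-sample proportions). Rows are samples,
#' columns are taxa. All kernel constructors in the package take this object
#' (or a bare numeric matrix, which is wrapped on the fly).
#'
#' @param values numeric matrix, N samples x D taxa, all entries >= 0.
#' @param sample_ids character vector of N unique sample identifiers.
#'   Defaults to `rownames(values)` or `"S1".."SN"`.
#' @param taxon_ids character vector of D unique taxon identifiers.
#'   Defaults to `colnames(values)` or `"T1".."TD"`.
#' @param scale `"counts"` or `"relative"`. Relative tables must have rows
#'   summing to 1 (tolerance 1e-8).
#' @param provenance character vector recording preprocessing steps applied.
#'
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (matrix with dimnames), `scale` and `provenance`.
#' @export
abundance_table <- function(values, sample_ids = NULL, taxon_ids = NULL,
                            scale = c("counts", "relative"),
                            provenance = character()) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(values)
    if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  if (length(taxon_ids) != ncol(values))
    stop("length(taxon_ids) must equal ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon_ids: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (anyNA(values)) stop("abundance values contain NA/NaN")
  if (any(values < 0)) stop("abundance values must be non-negative")
  dimnames(values) <- list(sample_ids, taxon_ids)
  if (scale == "relative") {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-8))
      stop("scale = 'relative' but rows do not sum to 1: ",
           paste(sample_ids[abs(rs - 1) > 1e-8][1:min(5, sum(abs(rs - 1) > 1e-8))],
                 collapse = ", "))
  }
  structure(list(values = values, scale = scale, provenance = provenance),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table (", x$scale, "): ",
      nrow(x$values), " samples x ", ncol(x$values), " taxa\n", sep = "")
  zf <- mean(x$values == 0)
  cat(sprintf("  zero fraction: %.3f\n", zf))
  if (length(x$provenance))
    cat("  preprocessing:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# Accept an abundance_table or a bare matrix anywhere a table is expected.
as_abundance <- function(x, scale = "counts") {
  if (inherits(x, "abundance_table")) return(x)
  abundance_table(x, scale = scale)
}

#' Pseudocount zero replacement
#'
#' Adds a constant pseudocount below the detection limit to *all* entries of
#' the table (not only the zeros), so that every entry becomes strictly
#' positive and log-ratio transforms are defined. The default of 0.5 reads as
#' half of one read for count tables.
#'
#' @param table an `abundance_table` (or numeric matrix).
#' @param pseudocount positive constant added to every entry.
#' @return An `abundance_table` with strictly positive entries and updated
#'   provenance.
#' @export
replace_zeros <- function(table, pseudocount = 0.5) {
  table <- as_abundance(table)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  out <- table
  out$values <- table$values + pseudocount
  # a relative table offset by a constant is no longer closed to 1
  if (table$scale == "relative") out$scale <- "counts"
  out$provenance <- c(table$provenance,
                      sprintf("pseudocount=%g", pseudocount))
  out
}

#' Centered log-ratio (clr) transform
#'
#' Maps each sample composition x to log(x / G(x)) where G is the geometric
#' mean of the sample. Rows of the result sum to zero; the transform is
#' invariant to per-sample rescaling, which makes downstream kernels
#' compositional.
#'
#' @param table an `abundance_table` (or matrix) with strictly positive
#'   entries; apply [replace_zeros()] first if the table contains zeros.
#' @return N x D numeric matrix of clr coordinates, dimnames preserved.
#' @export
clr_transform <- function(table) {
  x <- as_abundance(table)$values
  if (any(x <= 0))
    stop("clr transform requires strictly positive entries; ",
         "apply replace_zeros() first")
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Normalizes count samples by the cumulative sum of each sample's counts up
#' to a chosen quantile of its nonzero counts, rather than by the full
#' library size, making the scaling robust to a few dominant taxa. Scaled
#' samples are put back on a common magnitude by multiplying with the median
#' of the per-sample scaling sums.
#'
#' @param table an `abundance_table` of counts.
#' @param quantile quantile in (0,1) of the nonzero counts up to which the
#'   cumulative sum is taken (default 0.5).
#' @return An `abundance_table` of normalized values with provenance noting
#'   the quantile.
#' @export
css_normalize <- function(table, quantile = 0.5) {
  table <- as_abundance(table)
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile <= 0 || quantile >= 1)
    stop("quantile must lie strictly inside (0, 1)")
  x <- table$values
  all_zero <- rowSums(x) == 0
  if (any(all_zero))
    stop("sample(s) with all-zero counts: ",
         paste(rownames(x)[all_zero], collapse = ", "))
  s <- vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]
    nz <- xi[xi > 0]
    q <- stats::quantile(nz, probs = quantile, names = FALSE)
    sum(xi[xi <= q])
  }, numeric(1))
  common <- stats::median(s)
  out <- table
  out$values <- x / s * common
  out$provenance <- c(table$provenance, sprintf("css(q=%g)", quantile))
  out
}

#' Close a count table to relative abundances
#'
#' @param table an `abundance_table` of counts.
#' @return An `abundance_table` with `scale = "relative"`.
#' @export
relative_abundance <- function(table) {
  table <- as_abundance(table)
  rs <- rowSums(table$values)
  if (any(rs == 0))
    stop("sample(s) with all-zero counts: ",
         paste(rownames(table$values)[rs == 0], collapse = ", "))
  out <- table
  out$values <- table$values / rs
  out$scale <- "relative"
  out$provenance <- c(table$provenance, "closed-to-1")
  out
}
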