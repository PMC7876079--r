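#' Read an abundance table from TSV
#'
#' Expects samples in rows: a header line, a first column named `sample_id`,
#' and one column per taxon. Duplicate ids, negative values and missing
#' entries are rejected with the offending rows/columns named.
#'
#' @param path file path.
#' @param scale `"counts"` or `"relative"`.
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, scale = "counts") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "sample_id"))
    stop("first column must be named 'sample_id', got '", names(df)[1], "'")
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))]
    stop("non-numeric taxon column(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(X)) {
    bad <- ids[rowSums(is.na(X)) > 0]
    stop("missing values in sample(s): ", paste(bad, collapse = ", "))
  }
  abundance_table(X, sample_ids = ids, scale = scale)
}

#' Write an abundance table to TSV
#'
#' @param table an `abundance_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  table <- as_abundance(table)
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kernel matrix from TSV
#'
#' Expects a header row and a first column both carrying the sample ids.
#' The matrix is validated on read: asymmetry beyond tolerance or clear
#' non-PSD-ness fails with the [check_psd()] report in the message.
#'
#' @param path file path.
#' @param validate run [check_psd()] and fail if it fails (default TRUE).
#' @param tol validation tolerance.
#' @return A `kernel_matrix`.
#' @export
read_kernel_matrix <- function(path, validate = TRUE, tol = 1e-8) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(M), ids))
    stop("kernel TSV header ids do not match first-column ids")
  rownames(M) <- ids
  if (validate) {
    rep <- check_psd(M, tol = tol)
    if (!rep$pass)
      stop(sprintf(paste0("kernel matrix failed validation: symmetry ",
                          "deviation %.3g, min eigenvalue %.3g (tol %g)"),
                   rep$symmetry_deviation, rep$min_eigenvalue, tol))
  }
  kernel_matrix(M, ids, meta = list(kernel = "precomputed", source = path),
                validate = FALSE)
}

#' Write a kernel matrix to TSV
#'
#' Values are written with 17 significant digits so that write -> read
#' round-trips are bit-exact for doubles.
#'
#' @param K a `kernel_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_kernel_matrix <- function(K, path) {
  M <- kmat(K)
  ids <- rownames(M)
  lines <- c(paste(c("sample_id", ids), collapse = "\t"),
             vapply(seq_len(nrow(M)), function(i)
               paste(c(ids[i], formatC(M[i, ], digits = 17, format = "g")),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with a `sample_id` first column. When `table` is given, alignment is
#' validated eagerly: samples of the abundance table missing from the
#' metadata (or vice versa) are an error listing them.
#'
#' @param path file path.
#' @param table optional `abundance_table` to validate against.
#' @return data frame with sample ids as row names.
#' @export
read_metadata <- function(path, table = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "sample_id"))
    stop("first column must be named 'sample_id', got '", names(df)[1], "'")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample_ids in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(df) <- ids
  df <- df[, -1, drop = FALSE]
  if (!is.null(table)) {
    table <- as_abundance(table)
    missing <- setdiff(rownames(table$values), ids)
    if (length(missing))
      stop("metadata is missing sample(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read long-format longitudinal data
#'
#' TSV with columns `sample_id`, `individual_id`, `time`, then one column per
#' taxon; reshaped to a `time_series_table` on the union time grid, with NA
#' for unobserved (individual, time) combinations.
#'
#' @param path file path.
#' @return A `time_series_table`.
#' @export
read_timeseries_long <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "time")
  if (!identical(names(df)[1:3], need))
    stop("first three columns must be ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  key <- paste(df$individual_id, df$time)
  if (anyDuplicated(key))
    stop("duplicate (individual, time) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  inds <- unique(as.character(df$individual_id))
  times <- sort(unique(as.numeric(df$time)))
  taxa <- names(df)[-(1:3)]
  arr <- array(NA_real_, dim = c(length(inds), length(taxa), length(times)),
               dimnames = list(inds, taxa, as.character(times)))
  for (r in seq_len(nrow(df))) {
    arr[as.character(df$individual_id[r]), ,
        as.character(as.numeric(df$time[r]))] <-
      as.numeric(df[r, -(1:3)])
  }
  time_series_table(arr, inds, taxa, times)
}

#' Write longitudinal data in long format
#'
#' @param tst a `time_series_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_long <- function(tst, path) {
  stopifnot(inherits(tst, "time_series_table"))
  v <- tst$values
  d <- dim(v)
  rows <- list()
  for (t in seq_len(d[3])) {
    slice <- v[, , t, drop = FALSE][, , 1]
    keep <- rowSums(is.na(slice)) < ncol(slice)
    if (!any(keep)) next
    rows[[t]] <- data.frame(
      sample_id = paste0(rownames(slice)[keep], "_t", tst$times[t]),
      individual_id = rownames(slice)[keep],
      time = tst$times[t],
      slice[keep, , drop = FALSE],
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
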