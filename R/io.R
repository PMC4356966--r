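# Plain-text input/output.  Datasets live on disk as 0/1 delimited text
# (comma or tab, auto-detected, optional header row of node labels) and
# are mapped to the +1/-1 spin coding at the boundary via sigma = 2y - 1.

detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else " "
}

#' Read a binary dataset from delimited text
#'
#' Rows are replications, columns nodes; entries must be 0 or 1 and are
#' converted to -1/+1.  The delimiter (comma or tab) and the presence of a
#' header row are detected automatically.
#'
#' @param path file path.
#' @return `N x n` matrix of +1/-1 states; node labels, if present, become
#'   column names.
#' @export
read_ising_data <- function(path) {
  if (!file.exists(path)) stop(sprintf("data file not found: %s", path))
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop(sprintf("data file is empty: %s", path))
  sep <- detect_sep(first)
  tokens <- strsplit(first, sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(tokens))))
  df <- utils::read.table(path, header = header, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(apply(df, 1, function(z) any(is.na(suppressWarnings(as.numeric(z))))))[1]
    stop(sprintf("non-numeric entry in %s at data line %d", path, bad))
  }
  if (!all(m %in% c(0, 1))) {
    bad <- which(apply(m, 1, function(z) !all(z %in% c(0, 1))))[1]
    stop(sprintf("entries must be 0/1 in %s; first bad line: %d", path, bad))
  }
  out <- 2 * m - 1
  if (header) rownames(out) <- NULL else dimnames(out) <- NULL
  out
}

#' Write a binary dataset as comma-separated 0/1 text
#'
#' @param data `N x n` matrix of +1/-1 states.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ising_data <- function(data, path) {
  data <- check_dataset(data)
  y <- (data + 1) / 2
  colnames(y) <- if (!is.null(colnames(data))) colnames(data)
                 else sprintf("n%d", seq_len(ncol(y)))
  utils::write.table(y, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read or write a numeric matrix as delimited text
#'
#' Headerless comma- or tab-delimited numeric matrices (connectivity
#' matrices, loadings, sufficient statistics, chain draws).
#'
#' @param path file path.
#' @return For `read_delim_matrix`, a numeric matrix.
#' @export
read_delim_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path))
  sep <- detect_sep(readLines(path, n = 1))
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop(sprintf("non-numeric entries in %s", path))
  m
}

#' @rdname read_delim_matrix
#' @param x numeric matrix or vector.
#' @export
write_delim_matrix <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scree listing of an eigenvalue spectrum
#'
#' Two-column text (index, eigenvalue), eigenvalues in decreasing order.
#'
#' @param spec an [ising_spectrum()] or numeric vector of eigenvalues.
#' @param path output file path.
#' @export
write_scree <- function(spec, path) {
  lambda <- if (inherits(spec, "ising_spectrum")) spec$lambda else as.numeric(spec)
  utils::write.table(data.frame(index = seq_along(lambda), eigenvalue = lambda),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
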