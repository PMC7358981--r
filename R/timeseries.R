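#' Drop initial volumes from a time-series matrix
#'
#' rs-fMRI acquisitions typically discard the leading volumes to let the
#' scanner signal reach steady state; with 140 acquired volumes and the
#' default of 10 discarded, K = 130 timepoints remain.
#'
#' @param x Numeric matrix, rows = ROI, columns = timepoints.
#' @param n_discard Number of leading columns to drop (default 10).
#' @return The matrix without its first `n_discard` columns.
#' @examples
#' x <- matrix(rnorm(26 * 140), nrow = 26)
#' ncol(discard_initial_volumes(x))   # 130
#' @export
discard_initial_volumes <- function(x, n_discard = 10L) {
  x <- as.matrix(x)
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("`n_discard` must be non-negative", call. = FALSE)
  if (n_discard >= ncol(x)) {
    stop("`n_discard` (", n_discard, ") must be smaller than the number of ",
         "timepoints (", ncol(x), ")", call. = FALSE)
  }
  if (n_discard == 0L) return(x)
  x[, -seq_len(n_discard), drop = FALSE]
}

#' Read one subject's ROI time series from delimited text
#'
#' Expects one row per ROI and one column per timepoint. If the first column
#' is non-numeric it is taken as ROI abbreviations and used as row names; when
#' an atlas is supplied the labels must then match the atlas order exactly.
#'
#' @param file Path to a TSV/CSV file.
#' @param atlas Optional `dmn_atlas` used to validate row order.
#' @param sep Field separator (default tab).
#' @return Numeric matrix, rows = ROI, columns = timepoints.
#' @export
read_timeseries <- function(file, atlas = NULL, sep = "\t") {
  raw <- utils::read.table(file, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if (ncol(raw) > 1L && !is.numeric(raw[[1L]])) {
    labels <- as.character(raw[[1L]])
    raw <- raw[, -1L, drop = FALSE]
  }
  x <- as.matrix(raw)
  if (!is.numeric(x)) stop("time-series file contains non-numeric values",
                           call. = FALSE)
  if (anyNA(x)) stop("time-series file contains missing values", call. = FALSE)
  rownames(x) <- labels
  colnames(x) <- NULL
  if (!is.null(atlas) && !is.null(labels)) {
    if (!identical(labels, atlas$abbreviation)) {
      stop("ROI labels in ", file, " do not match the atlas row order",
           call. = FALSE)
    }
  }
  x
}

#' Write one subject's ROI time series as delimited text
#'
#' @param x Numeric matrix, rows = ROI (row names used as labels when set).
#' @param file Output path.
#' @param sep Field separator (default tab).
#' @return `file`, invisibly.
#' @export
write_timeseries <- function(x, file, sep = "\t") {
  x <- as.matrix(x)
  out <- data.frame(roi = if (is.null(rownames(x)))
    paste0("ROI", seq_len(nrow(x))) else rownames(x), x,
    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("roi", paste0("t", seq_len(ncol(x))))
  utils::write.table(out, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a square weighted network matrix from delimited text
#'
#' @param file Path to a delimited square matrix with an abbreviation header
#'   row and first column.
#' @param sep Field separator (default tab).
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_network <- function(file, sep = "\t") {
  raw <- utils::read.table(file, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE)
  W <- as.matrix(raw)
  validate_network(W)
}

#' Write a weighted network matrix as delimited text
#'
#' @param net Symmetric numeric matrix (zero diagonal) with node labels as
#'   dimnames.
#' @param file Output path.
#' @param sep Field separator (default tab).
#' @return `file`, invisibly.
#' @export
write_network <- function(net, file, sep = "\t") {
  net <- validate_network(net)
  out <- data.frame(node = rownames(net), net, check.names = FALSE)
  utils::write.table(out, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}
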