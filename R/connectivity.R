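#' Pearson dissimilarity between two series
#'
#' The functional connectivity weight between two ROI signals: one minus
#' their sample Pearson correlation, computed from the mean-centred cross
#' products normalised by the product of root sums of squares. Because the
#' same centring enters numerator and denominator, no n versus n-1 choice
#' arises. The correlation is clipped to \[-1, 1\] before subtraction to
#' guard against rounding drift, so the weight always lies in \[0, 2\]:
#' 0 for perfectly correlated series, 1 for uncorrelated, 2 for perfectly
#' anti-correlated. Negative correlations are retained as weights above 1;
#' no absolute value or thresholding is applied.
#'
#' @param a,b Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return A single weight in \[0, 2\].
#' @examples
#' pearson_dissimilarity(1:4, c(1, 2, 4, 3))   # 0.2
#' @export
pearson_dissimilarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(a) < 3L) stop("series must have length >= 3", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("series contain missing values", call. = FALSE)
  da <- a - mean(a)
  db <- b - mean(b)
  ssa <- sum(da^2)
  ssb <- sum(db^2)
  if (ssa == 0 || ssb == 0) {
    stop("degenerate signal: zero-variance series", call. = FALSE)
  }
  r <- sum(da * db) / sqrt(ssa * ssb)
  1 - min(1, max(-1, r))
}

#' Build a subject's weighted connectivity network
#'
#' Selects the rows of `ts` belonging to `scope` and computes all pairwise
#' Pearson dissimilarities, yielding a symmetric matrix with zero diagonal
#' whose entries lie in \[0, 2\]. For the whole-brain scope the result is
#' N = 26 x 26 with the default atlas; each hemisphere gives 13 x 13, equal
#' to the corresponding submatrix of the whole-brain network.
#'
#' Hemisphere membership is taken from the atlas when `ts` covers it
#' row-for-row; otherwise it is inferred from a ".L"/".R" suffix on the row
#' names (as written by [simulate_cohort()] for non-standard node counts).
#'
#' @param ts Numeric matrix, rows = ROI in atlas order, columns = timepoints.
#' @param scope `"both"`, `"left"` or `"right"`.
#' @param atlas Atlas data frame; consulted when `nrow(ts)` matches it.
#' @return Symmetric weight matrix with node abbreviations as dimnames.
#' @export
build_network <- function(ts, scope = c("both", "left", "right"),
                          atlas = dmn_atlas()) {
  scope <- match.arg(scope)
  ts <- as.matrix(ts)
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  if (ncol(ts) < 3L) stop("need at least 3 timepoints", call. = FALSE)

  labels <- rownames(ts)
  if (!is.null(atlas) && nrow(ts) == nrow(atlas)) {
    hemis <- atlas$hemisphere
    if (is.null(labels)) labels <- atlas$abbreviation
  } else if (!is.null(labels) && all(grepl("\\.(L|R)$", labels))) {
    hemis <- ifelse(grepl("\\.L$", labels), "left", "right")
  } else if (scope == "both") {
    hemis <- rep(NA_character_, nrow(ts))
    if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(ts)))
  } else {
    stop("hemispheric scope requires an atlas-sized matrix or ",
         "'.L'/'.R'-suffixed row names", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(ts)))

  rows <- switch(scope,
    both  = seq_len(nrow(ts)),
    left  = which(hemis == "left"),
    right = which(hemis == "right")
  )
  X <- ts[rows, , drop = FALSE]
  if (nrow(X) < 2L) stop("scope selects fewer than 2 nodes", call. = FALSE)

  Xc <- X - rowMeans(X)
  ss <- rowSums(Xc^2)
  if (any(ss == 0)) {
    bad <- labels[rows][ss == 0]
    stop("degenerate signal (zero variance) in ROI: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- tcrossprod(Xc) / sqrt(outer(ss, ss))
  R <- pmin(pmax(R, -1), 1)
  W <- 1 - R
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- list(labels[rows], labels[rows])
  W
}

# Shared validation for weighted network matrices: symmetric, zero diagonal,
# non-negative real entries. Returns the matrix (with symmetrised rounding
# noise removed) or errors.
validate_network <- function(net) {
  W <- as.matrix(net)
  if (nrow(W) != ncol(W)) stop("network matrix must be square", call. = FALSE)
  if (!is.numeric(W) || anyNA(W)) {
    stop("network matrix must be numeric with no missing values",
         call. = FALSE)
  }
  if (max(abs(W - t(W))) > 1e-8) {
    stop("network matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(W)) > 1e-12)) {
    stop("network matrix must have a zero diagonal", call. = FALSE)
  }
  if (any(W < 0)) stop("network weights must be non-negative", call. = FALSE)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (is.null(rownames(W))) {
    dimnames(W) <- list(paste0("ROI", seq_len(nrow(W))),
                        paste0("ROI", seq_len(nrow(W))))
  }
  W
}
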