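#' Integrated persistent feature (IPF) curve
#'
#' For filtration values \eqn{\lambda_0 = 0 \le \lambda_1 \le \dots \le
#' \lambda_{m-1}} the IPF at step i is
#' \deqn{IPF_i = \frac{m-i}{m(m-1)} \sum_{k=i+1}^{m-1} \lambda_k, \quad 0 \le i \le m-2,}
#' and 0 at i = m - 1. It weights the remaining aggregation cost (the tail
#' sum of filtration values still to be paid before the network becomes a
#' single component) by the fraction of components still separate, giving a
#' monotonically non-increasing curve that terminates at 0.
#'
#' @param lambdas Non-decreasing, non-negative numeric vector of length
#'   m >= 2 with `lambdas[1] == 0` (the filtration values, e.g. from
#'   [filtration_values()]).
#' @return A data frame of class `ipf_profile` with columns `lambda`, `ipf`.
#' @examples
#' ipf_curve(c(0, 0.2, 0.4))$ipf   # 0.3, 0.1333..., 0
#' @export
ipf_curve <- function(lambdas) {
  lambdas <- as.numeric(lambdas)
  m <- length(lambdas)
  if (m < 2L) stop("need at least 2 filtration values", call. = FALSE)
  if (anyNA(lambdas) || any(lambdas < 0)) {
    stop("filtration values must be non-negative and non-missing",
         call. = FALSE)
  }
  if (abs(lambdas[1L]) > 1e-12) {
    stop("the first filtration value must be 0", call. = FALSE)
  }
  if (any(diff(lambdas) < 0)) {
    stop("filtration values must be non-decreasing", call. = FALSE)
  }
  # tail[k] = sum of lambdas[k..m]
  tail_sums <- rev(cumsum(rev(lambdas)))
  ipf <- numeric(m)
  idx <- seq_len(m - 1L)                       # 1-based step j = i + 1
  ipf[idx] <- (m - idx + 1L) / (m * (m - 1L)) * c(tail_sums[-1L], 0)[idx]
  ipf[m] <- 0
  structure(data.frame(lambda = lambdas, ipf = ipf),
            class = c("ipf_profile", "data.frame"))
}

#' Ordinary least-squares slope
#'
#' Slope of the least-squares line of `ys` on `xs`; the scalar reduction used
#' for both persistent-feature curves.
#'
#' @param xs,ys Numeric vectors of equal length >= 2; `xs` must not be
#'   constant.
#' @return The OLS slope.
#' @export
slope_statistic <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length",
                                     call. = FALSE)
  if (length(xs) < 2L) stop("need at least 2 points", call. = FALSE)
  if (anyNA(xs) || anyNA(ys)) stop("inputs contain missing values",
                                   call. = FALSE)
  dx <- xs - mean(xs)
  sxx <- sum(dx^2)
  if (sxx == 0) stop("degenerate xs: all values identical", call. = FALSE)
  sum(dx * (ys - mean(ys))) / sxx
}

#' Slope of the IPF plot (SIP)
#'
#' Fits an OLS line to the IPF curve over all m filtration points (including
#' the origin point at lambda = 0) and returns its slope. The IPF curve is
#' non-increasing with positive initial value for any network with positive
#' MST weights, so SIP is negative; a steeper (more negative) SIP indicates
#' faster aggregation of connected components, interpretable as a higher
#' information-diffusion / convergence rate. SIP is invariant to a common
#' positive rescaling of all weights.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return The SIP scalar.
#' @export
compute_sip <- function(net) {
  lambdas <- filtration_values(minimum_spanning_tree(net))
  prof <- ipf_curve(lambdas)
  slope_statistic(prof$lambda, prof$ipf)
}

#' Betti number plot slope (BNP)
#'
#' The per-subject scalar reduction of the Betti number curve: the OLS slope
#' of the zeroth Betti number against the filtration value over the m
#' filtration points. Like SIP it is negative for any non-degenerate network
#' and more negative when components aggregate faster; unlike SIP it scales
#' inversely with a common rescaling of the weights.
#'
#' @param net Symmetric non-negative weight matrix with zero diagonal.
#' @return The BNP scalar.
#' @export
compute_bnp <- function(net) {
  prof <- betti0_curve(net)
  slope_statistic(prof$lambda, prof$betti0)
}
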