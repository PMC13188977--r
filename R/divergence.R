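#' Kolmogorov-Smirnov distance between two distance multisets
#'
#' The supremum absolute difference between the empirical CDFs of two
#' multisets of within-group dissimilarities, evaluated exactly over the
#' merged jump points. Sensitive to location-scale differences between the
#' two distributions. No asymptotic p-value is attached: within-group
#' distances are not independent, so significance must come from the
#' permutation engine.
#'
#' @param a,b [within_group_set()] objects or nonempty numeric vectors.
#' @return the KS statistic, a number in \eqn{[0, 1]}.
#' @export
ks_statistic <- function(a, b) {
  .kw_stat_cpp(set_values(a), set_values(b))[["K"]]
}

#' 1-Wasserstein distance between two distance multisets
#'
#' The integral \eqn{\int |F_A(z) - F_B(z)|\, dz} of the absolute difference
#' of the two empirical CDFs, computed exactly over the merged step
#' functions (no subsampling, so unequal cardinalities are handled exactly).
#' For equal cardinalities this equals the mean absolute difference of the
#' sorted values. Sensitive to tail and outlier differences.
#'
#' @inheritParams ks_statistic
#' @return the 1-Wasserstein distance, a nonnegative number.
#' @export
wasserstein1 <- function(a, b) {
  .kw_stat_cpp(set_values(a), set_values(b))[["W"]]
}

# Both statistics in one pass (used by the pooled-scheme replicate loop).
kw_statistics <- function(a, b) {
  .kw_stat_cpp(set_values(a), set_values(b))
}

set_values <- function(s) {
  v <- if (inherits(s, "within_group_set")) s$distances else as.numeric(s)
  if (length(v) == 0L) stop("distance set is empty")
  if (anyNA(v)) stop("distance set contains missing values")
  v
}
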