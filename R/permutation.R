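#' Null replicate within-group distance sets
#'
#' Generates `R` replicate families of within-group distance multisets whose
#' dispersion is, by construction, the same in every group, for use as a
#' permutation null. Two schemes are available:
#'
#' * `"labels"` (default): the group labels are uniformly permuted over the
#'   samples and the within-group sets re-extracted from the fixed
#'   dissimilarity matrix. This preserves the dependence structure among
#'   within-group distances (they share samples, so they are not independent)
#'   and is exact whenever the samples are exchangeable under the null.
#' * `"pooled"`: the observed within-group distances of all groups are pooled
#'   and randomly partitioned into sets of the original cardinalities. This
#'   never touches between-group distances, making it a location-robust
#'   option when group centroids may differ.
#'
#' Every replicate preserves the per-group cardinalities
#' \eqn{n_g (n_g - 1)/2}; under `"pooled"` the pooled multiset is preserved
#' exactly. Results are deterministic given `seed`.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param group group labels, one per sample; every group must have
#'   \eqn{n_g \ge 2}.
#' @param R number of replicates (\eqn{\ge 1}).
#' @param scheme `"labels"` or `"pooled"`.
#' @param seed optional integer seed.
#' @return an object of class `"replicate_stream"`: a list with elements
#'   `R`, `scheme`, `seed`, `cardinalities`, and `replicates` — a list of `R`
#'   families, each a named list of per-group numeric distance vectors.
#' @export
make_replicates <- function(d, group, R, scheme = c("labels", "pooled"),
                            seed = NULL) {
  scheme <- match.arg(scheme)
  d <- as_distance_matrix(d)
  group <- check_groups(group, nrow(d))
  if (!is.numeric(R) || length(R) != 1L || R < 1) stop("'R' must be >= 1")
  R <- as.integer(R)
  if (!is.null(seed)) set.seed(seed)

  obs <- within_group_sets(d, group)
  card <- lengths(obs)
  reps <- vector("list", R)
  if (scheme == "labels") {
    lab <- group
    for (r in seq_len(R)) {
      lab <- lab[shuffle_perm(length(lab))]
      reps[[r]] <- within_group_sets(d, lab)
    }
  } else {
    pooled <- unlist(obs, use.names = FALSE)
    ends <- cumsum(card)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (r in seq_len(R)) {
      shuffled <- pooled[shuffle_perm(length(pooled))]
      reps[[r]] <- stats::setNames(
        lapply(seq_along(card), function(g) shuffled[starts[g]:ends[g]]),
        names(card))
    }
  }
  structure(list(R = R, scheme = scheme, seed = seed,
                 cardinalities = card, replicates = reps),
            class = "replicate_stream")
}

#' @export
print.replicate_stream <- function(x, ...) {
  cat("Replicate stream:", x$R, "replicates, scheme '", x$scheme,
      "', group cardinalities ", paste(x$cardinalities, collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

# Fisher-Yates permutation of 1..n driven by runif(), one draw per swap,
# mirroring the in-kernel C++ shuffle exactly (same unif_rand call sequence),
# so R-level and C++-level replicate streams coincide for a given seed.
shuffle_perm <- function(n) {
  idx <- seq_len(n)
  for (i in n:2) {
    j <- floor(runif(1) * i) + 1
    if (j > i) j <- i
    tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
  }
  idx
}

#' Permutation p-value
#'
#' The standard add-one permutation p-value
#' \eqn{(1 + \#\{r : T_r > T_0\}) / (R + 1)} (strict inequality), which is
#' never zero and valid under exchangeability.
#'
#' @param t0 observed statistic.
#' @param treps numeric vector of replicate statistics.
#' @return a number in \eqn{[1/(R+1), 1]}.
#' @export
permutation_pvalue <- function(t0, treps) {
  if (length(treps) == 0L) stop("no replicate statistics supplied")
  (1 + sum(treps > t0)) / (length(treps) + 1)
}

#' Rank-based p-values for null replicates
#'
#' Assigns each replicate statistic the p-value \eqn{rank(-T_r)/R}: the
#' largest replicate gets \eqn{1/R}, the smallest gets 1. Each replicate is
#' effectively compared with the remaining \eqn{R - 1}, hence the divisor
#' \eqn{R}. Ties receive the maximum (most conservative) rank of the tied
#' block.
#'
#' @param treps numeric vector of replicate statistics.
#' @return numeric vector of p-values in \eqn{(0, 1]}.
#' @export
replicate_pvalues <- function(treps) {
  if (length(treps) == 0L) stop("no replicate statistics supplied")
  rank(-treps, ties.method = "max") / length(treps)
}
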