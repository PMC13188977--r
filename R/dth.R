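#' Omnibus combination of the KS and Wasserstein p-values
#'
#' Combines the permutation p-values of the Kolmogorov-Smirnov and
#' 1-Wasserstein tests into the omnibus statistic \eqn{m = 1 - \min(p_K,
#' p_W)}, for which larger values imply stronger evidence against
#' homogeneity. Monotone decreasing in each argument.
#'
#' @param pK,pW p-values in \eqn{(0, 1]}; vectors are combined elementwise.
#' @return \eqn{1 - \min(p_K, p_W)}, in \eqn{[0, 1)}.
#' @export
omnibus_m <- function(pK, pW) {
  if (any(pK <= 0 | pK > 1) || any(pW <= 0 | pW > 1))
    stop("p-values must lie in (0, 1]")
  1 - pmin(pK, pW)
}

#' Fisher's combination statistic
#'
#' \eqn{f = -\sum \ln p} over a collection of p-values, here the pairwise
#' omnibus p-values of all \eqn{G(G-1)/2} group pairs. Large values signal
#' joint evidence against homogeneity.
#'
#' @param p numeric vector of p-values in \eqn{(0, 1]}.
#' @return the Fisher statistic, a nonnegative number.
#' @export
fisher_statistic <- function(p) {
  if (length(p) == 0L) stop("no p-values supplied")
  if (any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]; the add-one permutation convention never produces 0")
  -sum(log(p))
}

#' Distance-based test of homogeneity of multivariate dispersions (DTH)
#'
#' Tests whether the distribution of within-group pairwise dissimilarities is
#' the same in every group. Unlike tests that compare a single dispersion
#' parameter (mean distance to centroid, mean squared within-group distance),
#' DTH compares the full empirical distributions \eqn{\bar F_g} of
#' within-group dissimilarities, using both the Kolmogorov-Smirnov distance
#' (powerful against location-scale differences) and the 1-Wasserstein
#' distance (powerful against tail/outlier differences) between each pair of
#' groups.
#'
#' For each pair of groups the two statistics are computed on the observed
#' data and on `R` null replicates generated by the permutation engine
#' ([make_replicates()]); each statistic is converted to an add-one
#' permutation p-value (observed) and rank-based p-values (replicates), and
#' the two are combined into the omnibus statistic \eqn{m = 1 - \min(p_K,
#' p_W)}. With two groups the final p-value is the permutation p-value of
#' \eqn{m}; with more groups the pairwise omnibus p-values are combined with
#' Fisher's statistic \eqn{f = -\sum \ln p_m} and the final p-value is the
#' permutation p-value of \eqn{f}. All replicate statistics for all pairs and
#' both statistics come from one shared replicate stream.
#'
#' Asymptotic null distributions are never used: within-group distances share
#' samples and are not independent.
#'
#' @param d symmetric pairwise dissimilarity matrix (or `dist` object). Use
#'   [dth_test_from_table()] to start from a feature table.
#' @param group group labels, one per sample; \eqn{G \ge 2} groups, each with
#'   \eqn{n_g \ge 2} samples.
#' @param R number of permutation replicates; the attainable p-value
#'   resolution is \eqn{1/(R+1)}.
#' @param scheme replicate-generation scheme, `"labels"` (default) or
#'   `"pooled"`; see [make_replicates()].
#' @param seed optional integer seed; identical seeds give bit-identical
#'   results.
#' @param metric optional character tag recording how `d` was obtained
#'   (stored in the result, not used in computation).
#' @param force_fisher run the multi-group (Fisher-combination) code path
#'   even when \eqn{G = 2}; the final p-value is identical to the dedicated
#'   two-group path apart from ties, so this is mainly a consistency check.
#' @return an object of class `"dth"`; see Details. Its elements include
#'   `per_pair` (a data frame with one row per group pair: `K0`, `W0`, `p0K`,
#'   `p0W`, `m0`, `p0m`), `fisher_f0` (for \eqn{G > 2}), `p.value`, `R`,
#'   `scheme`, `seed`, `metric` and the within-group distance sets.
#' @seealso [betadisper_test()], [go_perm_test()] for the comparator tests;
#'   [discretize_covariate()] for continuous covariates.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 10), 40)        # two groups, equal dispersion
#' g <- rep(c("a", "b"), each = 20)
#' dth_test(dist(x), g, R = 99, seed = 1)
#' @export
dth_test <- function(d, group, R = 999, scheme = c("labels", "pooled"),
                     seed = NULL, metric = NULL, force_fisher = FALSE) {
  scheme <- match.arg(scheme)
  d <- as_distance_matrix(d)
  group <- check_groups(group, nrow(d))
  if (!is.numeric(R) || length(R) != 1L || R < 1) stop("'R' must be >= 1")
  R <- as.integer(R)
  if (!is.null(seed)) set.seed(seed)

  G <- nlevels(group)
  sets <- within_group_sets(d, group)

  dvec <- d[upper.tri(d)]
  if (all(dvec == dvec[1L])) {
    warning("all pairwise dissimilarities are equal; ",
            "dispersion statistics are identically zero and p = 1 is returned")
    return(degenerate_dth_result(group, sets, R, scheme, seed, metric))
  }

  kw <- kernel_statistics(d, group, R, scheme)
  res <- dth_from_stats(kw$K, kw$W, G, force_fisher = force_fisher)

  pairs <- group_pairs(levels(group))
  per_pair <- data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                         K0 = kw$K[1L, ], W0 = kw$W[1L, ],
                         p0K = res$p0K, p0W = res$p0W,
                         m0 = res$m0, p0m = res$p0m,
                         row.names = NULL, stringsAsFactors = FALSE)

  structure(list(per_pair = per_pair,
                 fisher_f0 = res$fisher_f0,
                 p.value = res$p.value,
                 R = R, scheme = scheme, seed = seed,
                 metric = if (is.null(metric)) NA_character_ else metric,
                 G = G, n = nrow(d), group_sizes = as.integer(table(group)),
                 groups = levels(group),
                 within = sets,
                 call = match.call()),
            class = "dth")
}

#' DTH from a feature table
#'
#' Convenience front end composing [pairwise_dissimilarity()] and
#' [dth_test()]: computes the dissimilarity matrix with the requested metric
#' and runs the test on it.
#'
#' @param x feature table: numeric matrix or data frame, samples as rows.
#' @param group group labels, one per sample.
#' @param metric dissimilarity metric, as in [pairwise_dissimilarity()].
#' @inheritParams dth_test
#' @return an object of class `"dth"`.
#' @export
dth_test_from_table <- function(x, group,
                                metric = c("euclidean", "braycurtis", "jaccard"),
                                R = 999, scheme = c("labels", "pooled"),
                                seed = NULL, force_fisher = FALSE) {
  metric <- match.arg(metric)
  d <- pairwise_dissimilarity(x, metric)
  dth_test(d, group, R = R, scheme = scheme, seed = seed, metric = metric,
           force_fisher = force_fisher)
}

#' Discretize a continuous covariate into quantile groups
#'
#' Since the dispersion tests operate on groups, association between
#' dispersion and a continuous covariate is tested by discretizing the
#' covariate into near-equal-sized quantile bins and testing homogeneity
#' across the bins.
#'
#' @param x numeric covariate, one value per sample.
#' @param bins number of quantile groups (default 3).
#' @return a factor of length `length(x)` with `bins` levels; values equal to
#'   a bin boundary go to the lower bin.
#' @export
discretize_covariate <- function(x, bins = 3) {
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be numeric with no missing values")
  if (!is.numeric(bins) || length(bins) != 1L || bins < 2) stop("'bins' must be >= 2")
  bins <- as.integer(bins)
  if (length(x) < 2L * bins)
    stop("need at least ", 2L * bins, " samples for ", bins,
         " bins of >= 2 samples each")
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE)
  breaks <- unique(qs)
  if (length(breaks) < 3L)
    stop("covariate has too few distinct values to form ", bins,
         " quantile groups")
  g <- cut(x, breaks = breaks, include.lowest = TRUE, right = TRUE,
           labels = paste0("bin", seq_len(length(breaks) - 1L)))
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("quantile binning left group(s) with fewer than 2 samples; ",
         "try fewer bins")
  droplevels(g)
}

# ---- internals --------------------------------------------------------------

# Upper-triangle index arrays (0-based) matching d[upper.tri(d)] order
# (column-major: pair (i, j), i < j, ordered by j then i).
upper_tri_indices <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L)
}

# Observed + replicate K/W/V statistics for all group pairs, rows r = 0..R.
kernel_statistics <- function(d, group, R, scheme) {
  n <- nrow(d)
  G <- nlevels(group)
  if (scheme == "labels") {
    ut <- upper_tri_indices(n)
    out <- .dth_perm_kernel_cpp(d[upper.tri(d)], ut$i, ut$j,
                                as.integer(group) - 1L, G, R)
  } else {
    sets <- within_group_sets(d, group)
    card <- lengths(sets)
    pooled <- unlist(sets, use.names = FALSE)
    ends <- cumsum(card)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    P <- G * (G - 1L) / 2L
    K <- matrix(0, R + 1L, P)
    W <- matrix(0, R + 1L, P)
    V <- matrix(0, R + 1L, G)
    fam <- sets
    for (r in 0:R) {
      if (r > 0L) {
        shuffled <- pooled[shuffle_perm(length(pooled))]
        fam <- lapply(seq_len(G), function(g) shuffled[starts[g]:ends[g]])
      }
      V[r + 1L, ] <- vapply(fam, function(v) mean(v^2) / 2, numeric(1))
      p <- 1L
      for (g in seq_len(G - 1L)) for (h in (g + 1L):G) {
        st <- .kw_stat_cpp(fam[[g]], fam[[h]])
        K[r + 1L, p] <- st[["K"]]
        W[r + 1L, p] <- st[["W"]]
        p <- p + 1L
      }
    }
    out <- list(K = K, W = W, V = V)
  }
  out
}

# Algorithm core: from (R+1) x P matrices of replicate statistics (row 1 =
# observed) to per-pair p-values and the final DTH p-value.
dth_from_stats <- function(K, W, G, force_fisher = FALSE) {
  R <- nrow(K) - 1L
  P <- ncol(K)
  p0K <- numeric(P); p0W <- numeric(P)
  mr <- matrix(0, R, P)
  m0 <- numeric(P)
  for (p in seq_len(P)) {
    p0K[p] <- permutation_pvalue(K[1L, p], K[-1L, p])
    p0W[p] <- permutation_pvalue(W[1L, p], W[-1L, p])
    prK <- replicate_pvalues(K[-1L, p])
    prW <- replicate_pvalues(W[-1L, p])
    m0[p] <- omnibus_m(p0K[p], p0W[p])
    mr[, p] <- omnibus_m(prK, prW)
  }
  p0m <- vapply(seq_len(P), function(p)
    permutation_pvalue(m0[p], mr[, p]), numeric(1))

  if (G == 2L && !force_fisher) {
    list(p0K = p0K, p0W = p0W, m0 = m0, p0m = p0m,
         fisher_f0 = NA_real_, p.value = p0m[1L])
  } else {
    prm <- apply(mr, 2L, replicate_pvalues)
    if (is.null(dim(prm))) prm <- matrix(prm, nrow = R)
    f0 <- fisher_statistic(p0m)
    fr <- -rowSums(log(prm))
    list(p0K = p0K, p0W = p0W, m0 = m0, p0m = p0m,
         fisher_f0 = f0,
         p.value = permutation_pvalue(f0, fr))
  }
}

group_pairs <- function(levels) {
  G <- length(levels)
  t(utils::combn(levels, 2L))
}

degenerate_dth_result <- function(group, sets, R, scheme, seed, metric) {
  pairs <- group_pairs(levels(group))
  P <- nrow(pairs)
  per_pair <- data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                         K0 = rep(0, P), W0 = rep(0, P),
                         p0K = rep(1, P), p0W = rep(1, P),
                         m0 = rep(0, P), p0m = rep(1, P),
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_pair = per_pair,
                 fisher_f0 = if (nlevels(group) > 2L) 0 else NA_real_,
                 p.value = 1,
                 R = as.integer(R), scheme = scheme, seed = seed,
                 metric = if (is.null(metric)) NA_character_ else metric,
                 G = nlevels(group), n = length(group),
                 group_sizes = as.integer(table(group)),
                 groups = levels(group),
                 within = sets,
                 call = sys.call(-1L)),
            class = "dth")
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.dth <- function(x, digits = 4, ...) {
  cat("\n\tDistance-based Test of Homogeneity of Dispersions (DTH)\n\n")
  cat(sprintf("%d groups (sizes %s), %d samples; %d permutations, scheme '%s'\n",
              x$G, paste(x$group_sizes, collapse = "/"), x$n, x$R, x$scheme))
  if (!is.na(x$metric)) cat("dissimilarity:", x$metric, "\n")
  cat("\nPer-pair statistics:\n")
  pp <- x$per_pair
  pp[] <- lapply(pp, function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(pp, row.names = FALSE)
  if (x$G > 2L && !is.na(x$fisher_f0))
    cat(sprintf("\nFisher combination statistic f0 = %s\n",
                format(signif(x$fisher_f0, digits))))
  cat(sprintf("\np-value = %s\n\n", format.pval(x$p.value, digits = digits)))
  invisible(x)
}

#' @export
summary.dth <- function(object, ...) {
  ws <- vapply(object$within, stats::sd, numeric(1))
  ms <- vapply(object$within, mean, numeric(1))
  structure(list(result = object,
                 group_summary = data.frame(
                   group = object$groups,
                   n = object$group_sizes,
                   n_pairs = lengths(object$within),
                   mean_within = ms, sd_within = ws,
                   row.names = NULL, stringsAsFactors = FALSE)),
            class = "summary.dth")
}

#' @export
print.summary.dth <- function(x, digits = 4, ...) {
  print(x$result, digits = digits)
  cat("Within-group dissimilarity summary:\n")
  gs <- x$group_summary
  gs[] <- lapply(gs, function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(gs, row.names = FALSE)
  invisible(x)
}

#' Plot the within-group dissimilarity ECDFs of a DTH fit
#'
#' Draws the mean empirical CDF \eqn{\bar F_g} of within-group
#' dissimilarities for each group — the curves whose differences the test
#' measures.
#'
#' @param x a `"dth"` object.
#' @param col colours, one per group.
#' @param lwd,xlab,ylab,main usual graphical parameters.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dth <- function(x, col = seq_along(x$within) + 1L, lwd = 2,
                     xlab = "within-group dissimilarity z",
                     ylab = expression(bar(F)[g](z)),
                     main = "Within-group dissimilarity ECDFs", ...) {
  rng <- range(unlist(x$within, use.names = FALSE))
  plot(NA, xlim = rng, ylim = c(0, 1), xlab = xlab, ylab = ylab,
       main = main, ...)
  for (k in seq_along(x$within)) {
    f <- mean_ecdf(x$within[[k]])
    graphics::lines(stats::stepfun(f$jump_points,
                                   c(0, f$cumulative_fractions)),
                    col = col[k], lwd = lwd, do.points = FALSE)
  }
  graphics::legend("bottomright", legend = x$groups, col = col, lwd = lwd,
                   bty = "n")
  invisible(x)
}
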