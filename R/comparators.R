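#' Principal-coordinates embedding of a dissimilarity matrix
#'
#' Classical scaling: eigendecomposition of the Gower-centered matrix
#' \eqn{-\frac12 J (D \circ D) J} with \eqn{J} the centering projector. For a
#' non-Euclidean dissimilarity (e.g. Bray-Curtis) some eigenvalues are
#' negative; the corresponding "imaginary" axes are kept separately so that
#' squared distances can be corrected by subtracting their contribution.
#' Eigenvalues with \eqn{|\lambda| < 10^{-10} \max|\lambda|} are dropped.
#'
#' @param d symmetric dissimilarity matrix (or `dist`), \eqn{n \ge 3}.
#' @return an object of class `"pcoa_embedding"`: list with `pos` and `neg`
#'   (score matrices on positive- and negative-eigenvalue axes, scaled by
#'   \eqn{\sqrt{|\lambda|}}) and `eigenvalues` (list with components `pos`
#'   and `neg`).
#' @export
pcoa_embed <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("principal-coordinates embedding needs at least 3 samples")
  a <- -0.5 * d * d
  rm <- rowMeans(a)
  b <- a - outer(rm, rm, `+`) + mean(a)
  e <- eigen(b, symmetric = TRUE)
  keep <- abs(e$values) >= 1e-10 * max(abs(e$values))
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  pos <- vals > 0
  scores <- sweep(vecs, 2L, sqrt(abs(vals)), `*`)
  rownames(scores) <- rownames(d)
  structure(list(pos = scores[, pos, drop = FALSE],
                 neg = scores[, !pos, drop = FALSE],
                 eigenvalues = list(pos = vals[pos], neg = vals[!pos])),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat("Principal-coordinates embedding:", nrow(x$pos), "samples;",
      ncol(x$pos), "positive and", ncol(x$neg), "negative axes\n")
  invisible(x)
}

#' Distances to group centroids in principal-coordinates space
#'
#' For each sample, the distance to the centroid of its own group in the
#' embedded space, with the non-Euclidean correction: squared distance on the
#' positive axes minus squared distance on the negative axes, clamped at zero
#' before the square root.
#'
#' @param embedding a [pcoa_embed()] result, or a dissimilarity matrix which
#'   is embedded first.
#' @param group group labels, one per sample.
#' @return numeric vector of distances to the own-group centroid.
#' @export
centroid_distances <- function(embedding, group) {
  if (!inherits(embedding, "pcoa_embedding")) embedding <- pcoa_embed(embedding)
  n <- nrow(embedding$pos)
  group <- check_groups(group, n)
  d2 <- numeric(n)
  for (part in c("pos", "neg")) {
    x <- embedding[[part]]
    if (ncol(x) == 0L) next
    cen <- rowsum(x, group) / as.vector(table(group))
    dif <- x - cen[as.integer(group), , drop = FALSE]
    contrib <- rowSums(dif * dif)
    d2 <- d2 + if (part == "pos") contrib else -contrib
  }
  sqrt(pmax(d2, 0))
}

#' Levene-type permutation test on distances to group centroids
#'
#' The classical multivariate dispersion test in the style of PERMDISP /
#' vegan's `betadisper`: embed the samples by principal coordinates, compute
#' each sample's distance to its group centroid (with the sign-split
#' correction for non-Euclidean axes), and compare groups with a one-way
#' ANOVA F on those distances. Significance is assessed by permuting group
#' labels and recomputing centroids and F for each permutation; the p-value
#' is \eqn{(1 + \#\{F_r > F_0\})/(R+1)}.
#'
#' This is a reimplementation from first principles (no bias adjustment,
#' mean centroids only), sensitive to differences in mean dispersion but not
#' to differences in the shape of the dispersion distribution.
#'
#' @inheritParams dth_test
#' @return an object of class `"dth_comparator"` with elements `statistic`
#'   (observed F), `p.value`, `method = "betadisper"`, `distances` (observed
#'   centroid distances), `R`, `seed`.
#' @export
betadisper_test <- function(d, group, R = 999, seed = NULL) {
  d <- as_distance_matrix(d)
  group <- check_groups(group, nrow(d))
  if (!is.numeric(R) || length(R) != 1L || R < 1) stop("'R' must be >= 1")
  R <- as.integer(R)
  if (!is.null(seed)) set.seed(seed)
  emb <- pcoa_embed(d)
  f <- .betadisper_perm_kernel_cpp(emb$pos, emb$neg,
                                   as.integer(group) - 1L, nlevels(group), R)
  structure(list(statistic = f[1L],
                 p.value = permutation_pvalue(f[1L], f[-1L]),
                 method = "betadisper",
                 distances = centroid_distances(emb, group),
                 R = R, seed = seed, G = nlevels(group), n = nrow(d)),
            class = "dth_comparator")
}

#' Permutation test on mean squared within-group dissimilarities
#'
#' A permutation analogue of the Gijbels-Omelka style dispersion test: each
#' group's dispersion is summarised by \eqn{\hat V_g}, the mean of
#' \eqn{\phi_{ij}^2 / 2} over its within-group dissimilarities (the
#' U-statistic form of the variance: for Euclidean distances on univariate
#' data it reproduces the sample variance), and the test statistic is the
#' size-weighted between-group spread \eqn{\sum_g n_g (\hat V_g - \bar
#' V)^2} with \eqn{\bar V = \sum_g n_g \hat V_g / n}. The p-value comes from
#' the shared permutation engine. Any positive rescaling of \eqn{\hat V_g}
#' cancels in the permutation p-value.
#'
#' Only the permutation version is provided; no asymptotic null distribution
#' is used. This is a reimplementation from the method's description, not a
#' reproduction of the original authors' code.
#'
#' @inheritParams dth_test
#' @return an object of class `"dth_comparator"` with elements `statistic`,
#'   `p.value`, `method = "go_perm"`, `dispersions` (the observed
#'   \eqn{\hat V_g}), `R`, `scheme`, `seed`.
#' @export
go_perm_test <- function(d, group, R = 999, scheme = c("labels", "pooled"),
                         seed = NULL) {
  scheme <- match.arg(scheme)
  d <- as_distance_matrix(d)
  group <- check_groups(group, nrow(d))
  if (!is.numeric(R) || length(R) != 1L || R < 1) stop("'R' must be >= 1")
  R <- as.integer(R)
  if (!is.null(seed)) set.seed(seed)
  kw <- kernel_statistics(d, group, R, scheme)
  t_all <- go_statistic_rows(kw$V, as.integer(table(group)))
  structure(list(statistic = t_all[1L],
                 p.value = permutation_pvalue(t_all[1L], t_all[-1L]),
                 method = "go_perm",
                 dispersions = stats::setNames(kw$V[1L, ], levels(group)),
                 R = R, scheme = scheme, seed = seed,
                 G = nlevels(group), n = nrow(d)),
            class = "dth_comparator")
}

# GO-type statistic for each row of a (R+1) x G matrix of per-group
# dispersions V-hat: sum_g n_g (V_g - Vbar)^2, Vbar = sum n_g V_g / n.
go_statistic_rows <- function(v, sizes) {
  n <- sum(sizes)
  vbar <- as.vector(v %*% sizes) / n
  rowSums(sweep(v - vbar, 2L, sizes, FUN = function(a, w) a^2 * w))
}

#' @export
print.dth_comparator <- function(x, digits = 4, ...) {
  label <- switch(x$method,
    betadisper = "Levene-type permutation test on distances to group centroids",
    go_perm = "Permutation test on mean squared within-group dissimilarities",
    x$method)
  cat("\n\t", label, "\n\n", sep = "")
  cat(sprintf("%d groups, %d samples; %d permutations\n", x$G, x$n, x$R))
  cat(sprintf("statistic = %s, p-value = %s\n\n",
              format(signif(x$statistic, digits)),
              format.pval(x$p.value, digits = digits)))
  invisible(x)
}
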