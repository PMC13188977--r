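#' Pairwise dissimilarity matrix from a feature table
#'
#' Computes the full symmetric matrix of pairwise dissimilarities between the
#' rows (samples) of a feature table. Euclidean distance is suitable for
#' continuous measurements; Bray-Curtis and binary Jaccard are the standard
#' ecological dissimilarities for abundance and presence/absence data.
#'
#' Bray-Curtis is \eqn{\sum_k |x_k - y_k| / \sum_k (x_k + y_k)}; Jaccard is
#' the binary form \eqn{1 - |shared| / |union|} where a feature is "present"
#' when its value is strictly positive. Both are bounded in \eqn{[0, 1]} and
#' require nonnegative data with no all-zero sample.
#'
#' The matrix is computed once for \eqn{i < j} and mirrored, so it is exactly
#' symmetric with a zero diagonal.
#'
#' @param x numeric matrix or data frame, samples as rows, features as
#'   columns. Row names, when present, become the sample ids of the result.
#' @param metric one of `"euclidean"`, `"braycurtis"`, `"jaccard"`.
#' @return a symmetric numeric matrix with zero diagonal and the sample ids
#'   as dimnames.
#' @examples
#' x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(0, 1, 5))
#' pairwise_dissimilarity(x, "braycurtis")["a", "b"]  # 4/12 = 1/3
#' @export
pairwise_dissimilarity <- function(x,
                                   metric = c("euclidean", "braycurtis", "jaccard")) {
  metric <- match.arg(metric)
  x <- as_feature_matrix(x)
  if (metric %in% c("braycurtis", "jaccard")) {
    if (any(x < 0))
      stop("negative entries are not allowed with metric '", metric, "'")
    zero <- rowSums(x) == 0
    if (any(zero))
      stop("sample(s) ", paste(rownames(x)[zero], collapse = ", "),
           " have all-zero rows; '", metric, "' is undefined for them")
  }
  d <- switch(metric,
    euclidean  = stats::dist(x, method = "euclidean"),
    braycurtis = vegan::vegdist(x, method = "bray"),
    jaccard    = vegan::vegdist(x, method = "jaccard", binary = TRUE))
  out <- as.matrix(d)
  dimnames(out) <- list(rownames(x), rownames(x))
  diag(out) <- 0
  out
}

#' Within-group dissimilarity multiset
#'
#' Extracts \eqn{\Phi_g = \{\phi_{ij} : g_i = g_j = g,\ i < j\}}, the multiset
#' of all pairwise dissimilarities between samples of group `g`. Its
#' \eqn{n_g (n_g - 1) / 2} elements characterise the dispersion of the group.
#'
#' @param d symmetric dissimilarity matrix (or `dist` object).
#' @param group group labels, one per sample.
#' @param g the group to extract; defaults to the first level.
#' @return an object of class `"within_group_set"`: a list with elements
#'   `group` and `distances`.
#' @export
within_group_set <- function(d, group, g = NULL) {
  d <- as_distance_matrix(d)
  group <- as.factor(group)
  if (length(group) != nrow(d))
    stop("length of 'group' (", length(group),
         ") does not match the number of samples (", nrow(d), ")")
  if (is.null(g)) g <- levels(group)[1L]
  idx <- which(group == g)
  if (length(idx) < 2L)
    stop("group '", g, "' too small to define within-group distances (n = ",
         length(idx), ", need >= 2)")
  sub <- d[idx, idx, drop = FALSE]
  structure(list(group = as.character(g),
                 distances = sub[upper.tri(sub)]),
            class = "within_group_set")
}

#' @export
print.within_group_set <- function(x, ...) {
  cat("Within-group dissimilarities for group '", x$group, "': ",
      length(x$distances), " pairs\n", sep = "")
  print(summary(x$distances))
  invisible(x)
}

# All within-group sets at once, as a plain list of numeric vectors named by
# group level. Internal workhorse for the test drivers.
within_group_sets <- function(d, group) {
  group <- as.factor(group)
  lapply(stats::setNames(levels(group), levels(group)), function(g)
    within_group_set(d, group, g)$distances)
}

#' Mean empirical CDF of within-group dissimilarities
#'
#' The step function \eqn{\bar F_g(z)}: the proportion of within-group sample
#' pairs of group \eqn{g} whose dissimilarity is at most \eqn{z}. Averaging
#' the per-sample "fraction of groupmates within distance z" over the samples
#' of the group gives the same function as pooling all \eqn{n_g(n_g-1)/2}
#' pairs, which is the form computed here.
#'
#' @param s a [within_group_set()] or a nonempty numeric vector of distances.
#' @return an object of class `"dth_ecdf"`: list with `jump_points` (sorted
#'   distinct distances) and `cumulative_fractions` (values of the CDF at the
#'   jumps, ending in exactly 1). The object is also callable-free: use
#'   [eval_ecdf()] to evaluate it.
#' @export
mean_ecdf <- function(s) {
  v <- if (inherits(s, "within_group_set")) s$distances else as.numeric(s)
  if (length(v) == 0L) stop("cannot build an ECDF from an empty distance set")
  z <- sort(unique(v))
  counts <- cumsum(tabulate(match(sort(v), z)))
  structure(list(jump_points = z,
                 cumulative_fractions = counts / length(v),
                 n = length(v)),
            class = "dth_ecdf")
}

#' Evaluate a mean empirical CDF
#'
#' @param f object from [mean_ecdf()].
#' @param z numeric vector of evaluation points.
#' @return \eqn{\bar F_g(z)} for each element of `z` (right-continuous, weak
#'   inequality: a jump point is included at its own location).
#' @export
eval_ecdf <- function(f, z) {
  stopifnot(inherits(f, "dth_ecdf"))
  i <- findInterval(z, f$jump_points)
  c(0, f$cumulative_fractions)[i + 1L]
}

#' @export
print.dth_ecdf <- function(x, ...) {
  cat("Mean ECDF of within-group dissimilarities:",
      length(x$jump_points), "jumps over", x$n, "pairs; range [",
      format(min(x$jump_points)), ",", format(max(x$jump_points)), "]\n")
  invisible(x)
}

# ---- input validation helpers -----------------------------------------------

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("feature table must be a numeric matrix or data frame")
  if (anyNA(x)) stop("feature table contains missing values")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  x
}

as_distance_matrix <- function(d, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.data.frame(d)) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("'d' must be a square numeric dissimilarity matrix or a 'dist' object")
  if (anyNA(d)) stop("dissimilarity matrix contains missing values")
  if (any(d < 0)) stop("dissimilarity matrix has negative entries")
  if (any(abs(diag(d)) > 1e-12)) stop("dissimilarity matrix has a nonzero diagonal")
  asym <- max(abs(d - t(d)))
  if (asym > tol)
    stop("dissimilarity matrix is asymmetric (max |d - t(d)| = ",
         format(asym), ")")
  if (asym > 0) {
    warning("symmetrizing dissimilarity matrix (max asymmetry ", format(asym), ")")
    d <- (d + t(d)) / 2
  }
  diag(d) <- 0
  d
}

# Validates group labels against a distance matrix; returns a factor with all
# group sizes >= 2 (dropping unused levels).
check_groups <- function(group, n, min_size = 2L) {
  group <- droplevels(as.factor(group))
  if (length(group) != n)
    stop("length of 'group' (", length(group),
         ") does not match the number of samples (", n, ")")
  if (anyNA(group)) stop("'group' contains missing values")
  sizes <- table(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups (G >= 2)")
  if (any(sizes < min_size))
    stop("every group must contain at least ", min_size, " samples; group(s) ",
         paste(names(sizes)[sizes < min_size], collapse = ", "), " too small")
  group
}
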