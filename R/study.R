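#' Monte-Carlo size and power study of the dispersion tests
#'
#' Runs the full simulation benchmark: over a grid of scenarios, group
#' numbers and deviation parameters \eqn{\theta}, repeatedly simulates data
#' ([simulate_normal()] with Euclidean distance, or [simulate_negbin()] with
#' Bray-Curtis), applies the requested tests to each dataset, and records the
#' fraction of p-values \eqn{\le \alpha} — the empirical size (\eqn{\theta =
#' 0}) or power (\eqn{\theta > 0}) of each test.
#'
#' All requested methods are applied to the same simulated datasets (and DTH
#' and the GO-type test share one replicate stream per dataset), so method
#' comparisons are paired.
#'
#' @param family `"normal"` or `"negbin"`.
#' @param scenarios character vector of scenario codes (`"S0"`-`"S3"` for
#'   normal, `"S1"`-`"S3"` for negbin).
#' @param G integer vector of group numbers (subset of 2, 3, 5).
#' @param theta numeric vector of deviation parameters.
#' @param methods subset of `"dth"`, `"go_perm"`, `"betadisper"`.
#' @param n_reps simulated datasets per grid cell.
#' @param R permutation replicates per test.
#' @param alpha nominal level.
#' @param n,d,mu passed to the simulators.
#' @param scheme permutation scheme for DTH and the GO-type test.
#' @param seed master seed; the whole study is deterministic given it.
#' @param verbose print one progress line per grid cell.
#' @return a data frame of class `"dth_study"`: one row per (scenario, G,
#'   theta, method) with the empirical `rejection_rate` and the study
#'   settings; attributes `alpha` and `seed`.
#' @export
run_study <- function(family = c("normal", "negbin"),
                      scenarios = NULL,
                      G = c(2, 3, 5),
                      theta = 0,
                      methods = c("dth", "go_perm", "betadisper"),
                      n_reps = 500, R = 999, alpha = 0.05,
                      n = 150, d = 500, mu = 10,
                      scheme = c("labels", "pooled"),
                      seed = NULL, verbose = FALSE) {
  family <- match.arg(family)
  scheme <- match.arg(scheme)
  if (is.null(scenarios))
    scenarios <- if (family == "normal") c("S0", "S1", "S2", "S3")
                 else c("S1", "S2", "S3")
  methods <- match.arg(methods, c("dth", "go_perm", "betadisper"),
                       several.ok = TRUE)
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  metric <- if (family == "normal") "euclidean" else "braycurtis"

  grid <- expand.grid(scenario = scenarios, G = as.integer(G),
                      theta = theta, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid) * length(methods))
  k <- 1L
  for (cell in seq_len(nrow(grid))) {
    sc <- grid$scenario[cell]; gg <- grid$G[cell]; th <- grid$theta[cell]
    rej <- stats::setNames(numeric(length(methods)), methods)
    for (rep in seq_len(n_reps)) {
      sim <- if (family == "normal")
        simulate_normal(sc, G = gg, theta = th, n = n, d = d)
      else
        simulate_negbin(sc, G = gg, theta = th, n = n, d = d, mu = mu)
      dm <- pairwise_dissimilarity(sim$table, metric)
      pvals <- evaluate_methods(dm, sim$group, methods, R = R, scheme = scheme)
      rej <- rej + (pvals <= alpha)
    }
    rates <- rej / n_reps
    if (verbose)
      message(sprintf("%s %s G=%d theta=%g: %s", family, sc, gg, th,
                      paste(sprintf("%s=%.3f", methods, rates), collapse = " ")))
    for (m in methods) {
      rows[[k]] <- data.frame(family = family, scenario = sc, G = gg,
                              theta = th, method = m,
                              rejection_rate = rates[[m]],
                              n_reps = n_reps, R = R, alpha = alpha,
                              n = n, d = d, stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  class(out) <- c("dth_study", "data.frame")
  out
}

# Apply the selected tests to one dissimilarity matrix, reusing a single
# permutation-kernel call for DTH and the GO-type statistic (they share the
# replicate stream by construction).
evaluate_methods <- function(d, group, methods, R, scheme = "labels") {
  group <- check_groups(group, nrow(d))
  out <- stats::setNames(numeric(length(methods)), methods)
  need_kernel <- any(c("dth", "go_perm") %in% methods)
  if (need_kernel) {
    kw <- kernel_statistics(d, group, R, scheme)
    if ("dth" %in% methods)
      out[["dth"]] <- dth_from_stats(kw$K, kw$W, nlevels(group))$p.value
    if ("go_perm" %in% methods) {
      t_all <- go_statistic_rows(kw$V, as.integer(table(group)))
      out[["go_perm"]] <- permutation_pvalue(t_all[1L], t_all[-1L])
    }
  }
  if ("betadisper" %in% methods)
    out[["betadisper"]] <- betadisper_test(d, group, R = R)$p.value
  out
}

#' @export
print.dth_study <- function(x, digits = 3, ...) {
  cat("Monte-Carlo dispersion study:", attr(x, "alpha"), "nominal level\n")
  y <- as.data.frame(x)
  y$rejection_rate <- signif(y$rejection_rate, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a study result as a tidy TSV
#'
#' @param x a [run_study()] result.
#' @param path output file.
#' @export
write_study <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
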