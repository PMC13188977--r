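# Shared fixtures and independent reference implementations used as oracles.

# Random small Euclidean distance matrix with labelled groups.
toy_distance <- function(n = 12, d = 4, G = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n)
  rownames(x) <- paste0("s", seq_len(n))
  list(d = as.matrix(dist(x)), x = x,
       group = factor(rep(paste0("g", seq_len(G)), length.out = n)))
}

# Exact integral of |F_a - F_b| over the merged step partition: a Riemann sum
# whose grid contains every jump point, built only from stats::ecdf.
riemann_wasserstein <- function(a, b) {
  z <- sort(unique(c(a, b)))
  if (length(z) == 1L) return(0)
  fa <- stats::ecdf(a)(z)
  fb <- stats::ecdf(b)(z)
  sum(abs(fa - fb)[-length(z)] * diff(z))
}

# Reference KS: sup over merged jump points of the ECDF difference.
reference_ks <- function(a, b) {
  z <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(z) - stats::ecdf(b)(z)))
}

# Mean ECDF by the average-over-samples definition: for each sample i of
# group g, the fraction of its groupmates within distance z, averaged over
# the samples of the group.
mean_ecdf_by_samples <- function(d, group, g, z) {
  idx <- which(group == g)
  vapply(z, function(zz) {
    mean(vapply(idx, function(i) {
      others <- setdiff(idx, i)
      mean(d[i, others] <= zz)
    }, numeric(1)))
  }, numeric(1))
}

# Write a (possibly invalid) square distance matrix without validation, to
# exercise the reader's error paths.
write_distance_matrix_raw <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Distance matrix whose two groups have prescribed within-group distances
# (between-group entries constant). labels (1,1,2,2) layout for 2+2 samples.
block_distance_2x2 <- function(phi1, phi2, between = max(phi1, phi2) + 1) {
  d <- matrix(between, 4, 4)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- phi1
  d[3, 4] <- d[4, 3] <- phi2
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  d
}
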