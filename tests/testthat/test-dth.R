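test_that("omnibus and Fisher combiners follow their formulas", {
  expect_equal(omnibus_m(1, 1), 0)
  expect_equal(omnibus_m(0.2, 0.05), 0.95)
  expect_equal(omnibus_m(0.01, 1), 0.99)
  expect_error(omnibus_m(0, 0.5), "\\(0, 1\\]")
  expect_error(omnibus_m(0.5, 1.2), "\\(0, 1\\]")

  expect_equal(fisher_statistic(c(1, 1, 1)), 0)
  expect_equal(fisher_statistic(exp(-1)), 1)
  expect_equal(fisher_statistic(c(0.5, 0.1)), -log(0.5) - log(0.1))
  expect_error(fisher_statistic(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("identical within-group distributions give a null-looking test", {
  # two groups with bit-identical within-group distance multisets: duplicate
  # the same within-group block, constant between-group distances
  set.seed(10)
  x <- matrix(rnorm(10 * 3), 10)
  blk <- as.matrix(dist(x))
  d <- rbind(cbind(blk, matrix(50, 10, 10)),
             cbind(matrix(50, 10, 10), blk))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  g <- rep(c("a", "b"), each = 10)
  r <- dth_test(d, g, R = 99, seed = 4)
  expect_equal(r$per_pair$K0, 0)
  expect_equal(r$per_pair$W0, 0)
  expect_gte(r$p.value, 0.5)
})

test_that("results are bit-identical across runs with the same seed", {
  toy <- toy_distance(n = 20, G = 2, seed = 2)
  r1 <- dth_test(toy$d, toy$group, R = 99, seed = 123)
  r2 <- dth_test(toy$d, toy$group, R = 99, seed = 123)
  expect_identical(r1$p.value, r2$p.value)
  expect_identical(r1$per_pair, r2$per_pair)
  r3 <- dth_test(toy$d, toy$group, R = 99, seed = 124)
  expect_false(identical(r1$per_pair$p0K, r3$per_pair$p0K))
})

test_that("two-group path agrees with the Fisher path on seeded data", {
  for (seed in c(11, 22, 33, 44)) {
    toy <- toy_distance(n = 16, G = 2, seed = seed)
    p2 <- dth_test(toy$d, toy$group, R = 49, seed = seed)$p.value
    pf <- dth_test(toy$d, toy$group, R = 49, seed = seed,
                   force_fisher = TRUE)$p.value
    expect_equal(p2, pf)
  }
})

test_that("G = 3 runs the Fisher combination over all pairs", {
  toy <- toy_distance(n = 15, G = 3, seed = 9)
  r <- dth_test(toy$d, toy$group, R = 49, seed = 1)
  expect_equal(nrow(r$per_pair), 3)
  expect_equal(r$fisher_f0, -sum(log(r$per_pair$p0m)))
  expect_gte(r$p.value, 1 / 50)
})

test_that("inflating one group's dispersion lowers the p-value on average", {
  ps <- vapply(1:15, function(seed) {
    toy <- toy_distance(n = 20, G = 2, seed = seed)
    d2 <- toy$d
    idx <- which(toy$group == "g2")
    d2[idx, idx] <- d2[idx, idx] * 2.5      # inflate within-group spread
    c(dth_test(toy$d, toy$group, R = 59, seed = seed)$p.value,
      dth_test(d2, toy$group, R = 59, seed = seed)$p.value)
  }, numeric(2))
  expect_lt(mean(ps[2, ]), mean(ps[1, ]))
})

test_that("degenerate all-equal distances return p = 1 with a warning", {
  d <- matrix(2, 8, 8); diag(d) <- 0
  expect_warning(r <- dth_test(d, rep(1:2, each = 4), R = 19),
                 "identically zero")
  expect_equal(r$p.value, 1)
  expect_equal(r$per_pair$K0, 0)
})

test_that("invalid designs are rejected", {
  toy <- toy_distance(n = 10, G = 2, seed = 1)
  expect_error(dth_test(toy$d, rep("a", 10), R = 9), "at least 2 groups")
  expect_error(dth_test(toy$d, c(rep("a", 9), "b"), R = 9), "too small")
  expect_error(dth_test(toy$d, toy$group, R = 0), ">= 1")
  expect_error(dth_test(toy$d[1:9, 1:10], toy$group), "square")
})

test_that("table and distance-matrix entry points give identical results", {
  set.seed(5)
  x <- matrix(rpois(18 * 12, 8), 18)
  rownames(x) <- paste0("s", 1:18)
  g <- rep(c("a", "b"), 9)
  r1 <- dth_test_from_table(x, g, metric = "braycurtis", R = 49, seed = 6)
  r2 <- dth_test(pairwise_dissimilarity(x, "braycurtis"), g, R = 49, seed = 6)
  expect_identical(r1$p.value, r2$p.value)
  expect_identical(r1$per_pair, r2$per_pair)
  expect_equal(r1$metric, "braycurtis")

  x[3, ] <- 0
  expect_error(dth_test_from_table(x, g, metric = "braycurtis", R = 9), "s3")
})

test_that("discretize_covariate builds near-equal quantile groups", {
  expect_equal(as.integer(discretize_covariate(1:4, 2)), c(1, 1, 2, 2))
  g3 <- discretize_covariate(1:12, 3)
  expect_equal(unname(as.vector(table(g3))), c(4, 4, 4))
  # ties go to the lower bin
  gt <- discretize_covariate(c(1, 2, 2, 2, 3, 4), 2)
  expect_equal(as.integer(gt), c(1, 1, 1, 1, 2, 2))
  expect_error(discretize_covariate(rep(1, 10), 2), "distinct")
  expect_error(discretize_covariate(1:5, 3), "at least 6")
  expect_error(discretize_covariate(1:10, 1), ">= 2")
})

test_that("print, summary and plot methods run on a fitted object", {
  toy <- toy_distance(n = 12, G = 2, seed = 8)
  r <- dth_test(toy$d, toy$group, R = 19, seed = 1, metric = "euclidean")
  expect_output(print(r), "Distance-based Test")
  expect_output(print(summary(r)), "Within-group dissimilarity summary")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(r))
})
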