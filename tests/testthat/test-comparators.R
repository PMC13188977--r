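test_that("pcoa_embed reproduces Euclidean geometry exactly", {
  set.seed(3)
  x <- matrix(rnorm(12 * 2), 12)
  emb <- pcoa_embed(as.matrix(dist(x)))
  expect_equal(ncol(emb$neg), 0)
  expect_true(all(emb$eigenvalues$pos > 0))
  rec <- as.matrix(dist(emb$pos))
  expect_equal(rec, as.matrix(dist(x)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("pcoa_embed handles simplex and non-Euclidean inputs", {
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  emb <- pcoa_embed(d3)
  expect_length(emb$eigenvalues$pos, 2)
  expect_equal(emb$eigenvalues$pos[1], emb$eigenvalues$pos[2])

  set.seed(4)
  cnt <- matrix(rpois(15 * 10, 4), 15)
  rownames(cnt) <- paste0("s", 1:15)
  cnt[rowSums(cnt) == 0, 1] <- 1
  db <- pairwise_dissimilarity(cnt, "braycurtis")
  emb2 <- pcoa_embed(db)
  a <- -0.5 * db^2
  b <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  expect_equal(sum(unlist(emb2$eigenvalues)), sum(diag(b)), tolerance = 1e-8)
  expect_gt(length(emb2$eigenvalues$neg), 0)  # Bray-Curtis is non-Euclidean
  expect_error(pcoa_embed(matrix(0, 2, 2)), "at least 3")
})

test_that("centroid distances match a raw-coordinate oracle for Euclidean data", {
  set.seed(5)
  x <- matrix(rnorm(24 * 5), 24)
  g <- rep(c("a", "b", "c"), each = 8)
  mine <- centroid_distances(pcoa_embed(as.matrix(dist(x))), g)
  cen <- apply(x, 2, function(col) tapply(col, g, mean))
  oracle <- sqrt(rowSums((x - cen[g, ])^2))
  expect_equal(mine, oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("betadisper-style test agrees with vegan on observed quantities", {
  set.seed(6)
  cnt <- matrix(rpois(21 * 12, 6), 21)
  rownames(cnt) <- paste0("s", 1:21)
  g <- rep(c("a", "b", "c"), each = 7)
  db <- pairwise_dissimilarity(cnt, "braycurtis")
  bt <- betadisper_test(db, g, R = 19, seed = 2)
  ref <- vegan::betadisper(as.dist(db), g, type = "centroid")
  expect_equal(unname(centroid_distances(pcoa_embed(db), g)),
               unname(ref$distances), tolerance = 1e-8)
  expect_equal(bt$statistic, stats::anova(ref)$`F value`[1], tolerance = 1e-8)
})

test_that("mirror-image groups have equal dispersion under betadisper", {
  set.seed(7)
  x <- matrix(rnorm(10 * 4), 10)
  x2 <- rbind(x, -x)                    # identical within-group geometry
  g <- rep(c("a", "b"), each = 10)
  bt <- betadisper_test(as.matrix(dist(x2)), g, R = 99, seed = 3)
  expect_lt(bt$statistic, 1e-12)
  expect_gt(bt$p.value, 0.5)
  bt2 <- betadisper_test(as.matrix(dist(x2)), g, R = 99, seed = 3)
  expect_identical(bt$p.value, bt2$p.value)
})

test_that("GO-type statistic matches its hand-evaluated formula", {
  d <- block_distance_2x2(phi1 = 2, phi2 = 4)
  gt <- go_perm_test(d, c(1, 1, 2, 2), R = 9, seed = 1)
  # Vhat = (2, 8), Vbar = 5, T = 2*9 + 2*9 = 36
  expect_equal(unname(gt$dispersions), c(2, 8))
  expect_equal(gt$statistic, 36)

  set.seed(8)
  x <- matrix(rnorm(20 * 3), 20)
  x2 <- rbind(x, x + 50)
  g <- rep(c("a", "b"), each = 20)
  gt2 <- go_perm_test(dist(x2), g, R = 49, seed = 2)
  expect_equal(gt2$statistic, 0, tolerance = 1e-10)
  expect_equal(gt2$p.value, 1)
})

test_that("GO-type test is invariant to relabeling, location and scaling", {
  toy <- toy_distance(n = 14, G = 2, seed = 9)
  t1 <- go_perm_test(toy$d, toy$group, R = 9, seed = 5)$statistic
  relab <- factor(toy$group, levels = rev(levels(toy$group)))
  t2 <- go_perm_test(toy$d, relab, R = 9, seed = 5)$statistic
  expect_equal(t1, t2)

  shifted <- toy$x + matrix(rep(c(3, -1, 2, 5), each = nrow(toy$x)), nrow(toy$x))
  t3 <- go_perm_test(as.matrix(dist(shifted)), toy$group, R = 9, seed = 5)$statistic
  expect_equal(t1, t3)

  # any positive rescaling of the dispersions cancels in the p-value
  p1 <- go_perm_test(toy$d, toy$group, R = 99, seed = 7)$p.value
  p2 <- go_perm_test(toy$d * 3, toy$group, R = 99, seed = 7)$p.value
  expect_identical(p1, p2)
})

test_that("go_perm_test supports the pooled scheme", {
  toy <- toy_distance(n = 12, G = 2, seed = 10)
  gp <- go_perm_test(toy$d, toy$group, R = 29, scheme = "pooled", seed = 4)
  expect_s3_class(gp, "dth_comparator")
  expect_gte(gp$p.value, 1 / 30)
  expect_lte(gp$p.value, 1)
})
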