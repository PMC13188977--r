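test_that("gamma_kappa has its closed-form values and normalising property", {
  expect_equal(gamma_kappa(0.25), pi)
  expect_equal(gamma_kappa(0.5), 4 / pi)
  expect_error(gamma_kappa(0), "> 0")
  # Monte-Carlo oracle: E sqrt(v_i + v_j) = 1 for v ~ Gamma(alpha, kappa)
  set.seed(60)
  for (alpha in c(0.4, 1, 2.5)) {
    k <- gamma_kappa(alpha)
    s <- sqrt(rgamma(1e6, shape = 2 * alpha, scale = k))  # v_i + v_j
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - 1), 3 * se + 1e-4)
  }
})

test_that("normal scenarios collapse to one distribution at theta = 0", {
  for (sc in c("S0", "S1", "S2", "S3")) for (G in c(2, 3, 5)) {
    par <- DTH:::normal_scenario_params(sc, G, 0)
    flat <- unlist(par[names(par) != "kind"])
    per_group <- matrix(flat, ncol = G, byrow = TRUE)
    expect_true(all(apply(per_group, 1, function(row) all(row == row[1]))),
                info = paste(sc, G))
  }
  # S1 keeps mu + sigma^2/2 = 3/2 (constant mean dispersion) at every theta
  for (theta in c(0, 0.7, 2)) for (G in c(2, 3, 5)) {
    par <- DTH:::normal_scenario_params("S1", G, theta)
    expect_equal(par$mu + par$sigma2 / 2, rep(1.5, G))
  }
  expect_error(DTH:::normal_scenario_params("S1", 4, 0), "unknown scenario")
})

test_that("normal simulator matches its moments", {
  sim <- simulate_normal("S1", G = 2, theta = 0.5, n = 4000, d = 12, seed = 21)
  for (g in levels(sim$group)) {
    rows <- sim$table[sim$group == g, ]
    expect_lt(max(abs(colMeans(rows))), 0.2)        # zero-mean coordinates
    vbar <- mean(apply(rows, 1, var))
    mu_g <- if (g == "g1") 1 else 0.5
    sg2 <- 3 - 2 * mu_g
    ev <- exp(mu_g + sg2 / 2)                        # = e^{3/2} in S1
    expect_equal(ev, exp(1.5))
    v <- sim$dispersions[sim$group == g]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(vbar - ev), 4 * se + 0.05)
  }
  expect_identical(simulate_normal("S2", 3, 1, n = 30, d = 5, seed = 2)$table,
                   simulate_normal("S2", 3, 1, n = 30, d = 5, seed = 2)$table)
})

test_that("negative-binomial simulator matches its printed moments", {
  # conditional moments at fixed r (S3, theta = 0 gives r = 1 everywhere)
  sim <- simulate_negbin("S3", G = 2, theta = 0, n = 200, d = 500, mu = 10,
                         seed = 31)
  y <- as.vector(sim$table)
  expect_equal(mean(y), 10, tolerance = 0.02)
  expect_equal(var(y), 10 + 100 / 1, tolerance = 0.05)

  # unconditional variance mu + mu^2 * alpha/beta for inverse-gamma dispersion
  sim2 <- simulate_negbin("S2", G = 2, theta = 0, n = 400, d = 500, mu = 10,
                          seed = 32)
  expect_equal(var(as.vector(sim2$table)), 10 + 100 * 3 / 5, tolerance = 0.1)
  # and E(1/r) = alpha/beta
  expect_equal(mean(1 / sim2$size_params), 3 / 5, tolerance = 0.1)

  expect_identical(simulate_negbin("S1", 2, 1, n = 20, d = 10, seed = 3)$table,
                   simulate_negbin("S1", 2, 1, n = 20, d = 10, seed = 3)$table)
  expect_error(DTH:::negbin_scenario_params("S0", 2, 0), "unknown scenario")
})

test_that("gamma-mixture design keeps mean within-group distance constant", {
  # the property engineered by gamma_kappa(): groups differ in dispersion
  # distribution but not in expected within-group distance
  means <- replicate(25, {
    sim <- simulate_normal("S0", G = 2, theta = 1.5, n = 80, d = 60)
    d <- pairwise_dissimilarity(sim$table, "euclidean")
    vapply(DTH:::within_group_sets(d, sim$group), mean, numeric(1))
  })
  diff <- means[1, ] - means[2, ]
  expect_lt(abs(mean(diff)), 2 * sd(diff) / sqrt(ncol(means)) + 0.01)
})

test_that("continuous-covariate simulator behaves as designed", {
  sim <- simulate_continuous(n = 40, d = 8, dispersion_slope = 0, seed = 41)
  expect_true(all(sim$covariate >= 0 & sim$covariate <= 1))
  expect_equal(dim(sim$table), c(40, 8))
  # strong slope: dispersion increases with the covariate
  sim2 <- simulate_continuous(n = 300, d = 30, dispersion_slope = 3, seed = 42)
  rowvar <- apply(sim2$table, 1, var)
  expect_gt(cor(sim2$covariate, rowvar), 0.5)
  expect_error(simulate_continuous(n = 4), "at least 6")
})

test_that("discretized continuous covariate feeds the test (null and signal)", {
  set.seed(43)
  sim0 <- simulate_continuous(n = 60, d = 40, dispersion_slope = 0)
  g0 <- discretize_covariate(sim0$covariate, 3)
  p0 <- dth_test_from_table(sim0$table, g0, metric = "euclidean", R = 99)$p.value
  expect_gte(p0, 0.01)
  sim1 <- simulate_continuous(n = 150, d = 100, dispersion_slope = 2)
  g1 <- discretize_covariate(sim1$covariate, 3)
  p1 <- dth_test_from_table(sim1$table, g1, metric = "euclidean", R = 99)$p.value
  expect_lt(p1, 0.05)
})

test_that("run_study produces a tidy deterministic rate table", {
  st <- run_study("normal", scenarios = "S3", G = 2, theta = c(0, 2),
                  methods = c("dth", "go_perm"), n_reps = 2, R = 19,
                  n = 20, d = 10, seed = 51)
  expect_s3_class(st, "dth_study")
  expect_equal(nrow(st), 4)                       # 2 theta x 2 methods
  expect_true(all(st$rejection_rate %in% c(0, 0.5, 1)))
  st2 <- run_study("normal", scenarios = "S3", G = 2, theta = c(0, 2),
                   methods = c("dth", "go_perm"), n_reps = 2, R = 19,
                   n = 20, d = 10, seed = 51)
  expect_identical(as.data.frame(st), as.data.frame(st2))
  st3 <- run_study("negbin", scenarios = "S1", G = 2, theta = 0,
                   methods = "betadisper", n_reps = 1, R = 9,
                   n = 16, d = 12, seed = 52)
  expect_true(st3$rejection_rate %in% c(0, 1))
})
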