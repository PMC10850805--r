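# Kernels are checked against hand formulas and the corresponding stats::
# reference implementations on random fixtures.

test_that("welch_t matches the hand formula and stats::t.test", {
  res <- welch_t(c(-1.0, -0.8, -0.9), c(-0.2, 0.0, -0.1))
  # sd = 0.1 in both groups, se = 0.1*sqrt(2/3), t = -0.8/se
  expect_equal(res$statistic, -0.8 / (0.1 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:25) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    ref <- t.test(a, b)
    res <- welch_t(a, b)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
    ref_p <- t.test(a, b, var.equal = TRUE)
    res_p <- welch_t(a, b, pooled = TRUE)
    expect_equal(res_p$statistic, unname(ref_p$statistic), tolerance = 1e-10)
  }

  same <- c(1, 2, 3)
  res0 <- welch_t(same, same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(welch_t(c(1, 1), c(1, 1)), "degenerate")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("mann_whitney exact path: enumeration oracle and edge cases", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$method, "mann_whitney_exact")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)   # 2 / choose(6, 3) labelings as extreme

  # identical multisets have ties -> normal path, p = 1-ish; force exact
  # refusal warning
  expect_warning(res_t <- mann_whitney(c(1, 2, 3), c(1, 2, 3),
                                       mode = "exact"), "ties")
  expect_equal(res_t$method, "mann_whitney_normal")
  expect_equal(res_t$p_value, 1)

  # exact agrees with stats::wilcox.test exact p on tie-free data
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    res <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("mann_whitney exact and normal paths agree within 0.02 at n = 8", {
  set.seed(31)
  diffs <- replicate(200, {
    a <- rnorm(8); b <- rnorm(8, mean = runif(1, -1, 1))
    abs(mann_whitney(a, b, mode = "exact")$p_value -
          mann_whitney(a, b, mode = "normal")$p_value)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("welch_anova matches oneway.test and collapses to t^2", {
  g3 <- list(c(1, 2, 3, 2), c(1, 2, 3, 2), c(1, 2, 3, 2))
  res <- welch_anova(g3)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  set.seed(41)
  for (i in 1:20) {
    groups <- lapply(1:3, function(k) rnorm(sample(4:10, 1), mean = k / 2,
                                            sd = runif(1, 0.5, 2)))
    ref <- oneway.test(y ~ g, data.frame(
      y = unlist(groups), g = factor(rep(seq_along(groups),
                                         lengths(groups)))))
    res <- welch_anova(groups)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }

  a <- rnorm(8); b <- rnorm(9, 1)
  expect_equal(welch_anova(list(a, b))$statistic,
               welch_t(a, b)$statistic^2, tolerance = 1e-10)
  expect_equal(welch_anova(list(a, b))$p_value, welch_t(a, b)$p_value,
               tolerance = 1e-10)
  expect_error(welch_anova(list(a)), ">= 2 groups")
  expect_error(welch_anova(list(a, rep(1, 5))), "zero-variance")
})

test_that("dunnett_adjust: k = 1 reduces to the t-test; adjusted >= raw", {
  set.seed(51)
  a <- rnorm(10); ctrl <- rnorm(10, 0.8)
  adj <- dunnett_adjust(list(ctrl, a), control_index = 1, mc_draws = 4e5,
                        mc_seed = 99)
  raw <- welch_t(a, ctrl)$p_value
  expect_equal(unname(adj$adjusted), raw, tolerance = 0.005)

  for (i in 1:20) {
    groups <- lapply(1:4, function(k) rnorm(6, mean = runif(1, -1, 1)))
    adj <- dunnett_adjust(groups, control_index = 1, mc_draws = 5000,
                          mc_seed = i)
    expect_true(all(adj$adjusted >= adj$raw - 1e-12))
    expect_true(all(adj$adjusted <= 1))
  }
  expect_error(dunnett_adjust(list(rnorm(1), rnorm(5))), "control")
})

test_that("dunnett MC draw is reproducible under mc_seed and leaves the RNG alone", {
  groups <- list(rnorm(8), rnorm(8), rnorm(8))
  set.seed(1); before <- runif(1)
  set.seed(1)
  a1 <- dunnett_adjust(groups, mc_draws = 2000, mc_seed = 7)
  after <- runif(1)
  a2 <- dunnett_adjust(groups, mc_draws = 2000, mc_seed = 7)
  expect_identical(a1$adjusted, a2$adjusted)
  expect_equal(before, after)   # caller RNG stream untouched
})

test_that("holm_sidak follows the step-down formula", {
  expect_equal(holm_sidak(0.01)$adjusted, 0.01)
  raw <- c(0.01, 0.04, 0.03)
  # sorted {0.01, 0.03, 0.04}: 1-(1-.01)^3, then max with 1-(1-.03)^2,
  # then max with 1-(1-.04)^1
  adj <- holm_sidak(raw)$adjusted
  expect_equal(adj[1], 1 - 0.99^3, tolerance = 1e-12)
  expect_equal(adj[2], 1 - 0.97^2, tolerance = 1e-12)  # 0.0591 > 0.04
  expect_equal(adj[3], 1 - 0.97^2, tolerance = 1e-12)  # monotone lift
  expect_equal(holm_sidak(rep(1, 4))$adjusted, rep(1, 4))
  set.seed(3)
  hs <- holm_sidak(runif(10))
  expect_true(all(hs$adjusted >= hs$raw & hs$adjusted <= 1))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cohens_d: hand value, zero, scale invariance", {
  expect_equal(cohens_d(c(-0.2, 0.0, -0.1), c(-1.0, -0.8, -0.9)), 8,
               tolerance = 1e-12)
  x <- c(1, 2, 3)
  expect_equal(cohens_d(x, x), 0)
  set.seed(61)
  a <- rnorm(10); b <- rnorm(12, 1)
  for (c0 in c(2.5, -3)) {
    expect_equal(cohens_d(c0 * a, c0 * b), sign(c0) * cohens_d(a, b),
                 tolerance = 1e-12)
  }
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), "pooled SD")
})

test_that("pearson_cor matches cor.test and handles degeneracy", {
  x <- 1:5
  res <- pearson_cor(x, x)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 0)
  expect_equal(pearson_cor(x, -x)$statistic, -1)
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- 0.5 * x + rnorm(length(x))
    ref <- cor.test(x, y)
    res <- pearson_cor(x, y)
    expect_equal(res$statistic, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_cor(1:2, 2:1), ">= 3")
})

test_that("within-group permutation never changes any kernel output", {
  set.seed(81)
  a <- rnorm(9); b <- rnorm(7, 0.5); cc <- rnorm(8, 1)
  perm <- function(x) sample(x)
  expect_equal(welch_t(perm(a), perm(b))$p_value, welch_t(a, b)$p_value)
  expect_equal(mann_whitney(perm(a), perm(b))$p_value,
               mann_whitney(a, b)$p_value)
  expect_equal(welch_anova(list(perm(a), perm(b), perm(cc)))$p_value,
               welch_anova(list(a, b, cc))$p_value)
  expect_equal(cohens_d(perm(a), perm(b)), cohens_d(a, b))
})

test_that("null p-values are approximately uniform (KS at alpha = 0.001)", {
  set.seed(91)
  p_w <- replicate(1000, welch_t(rnorm(10), rnorm(10))$p_value)
  expect_gt(ks.test(p_w, "punif")$p.value, 0.001)
  p_a <- replicate(1000, welch_anova(list(rnorm(8), rnorm(8),
                                          rnorm(8)))$p_value)
  expect_gt(ks.test(p_a, "punif")$p.value, 0.001)
})
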