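test_that("normality screen passes Gaussian samples and rejects heavy log-normals", {
  set.seed(21)
  norm_flags <- replicate(100, normality_check(rnorm(200))$normal)
  lnorm_flags <- replicate(100, normality_check(rlnorm(200, 0, 1))$normal)
  expect_gte(mean(norm_flags), 0.90)
  expect_lte(mean(lnorm_flags), 0.10)
  r <- normality_check(rnorm(50))
  expect_true(r$statistic >= 0 && r$statistic <= 1)
  expect_error(normality_check(rep(2, 10)), class = "immflow_degenerate_error")
})

test_that("two-group test: identical groups, oracle agreement, degenerate input", {
  x <- c(1, 2, 3, 4)
  r <- two_group_test(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(22)
  a <- rnorm(15); b <- rnorm(20, 0.5)
  for (variant in c("student", "welch")) {
    mine <- two_group_test(a, b, variant)
    ref <- t.test(a, b, var.equal = variant == "student")
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(two_group_test(c(1, 1), c(1, 1)),
               class = "immflow_degenerate_error")
  expect_error(two_group_test(1, c(1, 2)),
               class = "immflow_insufficient_samples_error")
})

test_that("raw-vector and summary-statistic forms agree (student)", {
  set.seed(23)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), runif(1, -1, 1))
    raw <- two_group_test(a, b)
    summ <- two_group_test(list(mean = mean(a), sd = sd(a), n = length(a)),
                           list(mean = mean(b), sd = sd(b), n = length(b)))
    expect_equal(summ$statistic, raw$statistic, tolerance = 1e-9)
    expect_equal(summ$p_value, raw$p_value, tolerance = 1e-9)
  }
})

test_that("ANOVA omnibus matches aov and has calibrated null behaviour", {
  set.seed(24)
  g <- list(a = rnorm(30), b = rnorm(25), c = rnorm(35))
  res <- anova_bonferroni(g)
  y <- unlist(g); f <- factor(rep(names(g), sapply(g, length)))
  ref <- summary(aov(y ~ f))[[1]]
  expect_equal(res$omnibus$statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$omnibus$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  # null calibration: 3 groups of 50, 1000 simulations
  set.seed(25)
  rej <- 0
  for (i in 1:1000) {
    gg <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
    if (anova_bonferroni(gg, contrasts = list(c("a", "b")))$omnibus$p_value < 0.05)
      rej <- rej + 1
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("ANOVA detects a 3-SD shifted group", {
  set.seed(26)
  g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 3))
  expect_lt(anova_bonferroni(g)$omnibus$p_value, 0.001)
})

test_that("Bonferroni adjustment: m=1 identity, monotone in m, capped at 1", {
  set.seed(27)
  g <- list(a = rnorm(20), b = rnorm(20, 1), c = rnorm(20), d = rnorm(20))
  r1 <- anova_bonferroni(g, contrasts = list(c("a", "b")))
  expect_equal(r1$contrasts[[1]]$adjusted_p, r1$contrasts[[1]]$p_value)
  all_pairs <- combn(names(g), 2, simplify = FALSE)
  prev <- 0
  for (m in 1:6) {
    r <- anova_bonferroni(g, contrasts = all_pairs[1:m])
    adj <- r$contrasts[[1]]$adjusted_p
    expect_gte(adj, prev)
    expect_gte(adj, r$contrasts[[1]]$p_value)
    expect_lte(adj, 1)
    prev <- adj
  }
  expect_error(anova_bonferroni(list(a = rnorm(5), b = 1)), "b")
  expect_error(anova_bonferroni(g, contrasts = list(c("a", "zz"))),
               class = "immflow_lookup_error")
})

test_that("univariate regression: exact fits, flat fits, identity with Pearson r^2", {
  r <- suppressWarnings(univariate_regression(1:10, 2 * (1:10)))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  r <- univariate_regression(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r$slope, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  set.seed(28)
  x <- rnorm(50); y <- 0.3 * x + rnorm(50)
  r <- univariate_regression(x, y)
  expect_equal(r$r_squared, cor(x, y)^2, tolerance = 1e-10)
  ref <- summary(lm(y ~ x))
  expect_equal(r$f_statistic, unname(ref$fstatistic[1]), tolerance = 1e-10)
  expect_error(univariate_regression(rep(1, 10), rnorm(10)),
               class = "immflow_degenerate_error")
  expect_error(univariate_regression(1:2, 1:2),
               class = "immflow_insufficient_samples_error")
})
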