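test_that("Mann-Whitney U: worked examples and the U identity", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$extras$U_x, 0)
  expect_equal(r$p_value, 0.1)  # exact: 2 of the C(6,3)=20 labelings
  expect_identical(r$extras$method, "exact permutation")

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  set.seed(41)
  for (case in 1:5) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    r <- mann_whitney_u(x, y)
    expect_equal(r$extras$U_x + r$extras$U_y, length(x) * length(y))
    expect_gte(r$p_value, 0); expect_lte(r$p_value, 1)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test on both branches", {
  set.seed(42)
  # exact branch (no ties, small n)
  for (case in 1:5) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$extras$U_x, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  # approximate branch with ties and continuity correction
  for (case in 1:5) {
    x <- sample(1:15, 40, replace = TRUE)
    y <- sample(3:18, 35, replace = TRUE)
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_identical(mine$extras$method, "normal approximation")
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis: hand-computed H, ties, and base-R agreement", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$extras$df, 2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(43)
  for (case in 1:5) {
    g <- lapply(1:3, function(i) sample(1:8, sample(5:12, 1), replace = TRUE))
    mine <- kruskal_wallis(g)
    ref <- kruskal.test(unlist(g), rep(1:3, lengths(g)))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, oracle_kruskal_H(g), tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("k = 2 Kruskal-Wallis equals the squared untied Mann-Whitney z", {
  set.seed(44)
  x <- rnorm(12); y <- rnorm(15)
  kw <- kruskal_wallis(list(x, y))
  u <- mann_whitney_u(x, y)$extras$U_x
  nx <- 12; ny <- 15; n <- nx + ny
  z_uncorrected <- (u - nx * ny / 2) / sqrt(nx * ny * (n + 1) / 12)
  expect_equal(kw$statistic, z_uncorrected^2, tolerance = 1e-10)
})

test_that("Dunn post-hoc: worked example, identical groups, Bonferroni cap", {
  d <- dunn_posthoc(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
                    labels = c("a", "b", "c"))
  tab <- d$extras$pairs
  row13 <- tab[tab$group1 == "a" & tab$group2 == "c", ]
  expect_equal(row13$z, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(row13$p_adjusted, 6 * pnorm(6 / sqrt(5), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(row13$p_adjusted, 0.0219, tolerance = 5e-3)

  same <- dunn_posthoc(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(same$extras$pairs$z == 0))
  expect_true(all(same$extras$pairs$p_adjusted == 1))

  set.seed(45)
  g <- lapply(1:4, function(i) rnorm(8, mean = i))
  dd <- dunn_posthoc(g)
  expect_true(all(dd$extras$pairs$p_adjusted <= 1))
  expect_true(all(dd$extras$pairs$p_adjusted >=
                    dd$extras$pairs$p_unadjusted - 1e-15))
  expect_equal(nrow(dd$extras$pairs), 6)
})

test_that("tests are invariant under group reordering", {
  set.seed(46)
  g <- list(a = rnorm(10), b = rnorm(12, 1), c = rnorm(9, 2))
  kw1 <- kruskal_wallis(g)
  kw2 <- kruskal_wallis(rev(g))
  expect_equal(kw1$statistic, kw2$statistic, tolerance = 1e-12)
  d1 <- dunn_posthoc(g)
  d2 <- dunn_posthoc(rev(g))
  key <- function(t) {
    pair <- paste(pmin(t$group1, t$group2), pmax(t$group1, t$group2))
    setNames(t$p_adjusted, pair)[order(pair)]
  }
  expect_equal(key(d1$extras$pairs), key(d2$extras$pairs), tolerance = 1e-12)
})

test_that("null Kruskal-Wallis rejection rate is roughly calibrated (smoke)", {
  # 300-replicate sanity band; the tight 2000-replicate calibration bound
  # is asserted in test-acceptance.R
  set.seed(47)
  rej <- mean(replicate(300, {
    kruskal_wallis(list(rnorm(30), rnorm(30), rnorm(30)))$p_value < 0.05
  }))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.12)
})

test_that("linear regression: worked example, perfect fit, log transform", {
  r <- linear_regression(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$slope, 0.6)
  expect_equal(r$r_squared, 0.36)

  perf <- linear_regression(1:10, 2 * (1:10))
  expect_equal(perf$slope, 2)
  expect_equal(perf$r_squared, 1)

  cst <- linear_regression(1:10, rep(4, 10))
  expect_equal(cst$slope, 0)
  expect_equal(cst$r_squared, 0)

  set.seed(48)
  x <- runif(20, 1, 50); y <- 3 * log(x) + rnorm(20, sd = 0.3)
  mine <- linear_regression(x, y, log_x = TRUE)
  ref <- summary(lm(y ~ log(x)))
  expect_equal(mine$slope, unname(coef(ref)[2, 1]), tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$r.squared, tolerance = 1e-10)
  expect_equal(mine$p_value, unname(coef(ref)[2, 4]), tolerance = 1e-10)

  expect_warning(linear_regression(c(0, 1, 2, 3), 1:4, log_x = TRUE),
                 "non-positive")
  expect_error(linear_regression(rep(2, 5), 1:5), "zero variance")
})

test_that("rank statistics match a from-scratch ranking oracle at small N", {
  set.seed(49)
  for (case in 1:10) {
    pooled <- sample(1:6, 12, replace = TRUE)
    g <- split(pooled, rep(1:3, each = 4))
    names(g) <- NULL
    expect_equal(kruskal_wallis(g)$statistic, oracle_kruskal_H(g),
                 tolerance = 1e-10)
    r_mine <- rank(pooled)
    expect_equal(r_mine, oracle_ranks(pooled))
  }
})
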