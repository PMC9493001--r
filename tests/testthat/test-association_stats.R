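test_that("Spearman correlation matches the closed form and cor.test", {
  # 1 - 6*sum(d^2)/(n(n^2-1)) with d^2-sum 4 over n = 5
  r <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)       # monotone map
  expect_equal(spearman_cor(1:10, exp(-(1:10)))$rho, -1)  # reversal

  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    if (i %% 3 == 0) y <- round(y)      # introduce ties
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    r <- spearman_cor(x, y)
    expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(r$p, ct$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(9)
  x <- rnorm(30); y <- x + rnorm(30); z <- rnorm(30)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(exp(x), y^3 + y)$rho)
  expect_equal(partial_spearman(x, y, z)$rho,
               partial_spearman(exp(x), y, atan(z))$rho)
})

test_that("partial Spearman follows the first-order partial formula", {
  # closed-form arithmetic: (0.8 - 0.25) / 0.75
  expect_equal((0.8 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25)),
               0.73333333, tolerance = 1e-7)
  # construct rank data with those pairwise rank correlations via the
  # package route and check against a direct rank computation
  set.seed(10)
  x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
  r <- partial_spearman(x, y, z)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_direct <- (cor(rx, ry) - cor(rx, rz) * cor(ry, rz)) /
    sqrt((1 - cor(rx, rz)^2) * (1 - cor(ry, rz)^2))
  expect_equal(r$rho, r_direct, tolerance = 1e-12)

  # z uncorrelated with x and y: partial collapses to the simple rho
  # (exact when the sample rank correlations with z are zero; here checked
  # in a large-n simulation where they are merely small)
  set.seed(11)
  n <- 4000
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- rnorm(n)
  expect_equal(partial_spearman(x, y, z)$rho, spearman_cor(x, y)$rho,
               tolerance = 0.02)
})

test_that("Mann-Whitney U matches exact enumeration and identities", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_true(mw$exact)
  expect_equal(mw$p, 0.1)   # 2/20 assignments as extreme

  # identical groups: U equals its null mean
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$U, 4.5)

  # complement identity under group swap
  set.seed(12)
  a <- rnorm(8); b <- rnorm(6)
  expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U, 48)

  # exact path agrees with wilcox.test's exact p
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # tie-corrected normal path agrees with wilcox.test
  for (i in 1:10) {
    a <- sample(1:6, 15, TRUE); b <- sample(2:7, 12, TRUE)
    expect_equal(mann_whitney(a, b)$p,
                 suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty group")
})

test_that("paired t statistic behaves under shifts and the null", {
  r <- paired_t(c(1, 2, 3), c(2, 2, 2))   # d = (-1, 0, 1)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  set.seed(13)
  x <- rnorm(20)
  expect_gt(paired_t(x + 0.5, x + rnorm(20, 0, 1e-6))$t, 0)
  expect_lt(paired_t(x - 0.5, x + rnorm(20, 0, 1e-6))$t, 0)

  # agreement with t.test
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    tt <- t.test(x, y, paired = TRUE)
    r <- paired_t(x, y)
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  }
  expect_error(paired_t(1:5, 1:5 + 2), "zero-variance")
})

test_that("paired t holds its nominal type-I error under the null", {
  set.seed(14)
  rej <- mean(replicate(2000, paired_t(rnorm(50), rnorm(50))$p < 0.05))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("OLS matches the normal-equations oracle to 1e-10", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    y <- 0.3 + 0.7 * X[, 1] - 0.2 * X[, 2] + rnorm(n)
    f <- ols_fit(y, X)
    # independent oracle: solve the normal equations directly
    Xd <- cbind(1, X)
    beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
    res <- y - Xd %*% beta
    s2 <- sum(res^2) / (n - 3)
    se <- sqrt(diag(s2 * solve(t(Xd) %*% Xd)))
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    f_or <- (sum((y - mean(y))^2) - sum(res^2)) / 2 / s2
    expect_equal(f$coefficients$estimate, as.numeric(beta),
                 tolerance = 1e-10)
    expect_equal(f$coefficients$se, unname(se), tolerance = 1e-10)
    expect_equal(f$r_squared, r2, tolerance = 1e-10)
    expect_equal(f$f_stat, f_or, tolerance = 1e-10)
    expect_equal(f$coefficients$ci_lo,
                 as.numeric(beta) - qt(0.975, n - 3) * unname(se),
                 tolerance = 1e-10)
    expect_equal(f$df2, n - 3)
  }
})

test_that("OLS recovers exact linear data and the null R^2 level", {
  x1 <- c(1, 2, 3, 4, 5, 7); x2 <- c(2, 1, 5, 3, 8, 2)
  y <- 1 + 2 * x1 - 3 * x2
  # lm warns about the (intended) perfect fit
  f <- suppressWarnings(ols_fit(y, cbind(x1, x2)))
  expect_equal(f$coefficients$estimate, c(1, 2, -3), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  # y independent of X: E[R^2] = k/(n-1) = 2/49
  set.seed(16)
  r2 <- replicate(400, ols_fit(rnorm(50), matrix(rnorm(100), 50))$r_squared)
  expect_lt(abs(mean(r2) - 2 / 49), 0.01)

  expect_error(ols_fit(rnorm(10), cbind(1:10, 2 * (1:10))),
               "rank-deficient")
})
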