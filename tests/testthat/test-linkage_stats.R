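test_that("descriptives reproduce the five-number summary and skewness signs", {
  d <- descriptives(c(1, 2, 3, 4, 5))
  expect_equal(c(d$min, d$q1, d$median, d$q3, d$max), c(1, 2, 3, 4, 5))
  expect_equal(d$skewness, 0)
  expect_gt(descriptives(c(1, 1, 1, 10))$skewness, 0)
  dc <- descriptives(rep(2, 10))
  expect_true(dc$constant)
  expect_true(is.na(dc$skewness))
  expect_error(descriptives(c(1, 2)), "at least 3")
})

test_that("shapiro-wilk p-values are roughly uniform under normality", {
  set.seed(5)
  p <- replicate(200, descriptives(rnorm(50))$shapiro_p)
  expect_gt(mean(p < 0.5), 0.4)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("pearson r and its t-test match the analytic formula", {
  expect_equal(pearson_with_t(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_with_t(c(1, 2, 3), c(6, 4, 2))$r, -1)
  # a correlation of -0.417 at n = 57 is significant beyond the 1% level
  set.seed(8)
  x <- rnorm(57)
  y <- -0.417 * x + rnorm(57)
  ct <- pearson_with_t(x, y)
  expect_equal(ct$t_stat, ct$r * sqrt(55) / sqrt(1 - ct$r^2))
  expect_equal(ct$p_t, 2 * pt(-abs(ct$t_stat), 55))
  t417 <- -0.417 * sqrt(55) / sqrt(1 - 0.417^2)
  expect_lt(2 * pt(t417, 55), 0.01)
  expect_error(pearson_with_t(rep(1, 5), 1:5), "zero variance")
})

test_that("bootstrap p is floored, capped, seeded and sensible", {
  x <- 1:20
  expect_equal(bootstrap_p(x, 2 * x, B = 999, seed = 3), 1 / 1000)
  p1 <- bootstrap_p(rnorm(30), rnorm(30), B = 499, seed = 7)
  p2 <- bootstrap_p(rnorm(30), rnorm(30), B = 499, seed = 7)
  set.seed(7)
  xa <- rnorm(30); ya <- rnorm(30)
  expect_identical(bootstrap_p(xa, ya, B = 499, seed = 42),
                   bootstrap_p(xa, ya, B = 499, seed = 42))
  expect_error(bootstrap_p(1:10, 1:10, B = 50), "at least 99")
  expect_lte(bootstrap_p(xa, ya, B = 199, seed = 1), 1)
})

test_that("shared variance matches lm and collapses to r^2 for one predictor", {
  set.seed(21)
  X <- matrix(rnorm(40 * 3), 40)
  y <- X %*% c(0.5, -0.2, 0.1) + rnorm(40)
  sv <- shared_variance(y, X)
  fit <- summary(lm(y ~ X))
  expect_equal(sv$r_squared, fit$r.squared, tolerance = 1e-10)
  expect_equal(sv$f_stat, unname(fit$fstatistic[1]), tolerance = 1e-10)
  x1 <- rnorm(30); y1 <- 0.4 * x1 + rnorm(30)
  expect_equal(shared_variance(y1, cbind(x1))$r_squared,
               pearson_with_t(x1, y1)$r^2, tolerance = 1e-12)
  expect_error(shared_variance(y, cbind(X, X[, 1])), "collinear")
})

test_that("orthogonal predictors add their squared correlations exactly", {
  # construct exact sample geometry: orthonormal centred z1, z2, residual e
  n <- 24
  raw <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  z1 <- raw[, 1]; z2 <- raw[, 2]; e <- raw[, 3]
  y <- 0.3 * z1 + 0.4 * z2 + sqrt(1 - 0.09 - 0.16) * e
  sv <- shared_variance(y, cbind(z1, z2))
  expect_equal(sv$r_squared, 0.25, tolerance = 1e-12)
})

test_that("F back-calculation matches pf", {
  ft <- r2_f_test(0.25, 2, 30)
  expect_equal(ft$f_stat, (0.25 / 2) / (0.75 / 27))
  expect_equal(ft$p_f, pf(ft$f_stat, 2, 27, lower.tail = FALSE))
})

test_that("canonical correlations agree with the eigen oracle and cancor", {
  set.seed(31)
  for (i in 1:25) {
    d <- sample_canonical_pair(60, 4, 6, c(0.6, 0.3, 0.1, 0.05))
    fit <- cca(d$X, d$Y)
    expect_equal(fit$cor, cca_oracle(d$X, d$Y), tolerance = 1e-8)
    cc <- cancor(scale(d$X), scale(d$Y))
    expect_equal(fit$cor, cc$cor, tolerance = 1e-8)
  }
})

test_that("degenerate and one-dimensional CCA cases behave", {
  set.seed(32)
  x <- rnorm(30)
  expect_equal(cca(cbind(x), cbind(x))$cor, 1)
  y <- -0.5 * x + rnorm(30, 0, sqrt(0.75))
  fit <- cca(cbind(x), cbind(y))
  expect_equal(fit$cor, abs(cor(x, y)))
  X <- matrix(rnorm(60), 30)
  expect_error(cca(cbind(X, X[, 1] + 1e-9 * rnorm(30)), cbind(y)),
               "ill-conditioned")
  expect_error(cca(X[1:5, ], matrix(rnorm(5 * 4), 5)), "more rows")
})

test_that("CCA is invariant to affine rescaling and loadings are orthogonal", {
  set.seed(33)
  d <- sample_canonical_pair(80, 4, 6, c(0.6, 0.3, 0.1, 0.05))
  f1 <- cca(d$X, d$Y)
  X2 <- sweep(sweep(d$X, 2, c(2, -3, 0.5, 10), "*"), 2, c(1, 2, 3, 4), "+")
  f2 <- cca(X2, d$Y)
  expect_equal(f1$cor, f2$cor, tolerance = 1e-10)
  expect_true(all(rowSums(f1$loadings_x^2) <= 1 + 1e-8))
  expect_true(all(rowSums(f1$loadings_y^2) <= 1 + 1e-8))
  # orientation: largest-magnitude loading of each variate is positive
  expect_true(all(apply(f1$loadings_x, 2, function(l) l[which.max(abs(l))]) > 0))
})

test_that("large-sample canonical correlations recover the population values", {
  set.seed(34)
  d <- sample_canonical_pair(20000, 3, 3, c(0.6, 0.2, 0))
  fit <- cca(d$X, d$Y)
  expect_lt(abs(fit$cor[1] - 0.6), 0.02)
  expect_lt(abs(fit$cor[2] - 0.2), 0.02)
})

test_that("sequential Wilks lambdas follow the product formula", {
  lam <- wilks_lambda(c(0.584, 0.400))
  expect_equal(lam[1], (1 - 0.584^2) * (1 - 0.4^2))
  expect_equal(round(lam[1], 4), 0.5535)
  expect_equal(lam[2], 0.84)
  expect_equal(wilks_lambda(c(0, 0, 0)), c(1, 1, 1))
  expect_equal(wilks_lambda(c(1, 0.5))[1], 0)
  expect_error(wilks_lambda(c(0.5, 1.2)), "0, 1")
})

test_that("the Wilks permutation test is seeded, bounded and detects identity", {
  set.seed(35)
  X <- matrix(rnorm(40 * 3), 40)
  Y <- X[, c(2, 3, 1)]
  pp <- cca_permutation_p(X, Y, B = 199, seed = 5)
  expect_equal(pp$p[1], 1 / 200)
  expect_true(all(pp$p >= 1 / 200 & pp$p <= 1))
  pp2 <- cca_permutation_p(X, Y, B = 199, seed = 5)
  expect_identical(pp$p, pp2$p)
  expect_error(cca_permutation_p(X, Y, B = 10), "at least 99")
  # Wilks sequence reconstructs from the returned canonical correlations
  fit <- cca(X, matrix(rnorm(40 * 4), 40))
  expect_equal(fit$wilks, wilks_lambda(fit$cor))
})
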