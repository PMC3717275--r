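test_that("LCT statistic equals the inverse-covariance quadratic form", {
  # frozen fixture value from the dense-inverse oracle
  xf <- fixture_10x4()
  xc <- center_columns(xf, "samples_by_genes")
  fit <- shrink_covariance(xc)
  v <- orthogonal_transform(xc, fit)
  y <- fixture_y10()
  expect_equal(lct_statistic(y, v), 0.049392060439561, tolerance = 1e-10)

  set.seed(71)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    p <- sample(2:50, 1)
    x <- rand_matrix(n, p)
    y <- rnorm(n)
    xc <- center_columns(x, "samples_by_genes")
    fit <- shrink_covariance(xc)
    v <- orthogonal_transform(xc, fit)
    expect_equal(lct_statistic(y, v),
                 oracle_lct_quadform(x, y, fit$omega_star),
                 tolerance = 1e-8)
  }
})

test_that("LCT statistic vanishes for an orthogonal phenotype and ignores gene scale", {
  set.seed(72)
  x <- rand_matrix(12, 4)
  xc <- center_columns(x, "samples_by_genes")
  fit <- shrink_covariance(xc)
  v <- orthogonal_transform(xc, fit)
  # project a phenotype onto the orthocomplement of V's columns (and of 1)
  y0 <- rnorm(12)
  y_orth <- residuals(lm(y0 ~ v))
  expect_equal(lct_statistic(y_orth, v), 0, tolerance = 1e-20)

  # rescaling one gene leaves the statistic unchanged (recompute the pipeline)
  y <- rnorm(12)
  x2 <- x
  x2[, 3] <- x2[, 3] * 17
  xc2 <- center_columns(x2, "samples_by_genes")
  v2 <- orthogonal_transform(xc2, shrink_covariance(xc2))
  expect_equal(lct_statistic(y, v2), lct_statistic(y, v), tolerance = 1e-8)

  expect_error(lct_statistic(rnorm(5), v), "does not match")
})

test_that("LCT2 reduces to the OLS fitted-value norm without shrinkage", {
  set.seed(81)
  x <- rand_matrix(20, 3)
  y <- rnorm(20)
  xc <- center_columns(x, "samples_by_genes")
  fit0 <- shrink_covariance(xc, lambda = 0)
  ols <- lm(y ~ x)
  expect_equal(lct2_statistic(y, xc, fit0),
               sum((fitted(ols) - mean(y))^2), tolerance = 1e-8)

  # frozen fixture value from the dense-inverse oracle at the estimated lambda
  xf <- fixture_10x4()
  xcf <- center_columns(xf, "samples_by_genes")
  fitf <- shrink_covariance(xcf)
  expect_equal(lct2_statistic(fixture_y10(), xcf, fitf),
               0.566110887737036, tolerance = 1e-10)

  # a phenotype with zero sample covariance to every gene gives 0
  y0 <- residuals(lm(rnorm(20) ~ x))
  expect_equal(lct2_statistic(y0, xc, fit0), 0, tolerance = 1e-18)
})

test_that("SAM-GS is the sum of squared per-gene slope t-statistics", {
  set.seed(91)
  x <- rand_matrix(15, 6)
  y <- rnorm(15)
  xc <- center_columns(x, "samples_by_genes")

  # single-gene set equals the squared classical t for the slope
  for (h in 1:3) {
    xh <- center_columns(x[, h, drop = FALSE], "samples_by_genes")
    tstat <- summary(lm(y ~ x[, h]))$coefficients[2, "t value"]
    expect_equal(samgs_statistic(y, xh), tstat^2, tolerance = 1e-10)
  }

  # additivity over genes
  x12 <- center_columns(x[, 1:2], "samples_by_genes")
  x1 <- center_columns(x[, 1, drop = FALSE], "samples_by_genes")
  x2 <- center_columns(x[, 2, drop = FALSE], "samples_by_genes")
  expect_equal(samgs_statistic(y, x12),
               samgs_statistic(y, x1) + samgs_statistic(y, x2))

  # orthogonal phenotype: all slopes zero
  y_orth <- residuals(lm(rnorm(15) ~ x))
  expect_equal(samgs_statistic(y_orth, xc), 0, tolerance = 1e-18)

  # perfect collinearity is refused with the offending gene named
  expect_error(samgs_statistic(x[, 2], xc), "degenerate regression")
})

test_that("Global Test statistic matches its expanded-sum form", {
  set.seed(101)
  x <- rand_matrix(10, 5)
  y <- rnorm(10)
  xc <- center_columns(x, "samples_by_genes")
  expanded <- sum(sapply(seq_len(5), function(h) {
    sum((x[, h] - mean(x[, h])) * (y - mean(y)))^2
  })) / 5
  expect_equal(globaltest_statistic(y, xc), expanded)

  # constant phenotype gives 0
  expect_equal(globaltest_statistic(rep(2, 10), xc), 0)

  # hand-computed: y equal to a single centered gene, the other gene zero
  xg <- cbind(c(1, -1, 2, -2), 0)
  xcg <- center_columns(xg, "samples_by_genes")
  expect_equal(globaltest_statistic(c(1, -1, 2, -2), xcg), (1 + 1 + 4 + 4)^2 / 2)
})

test_that("permutation p-values use the add-one convention and handle extremes", {
  # constant phenotype: every permuted statistic ties the observed, p = 1
  xc <- center_columns(rand_matrix(8, 3), "samples_by_genes")
  res <- permutation_pvalue(function(y) globaltest_statistic(y, xc),
                            rep(1, 8), B = 50, seed = 1)
  expect_equal(res$p_value, 1)

  # observed strictly exceeds every permuted value: p = 1/(B+1)
  w <- 1:5
  res2 <- permutation_pvalue(function(y) sum(y * w), 1:5, B = 99, seed = 2)
  expect_equal(res2$p_value, 1 / 100)
  expect_equal(res2$n_permutations, 99)
  expect_error(permutation_pvalue(function(y) 1, 1:5, B = 0), "at least 1")
})

test_that("Monte Carlo permutation p-values agree with exhaustive enumeration", {
  set.seed(111)
  n <- 5
  x <- rand_matrix(n, 3)
  y <- rnorm(n)
  xc <- center_columns(x, "samples_by_genes")
  fit <- shrink_covariance(xc)
  v <- orthogonal_transform(xc, fit)
  obs <- lct_statistic(y, v)
  perms <- all_permutations(n)  # 120 rows
  exact_stats <- apply(perms, 1, function(idx) lct_statistic(y[idx], v))
  p_exact <- mean(exact_stats >= obs - 1e-12)
  res <- permutation_pvalue(function(yy) lct_statistic(yy, v), y,
                            B = 10000, seed = 3)
  expect_lt(abs(res$p_value - p_exact), 0.02)
})

test_that("p-values are invariant to affine phenotype maps and gene order", {
  set.seed(121)
  x <- rand_matrix(12, 8)
  y <- rnorm(12)
  r1 <- gsa_test(t(x), y, B = 200, seed = 5)
  r2 <- gsa_test(t(x), 3 * y + 7, B = 200, seed = 5)
  expect_equal(r1$p_value, r2$p_value)

  r3 <- gsa_test(t(x[, sample(8)]), y, B = 200, seed = 5)
  expect_equal(r1$p_value[r1$method %in% c("LCT", "LCT2")],
               r3$p_value[r3$method %in% c("LCT", "LCT2")])
})

test_that("the vectorized engine reproduces the generic permutation test", {
  set.seed(131)
  x <- rand_matrix(10, 6)
  y <- rnorm(10)
  xc <- center_columns(x, "samples_by_genes")
  fit <- shrink_covariance(xc)
  v <- orthogonal_transform(xc, fit)
  B <- 150
  fast <- gsa_test(xc, y, B = B, seed = 9)
  stats <- list(
    LCT = function(yy) lct_statistic(yy, v),
    LCT2 = function(yy) lct2_statistic(yy, xc, fit),
    SAMGS = function(yy) samgs_statistic(yy, xc),
    GLOBAL = function(yy) globaltest_statistic(yy, xc)
  )
  for (m in names(stats)) {
    slow <- permutation_pvalue(stats[[m]], y, B = B, seed = 9, method = m)
    expect_equal(fast$p_value[fast$method == m], slow$p_value)
    expect_equal(fast$statistic[fast$method == m], slow$statistic)
  }
})

test_that("null p-values are close to uniform for all four statistics", {
  set.seed(141)
  sc <- simulation_scenario(10, 20, 5, 5, 0.3, n_replicates = 1,
                            n_permutations = 100, seed = 141)
  ps <- matrix(NA_real_, 200, 4)
  for (i in 1:200) {
    dat <- simulate_dataset(sc, 141000 + i)
    ps[i, ] <- gsa_test(t(dat$x), dat$y, B = 100)$p_value
  }
  expect_true(all(abs(colMeans(ps) - 0.5) < 0.08))
})
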