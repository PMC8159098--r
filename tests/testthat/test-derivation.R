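# independent oracle: explicit covariance matrix + dense eigendecomposition,
# with the same sign convention applied afterwards
oracle_pca <- function(X) {
  xc <- sweep(X, 2, colMeans(X))
  cv <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(ncol(X)))
    for (j in seq_len(ncol(X)))
      cv[i, j] <- sum(xc[, i] * xc[, j]) / (nrow(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  A <- eg$vectors
  for (j in seq_len(ncol(A))) {
    k <- which.max(abs(A[, j]))
    if (A[k, j] < 0) A[, j] <- -A[, j]
  }
  list(values = eg$values, vectors = A)
}

test_that("PCA recovers exact low-rank and diagonal structure", {
  x1 <- c(-3, -1, 1, 3)
  fm <- feature_matrix(cbind(a = x1, b = 2 * x1), c(1, 2, 3, 4))
  p <- sl_pca(fm)
  expect_equal(abs(p$A[, 1]), c(1, 2) / sqrt(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(p$eigenvalues[2], 0, tolerance = 1e-9)

  # orthogonal columns with variances (4, 1): loadings are the identity
  X <- cbind(a = x1 / sd(x1) * 2, b = c(1, -1, -1, 1) / sd(c(1, -1, -1, 1)))
  p2 <- sl_pca(feature_matrix(X, c(1, 2, 3, 4)))
  expect_equal(p2$A, diag(2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(p2$eigenvalues, c(4, 1), tolerance = 1e-9)
})

test_that("PCA matches the brute-force covariance eigendecomposition", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:60, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    got <- sl_pca(feature_matrix(X, rnorm(n)))
    want <- oracle_pca(X)
    expect_equal(got$eigenvalues, want$values, tolerance = 1e-8)
    expect_equal(got$A, want$vectors, tolerance = 1e-8, ignore_attr = TRUE)
    # defining relation Z = X_centered A
    xc <- sweep(X, 2, colMeans(X))
    expect_lt(max(abs(got$Z - xc %*% got$A)), 1e-9)
    # orthonormal loadings, non-increasing eigenvalues
    expect_lt(max(abs(crossprod(got$A) - diag(p))), 1e-9)
    expect_true(all(diff(got$eigenvalues) <= 1e-12))
  }
})

test_that("eigenvalues conserve total variance and scores have diagonal covariance", {
  set.seed(33)
  X <- matrix(rnorm(50 * 6), 50, 6)
  p <- sl_pca(feature_matrix(X, rnorm(50)))
  expect_equal(sum(p$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-8)
  expect_lt(max(abs(colMeans(p$Z))), 1e-8)
  expect_equal(cov(p$Z), diag(p$eigenvalues), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("VIFs are 1 for orthogonal columns and follow the 1/(1-R^2) closed form", {
  # exactly orthogonal standardized columns
  x1 <- c(-3, -1, 1, 3); x2 <- c(1, -1, -1, 1)
  fm <- feature_matrix(cbind(a = x1, b = x2), 1:4)
  expect_equal(unname(variance_inflation_factors(fm)), c(1, 1),
               tolerance = 1e-9)

  # sample correlation exactly 0.6: VIF = 1 / (1 - 0.36) = 1.5625
  u <- x1 / sqrt(sum(x1^2)); e <- x2 / sqrt(sum(x2^2))
  v <- 0.6 * u + sqrt(1 - 0.36) * e
  vif <- variance_inflation_factors(feature_matrix(cbind(u = u, v = v), 1:4))
  expect_equal(unname(vif), c(1.5625, 1.5625), tolerance = 1e-9)
  # cross-check against the explicit 2x2 inverse
  s <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(unname(vif), diag(solve(s)), tolerance = 1e-9)

  # duplicated column: infinite VIF on both copies, no crash
  set.seed(9)
  z <- rnorm(20)
  vif2 <- variance_inflation_factors(
    feature_matrix(cbind(a = z, b = z, c = rnorm(20)), rnorm(20)))
  expect_identical(unname(is.infinite(vif2)), c(TRUE, TRUE, FALSE))
  expect_gte(min(vif2), 1)
})

test_that("PCR solves the normal equations and reduces to hand arithmetic", {
  # single score column, exact fit
  fit <- pcr_fit(matrix(c(1, 2), ncol = 1), c(2, 4))
  expect_equal(unname(fit$gamma_hat), 2)
  expect_equal(fit$residuals, c(0, 0))

  set.seed(14)
  Z <- matrix(rnorm(120), 40, 3)
  gam <- c(0.5, -1.2, 2)
  y <- drop(Z %*% gam) + rnorm(40, 0, 0.1)
  fit2 <- pcr_fit(Z, y)
  # normal-equations oracle by explicit inverse
  oracle <- drop(solve(t(Z) %*% Z) %*% t(Z) %*% y)
  expect_equal(unname(fit2$gamma_hat), oracle, tolerance = 1e-9)
  se <- sqrt(diag(solve(t(Z) %*% Z)) * sum(fit2$residuals^2) / (40 - 3))
  expect_true(all(abs(fit2$gamma_hat - gam) < 3 * se + 1e-9))
  # residuals orthogonal to the regressors
  expect_lt(max(abs(crossprod(Z, fit2$residuals))), 1e-9)
})

test_that("full-rank PCR reproduces ordinary least squares on the centered matrix", {
  set.seed(26)
  X <- matrix(rnorm(45 * 5), 45, 5)
  y <- rnorm(45)
  fm <- feature_matrix(X, y)
  p <- sl_pca(fm)
  fit <- pcr_fit(p, fm$y_centered)           # m = p
  ols <- stats::lm.fit(fm$X_centered, fm$y_centered)
  expect_equal(fit$fitted, unname(ols$fitted.values), tolerance = 1e-8)
  # implied original-coordinate coefficients agree with OLS (gamma = A' beta)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-8)
})

test_that("candidate ranking prefers the exactly-explaining parameter", {
  set.seed(41)
  x <- runif(30, 5, 30)
  noise_col <- rnorm(30)
  y <- 3 * x
  fm <- feature_matrix(cbind(driver = x, noise = noise_col), y)
  rk <- rank_candidates(fm)
  expect_identical(rk$table$parameter[1], "driver")
  expect_lt(rk$table$sum_abs_resid[1], 1e-9)
  # centered residuals sum to ~0 for every candidate, as reported
  expect_lt(max(rk$table$abs_sum_resid), 1e-9)

  expect_error(rank_candidates(fm, vif_threshold = 0.5), "threshold")
})

test_that("ranking is invariant to positive rescaling of a candidate column", {
  set.seed(52)
  X <- cbind(a = runif(40, 1, 2), b = runif(40, 1, 2), c = runif(40, 1, 2))
  y <- 1.2 * X[, "b"] + rnorm(40, 0, 0.05)
  r1 <- rank_candidates(feature_matrix(X, y))
  X2 <- X; X2[, "b"] <- 37.5 * X2[, "b"]
  r2 <- rank_candidates(feature_matrix(X2, y))
  expect_identical(r1$table$parameter, r2$table$parameter)
  expect_equal(r1$table$sum_abs_resid, r2$table$sum_abs_resid, tolerance = 1e-9)
})

test_that("model derivation selects the constructed driver and recovers beta", {
  fm <- simulate_feature_matrix(n = 200, noise_sd = 0, seed = 61)
  der <- derive_sl_model(fm)
  expect_identical(der$selected, "acc_range_mag")
  expect_equal(unname(coef(der$model)), 0.72, tolerance = 1e-9)

  # with noise, recovery within the analytic single-regressor standard error
  fm2 <- simulate_feature_matrix(n = 300, noise_sd = 0.03, seed = 62)
  der2 <- derive_sl_model(fm2)
  expect_identical(der2$selected, "acc_range_mag")
  g <- fm2$X[, "acc_range_mag"]^0.1
  se <- 0.03 / sqrt(sum(g^2))
  expect_lt(abs(coef(der2$model) - 0.72), 3 * se + 0.02)
})

test_that("duplicated columns are flagged and excluded before ranking", {
  fm <- simulate_feature_matrix(n = 120, duplicate_pair = TRUE, seed = 71)
  vif <- variance_inflation_factors(fm)
  expect_true(is.infinite(vif["vel_mean_x"]) && is.infinite(vif["vel_mean_y"]))
  rk <- rank_candidates(fm)
  expect_true(all(c("vel_mean_x", "vel_mean_y") %in% rk$excluded))
})
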