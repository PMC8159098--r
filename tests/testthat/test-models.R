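est1 <- function(model, data, constant, user = NULL)
  estimate_stride_length(data, model = model, constant = constant, user = user)

test_that("all five estimators reproduce hand-computable values", {
  expect_equal(est1("proposed", data.frame(a_range = 1), 1.3), 1.3)
  expect_equal(est1("proposed", data.frame(a_range = 1024), 0.7), 1.4)
  expect_equal(est1("proposed", data.frame(a_range = 0), 0.7), 0)
  expect_error(est1("proposed", data.frame(a_range = -1), 0.7), "negative")

  expect_equal(est1("weinberg", data.frame(a_max = 16, a_min = 0), 1), 2)
  expect_equal(est1("weinberg", data.frame(a_max = 3, a_min = 3), 1), 0)
  expect_equal(est1("weinberg", data.frame(a_max = 81.5, a_min = 0.5), 0.5), 1.5)
  expect_error(est1("weinberg", data.frame(a_max = 0, a_min = 1), 1), "a_max")

  expect_equal(est1("kim", data.frame(a_mean = 8), 1), 2)
  expect_equal(est1("kim", data.frame(a_mean = 0), 1), 0)
  expect_equal(est1("kim", data.frame(a_mean = 27), 0.3), 0.9)

  u <- user_profile(height_m = 1.8, leg_length_m = 1)
  expect_equal(est1("zijlstra_hof", data.frame(V = 0), 1, u), 0)
  expect_equal(est1("zijlstra_hof", data.frame(V = 1), 1, u), 2)  # V = L
  expect_equal(est1("zijlstra_hof", data.frame(V = 0.02), 1, u),
               2 * sqrt(0.0396))
  expect_error(est1("zijlstra_hof", data.frame(V = 2.5), 1, u), "outside")
  expect_error(est1("zijlstra_hof", data.frame(V = 0.02), 1), "leg length")

  expect_equal(est1("tian", data.frame(F = 4), 1, u), 3.6)
  expect_equal(est1("tian", data.frame(F = 1), 0.4,
                    user_profile(height_m = 1.75)), 0.7)
  expect_error(est1("tian", data.frame(F = 1), 1), "height")
})

test_that("estimators are homogeneous in the constant and monotone in the regressor", {
  u <- user_profile(height_m = 1.77, leg_length_m = 1.05)
  cases <- list(
    proposed = data.frame(a_range = sort(runif(20, 0.5, 30))),
    weinberg = data.frame(a_max = sort(runif(20, 0, 10)), a_min = 0),
    kim = data.frame(a_mean = sort(runif(20, 0, 10))),
    zijlstra_hof = data.frame(V = sort(runif(20, 0, 1.05))),
    tian = data.frame(F = sort(runif(20, 0.5, 3))))
  set.seed(88)
  for (mdl in names(cases)) {
    d <- cases[[mdl]]
    e1 <- est1(mdl, d, 0.8, u)
    expect_equal(est1(mdl, d, 2.4, u), 3 * e1, tolerance = 1e-12)
    expect_true(all(diff(e1) >= 0))
  }
})

test_that("the proposed estimate is invariant under rotation of the raw axes", {
  w <- quick_walk(seed = 10, duration = 40)
  acc <- w$accel$pelvis
  segs <- data.frame(start = w$truth$start_idx, end = w$truth$end_idx)
  r <- random_rotation(55)
  in1 <- stride_inputs(acc, segs)
  in2 <- stride_inputs(apply_rotation(acc, r), segs)
  expect_lt(max(abs(in2$a_range - in1$a_range)), 1e-9)
  e1 <- est1("proposed", in1, 0.72)
  e2 <- est1("proposed", in2, 0.72)
  expect_lt(max(abs(e2 - e1)), 1e-9)
  # the oriented-input models see different inputs after rotation
  expect_gt(max(abs(in2$a_max - in1$a_max)), 1e-3)
  expect_gt(max(abs(in2$a_mean - in1$a_mean)), 1e-3)
})

test_that("constant tuning is the single-regressor least-squares estimator", {
  # g = (1, 2), d = (2, 4) -> constant 2 (exact fit)
  d <- data.frame(a_max = c(1, 16), a_min = 0, length_m = c(2, 4))
  expect_equal(tune_constant(d, "weinberg"), 2)

  # single stride: g = 3, d = 1.2 -> 0.4
  one <- data.frame(a_range = 3^10, length_m = 1.2)
  expect_equal(tune_constant(one, "proposed"), 0.4, tolerance = 1e-12)

  # constant regressor value 1: the constant is the mean stride length
  flat <- data.frame(a_range = 1, length_m = c(1.1, 1.3, 1.5))
  expect_equal(tune_constant(flat, "proposed"), 1.3)

  # perturbing the estimate never decreases the squared error
  set.seed(30)
  dd <- data.frame(a_range = runif(50, 5, 30))
  dd$length_m <- 0.7 * dd$a_range^0.1 + rnorm(50, 0, 0.05)
  fit <- sl_model(dd, "proposed")
  sse <- function(k) sum((dd$length_m - k * dd$a_range^0.1)^2)
  k0 <- coef(fit)[[1]]
  expect_lte(sse(k0), sse(k0 * 1.01))
  expect_lte(sse(k0), sse(k0 * 0.99))
})

test_that("tuning recovers a known Weinberg constant within its standard error", {
  set.seed(71)
  n <- 400
  amax <- runif(n, 5, 25); amin <- runif(n, -8, 0)
  g <- (amax - amin)^0.25
  d <- data.frame(a_max = amax, a_min = amin,
                  length_m = 0.45 * g + rnorm(n, 0, 0.03))
  k <- tune_constant(d, "weinberg")
  se <- 0.03 / sqrt(sum(g^2))
  expect_lt(abs(k - 0.45), max(3 * se, 0.01))
})

test_that("vertical displacement integrates a sinusoidal oscillation to 2A", {
  expect_equal(vertical_displacement(rep(0, 100), fs = 100), 0)

  fs <- 100; A <- 0.02; omega <- 2 * pi
  tt <- seq(0, 1, by = 1 / fs)   # one full period
  az <- -A * omega^2 * sin(omega * tt)
  expect_equal(vertical_displacement(az, fs = fs), 2 * A, tolerance = 0.01)

  expect_error(vertical_displacement(c(1, 2), fs = 100), "3 samples")

  # simulator pelvis channel: V within 5% of the configured excursion
  w <- quick_walk(seed = 3, duration = 40)
  acc <- w$accel$pelvis
  tr <- w$truth[5:20, ]
  v_est <- vapply(seq_len(nrow(tr)), function(i) {
    vertical_displacement(acc$values[tr$start_idx[i]:(tr$end_idx[i] - 1), 3],
                          fs = acc$fs)
  }, numeric(1))
  expect_lt(max(abs(v_est - tr$V_m) / tr$V_m), 0.05)
})

test_that("the tuning split follows the 5/10-minute protocol", {
  strides <- data.frame(start_s = seq(0, 899, by = 1.1))
  sp <- tuning_split(strides, track_duration_s = 900)
  expect_true(all(strides$start_s[sp$tuning] < 300))
  expect_true(all(strides$start_s[sp$evaluation] >= 300))
  expect_identical(sp$evaluation, !sp$tuning)

  short <- data.frame(start_s = seq(0, 89, by = 1.1))
  expect_warning(sps <- tuning_split(short, track_duration_s = 90),
                 "proportional")
  expect_equal(sum(sps$tuning) / nrow(short), 1 / 3, tolerance = 0.05)

  # universal pooling merges the per-track tuning windows
  t1 <- data.frame(start_s = seq(0, 899, by = 1.0), a_range = 10, length_m = 1)
  t2 <- data.frame(start_s = seq(0, 899, by = 1.5), a_range = 12, length_m = 1.1)
  pooled <- pool_tuning_strides(list(t1, t2))
  expect_identical(nrow(pooled), sum(t1$start_s < 300) + sum(t2$start_s < 300))
})

test_that("personalized constants differ across tracks with different true constants", {
  mk <- function(beta, seed) {
    d <- simulate_powerlaw_strides(beta = beta, n = 400, noise_sd = 0.02,
                                   seed = seed)
    d$start_s <- seq(0, by = 1.1, length.out = nrow(d))
    d
  }
  tr1 <- mk(0.6, 81); tr2 <- mk(0.8, 82)
  fit1 <- sl_model(tr1[tuning_split(tr1)$tuning, ], "proposed")
  fit2 <- sl_model(tr2[tuning_split(tr2)$tuning, ], "proposed")
  uni <- sl_model(pool_tuning_strides(list(tr1, tr2)), "proposed",
                  scope = "universal")
  expect_equal(coef(fit1)[[1]], 0.6, tolerance = 0.01)
  expect_equal(coef(fit2)[[1]], 0.8, tolerance = 0.01)
  expect_gt(coef(uni)[[1]], coef(fit1)[[1]])
  expect_lt(coef(uni)[[1]], coef(fit2)[[1]])
})

test_that("sl_model objects expose the standard modelling interface", {
  set.seed(55)
  dd <- data.frame(a_range = runif(60, 5, 30))
  dd$length_m <- 0.72 * dd$a_range^0.1 + rnorm(60, 0, 0.03)
  fit <- sl_model(dd, "proposed")
  expect_s3_class(fit, "sl_model")
  expect_named(coef(fit), "beta")
  expect_equal(fitted(fit) + residuals(fit), dd$length_m)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, data.frame(a_range = 1024)),
               coef(fit)[[1]] * 2)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.sl_model")
  expect_output(print(sm), "MAE")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(60L, 3L))
  expect_output(print(fit), "power law")

  # round trip through the JSON model file
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(coef(back)[[1]], coef(fit)[[1]])
  expect_identical(back$model, "proposed")
  unlink(path)
})
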