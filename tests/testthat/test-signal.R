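test_that("zero-phase Butterworth passes DC exactly and halves power at the cutoff", {
  s <- uniform_series(rep(3.7, 500), fs = 100)
  expect_lt(max(abs(lowpass_butterworth(s, 5, 4)$values - 3.7)), 1e-8)

  # forward-backward application squares the magnitude: |H(fc)|^2 = 1/2
  sc <- sine_series(5, fs = 100, dur = 20)
  f <- lowpass_butterworth(sc, 5, 4)
  mid <- 500:1500
  expect_equal(max(abs(f$values[mid])), 0.5, tolerance = 1e-3)
})

test_that("Butterworth separates in-band from out-of-band components", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 1 * tt) + sin(2 * pi * 20 * tt)
  f <- lowpass_butterworth(uniform_series(x, fs), 5, 4)
  # FFT amplitude at 1 and 20 Hz over an integer number of cycles
  seg <- f$values[1:2000]
  amp <- function(sig, freq) {
    n <- length(sig)
    2 * abs(fft(sig)[round(freq * n / fs) + 1]) / n
  }
  expect_equal(amp(seg, 1), 1, tolerance = 0.01)
  expect_lt(amp(seg, 20), 1 / 40)
})

test_that("Butterworth is linear and introduces no phase shift", {
  set.seed(7)
  fs <- 100
  x <- rnorm(600); y <- rnorm(600)
  fl <- function(v) lowpass_butterworth(uniform_series(v, fs), 5, 4)$values[, 1]
  expect_lt(max(abs(fl(2.5 * x - 1.3 * y) - (2.5 * fl(x) - 1.3 * fl(y)))), 1e-9)

  s <- sine_series(1, fs = fs, dur = 20)
  f <- lowpass_butterworth(s, 5, 4)
  cc <- ccf(f$values[, 1], s$values[, 1], lag.max = 30, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("Butterworth rejects invalid cutoffs and too-short series", {
  s <- uniform_series(rnorm(500), fs = 100)
  expect_error(lowpass_butterworth(s, 50, 4), "cutoff")
  expect_error(lowpass_butterworth(s, 60, 4), "cutoff")
  expect_error(lowpass_butterworth(uniform_series(rnorm(10), 100), 5, 4),
               "too short")
})

test_that("spline gap filling recovers interior gaps and refuses boundary gaps", {
  tt <- seq(0, 1, by = 0.01)
  cubic <- 2 + 0.5 * tt - 3 * tt^2 + 1.2 * tt^3
  mask <- rep(TRUE, length(tt)); mask[40:44] <- FALSE
  ms <- masked_series(cubic, fs = 100, mask = mask)
  filled <- fill_gaps_spline(ms)
  # cubic splines reproduce cubics exactly between knots
  expect_lt(max(abs(filled$values[, 1] - cubic)), 1e-9)
  # valid samples untouched bit-for-bit
  expect_identical(filled$values[mask, 1], cubic[mask])

  # unmasked series pass through unchanged
  s_ok <- masked_series(cubic, fs = 100)
  expect_identical(fill_gaps_spline(s_ok)$values[, 1], cubic)

  mask2 <- rep(TRUE, length(tt)); mask2[1] <- FALSE
  expect_error(fill_gaps_spline(masked_series(cubic, 100, mask = mask2)),
               "boundary")
})

test_that("linear resampling reproduces affine signals and matches its error bound", {
  # identity on an already-aligned grid
  s <- uniform_series(sin(seq(0, 5, by = 0.01)), fs = 100)
  r <- resample_linear(s, target_fs = 100)
  expect_equal(r$values[, 1], s$values[, 1], tolerance = 1e-12)

  # irregular ramp: linear interpolation is exact on affine functions
  set.seed(3)
  tt <- cumsum(runif(200, 0.005, 0.03))
  r2 <- resample_linear(tt, tt, target_fs = 100)
  expect_lt(max(abs(r2$values[, 1] - series_time(r2))), 1e-12)

  # sinusoid: max error bounded by dt^2/8 * max|y''|
  t3 <- seq(0, 5, by = 1 / 77)
  y3 <- sin(2 * pi * t3)
  r3 <- resample_linear(t3, y3, target_fs = 100)
  truth <- sin(2 * pi * series_time(r3))
  bound <- (1 / 77)^2 / 8 * (2 * pi)^2
  expect_lt(max(abs(r3$values[, 1] - truth)), bound * 1.01)

  expect_error(resample_linear(c(0), c(1), 100), "single-sample")
  expect_error(resample_linear(c(0, 0, 1), c(1, 2, 3), 100), "increasing")
})

test_that("wavelet denoising is exact on constants and zeros and reduces noise", {
  s <- uniform_series(rep(2.4, 300), fs = 100)
  expect_lt(max(abs(wavelet_denoise(s)$values - 2.4)), 1e-12)

  z <- uniform_series(rep(0, 257), fs = 100)  # length not a power of two
  expect_identical(max(abs(wavelet_denoise(z)$values)), 0)

  set.seed(42)
  tt <- seq(0, 10, by = 0.01)
  clean <- sin(2 * pi * tt)
  noisy <- clean + rnorm(length(tt), 0, 0.3)
  den <- wavelet_denoise(uniform_series(noisy, 100))$values[, 1]
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))

  expect_error(wavelet_denoise(uniform_series(rnorm(8), 100)), "at least 16")
})

test_that("moving average has movmean semantics with earlier-offset even windows", {
  expect_equal(moving_average(rep(5, 40), 10), rep(5, 40))
  # interior of a ramp with a full symmetric window is unchanged
  x <- seq_len(50)
  m <- moving_average(x, 5)
  expect_equal(m[3:48], as.numeric(x[3:48]))

  # impulse response: plateau of 1/10 over the window span, by direct
  # convolution oracle (window i-5 ... i+4)
  imp <- rep(0, 60); imp[30] <- 1
  m10 <- moving_average(imp, 10)
  oracle <- vapply(seq_along(imp), function(i) {
    w <- max(1, i - 5):min(60, i + 4)
    mean(imp[w])
  }, numeric(1))
  expect_equal(m10, oracle)
  expect_identical(which(m10 > 0), 26:35)  # sample 30 seen by centers 26..35
  expect_equal(unique(m10[26:35]), 0.1)

  expect_error(moving_average(1:10, 0), "window")
})

test_that("finite differences are exact on affine and quadratic series", {
  fs <- 100
  tt <- seq(0, 1, by = 1 / fs)
  expect_equal(finite_difference(2 * tt, fs = fs), rep(2, length(tt)))
  d <- finite_difference(0.5 * tt^2, fs = fs)
  expect_equal(d[2:(length(tt) - 1)], tt[2:(length(tt) - 1)])

  # Taylor remainder bound for a sinusoid: |err| <= (2 pi)^3 dt^2 / 6
  y <- sin(2 * pi * tt)
  dy <- finite_difference(y, fs = fs)
  interior <- 2:(length(tt) - 1)
  err <- abs(dy[interior] - 2 * pi * cos(2 * pi * tt[interior]))
  expect_lt(max(err), (2 * pi)^3 * (1 / fs)^2 / 6)

  expect_error(finite_difference(c(1, 2), fs = fs), "3 samples")
})

test_that("differentiation then trapezoidal integration recovers affine series", {
  fs <- 50
  tt <- seq(0, 2, by = 1 / fs)
  y <- 1.7 - 0.4 * tt
  d <- finite_difference(y, fs = fs)
  cum <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 / fs))
  expect_lt(max(abs((cum + y[1]) - y)), 1e-9)
})

test_that("conditioning filters are linear operators", {
  set.seed(99)
  fs <- 100
  x <- rnorm(512); y <- rnorm(512)
  for (f in list(function(v) moving_average(v, 10),
                 function(v) finite_difference(v, fs = fs))) {
    expect_lt(max(abs(f(2 * x + 3 * y) - (2 * f(x) + 3 * f(y)))), 1e-9)
  }
})
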