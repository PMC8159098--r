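#' Zero-phase lowpass Butterworth filter
#'
#' Applies a lowpass Butterworth filter forward and backward so the net phase
#' response is zero: gait events must not be shifted in time by conditioning.
#' The effective magnitude response is the squared one-pass magnitude, so the
#' gain at the cutoff frequency is 1/2 rather than 1/sqrt(2). Edge transients
#' are controlled by removing the channel mean and padding both ends with an
#' odd (point-symmetric) reflection before filtering.
#'
#' @param s a [uniform_series()] with no invalid samples.
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist frequency
#'   `fs/2`. Default 5.
#' @param order filter order (one pass); default 4.
#' @return A [uniform_series()] of the same length and sampling rate.
#' @examples
#' s <- uniform_series(sin(2 * pi * 1 * seq(0, 5, by = 0.01)), fs = 100)
#' f <- lowpass_butterworth(s, cutoff = 5, order = 4)
#' @export
lowpass_butterworth <- function(s, cutoff = 5, order = 4) {
  stopifnot(inherits(s, "uniform_series"))
  if (!is.null(s$mask) && any(!s$mask))
    stop("series contains invalid samples; fill gaps before filtering")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= s$fs / 2)
    stop("'cutoff' must lie in (0, fs/2); got ", cutoff, " with fs = ", s$fs)
  if (order < 1) stop("'order' must be >= 1")
  n <- nrow(s$values)
  # pad long enough for the warm-up transient to decay inside the pad
  pad <- max(3L * (order + 1L), ceiling(3 * s$fs / cutoff))
  if (n <= pad %/% 3)
    stop("series too short (", n, " samples) for filter warm-up; need > ", pad %/% 3)
  pad <- min(pad, n - 1L)
  bf <- signal::butter(order, cutoff / (s$fs / 2), type = "low")
  out <- apply(s$values, 2L, function(x) {
    mu <- mean(x)
    xc <- x - mu
    left <- 2 * xc[1L] - xc[(pad + 1L):2L]
    right <- 2 * xc[n] - xc[(n - 1L):(n - pad)]
    yp <- signal::filtfilt(bf, c(left, xc, right))
    yp[(pad + 1L):(pad + n)] + mu
  })
  series_with_values(s, out)
}

#' Fill occlusion gaps by cubic spline interpolation
#'
#' Invalid samples (short marker occlusions) are replaced by cubic spline
#' interpolation through the valid samples of each channel; valid samples are
#' returned unchanged. Gaps touching either series boundary cannot be
#' interpolated and raise an error rather than extrapolate.
#'
#' @param s a [masked_series()] (a plain [uniform_series()] is returned
#'   as-is).
#' @return A [uniform_series()] with every sample valid.
#' @export
fill_gaps_spline <- function(s) {
  stopifnot(inherits(s, "uniform_series"))
  if (is.null(s$mask) || all(s$mask)) return(series_with_values(s, s$values))
  mask <- s$mask
  n <- length(mask)
  if (!mask[1L] || !mask[n]) {
    bad <- if (!mask[1L]) 1L else n
    stop("gap at series boundary (sample ", bad,
         "); refusing to extrapolate beyond the measured range")
  }
  if (sum(mask) < 4L)
    stop("need at least 4 valid samples per channel for spline gap filling")
  tt <- series_time(s)
  out <- s$values
  for (j in seq_len(ncol(out))) {
    f <- stats::splinefun(tt[mask], out[mask, j], method = "fmm")
    out[!mask, j] <- f(tt[!mask])
  }
  series_with_values(s, out)
}

#' Resample a time series to a uniform grid by linear interpolation
#'
#' Accepts non-uniform input timestamps (smartphone sensors log at an uneven
#' rate) and returns values on a uniform grid at `target_fs` spanning the
#' input time range.
#'
#' @param t numeric vector of strictly increasing timestamps in seconds, or a
#'   [uniform_series()] (then `values` is ignored).
#' @param values numeric vector or matrix of samples at `t`.
#' @param target_fs target sampling frequency in Hz; default 100.
#' @param labels optional channel labels for vector/matrix input.
#' @return A [uniform_series()] at `target_fs`.
#' @export
resample_linear <- function(t, values = NULL, target_fs = 100, labels = NULL) {
  if (inherits(t, "uniform_series")) {
    s <- t
    t <- series_time(s)
    values <- s$values
    if (is.null(labels)) labels <- s$labels
  }
  if (!is.numeric(target_fs) || target_fs <= 0) stop("'target_fs' must be positive")
  values <- as.matrix(values)
  if (length(t) != nrow(values)) stop("'t' and 'values' lengths differ")
  if (length(t) < 2L) stop("cannot resample a single-sample input")
  if (any(diff(t) <= 0)) stop("input timestamps must be strictly increasing")
  grid <- seq(t[1L], t[length(t)], by = 1 / target_fs)
  out <- apply(values, 2L, function(x) stats::approx(t, x, xout = grid)$y)
  uniform_series(out, fs = target_fs, t0 = t[1L], labels = labels)
}

# sym4 (least-asymmetric, 4 vanishing moments) orthogonal filter bank
.sym4_dec_lo <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
                  0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
                  -0.012603967262037833, 0.0322231006040427)
.sym4_dec_hi <- c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
                  0.29785779560527736, -0.80373875180591614, 0.49761866763201545,
                  0.02963552764599851, -0.07576571478927333)

# one analysis level of the periodized orthogonal DWT; x length must be even
.dwt_step <- function(x) {
  n <- length(x)
  k2 <- seq.int(0L, n - 2L, by = 2L)   # 0-based start of each window
  ca <- numeric(n %/% 2L)
  cd <- numeric(n %/% 2L)
  for (i in seq_along(.sym4_dec_lo)) {
    idx <- (k2 + i - 1L) %% n + 1L
    ca <- ca + .sym4_dec_lo[i] * x[idx]
    cd <- cd + .sym4_dec_hi[i] * x[idx]
  }
  list(ca = ca, cd = cd)
}

# inverse of .dwt_step (transpose of the orthogonal analysis operator)
.idwt_step <- function(ca, cd) {
  n <- 2L * length(ca)
  x <- numeric(n)
  k2 <- seq.int(0L, n - 2L, by = 2L)
  for (i in seq_along(.sym4_dec_lo)) {
    idx <- (k2 + i - 1L) %% n + 1L
    contrib <- .sym4_dec_lo[i] * ca + .sym4_dec_hi[i] * cd
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Wavelet denoising of a time series
#'
#' Orthogonal discrete wavelet transform (sym4, periodized) with soft
#' thresholding of the detail coefficients at the universal threshold
#' `sigma * sqrt(2 log n)`, where `sigma` is estimated from the median
#' absolute deviation of the finest-level detail coefficients (the standard
#' Donoho-Johnstone recipe). The transform is fully deterministic; signals
#' whose length is not a multiple of `2^levels` are symmetrically padded at
#' the end and truncated after reconstruction.
#'
#' @param s a [uniform_series()].
#' @param levels decomposition depth; default 4, capped so that at least 8
#'   approximation coefficients remain.
#' @return A denoised [uniform_series()] of the same length.
#' @export
wavelet_denoise <- function(s, levels = 4) {
  stopifnot(inherits(s, "uniform_series"))
  n0 <- nrow(s$values)
  if (n0 < 16L)
    stop("series too short for wavelet decomposition: need at least 16 samples, got ", n0)
  levels <- min(levels, floor(log2(n0 / 8)))
  levels <- max(levels, 1L)
  out <- apply(s$values, 2L, function(x) .denoise1(x, levels))
  series_with_values(s, out)
}

.denoise1 <- function(x, levels) {
  n0 <- length(x)
  mu <- mean(x)
  x <- x - mu        # work about the mean: constants pass through exactly
  block <- 2L^levels
  npad <- (block - n0 %% block) %% block
  if (npad > 0) {
    # symmetric (half-sample) extension at the tail
    ext <- x[n0:max(1L, n0 - npad + 1L)]
    x <- c(x, rep(ext, length.out = npad))
  }
  details <- vector("list", levels)
  ca <- x
  for (j in seq_len(levels)) {
    st <- .dwt_step(ca)
    ca <- st$ca
    details[[j]] <- st$cd
  }
  sigma <- stats::median(abs(details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  if (thr > 0) {
    details <- lapply(details, function(d) sign(d) * pmax(abs(d) - thr, 0))
  }
  for (j in rev(seq_len(levels))) {
    ca <- .idwt_step(ca, details[[j]])
  }
  ca[seq_len(n0)] + mu
}

#' Centered moving-average filter
#'
#' Mean over a centered window that shrinks symmetrically at the series
#' edges, preserving length (the usual `movmean` semantics). For an even
#' window the center is offset toward the earlier sample: window 10 spans
#' samples `i-5 ... i+4`.
#'
#' @param s a [uniform_series()] or numeric vector.
#' @param window window length in samples; default 10.
#' @return Same type as the input.
#' @export
moving_average <- function(s, window = 10) {
  if (window < 1) stop("'window' must be a positive integer")
  window <- as.integer(window)
  if (inherits(s, "uniform_series"))
    return(series_with_values(s, apply(s$values, 2L, .movmean1, window = window)))
  .movmean1(as.numeric(s), window)
}

.movmean1 <- function(x, window) {
  n <- length(x)
  lo <- window %/% 2L              # samples before the center
  hi <- window - lo - 1L           # samples after the center
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

#' Numerical derivative by finite differences
#'
#' Central differences at interior samples, first-order one-sided differences
#' at the two endpoints (the same scheme as MATLAB's `gradient`). Exact for
#' affine series everywhere and for quadratics at interior samples.
#'
#' @param s a [uniform_series()] or numeric vector.
#' @param fs sampling frequency in Hz (taken from the series when `s` is a
#'   [uniform_series()]).
#' @return Same type as the input: the derivative series.
#' @export
finite_difference <- function(s, fs = NULL) {
  if (inherits(s, "uniform_series")) {
    if (nrow(s$values) < 3L) stop("need at least 3 samples to differentiate")
    return(series_with_values(s, apply(s$values, 2L, .fdiff1, fs = s$fs)))
  }
  if (is.null(fs)) stop("'fs' is required for plain numeric input")
  if (length(s) < 3L) stop("need at least 3 samples to differentiate")
  .fdiff1(as.numeric(s), fs)
}

.fdiff1 <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d
}
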