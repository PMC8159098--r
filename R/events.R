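#' Locate local maxima with prominence and minimum-separation filtering
#'
#' Internal workhorse of both heel-strike and acceleration-peak stride
#' detection. Plateau maxima are reported at the first sample of the
#' plateau. Candidates are filtered by topographic prominence and then
#' greedily thinned (highest peak first) to respect the minimum separation.
#'
#' @param x numeric vector.
#' @param min_separation minimum distance between kept peaks, in samples.
#' @param min_prominence minimum topographic prominence.
#' @return Integer vector of strictly increasing peak indices (1-based).
#' @export
find_peaks <- function(x, min_separation = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau scan
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) .prominence(x, p), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (o in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[o]) < min_separation)) keep[o] <- TRUE
  }
  sort(cand[keep])
}

# topographic prominence of peak at index p: height above the higher of the
# two key saddles (minimum until the nearest higher ground on each side)
.prominence <- function(x, p) {
  n <- length(x)
  left <- x[p]
  if (p > 1L) for (i in (p - 1L):1L) {
    if (x[i] > x[p]) break
    if (x[i] < left) left <- x[i]
  }
  right <- x[p]
  if (p < n) for (i in (p + 1L):n) {
    if (x[i] > x[p]) break
    if (x[i] < right) right <- x[i]
  }
  x[p] - max(left, right)
}

# dominant frequency in [f_lo, f_hi] Hz of a detrended series, via FFT
.dominant_frequency <- function(x, fs, f_lo, f_hi) {
  x <- x - mean(x)
  n <- length(x)
  sp <- abs(stats::fft(x)[seq_len(n %/% 2L)])^2
  freq <- (seq_len(n %/% 2L) - 1L) * fs / n
  band <- freq >= f_lo & freq <= f_hi
  if (!any(band) || all(sp[band] == 0)) return(NA_real_)
  freq[band][which.max(sp[band])]
}

# fundamental period (seconds) of a quasi-periodic signal by sample
# autocorrelation: the shortest lag in [1/f_hi, 1/f_lo] whose autocorrelation
# is a local maximum within 20% of the best in the range. Robust against the
# low-frequency amplitude modulation that dominates the spectrum of an
# acceleration-magnitude signal, and against picking a multiple of the period.
.dominant_period_ac <- function(x, fs, f_lo, f_hi) {
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  lag_max <- min(length(x) - 2L, ceiling(fs / f_lo))
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[, 1L, 1L]
  # light smoothing: a period that falls between two sample lags splits its
  # autocorrelation mass over both, which would otherwise lose against its
  # own (exactly representable) multiples; boundary lags (no full smoothing
  # window) are excluded from the search rather than patched
  ac <- as.numeric(stats::filter(ac, rep(1 / 3, 3), sides = 2))
  lags <- max(2L, floor(fs / f_hi)):(lag_max - 1L)
  if (!length(lags) || lags[1L] > lags[length(lags)]) return(NA_real_)
  vals <- ac[lags + 1L]
  if (all(!is.finite(vals))) return(NA_real_)
  best <- max(vals, na.rm = TRUE)
  if (best <= 0) return(NA_real_)
  ok <- which(vals >= 0.75 * best)
  # earliest qualifying lag that is a local maximum of the autocorrelation
  for (i in ok) {
    l <- lags[i]
    if (l > 1L && l < lag_max && ac[l + 1L] >= ac[l] && ac[l + 1L] >= ac[l + 2L])
      return(l / fs)
  }
  lags[ok[1L]] / fs
}

#' Detect heel strikes from heel walking-direction displacement
#'
#' On a treadmill the heel marker's walking-direction displacement peaks at
#' each foot contact of that limb; heel strikes are the local maxima of the
#' (filtered) displacement. The expected stride period is estimated from the
#' dominant low-frequency spectral peak; candidate maxima are filtered with a
#' prominence threshold of `prominence_frac` times the inter-decile range and
#' a minimum separation of `separation_frac` times the expected period.
#'
#' @param heel_y a single-channel [uniform_series()] (heel displacement in
#'   the walking direction, meters) or a numeric vector with `fs` given.
#' @param fs sampling frequency in Hz (taken from the series if omitted).
#' @param cadence_range plausible stride-frequency band in Hz used to find
#'   the dominant period; default `c(0.3, 1.5)`.
#' @param separation_frac,prominence_frac detection parameters, see above.
#' @return Integer vector of heel-strike sample indices (possibly empty,
#'   with a warning when nothing is found).
#' @export
detect_heel_strikes <- function(heel_y, fs = NULL, cadence_range = c(0.3, 1.5),
                                separation_frac = 0.4, prominence_frac = 0.3) {
  if (inherits(heel_y, "uniform_series")) {
    fs <- heel_y$fs
    heel_y <- heel_y$values[, 1L]
  }
  if (is.null(fs)) stop("'fs' is required for plain numeric input")
  f0 <- .dominant_frequency(heel_y, fs, cadence_range[1L], cadence_range[2L])
  min_sep <- if (is.na(f0)) 1 else separation_frac * fs / f0
  idr <- diff(stats::quantile(heel_y, c(0.1, 0.9), names = FALSE))
  ev <- find_peaks(heel_y, min_separation = min_sep,
                   min_prominence = prominence_frac * idr)
  if (!length(ev)) warning("no heel-strike events found")
  ev
}

#' Reference stride lengths from heel displacement
#'
#' For each pair of consecutive heel strikes the stride length is the heel
#' displacement at the terminating strike minus the local minimum between
#' the two strikes (the heel swings backward and then forward by one stride
#' on a treadmill).
#'
#' @param heel_y heel walking-direction displacement ([uniform_series()] or
#'   numeric vector).
#' @param events strictly increasing heel-strike indices (>= 2).
#' @param anchor which strike anchors the difference; `"terminating"`
#'   (default) or `"initiating"`.
#' @return Numeric vector of stride lengths in meters, one per event pair.
#' @export
reference_stride_lengths <- function(heel_y, events,
                                     anchor = c("terminating", "initiating")) {
  anchor <- match.arg(anchor)
  if (inherits(heel_y, "uniform_series")) heel_y <- heel_y$values[, 1L]
  if (length(events) < 2L) stop("need at least 2 heel-strike events")
  if (any(diff(events) <= 0)) stop("'events' must be strictly increasing")
  vapply(seq_len(length(events) - 1L), function(i) {
    a <- events[i]; b <- events[i + 1L]
    peak <- if (anchor == "terminating") heel_y[b] else heel_y[a]
    peak - min(heel_y[a:b])
  }, numeric(1))
}

#' Stride segmentation from acceleration magnitude peaks
#'
#' The acceleration magnitude peaks at every step (heel-strike impacts),
#' i.e. twice per stride. The step period is estimated from the sample
#' autocorrelation of the magnitude signal (robust to the low-frequency
#' amplitude modulation of gait), step peaks are detected with a minimum
#' separation of `separation_frac` stride periods, and alternating peaks
#' are kept starting from the larger of the first two, so that the kept
#' peaks bound same-limb strides.
#'
#' @param accel_mag denoised acceleration magnitude ([uniform_series()] or
#'   numeric vector).
#' @param fs sampling frequency in Hz.
#' @param cadence_range plausible step-frequency band in Hz; default
#'   `c(0.6, 3)`.
#' @param separation_frac,prominence_frac see [detect_heel_strikes()].
#' @return Data frame with columns `start`, `end` (1-based half-open sample
#'   windows) and `duration_s`; zero rows when fewer than two same-limb
#'   peaks are found.
#' @export
detect_strides_accel <- function(accel_mag, fs = NULL, cadence_range = c(0.6, 3),
                                 separation_frac = 0.4, prominence_frac = 0.3) {
  if (inherits(accel_mag, "uniform_series")) {
    fs <- accel_mag$fs
    accel_mag <- accel_mag$values[, 1L]
  }
  if (is.null(fs)) stop("'fs' is required for plain numeric input")
  step_period <- .dominant_period_ac(accel_mag, fs, cadence_range[1L],
                                     cadence_range[2L])
  # the magnitude peaks once per step; the minimum separation is a fraction
  # of the stride period (two steps), which also rejects mid-stance ripples
  min_sep <- if (is.na(step_period)) 1 else separation_frac * 2 * step_period * fs
  idr <- diff(stats::quantile(accel_mag, c(0.1, 0.9), names = FALSE))
  pk <- find_peaks(accel_mag, min_separation = min_sep,
                   min_prominence = prominence_frac * idr)
  if (length(pk) < 3L) {
    if (!length(pk)) warning("no acceleration peaks found")
    return(data.frame(start = integer(0), end = integer(0),
                      duration_s = numeric(0)))
  }
  first <- if (accel_mag[pk[1L]] >= accel_mag[pk[2L]]) 1L else 2L
  same_limb <- pk[seq.int(first, length(pk), by = 2L)]
  if (length(same_limb) < 2L)
    return(data.frame(start = integer(0), end = integer(0),
                      duration_s = numeric(0)))
  data.frame(start = same_limb[-length(same_limb)],
             end = same_limb[-1L],
             duration_s = diff(same_limb) / fs)
}

#' Time offset between two recordings via their dominant spike
#'
#' Both recordings are assumed to contain one dominant spike event (the
#' synchronization jump). The lag of the dominant peaks fixes a coarse
#' offset which is then refined by the cross-correlation argmax in a window
#' around that lag. A positive offset means `b` lags `a` (shift `b` earlier
#' by the offset to align).
#'
#' @param a,b single-channel [uniform_series()] at the same sampling rate,
#'   or numeric vectors with `fs` given.
#' @param fs sampling frequency in Hz.
#' @param window half-width in seconds of the refinement window around the
#'   peak lag; default 0.5.
#' @param dominance required ratio of the largest |value| to the series
#'   inter-decile range for a spike to count as dominant; default 3.
#' @return Time offset in seconds.
#' @export
synchronize <- function(a, b, fs = NULL, window = 0.5, dominance = 3) {
  if (inherits(a, "uniform_series")) { fs <- a$fs; a <- a$values[, 1L] }
  if (inherits(b, "uniform_series")) b <- b$values[, 1L]
  if (is.null(fs)) stop("'fs' is required for plain numeric input")
  for (ser in list(a = a, b = b)) {
    idr <- diff(stats::quantile(ser, c(0.1, 0.9), names = FALSE))
    if (max(abs(ser - stats::median(ser))) < dominance * max(idr, .Machine$double.eps))
      stop("no dominant peak found in one of the series; cannot synchronize")
  }
  lag0 <- which.max(abs(b - stats::median(b))) - which.max(abs(a - stats::median(a)))
  w <- round(window * fs)
  lags <- (lag0 - w):(lag0 + w)
  cc <- vapply(lags, function(l) {
    ia <- seq_along(a)
    ib <- ia + l
    ok <- ib >= 1L & ib <= length(b)
    if (sum(ok) < 2L) return(-Inf)
    sum(a[ia[ok]] * b[ib[ok]])
  }, numeric(1))
  lags[which.max(cc)] / fs
}

#' Rigid rotation aligning a marker template to observed positions
#'
#' Least-squares (Kabsch) estimate of the proper rotation taking the three
#' template marker positions (phone frame) onto the observed positions (lab
#' frame), after removing the centroids. Used to express phone-frame
#' accelerations in the laboratory frame for the axis-dependent models.
#'
#' @param observed 3 x 3 matrix, one observed marker position per row (lab
#'   frame, meters).
#' @param template 3 x 3 matrix, the same markers in the phone frame.
#' @return An object of class `"rotation_alignment"`: list with `R` (3 x 3
#'   proper rotation, `R %*% template` direction = observed direction),
#'   `observed`, `template`.
#' @export
phone_alignment_rotation <- function(observed, template) {
  observed <- as.matrix(observed); template <- as.matrix(template)
  if (!all(dim(observed) == c(3L, 3L)) || !all(dim(template) == c(3L, 3L)))
    stop("'observed' and 'template' must be 3 x 3 matrices (3 markers x xyz)")
  oc <- sweep(observed, 2L, colMeans(observed))
  tc <- sweep(template, 2L, colMeans(template))
  if (min(svd(oc)$d[1:2]) < 1e-10 * max(svd(oc)$d[1], 1) ||
      min(svd(tc)$d[1:2]) < 1e-10 * max(svd(tc)$d[1], 1))
    stop("markers are collinear; rotation is degenerate")
  h <- crossprod(tc, oc)           # template^T observed
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  structure(list(R = r, observed = observed, template = template),
            class = "rotation_alignment")
}

#' @export
print.rotation_alignment <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rotation_alignment> rotation angle %.2f deg\n", ang))
  invisible(x)
}

#' Rotate a 3-channel series into another frame
#'
#' Per-sample matrix-vector product; preserves the per-sample Euclidean norm
#' (hence all acceleration-magnitude quantities).
#'
#' @param accel a 3-channel [uniform_series()].
#' @param rotation a `"rotation_alignment"` or a 3 x 3 rotation matrix.
#' @return The rotated [uniform_series()].
#' @export
apply_rotation <- function(accel, rotation) {
  stopifnot(inherits(accel, "uniform_series"))
  if (ncol(accel$values) != 3L) stop("'accel' must have 3 channels")
  r <- if (inherits(rotation, "rotation_alignment")) rotation$R else as.matrix(rotation)
  if (!all(dim(r) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(r) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal")
  series_with_values(accel, accel$values %*% t(r))
}

#' Export stride events as CSV
#'
#' Columns: `stride_id`, `start_idx`, `end_idx`, `duration_s`,
#' `ref_length_m` (NA when no reference is available).
#'
#' @param segments data frame with `start`, `end` (and optionally
#'   `duration_s`), e.g. from [detect_strides_accel()].
#' @param fs sampling frequency in Hz (used when `duration_s` is absent).
#' @param lengths optional reference stride lengths.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(segments, path, fs = NULL, lengths = NULL) {
  segments <- as.data.frame(segments)
  dur <- if ("duration_s" %in% names(segments)) segments$duration_s
         else (segments$end - segments$start) / fs
  df <- data.frame(stride_id = seq_len(nrow(segments)),
                   start_idx = segments$start, end_idx = segments$end,
                   duration_s = dur,
                   ref_length_m = if (is.null(lengths)) NA_real_ else lengths)
  utils::write.csv(format(df, digits = 6, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
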