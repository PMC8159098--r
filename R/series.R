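#' Uniformly sampled time series
#'
#' Lightweight container for a uniformly sampled scalar or multi-channel time
#' series, the common currency of the signal-conditioning and kinematics
#' functions. Values are stored as a numeric matrix with one column per
#' channel; a scalar series is a one-column matrix.
#'
#' @param values numeric vector or matrix (samples in rows, channels in
#'   columns).
#' @param fs sampling frequency in Hz; must be positive.
#' @param t0 time of the first sample in seconds (default 0).
#' @param labels optional character vector of channel labels.
#'
#' @return An object of class `"uniform_series"`: a list with elements
#'   `values` (matrix), `fs`, `t0` and `labels`.
#' @seealso [masked_series()], [series_time()]
#' @export
uniform_series <- function(values, fs, t0 = 0, labels = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop("a uniform series needs at least 2 samples")
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(labels) != ncol(values))
    stop("'labels' length must match the number of channels")
  colnames(values) <- labels
  structure(list(values = values, fs = fs, t0 = t0, labels = labels),
            class = "uniform_series")
}

#' Uniform series with a per-sample validity mask
#'
#' Marker occlusions in optical motion capture leave short runs of invalid
#' samples; a masked series carries those gaps explicitly so that
#' [fill_gaps_spline()] can interpolate them.
#'
#' @inheritParams uniform_series
#' @param mask logical vector, one entry per sample; `TRUE` marks a valid
#'   sample. Non-finite values are always treated as invalid.
#'
#' @return An object of class `c("masked_series", "uniform_series")` with the
#'   additional element `mask`.
#' @export
masked_series <- function(values, fs, mask = NULL, t0 = 0, labels = NULL) {
  s <- uniform_series(values, fs, t0 = t0, labels = labels)
  n <- nrow(s$values)
  if (is.null(mask)) mask <- rep(TRUE, n)
  mask <- as.logical(mask)
  if (length(mask) != n)
    stop("'mask' length (", length(mask), ") must equal the number of samples (", n, ")")
  mask[!stats::complete.cases(s$values) | !is.finite(rowSums(s$values))] <- FALSE
  if (sum(mask) < 2L)
    stop("a masked series needs at least 2 valid samples")
  s$mask <- mask
  class(s) <- c("masked_series", "uniform_series")
  s
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<%s> %d samples x %d channel(s) @ %g Hz, t0 = %g s\n",
              class(x)[1L], nrow(x$values), ncol(x$values), x$fs, x$t0))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  if (!is.null(x$mask))
    cat(sprintf("  invalid samples: %d\n", sum(!x$mask)))
  invisible(x)
}

#' Sample times of a uniform series
#'
#' @param s a [uniform_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_time <- function(s) {
  stopifnot(inherits(s, "uniform_series"))
  s$t0 + (seq_len(nrow(s$values)) - 1) / s$fs
}

#' @export
length.uniform_series <- function(x) nrow(x$values)

#' Euclidean magnitude of a 3-channel series
#'
#' Per-sample norm of a 3-axis signal, e.g. the acceleration magnitude
#' `|a|` that the orientation-invariant stride-length model is built on.
#'
#' @param s a 3-channel [uniform_series()].
#' @return A single-channel [uniform_series()] labelled `"mag"`.
#' @export
series_magnitude <- function(s) {
  stopifnot(inherits(s, "uniform_series"))
  if (ncol(s$values) != 3L) stop("magnitude needs a 3-channel series")
  out <- series_with_values(s, matrix(sqrt(rowSums(s$values^2)), ncol = 1L))
  out$labels <- colnames(out$values) <- "mag"
  out
}

# internal: replace values, keep metadata
series_with_values <- function(s, values) {
  values <- as.matrix(values)
  if (ncol(values) == length(s$labels)) {
    colnames(values) <- s$labels
  } else {
    s$labels <- colnames(values)
  }
  s$values <- values
  s$mask <- NULL
  class(s) <- "uniform_series"
  s
}
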