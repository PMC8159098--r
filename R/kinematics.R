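#' Derive velocity and acceleration from a marker trajectory
#'
#' Velocity is the finite-difference derivative of position smoothed with a
#' centered moving average; acceleration is the derivative of that smoothed
#' velocity, smoothed again. Per-sample speed `|v|` and acceleration
#' magnitude `|a|` (the rotation-invariant quantity the acceleration-range
#' model is built on) are computed alongside.
#'
#' @param traj a 3-channel [uniform_series()] of positions in meters
#'   (gap-filled, filtered, uniform).
#' @param smooth_window moving-average window in samples applied to each
#'   derivative; default 10.
#' @return An object of class `"kinematic_series"`: a list with matrices
#'   `r`, `v`, `a` (n x 3, m, m/s, m/s^2), vectors `v_mag`, `a_mag`, and
#'   `fs`, `t0`.
#' @export
derive_kinematics <- function(traj, smooth_window = 10) {
  stopifnot(inherits(traj, "uniform_series"))
  if (ncol(traj$values) != 3L) stop("'traj' must have exactly 3 channels (x, y, z)")
  if (nrow(traj$values) < 3L) stop("need at least 3 samples")
  r <- traj$values
  v <- apply(r, 2L, .fdiff1, fs = traj$fs)
  v <- apply(v, 2L, .movmean1, window = smooth_window)
  a <- apply(v, 2L, .fdiff1, fs = traj$fs)
  a <- apply(a, 2L, .movmean1, window = smooth_window)
  colnames(r) <- colnames(v) <- colnames(a) <- c("x", "y", "z")
  structure(list(r = r, v = v, a = a,
                 v_mag = sqrt(rowSums(v^2)), a_mag = sqrt(rowSums(a^2)),
                 fs = traj$fs, t0 = traj$t0),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d samples @ %g Hz (r, v, a + magnitudes)\n",
              nrow(x$r), x$fs))
  invisible(x)
}

# canonical 28-column order of the per-stride parameter set
.feature_names <- local({
  axes <- c("x", "y", "z", "mag")
  stats_v <- as.vector(outer(c("mean", "median", "range"), axes,
                             function(s, a) paste0("vel_", s, "_", a)))
  stats_a <- as.vector(outer(c("mean", "median", "range"), axes,
                             function(s, a) paste0("acc_", s, "_", a)))
  c("duration", "path_x", "path_y", "path_z", stats_v, stats_a)
})

#' Names of the 28 per-stride parameters
#'
#' Stride duration; traveled path per axis; mean, median and range of the
#' velocity and acceleration components and magnitudes.
#'
#' @return Character vector of length 28 in the canonical column order.
#' @export
stride_feature_names <- function() .feature_names

#' Per-stride parameter row
#'
#' Computes the 28 stride parameters over the half-open sample window
#' `[start, end)` (1-based): stride duration, traveled path in x/y/z, and
#' mean/median/range of velocity and acceleration in x/y/z and of their
#' magnitudes. "Traveled path" is the total variation (sum of absolute
#' sample-to-sample increments) by default; net displacement is available
#' via `path = "net"` (degenerate for treadmill walking, where net
#' walking-direction displacement is near zero).
#'
#' @param k a [derive_kinematics()] result.
#' @param start,end 1-based half-open sample window `[start, end)`.
#' @param path `"total_variation"` (default) or `"net"`.
#' @return Named numeric vector of length 28.
#' @export
stride_features <- function(k, start, end, path = c("total_variation", "net")) {
  stopifnot(inherits(k, "kinematic_series"))
  path <- match.arg(path)
  n <- nrow(k$r)
  if (!(start >= 1 && end > start && end <= n + 1))
    stop("stride window [", start, ", ", end, ") out of bounds for ", n, " samples")
  idx <- start:(end - 1L)
  if (length(idx) < 2L) stop("stride window must contain at least 2 samples")
  rw <- k$r[idx, , drop = FALSE]
  pathv <- if (path == "total_variation") {
    colSums(abs(diff(rw)))
  } else {
    abs(rw[nrow(rw), ] - rw[1L, ])
  }
  stat3 <- function(x) c(mean(x), stats::median(x), max(x) - min(x))
  cols <- cbind(k$v[idx, , drop = FALSE], k$v_mag[idx],
                k$a[idx, , drop = FALSE], k$a_mag[idx])
  # order: for v then a, stats grouped per axis x, y, z, mag
  vstats <- as.vector(vapply(c(1:3, 4L), function(j) stat3(cols[, j]), numeric(3)))
  astats <- as.vector(vapply(c(5:7, 8L), function(j) stat3(cols[, j]), numeric(3)))
  out <- c((end - start) / k$fs, pathv, vstats, astats)
  names(out) <- .feature_names
  out
}

#' Build the stride parameter matrix
#'
#' Assembles the n x 28 matrix `X` of per-stride parameters together with its
#' column-centered copy and the mean-centered response (reference stride
#' lengths), the inputs of the principal-component derivation.
#'
#' @param k a [derive_kinematics()] result.
#' @param segments data frame with columns `start`, `end` (1-based half-open
#'   windows), e.g. from [detect_strides_accel()] or built from
#'   [detect_heel_strikes()] events.
#' @param lengths reference stride lengths in meters, one per segment.
#' @param path passed to [stride_features()].
#' @return An object of class `"feature_matrix"`: list with `X` (n x 28),
#'   `X_centered`, `col_means`, `y` (raw lengths), `y_centered`, `n`, `p`.
#' @export
build_feature_matrix <- function(k, segments, lengths,
                                 path = c("total_variation", "net")) {
  path <- match.arg(path)
  segments <- as.data.frame(segments)
  if (nrow(segments) != length(lengths))
    stop("number of segments (", nrow(segments), ") and lengths (",
         length(lengths), ") differ")
  if (nrow(segments) < 2L) stop("need at least 2 strides")
  X <- t(vapply(seq_len(nrow(segments)), function(i) {
    stride_features(k, segments$start[i], segments$end[i], path = path)
  }, numeric(length(.feature_names))))
  rownames(X) <- seq_len(nrow(X))
  feature_matrix(X, lengths)
}

#' Construct a feature matrix object from a ready-made parameter matrix
#'
#' @param X numeric matrix, n strides x p parameters, with column names.
#' @param y reference stride lengths in meters (length n).
#' @return A `"feature_matrix"` object; see [build_feature_matrix()].
#' @export
feature_matrix <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("p", seq_len(ncol(X)))
  mu <- colMeans(X)
  structure(list(X = X, X_centered = sweep(X, 2L, mu), col_means = mu,
                 y = y, y_centered = y - mean(y),
                 n = nrow(X), p = ncol(X)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d strides x %d parameters, mean stride length %.3f m\n",
              x$n, x$p, mean(x$y)))
  invisible(x)
}

#' Export / import a feature matrix as CSV
#'
#' The CSV holds `stride_id`, the parameter columns in canonical order, and
#' `length_m`.
#'
#' @param fm a `"feature_matrix"` object.
#' @param path file path.
#' @return `write_features_csv` returns `path` invisibly;
#'   `read_features_csv` returns a `"feature_matrix"`.
#' @export
write_features_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(stride_id = seq_len(fm$n), fm$X, length_m = fm$y,
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 6, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("stride_id", "length_m")
  if (!all(need %in% names(df)))
    stop("feature CSV must contain columns: ", paste(need, collapse = ", "))
  X <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  feature_matrix(X, df$length_m)
}
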