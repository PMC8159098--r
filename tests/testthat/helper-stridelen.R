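# shared fixtures and independent oracles

sine_series <- function(freq, fs = 100, dur = 10, amp = 1, phase = 0) {
  tt <- seq(0, dur, by = 1 / fs)
  uniform_series(amp * sin(2 * pi * freq * tt + phase), fs = fs)
}

# uniformly random proper rotation (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# geodesic distance between rotations, degrees
rotation_angle_deg <- function(r1, r2) {
  rel <- crossprod(r1, r2)
  acos(min(1, max(-1, (sum(diag(rel)) - 1) / 2))) * 180 / pi
}

# O(n^2) definition-based peak oracle, independent of find_peaks():
# enumerate strict local maxima (plateaus at their first sample), compute
# prominence by full scans, then select iteratively by descending height
# removing everything within min_sep
naive_peaks <- function(x, min_sep, min_prom) {
  n <- length(x)
  cand <- c()
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (j < n && x[j + 1] < x[i]) cand <- c(cand, i)
  }
  keep_prom <- c()
  for (p in cand) {
    lmin <- x[p]
    for (i in rev(seq_len(p - 1))) {
      if (x[i] > x[p]) break
      lmin <- min(lmin, x[i])
    }
    rmin <- x[p]
    for (i in seq(p + 1, n, by = 1)) {
      if (i > n) break
      if (x[i] > x[p]) break
      rmin <- min(rmin, x[i])
    }
    if (x[p] - max(lmin, rmin) >= min_prom) keep_prom <- c(keep_prom, p)
  }
  out <- c()
  remaining <- keep_prom
  while (length(remaining)) {
    best <- remaining[which.max(x[remaining])]
    out <- c(out, best)
    remaining <- remaining[abs(remaining - best) >= min_sep]
  }
  sort(out)
}

# naive loop oracle for the 28 stride parameters
naive_stride_features <- function(k, start, end) {
  idx <- start:(end - 1)
  med <- function(v) stats::median(v)
  rng <- function(v) max(v) - min(v)
  out <- c((end - start) / k$fs)
  for (j in 1:3) out <- c(out, sum(abs(diff(k$r[idx, j]))))
  for (mat in list(cbind(k$v, k$v_mag), cbind(k$a, k$a_mag))) {
    for (j in 1:4) {
      v <- mat[idx, j]
      out <- c(out, mean(v), med(v), rng(v))
    }
  }
  stats::setNames(out, stride_feature_names())
}

# small noiseless walk shared by several tests
quick_walk <- function(seed = 11, duration = 60, speed = 4.6, noise = 0,
                       positions = "pelvis", ...) {
  simulate_walk(gait_config(speed_kmh = speed, duration_s = duration,
                            accel_noise_sd = noise, marker_noise_sd = 0,
                            positions = positions, seed = seed, ...))
}
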