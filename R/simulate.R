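#' Configuration for the treadmill gait simulator
#'
#' Defaults emulate the derivation protocol: treadmill walking at one of
#' 3.3, 4.6 or 5.9 km/h, a 15-minute track sampled at 100 Hz, and a subject
#' of mean height 1.77 m and leg length 1.05 m. The mean stride length
#' follows walking speed as `0.8 + 0.12 * speed_kmh` (m); stride-to-stride
#' variability uses SDs of 0.02 m (length) and 1% of the period, Gaussian
#' draws truncated at +/- 3 SD, matching the 1-2% stride variability of
#' healthy treadmill walking. Acceleration channels carry additive Gaussian
#' noise of 0.3 m/s^2 per axis by default; marker channels are noiseless by
#' default (optical reference accuracy is on the 0.1 mm scale).
#'
#' @param speed_kmh walking speed in km/h; default 4.6.
#' @param duration_s track duration in seconds; default 900 (15 min).
#' @param fs sampling frequency in Hz; default 100.
#' @param height_m,leg_length_m subject parameters; defaults 1.77 / 1.05.
#' @param stride_mean_m mean stride length (m); default from speed.
#' @param stride_sd_m stride-length SD (m); default 0.02.
#' @param period_sd_s stride-period SD (s); default 1% of the mean period.
#' @param accel_noise_sd acceleration noise SD per axis (m/s^2); default 0.3.
#' @param marker_noise_sd marker position noise SD (m); default 0.
#' @param positions sensor positions to simulate; subset of
#'   `c("pelvis", "upper_arm", "hand", "thigh")`.
#' @param orientation a single 3 x 3 rotation applied to every phone frame,
#'   or a named list of rotations per position; default identity.
#' @param pad_s still-standing padding at both ends in seconds; default 2.
#' @param seed mandatory integer seed for all stochastic output.
#' @return An object of class `"gait_config"`.
#' @export
gait_config <- function(speed_kmh = 4.6, duration_s = 900, fs = 100,
                        height_m = 1.77, leg_length_m = 1.05,
                        stride_mean_m = NULL, stride_sd_m = 0.02,
                        period_sd_s = NULL, accel_noise_sd = 0.3,
                        marker_noise_sd = 0,
                        positions = c("pelvis", "upper_arm", "hand", "thigh"),
                        orientation = NULL, pad_s = 2, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (any(c(speed_kmh, duration_s, fs, height_m, leg_length_m) <= 0))
    stop("speed, duration, fs, height and leg length must be positive")
  if (is.null(stride_mean_m)) stride_mean_m <- 0.8 + 0.12 * speed_kmh
  if (stride_mean_m > 2 * leg_length_m)
    stop("stride length ", stride_mean_m, " m exceeds 2 * leg length; no",
         " pendulum geometry exists")
  v <- speed_kmh / 3.6
  period_mean <- stride_mean_m / v
  if (is.null(period_sd_s)) period_sd_s <- 0.01 * period_mean
  positions <- match.arg(positions, several.ok = TRUE)
  structure(list(speed_kmh = speed_kmh, duration_s = duration_s, fs = fs,
                 height_m = height_m, leg_length_m = leg_length_m,
                 stride_mean_m = stride_mean_m, stride_sd_m = stride_sd_m,
                 period_mean_s = period_mean, period_sd_s = period_sd_s,
                 accel_noise_sd = accel_noise_sd,
                 marker_noise_sd = marker_noise_sd,
                 positions = positions, orientation = orientation,
                 pad_s = pad_s, seed = as.integer(seed)),
            class = "gait_config")
}

# truncated-normal draw: values clipped at mean +/- 3 sd (deterministic
# given the RNG stream, unlike rejection sampling)
.rtnorm3 <- function(n, mean, sd) {
  pmin(pmax(stats::rnorm(n, mean, sd), mean - 3 * sd), mean + 3 * sd)
}

# per-position scaling and phasing of the acceleration channels:
# amplitude factor relative to the pelvis vertical amplitude, phase shift of
# the step-frequency fundamental, and relative weight of the stride-frequency
# harmonic
.position_params <- list(
  pelvis    = list(scale = 1.0, phase = 0.0, harmonic = 0.25),
  upper_arm = list(scale = 0.8, phase = 0.9, harmonic = 0.45),
  hand      = list(scale = 1.1, phase = 1.7, harmonic = 0.55),
  thigh     = list(scale = 1.3, phase = 0.5, harmonic = 0.40)
)

#' Simulate a treadmill walk with per-stride ground truth
#'
#' Generates internally consistent marker trajectories and phone-style
#' linear accelerations for one treadmill track. The kinematic skeleton
#' follows the inverted-pendulum picture: each stride of drawn length `d`
#' swings the pelvis through a vertical excursion
#' `V = L (1 - cos(theta))` with `d = 2 L sin(theta)`, oscillating twice
#' per stride (once per step). The heel walking-direction trace is
#' quasi-periodic with a per-stride excursion equal to the drawn stride
#' length, so heel-strike detection plus the local-minimum rule recovers
#' the ground truth exactly on noiseless data. Acceleration channels are
#' the analytic second derivatives of the closed-form displacement model
#' (pelvis) or phase-shifted, amplitude-scaled copies of the gait
#' fundamental plus a stride-frequency harmonic (arm, hand, thigh), rotated
#' into the configured phone orientation, with additive Gaussian noise.
#'
#' @param cfg a [gait_config()].
#' @return An object of class `"simulated_walk"`: list with
#'   `t` (time vector), `heel`, `pelvis` (3-channel [uniform_series()],
#'   meters), `accel` (named list of 3-channel [uniform_series()], m/s^2,
#'   one per position), `truth` (data frame: `stride_id`, `start_idx`,
#'   `end_idx`, `start_s`, `duration_s`, `length_m`, `V_m`),
#'   `true_constants` (list; the pendulum construction makes the
#'   Zijlstra-Hof constant exactly 1), and `config`.
#' @export
simulate_walk <- function(cfg) {
  stopifnot(inherits(cfg, "gait_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  l <- cfg$leg_length_m
  n <- round(cfg$duration_s * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs

  # draw strides until the walking window [pad, duration - pad] is full
  walk_span <- cfg$duration_s - 2 * cfg$pad_s
  m_guess <- ceiling(walk_span / cfg$period_mean_s) + 10L
  periods <- .rtnorm3(m_guess, cfg$period_mean_s, cfg$period_sd_s)
  lengths <- .rtnorm3(m_guess, cfg$stride_mean_m, cfg$stride_sd_m)
  lengths <- pmin(lengths, 2 * l - 1e-6)
  bounds <- cfg$pad_s + cumsum(c(0, periods))
  m <- max(which(bounds <= cfg$duration_s - cfg$pad_s)) - 1L
  if (m < 1L) stop("duration too short for a single stride")
  periods <- periods[seq_len(m)]
  lengths <- lengths[seq_len(m)]
  bounds <- bounds[seq_len(m + 1L)]
  vdisp <- l * (1 - cos(asin(pmin(lengths / (2 * l), 1))))

  # map each sample to its stride (0 = pad / outside the walking window)
  stride_of <- findInterval(tt, bounds, left.open = FALSE)
  stride_of[tt >= bounds[m + 1L]] <- 0L
  inw <- stride_of >= 1L
  si <- stride_of[inw]
  tau <- tt[inw] - bounds[si]           # time within the current stride
  ti <- periods[si]
  di <- lengths[si]
  vi <- vdisp[si]
  sf <- 0.6                              # stance fraction of the cycle

  # heel walking-direction trace: baseline 0 at each heel strike, smooth dip
  # of depth d within the stride (belt carries the heel back, swing returns
  # it); lead-in/lead-out ramps from the standing rest position -d/2 make
  # the first and last strikes genuine local maxima
  heel_y <- numeric(n)
  stance <- tau < sf * ti
  hy <- numeric(length(tau))
  hy[stance] <- -di[stance] * (1 - (1 + cos(pi * tau[stance] / (sf * ti[stance]))) / 2)
  hy[!stance] <- -di[!stance] *
    (1 + cos(pi * (tau[!stance] - sf * ti[!stance]) / ((1 - sf) * ti[!stance]))) / 2
  heel_y[inw] <- hy
  ramp <- 0.5                            # transition time into/out of gait
  pre <- !inw & tt < bounds[1L]
  heel_y[pre] <- -lengths[1L] / 2
  tr <- pre & tt >= bounds[1L] - ramp
  heel_y[tr] <- -lengths[1L] / 2 *
    (1 + cos(pi * (tt[tr] - (bounds[1L] - ramp)) / ramp)) / 2
  post <- !inw & tt >= bounds[m + 1L]
  heel_y[post] <- -lengths[m] / 2
  tr <- post & tt < bounds[m + 1L] + ramp
  heel_y[tr] <- -lengths[m] / 2 *
    (1 - cos(pi * (tt[tr] - bounds[m + 1L]) / ramp)) / 2
  heel_z <- numeric(n)
  lift <- numeric(length(tau))
  lift[!stance] <- 0.05 * sin(pi * (tau[!stance] - sf * ti[!stance]) /
                                ((1 - sf) * ti[!stance]))
  heel_z[inw] <- lift
  heel_x <- numeric(n)

  # pelvis: vertical pendulum oscillation (twice per stride), small lateral
  # sway at stride frequency, small fore-aft ripple at step frequency, and a
  # small Gaussian displacement dip at each foot strike whose second
  # derivative is the heel-strike impact transient in the acceleration
  z0 <- l
  pel_z <- numeric(n)
  pel_z[!inw & tt < bounds[1L]] <- z0 - vdisp[1L] / 2
  pel_z[!inw & tt >= bounds[m + 1L]] <- z0 - vdisp[m] / 2
  omega_step <- 4 * pi / ti              # two oscillations per stride
  omega_stride <- 2 * pi / ti
  pel_z[inw] <- z0 - (vi / 2) * cos(omega_step * tau)
  pel_x <- numeric(n)
  pel_x[inw] <- 0.02 * sin(omega_stride * tau)
  pel_y <- numeric(n)
  pel_y[inw] <- 0.01 * sin(omega_step * tau)

  # impact transients: centers at every step (stride boundaries and
  # mid-stride contralateral strikes), displacement dip depth h chosen so
  # the acceleration spike is impact_rel times the pelvis vertical amplitude
  imp_sigma <- 0.012
  impact_rel <- 1.5
  amp_str <- (vdisp / 2) * (4 * pi / periods)^2   # per-stride accel amplitude
  # centers snapped to the sampling grid: stride windows start at impact
  # centers, and cutting a transient off-center would inject a spurious
  # velocity offset into double-integration estimates
  centers <- round(c(bounds[seq_len(m)], bounds[seq_len(m)] + periods / 2,
                     bounds[m + 1L]) * fs) / fs
  center_amp <- c(amp_str, amp_str, amp_str[m])
  imp_disp <- numeric(n)                 # displacement dips (negative)
  imp_acc <- numeric(n)                  # analytic second derivative
  for (k in seq_along(centers)) {
    h <- impact_rel * center_amp[k] * imp_sigma^2
    lo <- max(1L, floor((centers[k] - 4 * imp_sigma) * fs) + 1L)
    hi <- min(n, ceiling((centers[k] + 4 * imp_sigma) * fs) + 1L)
    dt <- tt[lo:hi] - centers[k]
    gg <- exp(-dt^2 / (2 * imp_sigma^2))
    imp_disp[lo:hi] <- imp_disp[lo:hi] - h * gg
    imp_acc[lo:hi] <- imp_acc[lo:hi] +
      h * (1 - dt^2 / imp_sigma^2) / imp_sigma^2 * gg
  }
  pel_z <- pel_z + imp_disp

  add_noise <- function(x) {
    if (cfg$marker_noise_sd > 0) x + stats::rnorm(length(x), 0, cfg$marker_noise_sd)
    else x
  }
  heel <- uniform_series(cbind(x = add_noise(heel_x), y = add_noise(heel_y),
                               z = add_noise(heel_z)), fs = fs)
  pelvis <- uniform_series(cbind(x = add_noise(pel_x), y = add_noise(pel_y),
                                 z = add_noise(pel_z)), fs = fs)

  # acceleration channels: analytic second derivatives of the pelvis model;
  # other positions reuse the gait fundamental with position-specific
  # amplitude, phase and harmonic content; every position carries the
  # step-impact transient so |a| peaks once per step
  amp <- (vi / 2) * omega_step^2         # pelvis vertical accel amplitude
  accel <- list()
  for (pos in cfg$positions) {
    pp <- .position_params[[pos]]
    ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
    if (pos == "pelvis") {
      az[inw] <- amp * cos(omega_step * tau)
      ay[inw] <- -0.01 * omega_step^2 * sin(omega_step * tau)
      ax[inw] <- -0.02 * omega_stride^2 * sin(omega_stride * tau)
      az <- az + imp_acc
    } else {
      base <- pp$scale * amp
      az[inw] <- base * cos(omega_step * tau + pp$phase)
      ay[inw] <- pp$harmonic * base * cos(omega_stride * tau + pp$phase / 2)
      ax[inw] <- 0.15 * base * sin(omega_stride * tau + pp$phase)
      az <- az + pp$scale * imp_acc
    }
    vals <- cbind(ax = ax, ay = ay, az = az)
    rot <- cfg$orientation
    if (is.list(rot) && !is.null(rot[[pos]])) rot <- rot[[pos]]
    if (!is.null(rot) && is.matrix(rot)) vals <- vals %*% t(rot)
    if (cfg$accel_noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(3L * n, 0, cfg$accel_noise_sd), n, 3L)
    colnames(vals) <- c("ax", "ay", "az")
    accel[[pos]] <- uniform_series(vals, fs = fs)
  }

  start_idx <- round(bounds[seq_len(m)] * fs) + 1L
  end_idx <- round(bounds[2:(m + 1L)] * fs) + 1L
  truth <- data.frame(stride_id = seq_len(m), start_idx = start_idx,
                      end_idx = end_idx, start_s = bounds[seq_len(m)],
                      duration_s = periods, length_m = lengths, V_m = vdisp)
  structure(list(t = tt, heel = heel, pelvis = pelvis, accel = accel,
                 truth = truth, true_constants = list(zijlstra_K = 1),
                 config = cfg),
            class = "simulated_walk")
}

#' @export
print.simulated_walk <- function(x, ...) {
  cat(sprintf("<simulated_walk> %.0f s @ %g Hz, %.1f km/h: %d strides (mean %.3f m)\n",
              x$config$duration_s, x$config$fs, x$config$speed_kmh,
              nrow(x$truth), mean(x$truth$length_m)))
  cat("  sensors:", paste(names(x$accel), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate strides that follow the power-law model exactly
#'
#' Draws per-stride acceleration-magnitude ranges and generates stride
#' lengths as `d = beta * a_range^exponent + N(0, noise_sd^2)` — the direct
#' target for parameter-recovery checks of the model fit.
#'
#' @param beta true constant (> 0); default 0.72.
#' @param exponent power-law exponent; default 0.1.
#' @param n number of strides; default 300.
#' @param noise_sd stride-length noise SD in meters; default 0.03.
#' @param a_range_lim range (m/s^2) of the uniform `a_range` draw; default
#'   `c(5, 30)`.
#' @param seed mandatory integer seed.
#' @return Data frame with columns `a_range` and `length_m`.
#' @export
simulate_powerlaw_strides <- function(beta = 0.72, exponent = 0.1, n = 300,
                                      noise_sd = 0.03, a_range_lim = c(5, 30),
                                      seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (beta <= 0 || n < 1) stop("'beta' must be positive and 'n' >= 1")
  set.seed(as.integer(seed))
  a <- stats::runif(n, a_range_lim[1L], a_range_lim[2L])
  d <- beta * a^exponent + stats::rnorm(n, 0, noise_sd)
  data.frame(a_range = a, length_m = d)
}

#' Simulate a stride parameter matrix with a designated driver column
#'
#' Generates the full 28-column parameter matrix with a configurable
#' latent-correlation structure: every non-driver column loads on a common
#' latent gait factor with a coefficient drawn uniformly from
#' `[0, rho_max]`, and the response is generated from the driver column
#' through the power law plus noise. This is the test bed for the
#' screening-and-ranking machinery: with the default driver the derivation
#' should select the acceleration-magnitude range.
#'
#' @param n number of strides; default 300.
#' @param driver name of the column that drives the response (default
#'   `"acc_range_mag"`), or `NULL` for a null dataset in which the response
#'   is pure noise and all columns are independent.
#' @param beta,exponent,noise_sd response model parameters; defaults 0.72,
#'   0.1, 0.03.
#' @param rho_max maximum latent loading of non-driver columns; default 0.5.
#' @param duplicate_pair if `TRUE`, column `vel_mean_x` is made an exact
#'   copy of `vel_mean_y` (to exercise the collinearity screen).
#' @param seed mandatory integer seed.
#' @return A `"feature_matrix"` object (see [feature_matrix()]).
#' @export
simulate_feature_matrix <- function(n = 300, driver = "acc_range_mag",
                                    beta = 0.72, exponent = 0.1,
                                    noise_sd = 0.03, rho_max = 0.5,
                                    duplicate_pair = FALSE, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(as.integer(seed))
  nms <- stride_feature_names()
  p <- length(nms)
  # loosely plausible scales for each parameter family
  base_mean <- rep(1, p); base_sd <- rep(0.2, p)
  names(base_mean) <- names(base_sd) <- nms
  base_mean["duration"] <- 1.1;  base_sd["duration"] <- 0.04
  base_mean[c("path_x", "path_y", "path_z")] <- c(0.06, 2.7, 0.25)
  base_sd[c("path_x", "path_y", "path_z")] <- c(0.01, 0.12, 0.04)
  vel <- grepl("^vel_", nms); acc <- grepl("^acc_", nms)
  base_mean[vel] <- 0.9;  base_sd[vel] <- 0.15
  base_mean[acc] <- 6;    base_sd[acc] <- 1.2
  base_mean["acc_range_mag"] <- 17.5; base_sd["acc_range_mag"] <- 4

  if (is.null(driver)) {
    X <- sapply(seq_len(p), function(j) stats::rnorm(n, base_mean[j], base_sd[j]))
    colnames(X) <- nms
    y <- 1.3 + stats::rnorm(n, 0, noise_sd)
    return(feature_matrix(X, y))
  }
  if (!driver %in% nms) stop("unknown driver column '", driver, "'")
  latent <- stats::runif(n, -sqrt(3), sqrt(3))   # unit-variance latent factor
  rho <- stats::runif(p, 0, rho_max)
  X <- matrix(0, n, p, dimnames = list(NULL, nms))
  for (j in seq_len(p)) {
    zj <- rho[j] * latent + sqrt(1 - rho[j]^2) * stats::rnorm(n)
    X[, j] <- base_mean[j] + base_sd[j] * zj
  }
  X[, driver] <- base_mean[driver] + base_sd[driver] * latent
  X[, driver] <- pmax(X[, driver], 0.5)
  if (duplicate_pair) X[, "vel_mean_x"] <- X[, "vel_mean_y"]
  y <- beta * X[, driver]^exponent + stats::rnorm(n, 0, noise_sd)
  feature_matrix(X, y)
}
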