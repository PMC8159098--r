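#' Standard conditioning of a marker trajectory
#'
#' Gap-fills occlusions by spline interpolation, then applies the
#' zero-phase lowpass Butterworth filter (5 Hz, order 4 by default).
#'
#' @param traj a [masked_series()] or [uniform_series()].
#' @param cutoff,order Butterworth parameters; defaults 5 Hz / 4.
#' @return A conditioned [uniform_series()].
#' @export
preprocess_trajectory <- function(traj, cutoff = 5, order = 4) {
  lowpass_butterworth(fill_gaps_spline(traj), cutoff = cutoff, order = order)
}

#' Standard conditioning of a phone acceleration recording
#'
#' Resamples (possibly non-uniform) accelerometer samples to a uniform grid
#' by linear interpolation, then wavelet-denoises each axis.
#'
#' @param t timestamps in seconds, or a [uniform_series()].
#' @param values acceleration samples (m/s^2) at `t`.
#' @param target_fs resampling rate in Hz; default 100.
#' @param denoise apply [wavelet_denoise()]; default `TRUE`.
#' @return A conditioned [uniform_series()].
#' @export
preprocess_accel <- function(t, values = NULL, target_fs = 100, denoise = TRUE) {
  s <- if (inherits(t, "uniform_series") && t$fs == target_fs) t
       else resample_linear(t, values, target_fs = target_fs)
  if (denoise) wavelet_denoise(s) else s
}

#' Per-stride model inputs from an acceleration recording
#'
#' Computes, for each stride segment, the inputs every supported
#' step-length model needs: the acceleration-magnitude range `a_range`, the
#' vertical extrema `a_max`/`a_min`, the mean absolute walking-direction
#' acceleration `a_mean`, the vertical displacement `V` by double
#' integration, the step frequency `F = 2 / duration` (a stride spans two
#' steps) and the stride `duration`. The vertical and walking-direction
#' axes are taken as the third and second channels, so phone-frame
#' recordings must be rotated into the lab frame first (see
#' [apply_rotation()]); `a_range` alone is frame-invariant.
#'
#' @param accel a 3-channel [uniform_series()] of lab-frame linear
#'   accelerations (m/s^2), conditioned.
#' @param segments data frame with 1-based half-open windows `start`, `end`.
#' @return Data frame with one row per stride: `start_s`, `duration`,
#'   `a_range`, `a_max`, `a_min`, `a_mean`, `V`, `F`.
#' @export
stride_inputs <- function(accel, segments) {
  stopifnot(inherits(accel, "uniform_series"))
  if (ncol(accel$values) != 3L) stop("'accel' must have 3 channels")
  segments <- as.data.frame(segments)
  fs <- accel$fs
  mag <- sqrt(rowSums(accel$values^2))
  out <- lapply(seq_len(nrow(segments)), function(i) {
    idx <- segments$start[i]:(segments$end[i] - 1L)
    az <- accel$values[idx, 3L]
    ay <- accel$values[idx, 2L]
    dur <- length(idx) / fs
    data.frame(start_s = accel$t0 + (segments$start[i] - 1L) / fs,
               duration = dur,
               a_range = max(mag[idx]) - min(mag[idx]),
               a_max = max(az), a_min = min(az),
               a_mean = mean(abs(ay)),
               V = vertical_displacement(az, fs),
               F = 2 / dur)
  })
  do.call(rbind, out)
}

#' Reference-annotated stride dataset from a simulated walk
#'
#' Runs the treadmill reference pipeline on a [simulate_walk()] output:
#' conditions the heel trajectory, detects heel strikes, computes reference
#' stride lengths, conditions the phone acceleration at the requested
#' position, and extracts the per-stride model inputs over the heel-strike
#' segments (the treadmill protocol segments phone signals by the optical
#' heel-strike events).
#'
#' @param walk a `"simulated_walk"`.
#' @param position sensor position; default `"pelvis"`.
#' @param denoise wavelet-denoise the acceleration; default `TRUE`.
#' @return Data frame: [stride_inputs()] columns plus `length_m` (heel
#'   -derived reference stride length).
#' @export
stride_dataset <- function(walk, position = "pelvis", denoise = TRUE) {
  stopifnot(inherits(walk, "simulated_walk"))
  if (!position %in% names(walk$accel))
    stop("position '", position, "' not simulated")
  heel <- preprocess_trajectory(walk$heel)
  heel_y <- uniform_series(heel$values[, 2L, drop = FALSE], fs = heel$fs)
  ev <- detect_heel_strikes(heel_y)
  if (length(ev) < 2L) stop("no strides detected in the heel trace")
  refs <- reference_stride_lengths(heel_y, ev)
  segs <- data.frame(start = ev[-length(ev)], end = ev[-1L])
  acc <- walk$accel[[position]]
  if (denoise) acc <- wavelet_denoise(acc)
  cbind(stride_inputs(acc, segs), length_m = refs)
}

#' Evaluate tuned models on a walk with the 5/10-minute protocol
#'
#' For each requested model: tune the constant on the strides of the first
#' five minutes of the track and evaluate on the remainder (personalized
#' scope), or apply a pre-tuned model (universal scope). Returns per-stride
#' results suitable for [build_report()].
#'
#' @param dataset a [stride_dataset()]-style data frame (inputs +
#'   `length_m` + `start_s`).
#' @param models character vector of model ids; default all five.
#' @param user a [user_profile()]; required for `zijlstra_hof` / `tian`.
#' @param fitted optional named list of pre-tuned `"sl_model"` objects
#'   (universal scope); when given, no tuning split is made and the whole
#'   dataset is evaluated.
#' @return List with `runs` (data frame: `model`, `est_m`, `ref_m`,
#'   `start_s`) and `fits` (named list of `"sl_model"`).
#' @export
evaluate_models <- function(dataset, models = .sl_models, user = NULL,
                            fitted = NULL) {
  runs <- list(); fits <- list()
  for (mdl in models) {
    if (is.null(fitted)) {
      sp <- tuning_split(dataset)
      fit <- sl_model(dataset[sp$tuning, , drop = FALSE], model = mdl,
                      user = user)
      evald <- dataset[sp$evaluation, , drop = FALSE]
    } else {
      fit <- fitted[[mdl]]
      evald <- dataset
    }
    est <- predict(fit, evald)
    runs[[mdl]] <- data.frame(model = mdl, est_m = est,
                              ref_m = evald$length_m,
                              start_s = evald$start_s)
    fits[[mdl]] <- fit
  }
  list(runs = do.call(rbind, runs), fits = fits)
}
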