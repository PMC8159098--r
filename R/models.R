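#' User profile for user-parameterized models
#'
#' The Zijlstra-Hof model needs the leg length and the Tian model the body
#' height; the acceleration-range and other acceleration-based models need
#' neither.
#'
#' @param height_m body height in meters.
#' @param leg_length_m leg length in meters (must be below `height_m`).
#' @return An object of class `"user_profile"`.
#' @export
user_profile <- function(height_m = NA_real_, leg_length_m = NA_real_) {
  if (!is.na(height_m) && !(height_m > 0 && height_m < 3))
    stop("'height_m' must lie in (0, 3)")
  if (!is.na(leg_length_m) && !(leg_length_m > 0))
    stop("'leg_length_m' must be positive")
  if (!is.na(height_m) && !is.na(leg_length_m) && leg_length_m >= height_m)
    stop("leg length must be smaller than height")
  structure(list(height_m = height_m, leg_length_m = leg_length_m),
            class = "user_profile")
}

.sl_models <- c("proposed", "weinberg", "kim", "zijlstra_hof", "tian")

# per-model regressor g(inputs) such that the estimate is constant * g;
# every supported model is of this single-constant form, so one least-squares
# estimator Chat = sum(g d) / sum(g^2) tunes them all
.sl_regressor <- function(model, data, user = NULL, exponent = 0.1,
                          regressor = NULL) {
  need <- function(cols) {
    miss <- setdiff(cols, names(data))
    if (length(miss))
      stop("model '", model, "' needs input column(s): ",
           paste(miss, collapse = ", "))
  }
  switch(model,
    proposed = {
      col <- if (!is.null(regressor) && regressor %in% names(data)) regressor
             else "a_range"
      need(col)
      v <- data[[col]]
      if (any(v < 0, na.rm = TRUE))
        stop("negative acceleration-magnitude range")
      v^exponent
    },
    weinberg = {
      need(c("a_max", "a_min"))
      d <- data$a_max - data$a_min
      if (any(d < 0, na.rm = TRUE)) stop("a_max < a_min in some stride")
      d^0.25
    },
    kim = {
      need("a_mean")
      if (any(data$a_mean < 0, na.rm = TRUE)) stop("negative a_mean")
      data$a_mean^(1 / 3)
    },
    zijlstra_hof = {
      need("V")
      if (is.null(user) || is.na(user$leg_length_m))
        stop("Zijlstra-Hof model needs the user's leg length")
      l <- user$leg_length_m
      v <- data$V
      if (any(v < 0 | v > 2 * l, na.rm = TRUE))
        stop("vertical displacement outside [0, 2L]")
      2 * sqrt(2 * l * v - v^2)
    },
    tian = {
      need("F")
      if (is.null(user) || is.na(user$height_m))
        stop("Tian model needs the user's height")
      if (any(data$F <= 0, na.rm = TRUE)) stop("step frequency must be positive")
      user$height_m * sqrt(data$F)
    },
    stop("unknown model '", model, "'")
  )
}

#' Fit a step/stride-length estimation model
#'
#' Fits the tunable constant of one of five single-constant step-length
#' models to reference stride lengths by least squares. Writing each model
#' as `d = C * g(inputs)`, the estimator is
#' `C_hat = sum(g_i d_i) / sum(g_i^2)`. The models are:
#'
#' * `"proposed"` — `beta * a_range^0.1`, the acceleration-magnitude-range
#'   power law (orientation-invariant: it only uses `|a|`).
#' * `"weinberg"` — `K * (a_max - a_min)^(1/4)` on vertical acceleration
#'   (inverted-pendulum basis).
#' * `"kim"` — `K * a_mean^(1/3)` on mean absolute walking-direction
#'   acceleration.
#' * `"zijlstra_hof"` — `2 * K * sqrt(2 * L * V - V^2)` with leg length `L`
#'   and vertical pelvis displacement `V` per stride.
#' * `"tian"` — `K * h * sqrt(F)` with body height `h` and step frequency
#'   `F`.
#'
#' Strides with a non-positive regressor value are dropped from the fit
#' with a warning.
#'
#' @param data data frame of per-stride model inputs with the reference
#'   column `length_m` (meters) and, as the model requires, `a_range`,
#'   `a_max`, `a_min` (m/s^2, vertical), `a_mean` (m/s^2,
#'   walking-direction), `V` (m), `F` (Hz).
#' @param model one of `"proposed"`, `"weinberg"`, `"kim"`,
#'   `"zijlstra_hof"`, `"tian"`.
#' @param user a [user_profile()] (required for `zijlstra_hof` and `tian`).
#' @param exponent power-law exponent of the proposed model; default 0.1.
#' @param scope tuning scope label, `"personalized"` or `"universal"`;
#'   metadata only.
#' @param regressor optional column name to use as the proposed model's
#'   input (default `"a_range"`).
#' @return An object of class `"sl_model"` with components `model`,
#'   `constant`, `exponent`, `user`, `scope`, `data`, `reference`,
#'   `fitted.values`, `residuals`, `n_dropped`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`.
#' @examples
#' d <- data.frame(a_range = c(10, 14, 18), length_m = c(1.25, 1.31, 1.36))
#' fit <- sl_model(d, model = "proposed")
#' coef(fit)
#' predict(fit, data.frame(a_range = 12))
#' @export
sl_model <- function(data, model = .sl_models, user = NULL, exponent = 0.1,
                     scope = c("personalized", "universal"), regressor = NULL) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  data <- as.data.frame(data)
  if (!"length_m" %in% names(data))
    stop("'data' must contain the reference column 'length_m'")
  g <- .sl_regressor(model, data, user, exponent, regressor)
  d <- data$length_m
  ok <- is.finite(g) & is.finite(d) & g > 0
  if (!any(ok)) stop("no strides with a positive regressor value; cannot tune")
  if (any(!ok))
    warning(sum(!ok), " stride(s) with non-positive regressor dropped from tuning")
  constant <- sum(g[ok] * d[ok]) / sum(g[ok]^2)
  fitted <- constant * g
  structure(list(model = model, constant = constant, exponent = exponent,
                 user = user, scope = scope,
                 regressor = if (is.null(regressor)) .default_regressor(model)
                             else regressor,
                 data = data, reference = d,
                 fitted.values = fitted, residuals = d - fitted,
                 n = sum(ok), n_dropped = sum(!ok)),
            class = "sl_model")
}

.default_regressor <- function(model) {
  switch(model, proposed = "a_range", weinberg = "a_max - a_min",
         kim = "a_mean", zijlstra_hof = "V", tian = "F")
}

#' Construct a step-length model from a known constant
#'
#' Builds an `"sl_model"` without tuning, e.g. from a stored model file or a
#' published constant.
#'
#' @inheritParams sl_model
#' @param constant the model constant (K or beta); must be positive.
#' @return An `"sl_model"` without fitted values or residuals.
#' @export
sl_model_from_constant <- function(constant, model = .sl_models, user = NULL,
                                   exponent = 0.1,
                                   scope = c("personalized", "universal")) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  if (!is.numeric(constant) || length(constant) != 1L || constant <= 0)
    stop("'constant' must be a single positive number")
  structure(list(model = model, constant = constant, exponent = exponent,
                 user = user, scope = scope,
                 regressor = .default_regressor(model),
                 data = NULL, reference = NULL, fitted.values = NULL,
                 residuals = NULL, n = 0L, n_dropped = 0L),
            class = "sl_model")
}

#' Estimate stride lengths from per-stride inputs
#'
#' Vectorized evaluation of any of the five models for a given constant;
#' the functional layer under [predict.sl_model()].
#'
#' @inheritParams sl_model
#' @param constant the model constant (K or beta).
#' @return Numeric vector of estimated stride lengths in meters.
#' @export
estimate_stride_length <- function(data, model = .sl_models, constant,
                                   user = NULL, exponent = 0.1,
                                   regressor = NULL) {
  model <- match.arg(model)
  constant * .sl_regressor(model, as.data.frame(data), user, exponent, regressor)
}

#' @export
print.sl_model <- function(x, ...) {
  lab <- c(proposed = "acceleration-magnitude range power law",
           weinberg = "Weinberg (vertical acceleration range ^ 1/4)",
           kim = "Kim (mean |a_walk| ^ 1/3)",
           zijlstra_hof = "Zijlstra-Hof (inverted pendulum)",
           tian = "Tian (height * sqrt(step frequency))")[x$model]
  cat(sprintf("Step-length model: %s\n", lab))
  cat(sprintf("  constant = %.5g (%s scope)", x$constant, x$scope))
  if (x$model == "proposed") cat(sprintf(", exponent = %.3g", x$exponent))
  cat("\n")
  if (x$n > 0) cat(sprintf("  tuned on %d stride(s)\n", x$n))
  invisible(x)
}

#' @export
coef.sl_model <- function(object, ...) {
  stats::setNames(object$constant,
                  if (object$model == "proposed") "beta" else "K")
}

#' @export
predict.sl_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted.values)) stop("no fitted values; supply 'newdata'")
    return(object$fitted.values)
  }
  estimate_stride_length(newdata, model = object$model,
                         constant = object$constant, user = object$user,
                         exponent = object$exponent,
                         regressor = object$regressor)
}

#' @export
fitted.sl_model <- function(object, ...) object$fitted.values

#' @export
residuals.sl_model <- function(object, ...) object$residuals

#' @export
summary.sl_model <- function(object, ...) {
  if (is.null(object$residuals)) {
    res <- list(model = object, errors = NULL)
    class(res) <- "summary.sl_model"
    return(res)
  }
  err <- stride_errors(object$fitted.values, object$reference)
  ou <- over_under_split(object$fitted.values, object$reference)
  res <- list(model = object, errors = err, over_under = ou)
  class(res) <- "summary.sl_model"
  res
}

#' @export
print.summary.sl_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$errors)) {
    cat(sprintf("  stride MAE %.2f cm (SD of |error| %.2f cm), n = %d\n",
                100 * x$errors$mae, 100 * x$errors$sd_abs, x$errors$n))
    cat(sprintf("  overestimated %.1f%% / underestimated %.1f%%\n",
                x$over_under$over_pct, x$over_under$under_pct))
  }
  invisible(x)
}

#' @export
plot.sl_model <- function(x, ...) {
  if (is.null(x$fitted.values)) stop("nothing to plot: model has no tuning data")
  graphics::plot(x$reference, x$fitted.values,
                 xlab = "reference stride length [m]",
                 ylab = "estimated stride length [m]",
                 main = sprintf("%s model (constant %.3g)", x$model, x$constant),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.sl_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$residuals)) stop("cannot simulate: model has no residuals")
  if (!is.null(seed)) set.seed(seed)
  sdr <- stats::sd(object$residuals)
  n <- length(object$fitted.values)
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(n, 0, sdr)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Vertical displacement per stride by double integration
#'
#' Double trapezoidal integration of vertical acceleration over one stride.
#' Gait is cyclic, so the vertical velocity returns to its starting value
#' at the end of the stride and the net vertical displacement over the
#' stride is zero. Drift is controlled by a linear detrend of the
#' integrated velocity whose slope is estimated from the difference of the
#' first- and second-half velocity means: exact for a genuine linear drift
#' ramp, yet insensitive to the periodic velocity itself (each half spans
#' about a whole oscillation), unlike a least-squares line or an
#' endpoint-anchored line, both of which are biased by large-amplitude
#' periodic content over short windows. The intercept is fixed by zero net
#' displacement; the returned V is the max-min range of the resulting
#' position trace.
#'
#' @param az vertical acceleration over one stride, gravity excluded
#'   ([uniform_series()] or numeric vector), m/s^2.
#' @param fs sampling frequency in Hz.
#' @return Vertical displacement V in meters.
#' @export
vertical_displacement <- function(az, fs = NULL) {
  if (inherits(az, "uniform_series")) { fs <- az$fs; az <- az$values[, 1L] }
  if (is.null(fs)) stop("'fs' is required for plain numeric input")
  n <- length(az)
  if (n < 3L) stop("stride segment must contain at least 3 samples")
  dt <- 1 / fs
  v <- .cumtrapz(az, dt)
  tt <- (seq_len(n) - 1) * dt
  half <- seq_len(n %/% 2L)
  slope <- (mean(v[-half]) - mean(v[half])) / (mean(tt[-half]) - mean(tt[half]))
  v <- v - slope * tt                              # zero net velocity drift
  v <- v - .cumtrapz(v, dt)[n] / tt[n]             # zero net displacement
  z <- .cumtrapz(v, dt)
  max(z) - min(z)
}

.cumtrapz <- function(x, dt) {
  n <- length(x)
  c(0, cumsum((x[-1L] + x[-n]) / 2 * dt))
}

#' Tune a model constant (functional interface)
#'
#' Equivalent to `coef(sl_model(...))`; provided for pipeline use.
#'
#' @inheritParams sl_model
#' @return The tuned constant (single positive number).
#' @export
tune_constant <- function(data, model = .sl_models, user = NULL,
                          exponent = 0.1) {
  unname(coef(sl_model(data, model = model, user = user, exponent = exponent)))
}

#' Split a stride sequence into tuning and evaluation sets
#'
#' Protocol split for constant tuning: the first 5 minutes of each track
#' tune the constant, the last 10 minutes evaluate it. Tracks shorter than
#' the 5-minute boundary fall back to a proportional 1/3 : 2/3 split with a
#' warning.
#'
#' @param strides data frame with a stride start-time column `start_s`
#'   (seconds from track start).
#' @param track_duration_s total track duration in seconds; default the
#'   last stride start time.
#' @param tuning_s tuning window length in seconds; default 300 (5 min).
#' @return List with logical vectors `tuning` and `evaluation` (evaluation
#'   is the complement of tuning).
#' @export
tuning_split <- function(strides, track_duration_s = NULL, tuning_s = 300) {
  strides <- as.data.frame(strides)
  if (!"start_s" %in% names(strides))
    stop("'strides' must contain a 'start_s' column")
  if (is.null(track_duration_s)) track_duration_s <- max(strides$start_s)
  boundary <- tuning_s
  if (track_duration_s < tuning_s) {
    warning("track (", round(track_duration_s), " s) shorter than the ",
            tuning_s, " s tuning window; using a proportional 1/3 split")
    boundary <- track_duration_s / 3
  }
  tune <- strides$start_s < boundary
  list(tuning = tune, evaluation = !tune)
}

#' Pool tuning strides across tracks for a universal constant
#'
#' Merges the tuning windows (first 5 minutes by default) of several
#' tracks; a single constant fitted on the pooled strides is the
#' "universal" constant, as opposed to per-track "personalized" constants.
#'
#' @param tracks list of per-track stride data frames, each with `start_s`
#'   and the model's input columns plus `length_m`.
#' @param tuning_s tuning window length in seconds; default 300.
#' @return One pooled data frame of tuning strides.
#' @export
pool_tuning_strides <- function(tracks, tuning_s = 300) {
  pooled <- lapply(tracks, function(tr) {
    sp <- tuning_split(tr, tuning_s = tuning_s)
    as.data.frame(tr)[sp$tuning, , drop = FALSE]
  })
  do.call(rbind, pooled)
}
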