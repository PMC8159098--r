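#' Read a time-series CSV
#'
#' Reads the package's CSV time-series schema: header `t,x,y,z` (trajectory,
#' meters) or `t,ax,ay,az` (acceleration, m/s^2), time in seconds, comma
#' delimiter, `.` decimal mark, optional `valid` column in {0,1}. Non-finite
#' values (and rows flagged invalid) become masked samples. Uniformly
#' sampled input is returned as a [masked_series()]; non-uniform input is
#' returned as a list with `t` and `values` for [resample_linear()].
#'
#' @param path CSV file path.
#' @return A [masked_series()] (uniform input) or a list with elements `t`,
#'   `values`, `labels` (non-uniform input).
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  schemas <- list(c("t", "x", "y", "z"), c("t", "ax", "ay", "az"))
  hit <- vapply(schemas, function(s) all(s %in% names(df)), logical(1))
  if (!any(hit))
    stop("header of ", path, " matches no schema; expected columns ",
         "t,x,y,z or t,ax,ay,az (line 1)")
  cols <- schemas[[which(hit)[1L]]]
  tt <- as.numeric(df$t)
  bad <- which(!is.finite(tt))
  if (length(bad))
    stop("non-numeric time value in ", path, " at line ", bad[1L] + 1L)
  nm <- which(diff(tt) <= 0)
  if (length(nm))
    stop("time not strictly increasing in ", path, " at line ", nm[1L] + 2L)
  vals <- as.matrix(df[, cols[-1L]])
  mask <- is.finite(rowSums(vals))
  if ("valid" %in% names(df)) mask <- mask & df$valid != 0
  dt <- diff(tt)
  uniform <- max(dt) - min(dt) < 1e-6 * stats::median(dt)
  if (uniform) {
    vals[!mask, ] <- 0  # placeholder values under the mask
    masked_series(vals, fs = 1 / stats::median(dt), mask = mask, t0 = tt[1L],
                  labels = cols[-1L])
  } else {
    list(t = tt, values = vals, labels = cols[-1L])
  }
}

#' Write a series as a time-series CSV
#'
#' Inverse of [read_timeseries_csv()]: writes `t` plus the channel columns
#' with 6 significant digits (byte-stable reports across platforms).
#'
#' @param s a [uniform_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(s, path) {
  stopifnot(inherits(s, "uniform_series"))
  df <- data.frame(t = series_time(s), s$values, check.names = FALSE)
  if (!is.null(s$mask)) df$valid <- as.integer(s$mask)
  utils::write.csv(format(df, digits = 6, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Store / load a step-length model as JSON
#'
#' The JSON document carries the model id, constant, exponent (proposed
#' model), user parameters and tuning scope.
#'
#' @param model an `"sl_model"`.
#' @param path JSON file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns an `"sl_model"` (without tuning data).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "sl_model"))
  doc <- list(model = model$model, constant = model$constant,
              exponent = model$exponent, scope = model$scope,
              user = if (!is.null(model$user))
                list(height_m = model$user$height_m,
                     leg_length_m = model$user$leg_length_m))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  user <- NULL
  if (!is.null(doc$user) && length(doc$user))
    user <- user_profile(height_m = doc$user$height_m %||% NA_real_,
                         leg_length_m = doc$user$leg_length_m %||% NA_real_)
  sl_model_from_constant(doc$constant, model = doc$model, user = user,
                         exponent = doc$exponent %||% 0.1,
                         scope = doc$scope %||% "personalized")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# full default configuration document; unknown keys are rejected
.default_config <- list(
  filter = list(cutoff_hz = 5, order = 4),
  resample = list(fs = 100),
  denoise = list(levels = 4),
  movavg = list(window = 10),
  detect = list(separation_frac = 0.4, prominence_frac = 0.3,
                stride_band_hz = c(0.3, 1.5), step_band_hz = c(0.6, 3)),
  derive = list(vif_threshold = 10, exponent = 0.1),
  tuning = list(scope = "personalized", tuning_s = 300),
  seed = 1L
)

#' Resolved run configuration
#'
#' Merges user overrides into the package's default configuration document
#' (filtering, denoising, detection, derivation, tuning, seed). Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param overrides named list (possibly nested) of overrides, or the path
#'   of a YAML file holding one (requires the `yaml` package).
#' @return The resolved configuration list, classed `"run_config"`.
#' @export
run_config <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML config files requires the 'yaml' package")
    overrides <- yaml::read_yaml(overrides)
  }
  cfg <- .default_config
  merge1 <- function(base, over, prefix = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        stop("unknown config key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge1(base[[k]], over[[k]], paste0(prefix, k, "."))
      } else base[[k]] <- over[[k]]
    }
    base
  }
  structure(merge1(cfg, overrides), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  flat <- function(l, prefix = "") {
    for (k in names(l)) {
      if (is.list(l[[k]])) flat(l[[k]], paste0(prefix, k, "."))
      else cat(sprintf("  %s%s = %s\n", prefix, k,
                       paste(l[[k]], collapse = ", ")))
    }
  }
  flat(unclass(x))
  invisible(x)
}
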