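#' Stride-level estimation errors
#'
#' Mean absolute error and standard deviations of estimated versus
#' reference stride lengths. The SD is taken over the absolute errors (the
#' quantity reported alongside MAEs); the SD of the signed errors is also
#' returned.
#'
#' @param est estimated stride lengths (m).
#' @param ref reference stride lengths (m), same length.
#' @return List with `n`, `mae`, `sd_abs`, `sd_signed` (all in the input
#'   unit) and the per-stride signed `errors` (`est - ref`).
#' @export
stride_errors <- function(est, ref) {
  if (length(est) != length(ref)) stop("'est' and 'ref' lengths differ")
  if (!length(est)) stop("no strides to evaluate")
  e <- est - ref
  list(n = length(e), mae = mean(abs(e)),
       sd_abs = if (length(e) > 1L) stats::sd(abs(e)) else 0,
       sd_signed = if (length(e) > 1L) stats::sd(e) else 0,
       errors = e)
}

#' Overestimation / underestimation breakdown
#'
#' Shares of over- and underestimated strides and the class-wise MAE/SD.
#' Exact ties (estimate equal to reference) are counted as overestimated so
#' the two shares sum to 100%; the tie count is reported separately.
#'
#' @inheritParams stride_errors
#' @return List with `over_pct`, `under_pct`, `ties`, and class summaries
#'   `over`, `under` (each a [stride_errors()]-style list or `NULL` for an
#'   empty class).
#' @export
over_under_split <- function(est, ref) {
  if (length(est) != length(ref)) stop("'est' and 'ref' lengths differ")
  if (!length(est)) stop("no strides to evaluate")
  over <- est >= ref
  cls <- function(sel) if (any(sel)) stride_errors(est[sel], ref[sel]) else NULL
  list(over_pct = 100 * mean(over), under_pct = 100 * mean(!over),
       ties = sum(est == ref), over = cls(over), under = cls(!over))
}

#' Walked-distance accuracy
#'
#' Relative error of the estimated total walked distance:
#' `p = |d_est - d_star| / d_star * 100`, in percent.
#'
#' @param d_est estimated walked distance (m), e.g. the sum of estimated
#'   stride lengths.
#' @param d_star exact walked distance (m); must be positive.
#' @return Percentage error `p` (vectorized over `d_est`).
#' @export
distance_accuracy <- function(d_est, d_star) {
  if (any(d_star <= 0)) stop("'d_star' must be positive")
  abs(d_est - d_star) / d_star * 100
}

#' Aggregate evaluation tables
#'
#' Builds long-format summary tables from per-stride evaluation results:
#' one row per (model, position, speed) group with counts, MAE and SD in
#' centimeters and the over/underestimation breakdown, plus a per-model
#' overall table pooled across groups.
#'
#' @param runs data frame of per-stride results with columns `model`,
#'   `position`, `speed`, `est_m`, `ref_m`.
#' @return List of two data frames, `by_group` and `overall`.
#' @export
build_report <- function(runs) {
  runs <- as.data.frame(runs)
  need <- c("model", "position", "speed", "est_m", "ref_m")
  miss <- setdiff(need, names(runs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  summarize <- function(df) {
    err <- stride_errors(df$est_m, df$ref_m)
    ou <- over_under_split(df$est_m, df$ref_m)
    data.frame(n = err$n, mae_cm = 100 * err$mae, sd_cm = 100 * err$sd_abs,
               sd_signed_cm = 100 * err$sd_signed,
               over_pct = ou$over_pct, under_pct = ou$under_pct,
               over_mae_cm = if (is.null(ou$over)) NA_real_ else 100 * ou$over$mae,
               under_mae_cm = if (is.null(ou$under)) NA_real_ else 100 * ou$under$mae)
  }
  key <- interaction(runs$model, runs$position, runs$speed, drop = TRUE)
  by_group <- do.call(rbind, lapply(split(runs, key), function(df) {
    cbind(data.frame(model = df$model[1L], position = df$position[1L],
                     speed = df$speed[1L]), summarize(df))
  }))
  overall <- do.call(rbind, lapply(split(runs, runs$model), function(df) {
    cbind(data.frame(model = df$model[1L]), summarize(df))
  }))
  rownames(by_group) <- rownames(overall) <- NULL
  list(by_group = by_group, overall = overall)
}

#' Write evaluation report CSVs
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed); files `overall.csv` and
#'   `by_position_speed.csv` are written there.
#' @return Invisibly, the written paths.
#' @export
write_report_csv <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "overall.csv")
  p2 <- file.path(dir, "by_position_speed.csv")
  utils::write.csv(format(report$overall, digits = 6, trim = TRUE), p1,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format(report$by_group, digits = 6, trim = TRUE), p2,
                   row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
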