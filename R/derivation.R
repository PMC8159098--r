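#' Principal component analysis of the stride parameter matrix
#'
#' Eigendecomposition of the sample covariance of the column-centered
#' parameter matrix, computed through the singular value decomposition of
#' the centered matrix. Columns of the loading matrix `A` are the
#' eigenvectors in descending eigenvalue order; scores satisfy
#' `Z = X_centered %*% A`. The sign of each eigenvector is fixed by making
#' its largest-magnitude loading positive, so output is reproducible across
#' linear-algebra backends.
#'
#' @param x a `"feature_matrix"` (see [feature_matrix()]) or a plain numeric
#'   matrix (centered internally).
#' @return An object of class `"sl_pca"`: list with `A` (p x p loadings),
#'   `Z` (n x p scores), `eigenvalues` (length p, descending), `col_means`.
#' @export
sl_pca <- function(x) {
  xc <- if (inherits(x, "feature_matrix")) x$X_centered
        else sweep(as.matrix(x), 2L, colMeans(as.matrix(x)))
  mu <- if (inherits(x, "feature_matrix")) x$col_means else colMeans(as.matrix(x))
  n <- nrow(xc); p <- ncol(xc)
  if (n < 2L) stop("PCA needs at least 2 rows")
  sv <- svd(xc, nu = 0, nv = p)
  a <- sv$v
  ev <- numeric(p)
  ev[seq_along(sv$d)] <- sv$d^2 / (n - 1L)
  # sign convention: largest-|loading| entry positive in every column
  for (j in seq_len(p)) {
    k <- which.max(abs(a[, j]))
    if (a[k, j] < 0) a[, j] <- -a[, j]
  }
  rownames(a) <- colnames(xc)
  colnames(a) <- paste0("PC", seq_len(p))
  z <- xc %*% a
  structure(list(A = a, Z = z, eigenvalues = ev, col_means = mu),
            class = "sl_pca")
}

#' @export
print.sl_pca <- function(x, ...) {
  p <- length(x$eigenvalues)
  expl <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  cat(sprintf("<sl_pca> %d components; %.1f%% variance in first %d\n",
              p, 100 * expl[min(3L, p)], min(3L, p)))
  invisible(x)
}

#' Variance inflation factors
#'
#' Each column is standardized to zero mean and unit sum of squares; the
#' VIF of column j is then the j-th diagonal element of the inverse of the
#' standardized cross-product matrix, equivalently `1 / (1 - R2_j)` where
#' `R2_j` is from regressing column j on the others. Mutually uncorrelated
#' columns give VIF exactly 1. Exactly collinear columns (including
#' zero-variance columns after centering) are reported as `Inf`, not an
#' error.
#'
#' @param x a `"feature_matrix"` or numeric matrix.
#' @return Named numeric vector of p VIFs (>= 1, possibly `Inf`).
#' @export
variance_inflation_factors <- function(x) {
  xc <- if (inherits(x, "feature_matrix")) x$X_centered
        else sweep(as.matrix(x), 2L, colMeans(as.matrix(x)))
  p <- ncol(xc)
  ss <- sqrt(colSums(xc^2))
  vif <- rep(Inf, p)
  names(vif) <- colnames(xc)
  ok <- ss > 0
  xs <- xc[, ok, drop = FALSE]
  xs <- sweep(xs, 2L, ss[ok], "/")
  s <- crossprod(xs)
  inv <- tryCatch(solve(s), error = function(e) NULL)
  if (!is.null(inv) && all(is.finite(diag(inv))) && all(diag(inv) > 1 - 1e-6)) {
    vif[ok] <- pmax(diag(inv), 1)
    return(vif)
  }
  # singular cross-product: fall back to per-column R^2 via least squares
  for (jj in seq_len(ncol(xs))) {
    others <- xs[, -jj, drop = FALSE]
    fit <- stats::lm.fit(others, xs[, jj])
    rss <- sum(fit$residuals^2)
    vif[which(ok)[jj]] <- if (rss < 1e-10) Inf else max(1 / rss, 1)
  }
  vif
}

#' Principal component regression fit
#'
#' Least-squares regression of the centered response on a subset of
#' principal-component scores: `gamma_hat = (Z'Z)^-1 Z'y`. With all p
#' components retained this reproduces ordinary least squares on the
#' centered parameter matrix; the implied coefficients in the original
#' coordinates are `beta = A_m %*% gamma_hat`.
#'
#' @param pca an `"sl_pca"` object, or a plain numeric score matrix `Z_m`
#'   (then no original-coordinate `beta` is computed).
#' @param y centered response vector (stride lengths about their mean, m).
#' @param m number of leading components to retain; default all.
#' @param components optional explicit component indices (overrides `m`).
#' @return An object of class `"sl_pcr"`: list with `gamma_hat`,
#'   `components`, `residuals`, `fitted`, `beta` (length p, implied original
#'   -coordinate coefficients; `NULL` for plain-matrix input).
#' @export
pcr_fit <- function(pca, y, m = NULL, components = NULL) {
  if (!inherits(pca, "sl_pca")) {
    zm <- as.matrix(pca)
    pca <- structure(list(Z = zm, A = NULL), class = "sl_pca_bare")
  }
  p <- ncol(pca$Z)
  if (is.null(components)) {
    if (is.null(m)) m <- p
    if (m < 1L || m > p) stop("'m' must be in 1..", p)
    components <- seq_len(m)
  }
  zm <- pca$Z[, components, drop = FALSE]
  n <- nrow(zm)
  if (n <= length(components))
    stop("need more strides (", n, ") than retained components (",
         length(components), ")")
  qz <- qr(zm)
  if (qz$rank < length(components)) {
    bad <- components[-seq_len(qz$rank)]
    stop("score columns are rank deficient (components ",
         paste(bad, collapse = ", "), ")")
  }
  gam <- qr.coef(qz, y)
  fitted <- drop(zm %*% gam)
  structure(list(gamma_hat = gam, components = components,
                 residuals = y - fitted, fitted = fitted,
                 beta = if (!is.null(pca$A))
                   drop(pca$A[, components, drop = FALSE] %*% gam)),
            class = "sl_pcr")
}

#' @export
print.sl_pcr <- function(x, ...) {
  cat(sprintf("<sl_pcr> %d component(s), residual SD %.4g\n",
              length(x$components), stats::sd(x$residuals)))
  invisible(x)
}

#' Screen and rank candidate stride parameters
#'
#' Columns with a variance inflation factor above `vif_threshold` are
#' excluded; for every surviving parameter a single-regressor least-squares
#' fit of the centered stride lengths on the centered column is computed.
#' Because a centered fit's residuals sum to zero identically, the absolute
#' residual sum cannot discriminate candidates; survivors are therefore
#' ranked by the sum of absolute residuals (default) or, alternatively, by
#' the absolute residual sum of the corresponding *uncentered* fit. Both
#' quantities are reported for every survivor. Ties break by column order.
#'
#' @param x a `"feature_matrix"`.
#' @param vif_threshold exclusion threshold; default 10 (classical rule).
#' @param criterion `"sum_abs_resid"` (default) or `"abs_sum_resid_uncentered"`.
#' @return An object of class `"sl_ranking"`: list with `vif`, `excluded`
#'   (names), `table` (one row per survivor, ranked), `criterion`.
#' @export
rank_candidates <- function(x, vif_threshold = 10,
                            criterion = c("sum_abs_resid",
                                          "abs_sum_resid_uncentered")) {
  stopifnot(inherits(x, "feature_matrix"))
  criterion <- match.arg(criterion)
  vif <- variance_inflation_factors(x)
  survivors <- which(vif <= vif_threshold)
  if (!length(survivors))
    stop("all parameters excluded at VIF threshold ", vif_threshold,
         "; raise the threshold")
  yc <- x$y_centered
  rows <- lapply(survivors, function(j) {
    xc <- x$X_centered[, j]
    b <- sum(xc * yc) / sum(xc^2)
    res_c <- yc - b * xc
    xr <- x$X[, j]
    br <- sum(xr * x$y) / sum(xr^2)
    res_u <- x$y - br * xr
    data.frame(parameter = colnames(x$X)[j], column = j, vif = vif[j],
               slope = b, sum_abs_resid = sum(abs(res_c)),
               abs_sum_resid = abs(sum(res_c)),
               abs_sum_resid_uncentered = abs(sum(res_u)),
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  metric <- if (criterion == "sum_abs_resid") tab$sum_abs_resid
            else tab$abs_sum_resid_uncentered
  tab <- tab[order(metric, tab$column), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(vif = vif, excluded = names(vif)[vif > vif_threshold],
                 table = tab, criterion = criterion),
            class = "sl_ranking")
}

#' @export
print.sl_ranking <- function(x, ...) {
  cat(sprintf("<sl_ranking> %d survivor(s) of %d parameters (VIF screen excluded %d)\n",
              nrow(x$table), length(x$vif), length(x$excluded)))
  cat(sprintf("  top candidate: %s (%s = %.4g)\n", x$table$parameter[1L],
              x$criterion, x$table[[x$criterion]][1L]))
  invisible(x)
}

#' Derive the stride-length model from the parameter matrix
#'
#' The end-to-end derivation: variance-inflation screening, per-candidate
#' ranking, selection of the top-ranked parameter, and a least-squares fit
#' of the power-law model `d = beta * parameter^exponent` (the estimator
#' `beta_hat = sum(g_i d_i) / sum(g_i^2)` with `g = parameter^exponent`).
#' On marker-derived gait data the selected parameter is the range of the
#' acceleration magnitude within the stride.
#'
#' @inheritParams rank_candidates
#' @param exponent fixed model exponent; default 0.1. Set
#'   `refit_exponent = TRUE` to refine it over `exponent_grid` by residual
#'   sum of squares (off by default; the exponent is a model constant).
#' @param refit_exponent,exponent_grid optional exponent grid refit.
#' @return An object of class `"sl_derivation"`: list with `ranking`
#'   (`"sl_ranking"`), `pca` (`"sl_pca"`), `selected` (parameter name),
#'   `model` (an [sl_model] fitted on the selected column), `n_dropped`
#'   (strides with non-positive parameter values, excluded from the fit).
#' @export
derive_sl_model <- function(x, vif_threshold = 10, exponent = 0.1,
                            criterion = c("sum_abs_resid",
                                          "abs_sum_resid_uncentered"),
                            refit_exponent = FALSE,
                            exponent_grid = seq(0.05, 0.5, by = 0.05)) {
  stopifnot(inherits(x, "feature_matrix"))
  ranking <- rank_candidates(x, vif_threshold, criterion)
  sel <- ranking$table$parameter[1L]
  par_vals <- x$X[, ranking$table$column[1L]]
  pos <- par_vals > 0
  if (!all(pos))
    warning(sum(!pos), " stride(s) with non-positive '", sel,
            "' dropped from the power-law fit")
  if (!any(pos)) stop("no strides with positive selected parameter")
  d <- x$y[pos]; v <- par_vals[pos]
  if (refit_exponent) {
    rss <- vapply(exponent_grid, function(e) {
      g <- v^e
      b <- sum(g * d) / sum(g^2)
      sum((d - b * g)^2)
    }, numeric(1))
    exponent <- exponent_grid[which.min(rss)]
  }
  dat <- data.frame(a_range = v, length_m = d)
  model <- sl_model(dat, model = "proposed", exponent = exponent,
                    regressor = sel)
  structure(list(ranking = ranking, pca = sl_pca(x), selected = sel,
                 model = model, exponent = exponent,
                 n_dropped = sum(!pos)),
            class = "sl_derivation")
}

#' @export
print.sl_derivation <- function(x, ...) {
  cat("Stride-length model derivation\n")
  cat(sprintf("  selected parameter : %s\n", x$selected))
  cat(sprintf("  fitted constant    : %.5g (exponent %.3g)\n",
              coef(x$model)[[1L]], x$exponent))
  cat(sprintf("  VIF-excluded       : %d of %d parameters\n",
              length(x$ranking$excluded), length(x$ranking$vif)))
  if (x$n_dropped > 0)
    cat(sprintf("  dropped strides    : %d (non-positive parameter)\n", x$n_dropped))
  invisible(x)
}

#' Export a derivation report
#'
#' Writes the per-parameter VIF/ranking table as CSV and the selected model
#' as JSON (see [write_model_json()]).
#'
#' @param derivation an `"sl_derivation"`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_derivation_report <- function(derivation, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(derivation, "sl_derivation"))
  if (!is.null(csv_path)) {
    vif <- derivation$ranking$vif
    tab <- derivation$ranking$table
    full <- data.frame(parameter = names(vif), vif = as.numeric(vif),
                       excluded = names(vif) %in% derivation$ranking$excluded)
    full <- merge(full, tab[, c("parameter", "slope", "sum_abs_resid",
                                "abs_sum_resid_uncentered")],
                  by = "parameter", all.x = TRUE, sort = FALSE)
    utils::write.csv(format(full, digits = 6, trim = TRUE), csv_path,
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) write_model_json(derivation$model, json_path)
  invisible(list(csv = csv_path, json = json_path))
}
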