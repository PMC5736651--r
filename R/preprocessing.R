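get_values <- function(x) if (inherits(x, "metric_matrix")) x$values else as.matrix(x)

#' Fit a per-feature global-scale correction
#'
#' Regresses every feature on the metric's global covariate (intracranial
#' volume for tissue volume, total surface area for area, mean cortical
#' thickness for thickness) by ordinary least squares with intercept, on
#' the supplied (training) subjects.  Applying the correction replaces
#' values by residuals, removing global-scale variation.  A ratio variant
#' (divide by covariate relative to its training mean) is available for
#' sensitivity analysis.
#'
#' @param m a \code{metric_matrix}.
#' @param table a \code{subject_table} aligned with \code{m} (same subject
#'   order).
#' @param covariate covariate column; defaults to the metric's declared
#'   global covariate.
#' @param method \code{"residual"} or \code{"ratio"}.
#' @return object of class \code{scale_correction}.
#' @export
fit_scale_correction <- function(m, table, covariate = NULL,
                                 method = c("residual", "ratio")) {
  method <- match.arg(method)
  covariate <- covariate %||% m$global_covariate
  if (!covariate %in% names(table))
    stopf("covariate column '%s' not present in subject table", covariate)
  if (!identical(m$subjects, table$subject_id))
    stopf("metric matrix and subject table must share subject order (join first)")
  g <- as.numeric(table[[covariate]])
  if (any(!is.finite(g)) || any(g <= 0))
    stopf("covariate '%s' must be finite and strictly positive", covariate)
  if (stats::sd(g) == 0)
    stopf("covariate '%s' is constant; scale correction undefined", covariate)
  X <- m$values
  gc <- g - mean(g)
  slope <- as.vector(crossprod(gc, X)) / sum(gc^2)
  if (method == "ratio") slope[] <- 0
  intercept <- colMeans(X) - slope * mean(g)
  structure(list(metric = m$metric, covariate = covariate, method = method,
                 intercept = intercept, slope = slope,
                 covariate_mean = mean(g), features = m$features,
                 n_fit = nrow(X), fit_subjects = m$subjects),
            class = "scale_correction")
}

#' Apply a fitted global-scale correction
#'
#' The correction may be fitted on a disjoint subject set (the
#' cross-validation harness fits on training folds only).
#'
#' @param m a \code{metric_matrix}.
#' @param correction a \code{scale_correction}.
#' @param table \code{subject_table} aligned with \code{m}, providing the
#'   covariate values of the subjects being corrected.
#' @return a \code{metric_matrix} of residualized values (same shape).
#' @export
apply_scale_correction <- function(m, correction, table) {
  if (!identical(m$features, correction$features))
    stopf("feature ids of matrix and correction do not match")
  if (!identical(m$subjects, table$subject_id))
    stopf("metric matrix and subject table must share subject order")
  g <- as.numeric(table[[correction$covariate]])
  if (any(!is.finite(g)) || any(g <= 0))
    stopf("covariate '%s' must be finite and strictly positive", correction$covariate)
  if (correction$method == "ratio") {
    vals <- m$values / (g / correction$covariate_mean)
  } else {
    fitted <- outer(g, correction$slope) +
      matrix(correction$intercept, nrow(m$values), ncol(m$values), byrow = TRUE)
    vals <- m$values - fitted
  }
  metric_matrix(m$metric, vals, m$subjects, m$features,
                global_covariate = m$global_covariate)
}

#' Mean-centre and reduce by SVD, retaining a variance fraction
#'
#' Computes the smallest orthonormal basis whose cumulative
#' squared-singular-value fraction reaches \code{variance_retained}
#' (capped at the numerical rank).  Variance is measured on the
#' mean-centred matrix; features are never z-scored.
#'
#' @param m a \code{metric_matrix} or plain matrix (n >= 2 rows).
#' @param variance_retained fraction in (0, 1].
#' @return object of class \code{svd_reduction} with fields \code{mean},
#'   \code{basis} (D x q, orthonormal columns), \code{singular_values},
#'   \code{variance_fraction_achieved}.
#' @export
fit_svd <- function(m, variance_retained = 0.95) {
  X <- get_values(m)
  if (nrow(X) < 2L) stopf("need at least 2 subjects for SVD reduction")
  if (!(variance_retained > 0 && variance_retained <= 1))
    stopf("variance_retained must be in (0, 1]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc)
  tot <- sum(s$d^2)
  if (tot <= .Machine$double.eps * nrow(X) * ncol(X))
    stopf("matrix has zero variance (all rows constant); SVD reduction undefined")
  rank <- sum(s$d > s$d[1] * 1e-12)
  cum <- cumsum(s$d^2) / tot
  q <- which(cum >= variance_retained - 1e-12)[1]
  if (is.na(q) || q > rank) q <- rank
  structure(list(mean = mu, basis = s$v[, seq_len(q), drop = FALSE],
                 singular_values = s$d[seq_len(q)],
                 variance_fraction_achieved = cum[q],
                 rank = rank, n_fit = nrow(X)),
            class = "svd_reduction")
}

#' Project rows into a fitted SVD subspace
#'
#' @param X raw rows (n x D matrix, or \code{metric_matrix}).
#' @param red an \code{svd_reduction}.
#' @return n x q matrix of reduced coordinates, \code{(x - mean) \%*\% basis}.
#' @export
transform_svd <- function(X, red) {
  X <- get_values(X)
  if (ncol(X) != length(red$mean))
    stopf("feature count mismatch: data has %d, reduction expects %d",
          ncol(X), length(red$mean))
  sweep(X, 2L, red$mean) %*% red$basis
}
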