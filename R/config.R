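#' Run configuration for the supervised NPE pipeline
#'
#' Collects every tunable parameter of the embedding and evaluation
#' pipeline into a validated list.  Defaults follow the reference analysis:
#' \code{k = 10} neighbours, \code{d = 3} manifold dimensions per metric,
#' SVD retaining 95\% of variance, and 10-fold cross-validation.
#'
#' @param k neighbour count for the supervised graph (>= 1).
#' @param d per-metric manifold dimension, \code{1 <= d <= k}.
#' @param variance_retained fraction of variance kept by the SVD reduction,
#'   in (0, 1].
#' @param n_folds number of cross-validation folds (>= 2).
#' @param use_site_constraint zero image similarity between same-site pairs
#'   so neighbours come from different scanners.
#' @param global_scale_correction residualize each feature on the metric's
#'   global covariate (icv / total_area / mean_thickness) before embedding.
#' @param scale_method \code{"residual"} (per-feature OLS residualization,
#'   default) or \code{"ratio"} (divide by covariate relative to its
#'   training mean), kept for sensitivity analysis.
#' @param age_bandwidth Gaussian bandwidth tau (years) for age similarity,
#'   or \code{"auto"} for the median absolute pairwise age difference.
#' @param image_bandwidth Gaussian bandwidth sigma for image similarity, or
#'   \code{"auto"} for the median pairwise distance in the reduced space.
#' @param combination_mode how image and age similarity combine before
#'   neighbour selection: \code{"product"} (default) or
#'   \code{"weighted_sum"}.
#' @param lambda weight on image similarity for \code{"weighted_sum"}.
#' @param ridge relative regularizer for ill-conditioned local Gram
#'   matrices in the reconstruction-weight solve.
#' @param rotate_axes align each metric's manifold axes with age and sex
#'   (orthogonal rotation fitted on training subjects).
#' @param stratified_folds stratify folds by sex and age decile.
#' @param gp_restarts random restarts for GP hyperparameter optimization.
#' @param random_seed integer seed; all randomness in the pipeline flows
#'   from this value.
#' @return an object of class \code{npe_config}.
#' @export
npe_config <- function(k = 10, d = 3, variance_retained = 0.95,
                       n_folds = 10,
                       use_site_constraint = TRUE,
                       global_scale_correction = FALSE,
                       scale_method = c("residual", "ratio"),
                       age_bandwidth = "auto",
                       image_bandwidth = "auto",
                       combination_mode = c("product", "weighted_sum"),
                       lambda = 0.5,
                       ridge = 1e-3,
                       rotate_axes = TRUE,
                       stratified_folds = TRUE,
                       gp_restarts = 3,
                       random_seed = 1L) {
  scale_method <- match.arg(scale_method)
  combination_mode <- match.arg(combination_mode)
  cfg <- list(k = as.integer(k), d = as.integer(d),
              variance_retained = as.numeric(variance_retained),
              n_folds = as.integer(n_folds),
              use_site_constraint = isTRUE(use_site_constraint),
              global_scale_correction = isTRUE(global_scale_correction),
              scale_method = scale_method,
              age_bandwidth = age_bandwidth,
              image_bandwidth = image_bandwidth,
              combination_mode = combination_mode,
              lambda = as.numeric(lambda),
              ridge = as.numeric(ridge),
              rotate_axes = isTRUE(rotate_axes),
              stratified_folds = isTRUE(stratified_folds),
              gp_restarts = as.integer(gp_restarts),
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  structure(cfg, class = "npe_config")
}

validate_config <- function(cfg) {
  if (cfg$k < 1L) stopf("k must be >= 1 (got %d)", cfg$k)
  if (cfg$d < 1L || cfg$d > cfg$k)
    stopf("d must satisfy 1 <= d <= k (got d=%d, k=%d)", cfg$d, cfg$k)
  if (!(cfg$variance_retained > 0 && cfg$variance_retained <= 1))
    stopf("variance_retained must be in (0, 1]")
  if (cfg$n_folds < 2L) stopf("n_folds must be >= 2")
  bw_ok <- function(b) identical(b, "auto") || (is.numeric(b) && is.finite(b) && b > 0)
  if (!bw_ok(cfg$age_bandwidth)) stopf("age_bandwidth must be 'auto' or a positive number")
  if (!bw_ok(cfg$image_bandwidth)) stopf("image_bandwidth must be 'auto' or a positive number")
  if (!(cfg$lambda >= 0 && cfg$lambda <= 1)) stopf("lambda must be in [0, 1]")
  if (cfg$ridge < 0) stopf("ridge must be >= 0")
  if (cfg$gp_restarts < 0L) stopf("gp_restarts must be >= 0")
  invisible(cfg)
}

#' Read/write a run configuration as JSON
#'
#' @param path file path.
#' @param cfg an \code{npe_config}.
#' @return \code{read_config} returns an \code{npe_config}.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(npe_config, c(raw[intersect(names(raw), names(formals(npe_config)))]))
}

#' @export
print.npe_config <- function(x, ...) {
  cat("Supervised NPE configuration\n")
  cat(sprintf("  k = %d, d = %d, variance retained = %.3g\n",
              x$k, x$d, x$variance_retained))
  cat(sprintf("  folds = %d (stratified: %s), seed = %d\n",
              x$n_folds, x$stratified_folds, x$random_seed))
  cat(sprintf("  site constraint: %s, scale correction: %s (%s)\n",
              x$use_site_constraint, x$global_scale_correction, x$scale_method))
  cat(sprintf("  combination: %s, bandwidths: image=%s age=%s\n",
              x$combination_mode,
              paste(x$image_bandwidth, collapse = ""),
              paste(x$age_bandwidth, collapse = "")))
  invisible(x)
}
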