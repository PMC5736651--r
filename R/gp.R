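# Gaussian-process regression with a squared-exponential kernel plus
# additive noise, hyperparameters fitted by maximizing the log marginal
# likelihood (L-BFGS-B on log parameters, seeded random restarts).
# Features are standardized with training-fold statistics; the target is
# centred on the training mean.

#' Fit a Gaussian-process regressor
#'
#' Covariance \eqn{k(x, x') = \sigma_f^2 \exp(-\|x-x'\|^2 / (2\ell^2)) +
#' \sigma_n^2 \delta_{xx'}} with isotropic length-scale \eqn{\ell}.  The
#' noise variance is floored at \code{noise_floor} so that noiseless
#' training data yields near-interpolation.
#'
#' @param X training features (n x p), zero-variance columns already
#'   handled by the caller.
#' @param y numeric target.
#' @param noise_floor lower bound on the noise variance.
#' @param restarts random restarts for the marginal-likelihood
#'   optimization.
#' @param seed integer seed making the restarts deterministic.
#' @param maxit optimizer iteration cap per restart.
#' @return object of class \code{gp_model}.
#' @export
gp_fit <- function(X, y, noise_floor = 1e-6, restarts = 3, seed = 1L, maxit = 60) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stopf("X and y sizes differ")
  xm <- colMeans(X)
  xs <- apply(X, 2L, stats::sd)
  xs[xs < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-12) {
    # constant target: predictive mean is that constant
    return(structure(list(constant = TRUE, ym = ym, xm = xm, xs = xs),
                     class = "gp_model"))
  }
  D2 <- as.matrix(stats::dist(Xs))^2
  med <- stats::median(D2[upper.tri(D2)][D2[upper.tri(D2)] > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  nll <- function(th) {
    ell2 <- exp(th[1]); sf2 <- exp(th[2]); sn2 <- noise_floor + exp(th[3])
    K <- sf2 * exp(-D2 / (2 * ell2)) + diag(sn2, n)
    U <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    alpha <- backsolve(U, backsolve(U, yc, transpose = TRUE))
    as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(U))) + 0.5 * n * log(2 * pi))
  }
  th0 <- c(log(med / 2), log(vy), log(0.1 * vy))
  starts <- list(th0)
  if (restarts > 0) {
    jit <- with_seed(seed, matrix(stats::runif(3 * restarts, -1.5, 1.5), ncol = 3))
    for (r in seq_len(restarts)) starts[[r + 1L]] <- th0 + jit[r, ]
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B",
                   lower = rep(-30, 3), upper = rep(30, 3),
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stopf("GP hyperparameter optimization failed")
  ell2 <- exp(best$par[1]); sf2 <- exp(best$par[2])
  sn2 <- noise_floor + exp(best$par[3])
  K <- sf2 * exp(-D2 / (2 * ell2)) + diag(sn2, n)
  U <- chol(K)
  alpha <- backsolve(U, backsolve(U, yc, transpose = TRUE))
  structure(list(constant = FALSE, Xs = Xs, xm = xm, xs = xs, ym = ym,
                 ell2 = ell2, sf2 = sf2, sn2 = sn2,
                 alpha = alpha, nll = best$value),
            class = "gp_model")
}

#' GP predictive mean
#'
#' @param gp a \code{gp_model}.
#' @param Xnew m x p feature matrix.
#' @return numeric vector of predictive means.
#' @export
gp_predict <- function(gp, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (isTRUE(gp$constant)) return(rep(gp$ym, nrow(Xnew)))
  Xn <- sweep(sweep(Xnew, 2L, gp$xm), 2L, gp$xs, "/")
  d2 <- outer(rowSums(Xn^2), rowSums(gp$Xs^2), "+") - 2 * Xn %*% t(gp$Xs)
  d2[d2 < 0] <- 0
  Kx <- gp$sf2 * exp(-d2 / (2 * gp$ell2))
  as.numeric(Kx %*% gp$alpha + gp$ym)
}

#' Fit a GP age regressor on training coordinates and predict test ages
#'
#' @param train_coords training manifold coordinates (>= 20 subjects:
#'   below that hyperparameter fitting is refused).
#' @param train_age training ages in years.
#' @param test_coords coordinates of held-out subjects.
#' @param restarts,seed,noise_floor passed to \code{gp_fit}.
#' @return numeric vector of predicted ages for the test rows.
#' @export
fit_predict_age <- function(train_coords, train_age, test_coords,
                            restarts = 3, seed = 1L, noise_floor = 1e-6) {
  train_coords <- as.matrix(train_coords)
  test_coords <- as.matrix(test_coords)
  if (nrow(train_coords) < 20L)
    stopf("refusing GP hyperparameter fitting with fewer than 20 training subjects (got %d)",
          nrow(train_coords))
  if (!all(is.finite(train_coords)) || !all(is.finite(test_coords)))
    stopf("non-finite coordinates")
  sds <- apply(train_coords, 2L, stats::sd)
  drop <- sds < 1e-12
  if (any(drop)) {
    warnf("dropping %d zero-variance coordinate feature(s)", sum(drop))
    train_coords <- train_coords[, !drop, drop = FALSE]
    test_coords <- test_coords[, !drop, drop = FALSE]
  }
  if (!ncol(train_coords)) return(rep(mean(train_age), nrow(test_coords)))
  gp <- gp_fit(train_coords, train_age, noise_floor = noise_floor,
               restarts = restarts, seed = seed)
  gp_predict(gp, test_coords)
}
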