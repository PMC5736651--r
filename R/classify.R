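# Linear discriminant sex classifier.  MASS::lda supplies the standard
# fit (class means, pooled covariance, empirical priors); a shrinkage
# fallback replaces the pooled covariance by a convex combination with a
# scaled identity only when it is ill-conditioned (condition > 1e8).

lda_fit <- function(X, g) {
  X <- as.matrix(X)
  g <- factor(g)
  if (nlevels(droplevels(g)) < 2L)
    stopf("sex classifier needs both classes in training (got one)")
  g <- droplevels(g)
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 1e-12
  if (!any(keep)) stopf("all coordinate features are constant")
  Xk <- X[, keep, drop = FALSE]
  # pooled within-class covariance, for the conditioning check
  Sp <- Reduce(`+`, lapply(levels(g), function(l) {
    Xi <- Xk[g == l, , drop = FALSE]
    crossprod(sweep(Xi, 2L, colMeans(Xi)))
  })) / (nrow(Xk) - nlevels(g))
  cond <- tryCatch(kappa(Sp, exact = TRUE), error = function(e) Inf)
  shrinkage <- 0
  if (!is.finite(cond) || cond > 1e8) {
    target <- mean(diag(Sp))
    gam <- 1e-3
    while (gam < 1) {
      Ss <- (1 - gam) * Sp + gam * diag(target, ncol(Sp))
      if (is.finite(kappa(Ss, exact = TRUE)) && kappa(Ss, exact = TRUE) <= 1e8) break
      gam <- gam * 10
    }
    shrinkage <- min(gam, 1)
    Sp <- (1 - shrinkage) * Sp + shrinkage * diag(target, ncol(Sp))
    mu <- rbind(colMeans(Xk[g == levels(g)[1], , drop = FALSE]),
                colMeans(Xk[g == levels(g)[2], , drop = FALSE]))
    priors <- as.numeric(table(g)) / length(g)
    Sinv <- solve(Sp)
    structure(list(kind = "shrinkage", keep = keep, levels = levels(g),
                   mu = mu, Sinv = Sinv, priors = priors,
                   shrinkage = shrinkage),
              class = "sex_classifier")
  } else {
    fit <- MASS::lda(Xk, grouping = g)
    structure(list(kind = "mass", keep = keep, levels = levels(g),
                   fit = fit, shrinkage = 0),
              class = "sex_classifier")
  }
}

lda_predict <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)[, model$keep, drop = FALSE]
  if (model$kind == "mass") {
    pr <- stats::predict(model$fit, Xnew)
    list(labels = as.character(pr$class), posterior = pr$posterior)
  } else {
    # two-class Gaussian discriminant with shared (shrunk) covariance
    lp <- vapply(1:2, function(ci) {
      m <- model$mu[ci, ]
      as.numeric(Xnew %*% model$Sinv %*% m) - 0.5 * sum(m * (model$Sinv %*% m)) +
        log(model$priors[ci])
    }, numeric(nrow(Xnew)))
    lp <- matrix(lp, ncol = 2)
    mx <- apply(lp, 1L, max)
    post <- exp(lp - mx)
    post <- post / rowSums(post)
    colnames(post) <- model$levels
    list(labels = model$levels[max.col(post, ties.method = "first")],
         posterior = post)
  }
}

#' Fit a linear discriminant sex classifier and predict test labels
#'
#' @param train_coords training manifold coordinates.
#' @param train_sex two-level labels (or a factor) for training subjects.
#' @param test_coords coordinates of held-out subjects.
#' @return list with \code{labels} (character) and \code{posterior}
#'   (matrix of class probabilities, rows summing to 1).
#' @export
fit_predict_sex <- function(train_coords, train_sex, test_coords) {
  model <- lda_fit(train_coords, train_sex)
  lda_predict(model, test_coords)
}
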