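#' Locally linear reconstruction weights over a neighbour graph
#'
#' For each subject i, finds the weights w (summing to 1, supported on i's
#' neighbours) minimizing the reconstruction error
#' \eqn{\|x_i - \sum_j w_j x_j\|^2}, via the local Gram system
#' \eqn{G w = 1} with \eqn{G_{jl} = (x_i - x_j)\cdot(x_i - x_l)}.  When G
#' is singular or has condition number above 1e12 (routine when k
#' neighbours live in a higher-dimensional reduced space), its diagonal is
#' ridged by \code{ridge * trace(G) / m} (m = row's neighbour count) and
#' the row is flagged in the diagnostics.
#'
#' @param Xr reduced rows (n x q).
#' @param graph a \code{neighbour_graph}; every subject needs >= 1
#'   neighbour.
#' @param ridge relative regularizer (default 1e-3).
#' @return object of class \code{recon_weights}: dense n x n matrix
#'   \code{W} (rows sum to 1, support on the graph) and a logical
#'   \code{regularized} vector.
#' @export
compute_reconstruction_weights <- function(Xr, graph, ridge = 1e-3) {
  Xr <- as.matrix(Xr)
  n <- nrow(Xr)
  if (length(graph$neighbours) != n) stopf("graph size does not match data rows")
  W <- matrix(0, n, n)
  regularized <- logical(n)
  for (i in seq_len(n)) {
    nb <- graph$neighbours[[i]]
    if (!length(nb)) stopf("subject %d has an empty neighbour row", i)
    m <- length(nb)
    if (m == 1L) {
      W[i, nb] <- 1
      next
    }
    Dif <- sweep(Xr[nb, , drop = FALSE], 2L, Xr[i, ])
    G <- tcrossprod(Dif)
    tr <- sum(diag(G))
    cond <- tryCatch(kappa(G, exact = TRUE), error = function(e) Inf)
    if (tr <= 0) {
      # all neighbours coincide with x_i: any convex weights reconstruct
      W[i, nb] <- 1 / m
      regularized[i] <- TRUE
      next
    }
    if (!is.finite(cond) || cond > 1e12) {
      G <- G + diag(ridge * tr / m, m)
      regularized[i] <- TRUE
    }
    w <- tryCatch(solve(G, rep(1, m)), error = function(e) NULL)
    if (is.null(w) || !all(is.finite(w)) || abs(sum(w)) < 1e-12) {
      G <- G + diag(ridge * tr / m, m)
      regularized[i] <- TRUE
      w <- solve(G, rep(1, m))
    }
    W[i, nb] <- w / sum(w)
  }
  dimnames(W) <- list(graph$subject_ids, graph$subject_ids)
  structure(list(W = W, regularized = regularized, ridge = ridge),
            class = "recon_weights")
}

#' Fit the NPE projection by a generalized eigenproblem
#'
#' Solves \eqn{X_r^T M X_r \, p = \lambda \, X_r^T X_r \, p} with
#' \eqn{M = (I - W)^T (I - W)}; the d eigenvectors of smallest eigenvalue
#' form the projection P, so the training embedding \eqn{Y = X_r P}
#' minimally distorts each subject's locally linear reconstruction.  For
#' numerical definiteness the right-hand matrix is regularized by
#' \code{eps * mean(diag) * I}.  Columns of P are scaled to unit norm with
#' the largest-magnitude entry positive, making serialized models
#' reproducible across eigensolver backends.
#'
#' @param Xr reduced rows (n x q).
#' @param W a \code{recon_weights} (or plain n x n weight matrix).
#' @param d embedding dimension, \code{d <= q}, \code{n > d}.
#' @param eps relative definiteness regularizer (default 1e-9).
#' @return object of class \code{npe_model}: \code{P} (q x d), training
#'   embedding \code{Y} (n x d), ascending \code{eigenvalues}, and slots
#'   for the composed \code{svd} reduction and axis \code{rotation} filled
#'   by the pipeline.
#' @export
fit_npe <- function(Xr, W, d, eps = 1e-9) {
  Xr <- as.matrix(Xr)
  if (inherits(W, "recon_weights")) W <- W$W
  n <- nrow(Xr); q <- ncol(Xr)
  d <- as.integer(d)
  if (d > q) stopf("d=%d exceeds the reduced dimension q=%d", d, q)
  if (n <= d) stopf("need more subjects (%d) than embedding dimensions (%d)", n, d)
  IW <- diag(n) - W
  M <- crossprod(IW)
  A <- crossprod(Xr, M %*% Xr)
  B <- crossprod(Xr)
  B <- B + diag(eps * mean(diag(B)), q)
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  U <- chol(B)
  # whiten: solve U^-T A U^-1, a standard symmetric problem
  T1 <- backsolve(U, A, transpose = TRUE)
  S <- backsolve(U, t(T1), transpose = TRUE)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  nonneg <- pmax(es$values, 0)
  avail <- sum(is.finite(es$values))
  if (d > avail) stopf("d=%d exceeds the available eigenvectors (%d)", d, avail)
  sel <- seq(q, q - d + 1L)           # eigen() sorts decreasing; take smallest d
  P <- backsolve(U, es$vectors[, sel, drop = FALSE])
  lambda <- nonneg[sel]
  # unit-norm columns, largest-magnitude entry positive
  for (j in seq_len(d)) {
    p <- P[, j]
    p <- p / sqrt(sum(p^2))
    if (p[which.max(abs(p))] < 0) p <- -p
    P[, j] <- p
  }
  Y <- Xr %*% P
  rownames(Y) <- rownames(Xr)
  structure(list(P = P, Y = Y, eigenvalues = lambda, eps = eps,
                 svd = NULL, rotation = NULL),
            class = "npe_model")
}

#' Project new raw data onto a fitted NPE manifold
#'
#' The linear solution generalises to unseen subjects: new rows are passed
#' through the stored SVD reduction and multiplied by P, with no
#' re-embedding.
#'
#' @param X_new_raw m x D matrix of raw feature rows (or
#'   \code{metric_matrix}).
#' @param model an \code{npe_model} whose \code{svd} slot holds the
#'   composed \code{svd_reduction}.
#' @return m x d matrix of manifold coordinates.
#' @export
transform_npe <- function(X_new_raw, model) {
  if (is.null(model$svd))
    stopf("model carries no svd_reduction; cannot transform raw data")
  Xr <- transform_svd(X_new_raw, model$svd)
  Xr %*% model$P
}

#' High-dimensional embedding vectors (feature-weight maps)
#'
#' The composition \code{basis \%*\% P} gives one length-D weight vector
#' per manifold axis: the spatial pattern of feature importance that maps
#' a raw feature row to an embedding coordinate.
#'
#' @param model an \code{npe_model} with its \code{svd} slot set.
#' @param z_score z-score each axis map for comparison across metrics.
#' @return D x d matrix (rows named by feature id when available).
#' @export
embedding_vectors <- function(model, z_score = FALSE) {
  if (is.null(model$svd)) stopf("model carries no svd_reduction")
  V <- model$svd$basis %*% model$P
  if (z_score) V <- apply(V, 2L, function(v) (v - mean(v)) / stats::sd(v))
  V
}
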