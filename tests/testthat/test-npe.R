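graph_from_lists <- function(nbrs) {
  structure(list(neighbours = nbrs, scores = lapply(nbrs, function(x) rep(1, length(x))),
                 short = rep(FALSE, length(nbrs)), k = max(lengths(nbrs)),
                 mode = "product", lambda = 0.5, masks = c(sex = FALSE, site = FALSE),
                 subject_ids = as.character(seq_along(nbrs))),
            class = "neighbour_graph")
}

test_that("reconstruction weights: midpoint, single neighbour, row sums", {
  # x1 is the midpoint of its two neighbours
  X <- rbind(c(0, 0), c(1, 1), c(-1, -1), c(5, 5))
  g <- graph_from_lists(list(c(2L, 3L), c(1L, 3L), c(1L, 2L), c(1L, 2L)))
  W <- compute_reconstruction_weights(X, g)
  expect_equal(W$W[1, c(2, 3)], c(0.5, 0.5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rowSums(W$W), rep(1, 4), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diag(W$W) == 0))

  # single neighbour: weight exactly 1
  g1 <- graph_from_lists(list(2L, 1L, 1L))
  W1 <- compute_reconstruction_weights(X[1:3, ], g1)
  expect_identical(W1$W[1, 2], 1)
})

test_that("reconstruction weights match the constrained least-squares oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 12; q <- 4; k <- 3
    X <- matrix(rnorm(n * q), n)
    nbrs <- oracle_knn(X, k)
    g <- graph_from_lists(nbrs)
    W <- compute_reconstruction_weights(X, g)
    for (i in seq_len(n)) {
      w_oracle <- oracle_lle_weights(X[i, ], X[nbrs[[i]], , drop = FALSE])
      expect_equal(unname(W$W[i, nbrs[[i]]]), w_oracle, tolerance = 1e-8)
    }
    # support restricted to the graph
    offg <- W$W
    for (i in seq_len(n)) offg[i, nbrs[[i]]] <- 0
    expect_true(all(offg == 0))
  }
})

test_that("singular local Gram systems are ridged and flagged", {
  # duplicate neighbours make the local Gram exactly singular
  X <- rbind(c(0, 0), c(1, 0), c(1, 0), c(0, 2))
  g <- graph_from_lists(list(c(2L, 3L), c(1L, 4L), c(1L, 4L), c(1L, 2L)))
  W <- compute_reconstruction_weights(X, g)
  expect_true(W$regularized[1])
  expect_equal(sum(W$W[1, ]), 1, tolerance = 1e-10)
})

test_that("NPE solves the generalized eigenproblem it advertises", {
  set.seed(3)
  n <- 30; q <- 6; d <- 3
  X <- matrix(rnorm(n * q), n)
  tab <- tiny_table(n = n, seed = 3)
  g <- make_graph(X, tab, k = 5)
  W <- compute_reconstruction_weights(X, g)
  mod <- fit_npe(X, W, d)

  # eigen-residual of each returned pair under the regularized pencil
  IW <- diag(n) - W$W
  M <- crossprod(IW)
  A <- crossprod(X, M %*% X)
  B <- crossprod(X)
  B <- B + diag(mod$eps * mean(diag(B)), q)
  for (j in seq_len(d)) {
    p <- mod$P[, j]
    r <- A %*% p - mod$eigenvalues[j] * (B %*% p)
    expect_lt(sqrt(sum(r^2)) / sqrt(sum(p^2)), 1e-8 * max(1, norm(A, "2")))
  }
  expect_true(all(diff(mod$eigenvalues) >= -1e-12))    # ascending
  expect_true(all(mod$eigenvalues >= 0))
  expect_equal(mod$Y, X %*% mod$P, tolerance = 1e-12, ignore_attr = TRUE)
  # unit-norm sign-fixed columns
  for (j in seq_len(d)) {
    expect_equal(sum(mod$P[, j]^2), 1, tolerance = 1e-10)
    expect_gt(mod$P[which.max(abs(mod$P[, j])), j], 0)
  }
  expect_true(all(apply(mod$Y, 2, sd) > 0))
})

test_that("returned direction beats random Rayleigh quotients (d = 1)", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 15; q <- 3
    X <- matrix(rnorm(n * q), n)
    tab <- tiny_table(n = n, seed = seed)
    g <- make_graph(X, tab, k = 4)
    W <- compute_reconstruction_weights(X, g)
    mod <- fit_npe(X, W, d = 1)
    IW <- diag(n) - W$W
    M <- crossprod(IW)
    rq <- function(y) as.numeric(crossprod(y, M %*% y) / crossprod(y))
    ours <- rq(X %*% mod$P[, 1])
    dirs <- matrix(rnorm(10000 * q), ncol = q)
    best_random <- min(apply(dirs, 1, function(p) rq(X %*% p)))
    expect_lte(ours, best_random * (1 + 1e-6) + 1e-12)
  }
})

test_that("duplicated subjects embed identically", {
  set.seed(9)
  X <- matrix(rnorm(10 * 3), 10)
  X <- rbind(X, X[1, ])  # subject 11 duplicates subject 1
  nbrs <- oracle_knn(X, 3)
  g <- graph_from_lists(nbrs)
  W <- compute_reconstruction_weights(X, g)
  mod <- fit_npe(X, W, 2)
  expect_equal(mod$Y[1, ], mod$Y[11, ], tolerance = 1e-8)
})

test_that("out-of-sample transform composes SVD and projection exactly", {
  co <- small_cohort(n = 50, D = 30, seed = 19)
  m <- co$matrices$volume
  tab <- co$table
  red <- fit_svd(m, 0.95)
  Xr <- transform_svd(m, red)
  rownames(Xr) <- tab$subject_id
  g <- make_graph(Xr, tab, k = 6)
  W <- compute_reconstruction_weights(Xr, g)
  mod <- fit_npe(Xr, W, 3)
  mod$svd <- red

  # training rows reproduce the stored embedding
  expect_equal(transform_npe(m, mod), mod$Y, tolerance = 1e-10, ignore_attr = TRUE)
  # the training mean row embeds at the origin
  expect_lt(max(abs(transform_npe(matrix(red$mean, 1), mod))), 1e-10)
  # linearity: points on a segment between two training rows map onto the
  # segment between their embeddings
  x1 <- m$values[1, ]; x2 <- m$values[2, ]
  for (t in c(0.25, 0.5, 0.75)) {
    yt <- transform_npe(matrix(t * x1 + (1 - t) * x2, 1), mod)
    expect_equal(as.numeric(yt),
                 as.numeric(t * mod$Y[1, ] + (1 - t) * mod$Y[2, ]),
                 tolerance = 1e-8)
  }
  expect_error(transform_npe(matrix(0, 1, 7), mod), "mismatch")
})

test_that("embedding is invariant to orthogonal rotation of the input space", {
  set.seed(12)
  n <- 25; q <- 5
  X <- matrix(rnorm(n * q), n)
  tab <- tiny_table(n = n, seed = 12)
  g <- make_graph(X, tab, k = 4)
  W <- compute_reconstruction_weights(X, g)
  Y1 <- fit_npe(X, W, 2)$Y
  Q <- qr.Q(qr(matrix(rnorm(q * q), q)))
  # same graph/weights (they depend only on distances, preserved by Q)
  W2 <- compute_reconstruction_weights(X %*% Q, g)
  Y2 <- fit_npe(X %*% Q, W2, 2)$Y
  for (j in 1:2) {
    expect_equal(abs(cor(Y1[, j], Y2[, j])), 1, tolerance = 1e-6)
  }
})

test_that("exactly locally linear data embeds with negligible residual cost", {
  set.seed(14)
  n <- 40
  latent <- cbind(seq(0, 1, length.out = n), runif(n))
  A <- matrix(rnorm(2 * 12), 2)
  X <- latent %*% A   # data on an exact 2-d linear manifold
  red <- fit_svd(X, 0.95)   # full-rank coordinates, as the pipeline provides
  Xr <- transform_svd(X, red)
  nbrs <- oracle_knn(Xr, 4)
  g <- graph_from_lists(nbrs)
  # exact reconstruction forces singular local Grams, so the ridge always
  # engages; keep it tiny so the residual it induces stays negligible
  W <- compute_reconstruction_weights(Xr, g, ridge = 1e-10)
  mod <- fit_npe(Xr, W, 2)
  cost <- sum((mod$Y - W$W %*% mod$Y)^2)
  expect_lt(cost, 1e-6 * sum(mod$Y^2))
})

test_that("embedding vectors map raw data to coordinates", {
  co <- small_cohort(n = 40, D = 25, seed = 23)
  m <- co$matrices$area
  red <- fit_svd(m, 0.9)
  Xr <- transform_svd(m, red)
  g <- make_graph(Xr, co$table, k = 5)
  W <- compute_reconstruction_weights(Xr, g)
  mod <- fit_npe(Xr, W, 2)
  mod$svd <- red
  V <- embedding_vectors(mod)
  expect_equal(dim(V), c(25, 2))
  # (x - mean) . V == embedding coordinate
  Xc <- sweep(m$values, 2, red$mean)
  expect_equal(Xc %*% V, mod$Y, tolerance = 1e-10, ignore_attr = TRUE)
  Vz <- embedding_vectors(mod, z_score = TRUE)
  expect_equal(apply(Vz, 2, mean), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(Vz, 2, sd), c(1, 1), tolerance = 1e-12)
})
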