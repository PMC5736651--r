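# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately assembled by a different route than the
# implementation they check.

# Small cohort builders -------------------------------------------------

tiny_table <- function(n = 8, seed = 1, n_sites = 2, sex_levels = c("F", "M")) {
  set.seed(seed)
  df <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    age = round(runif(n, 3, 21), 3),
    sex = sample(rep_len(sex_levels, n)),
    site = paste0("site", sample(rep_len(seq_len(n_sites), n))),
    stringsAsFactors = FALSE)
  subject_table(df, sex_levels = sex_levels)
}

small_cohort <- function(n = 120, D = 60, seed = 7, ...) {
  generate_cohort(generator_spec(
    n_subjects = n,
    n_features = c(volume = D, thickness = D, area = D),
    seed = seed, ...))
}

fast_config <- function(...) {
  npe_config(n_folds = 5, gp_restarts = 1, random_seed = 11, ...)
}

# Independent oracles ---------------------------------------------------

# Constrained least squares for locally linear reconstruction weights,
# assembled as the full KKT (Lagrange) system on the *uncentred* neighbour
# Gram matrix -- a different formulation than the implementation's
# centred-Gram solve.
oracle_lle_weights <- function(x, Z) {
  m <- nrow(Z)
  Q <- Z %*% t(Z)
  b <- as.numeric(Z %*% x)
  A <- rbind(cbind(2 * Q, rep(1, m)), c(rep(1, m), 0))
  rhs <- c(2 * b, 1)
  sol <- solve(A, rhs)
  sol[seq_len(m)]
}

# Plain Euclidean k-NN by double loop (excludes self; ties by index).
oracle_knn <- function(X, k) {
  n <- nrow(X)
  lapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j) sqrt(sum((X[i, ] - X[j, ])^2)), numeric(1))
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  })
}

# Textbook one-way ANOVA from explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  lv <- unique(groups)
  ssb <- sum(vapply(lv, function(g) {
    ni <- sum(groups == g); ni * (mean(values[groups == g]) - gm)^2
  }, numeric(1)))
  ssw <- sum(vapply(lv, function(g) {
    sum((values[groups == g] - mean(values[groups == g]))^2)
  }, numeric(1)))
  df1 <- length(lv) - 1
  df2 <- length(values) - length(lv)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = pf(F, df1, df2, lower.tail = FALSE))
}

# Exact GP predictive mean from first principles given hyperparameters.
oracle_gp_mean <- function(Xtr, ytr, Xte, ell2, sf2, sn2) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sf2 * exp(-pmax(d2, 0) / (2 * ell2))
  }
  K <- k(Xtr, Xtr) + diag(sn2, nrow(Xtr))
  as.numeric(k(Xte, Xtr) %*% solve(K, ytr - mean(ytr))) + mean(ytr)
}

# Best correlation achievable by any planar rotation, by brute grid.
oracle_grid_rotation <- function(Y, target, n_angles = 3600) {
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  best <- -Inf
  for (t in th) {
    r <- c(cos(t), sin(t))
    cc <- abs(cor(Y %*% r, target))
    if (cc > best) best <- cc
  }
  best
}

make_graph <- function(Xr, table, k, use_site = FALSE, ...) {
  A <- image_similarity(Xr)
  Am <- apply_constraints(A, table, use_site = use_site)
  a <- age_similarity(table)
  combine_and_select(Am, a, k, ...)
}
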