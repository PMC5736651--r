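test_that("image similarity matches its definition and the median anchor", {
  set.seed(2)
  X <- matrix(rnorm(5 * 3), 5)
  A <- image_similarity(X, bandwidth = "auto")
  # brute-force double loop oracle
  s2 <- A$bandwidth^2
  for (i in 1:5) for (j in 1:5) {
    expect_equal(A$values[i, j], exp(-sum((X[i, ] - X[j, ])^2) / s2),
                 tolerance = 1e-12)
  }
  expect_equal(A$values, t(A$values), tolerance = 1e-15)
  expect_true(all(A$values >= 0 & A$values <= 1))

  # identical rows have similarity 1
  X2 <- rbind(X, X[1, ])
  A2 <- image_similarity(X2)
  expect_equal(A2$values[1, 6], 1)

  # a pair at exactly the median squared distance scores exp(-1)
  d2 <- as.matrix(dist(X))^2
  med <- median(d2[upper.tri(d2)])
  at_med <- which(abs(d2 - med) < 1e-12 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(at_med)) {
    expect_equal(A$values[at_med[1, 1], at_med[1, 2]], exp(-1), tolerance = 1e-12)
  }

  # degenerate: all rows identical
  expect_error(image_similarity(matrix(1, 4, 3)), "identical")
})

test_that("age similarity matches its definition", {
  tab <- tiny_table(n = 6, seed = 4)
  a <- age_similarity(tab, bandwidth = "auto")
  for (i in 1:6) for (j in 1:6) {
    expect_equal(a$values[i, j],
                 exp(-((tab$age[i] - tab$age[j]) / a$bandwidth)^2),
                 tolerance = 1e-12)
  }
  # two ages 18 apart with tau = 18 give exp(-1)
  tab2 <- subject_table(data.frame(subject_id = c("a", "b"), age = c(3, 21),
                                   sex = c("F", "M"), site = "x"),
                        sex_levels = c("F", "M"))
  a2 <- age_similarity(tab2, bandwidth = 18)
  expect_equal(a2$values[1, 2], exp(-1), tolerance = 1e-12)
  # auto tau on two subjects is their (only) age gap
  expect_equal(age_similarity(tab2)$bandwidth, 18)

  tab3 <- subject_table(data.frame(subject_id = c("a", "b"), age = c(7, 7),
                                   sex = c("F", "M"), site = "x"),
                        sex_levels = c("F", "M"))
  expect_error(age_similarity(tab3), "ages equal")
})

test_that("supervised constraints zero the right pairs", {
  tab <- tiny_table(n = 10, seed = 5, n_sites = 3)
  X <- matrix(rnorm(10 * 4), 10)
  A <- image_similarity(X)
  Am <- apply_constraints(A, tab, use_site = TRUE)
  for (i in 1:10) for (j in 1:10) {
    if (tab$sex[i] != tab$sex[j]) expect_identical(Am$values[i, j], 0)
    if (tab$site[i] == tab$site[j]) expect_identical(Am$values[i, j], 0)
    if (i == j) expect_identical(Am$values[i, j], 0)
  }
  # single-site cohort with the site constraint: everything masked
  tab1 <- tab; tab1$site <- "only"
  tab1 <- subject_table(as.data.frame(tab1), attr(tab, "sex_levels"))
  Am1 <- apply_constraints(A, tab1, use_site = TRUE)
  expect_true(all(Am1$values == 0))
})

test_that("combine_and_select takes top-k with deterministic tie-breaks", {
  # hand fixture: row scores (0, .9, .8, .7), k = 2
  elig <- matrix(TRUE, 4, 4); diag(elig) <- FALSE
  Am <- structure(list(values = matrix(c(0, 1, 1, 1,
                                         1, 0, 1, 1,
                                         1, 1, 0, 1,
                                         1, 1, 1, 0), 4, byrow = TRUE),
                       bandwidth = 1, kind = "image_masked"),
                  class = "similarity_matrix")
  attr(Am, "eligible") <- elig
  a <- structure(list(values = matrix(c(0, .9, .8, .7,
                                        .9, 0, .5, .4,
                                        .8, .5, 0, .3,
                                        .7, .4, .3, 0), 4, byrow = TRUE),
                      bandwidth = 1, kind = "age"),
                 class = "similarity_matrix")
  g <- combine_and_select(Am, a, k = 2, mode = "product")
  expect_equal(g$neighbours[[1]], c(2L, 3L))

  # exact tie broken by smaller index
  a$values[1, ] <- c(0, .5, .5, .2)
  g <- combine_and_select(Am, a, k = 1, mode = "product")
  expect_equal(g$neighbours[[1]], 2L)

  # short row flagged, not fatal
  Am2 <- Am
  Am2$values[1, c(3, 4)] <- 0
  attr(Am2, "eligible")[1, c(3, 4)] <- FALSE
  expect_warning(g <- combine_and_select(Am2, a, k = 3, mode = "product"), "short")
  expect_true(g$short[1])
  expect_equal(g$neighbours[[1]], 2L)

  # fully starved row errors with the subject named
  Am2$values[1, ] <- 0
  attr(Am2, "eligible")[1, ] <- FALSE
  expect_error(combine_and_select(Am2, a, k = 2), "no eligible neighbours")
})

test_that("product mode with uniform age similarity reduces to Euclidean k-NN", {
  set.seed(17)
  n <- 20
  X <- matrix(rnorm(n * 3), n)
  df <- data.frame(subject_id = sprintf("s%02d", 1:n), age = runif(n, 3, 21),
                   sex = "F", site = paste0("site", rep(1:2, 10)),
                   stringsAsFactors = FALSE)
  df$sex <- rep("F", n)  # all same sex: sex mask never bites
  tab <- subject_table(df, sex_levels = c("F", "M"))
  A <- image_similarity(X)
  Am <- apply_constraints(A, tab, use_site = FALSE)
  ones <- structure(list(values = matrix(1, n, n), bandwidth = Inf, kind = "age"),
                    class = "similarity_matrix")
  g <- combine_and_select(Am, ones, k = 4, mode = "product")
  knn <- oracle_knn(X, 4)
  for (i in 1:n) expect_equal(g$neighbours[[i]], knn[[i]])
})

test_that("selected neighbours never violate active masks (randomized audit)", {
  for (seed in 1:5) {
    tab <- tiny_table(n = 30, seed = seed, n_sites = 3)
    set.seed(seed + 100)
    X <- matrix(rnorm(30 * 5), 30)
    g <- make_graph(X, tab, k = 5, use_site = TRUE)
    for (i in seq_len(30)) {
      nb <- g$neighbours[[i]]
      expect_false(i %in% nb)
      expect_true(all(tab$sex[nb] == tab$sex[i]))       # sex-pure lists
      expect_true(all(tab$site[nb] != tab$site[i]))
    }
  }
})

test_that("graph is equivariant under joint relabelling of subjects", {
  tab <- tiny_table(n = 24, seed = 8, n_sites = 2)
  set.seed(42)
  X <- matrix(rnorm(24 * 4), 24)
  g1 <- make_graph(X, tab, k = 3)
  perm <- sample(24)
  tabp <- subject_table(as.data.frame(tab)[perm, ], attr(tab, "sex_levels"))
  gp <- make_graph(X[perm, ], tabp, k = 3)
  inv <- order(perm)  # position of original subject i in the permuted data
  for (i in seq_len(24)) {
    expect_equal(perm[gp$neighbours[[inv[i]]]], g1$neighbours[[i]])
  }
})

test_that("product mode is monotone in age similarity", {
  set.seed(55)
  n <- 12
  X <- matrix(rnorm(n * 3), n)
  tab <- tiny_table(n = n, seed = 55)
  A <- image_similarity(X)
  Am <- apply_constraints(A, tab, use_site = FALSE)
  a <- age_similarity(tab)
  g0 <- combine_and_select(Am, a, k = 3)
  i <- 1L
  j <- g0$neighbours[[1]][3]  # weakest selected neighbour
  a2 <- a
  a2$values[i, j] <- min(1, a$values[i, j] * 1.5)
  a2$values[j, i] <- a2$values[i, j]
  g2 <- combine_and_select(Am, a2, k = 3)
  expect_true(j %in% g2$neighbours[[i]])
})
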