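test_that("GP regression interpolates, extrapolates smooth functions, and is checked
           against the closed form", {
  set.seed(8)
  n <- 100
  X <- matrix(runif(n * 2, -2, 2), n)
  age <- 2 * X[, 1] + 5          # noise-free smooth (linear) relation
  tr <- 1:80; te <- 81:100
  pred <- fit_predict_age(X[tr, ], age[tr], X[te, ], seed = 5)
  expect_lt(mean(abs(pred - age[te])), 0.05)

  # dual-route check: predictive mean recomputed from first principles
  gp <- gp_fit(X[tr, ], age[tr], seed = 5)
  Xs_te <- sweep(sweep(X[te, ], 2, gp$xm), 2, gp$xs, "/")
  oracle <- oracle_gp_mean(gp$Xs, age[tr], Xs_te, gp$ell2, gp$sf2, gp$sn2)
  expect_equal(gp_predict(gp, X[te, ]), oracle, tolerance = 1e-8)

  # test point identical to a training point: near-interpolation with the
  # floored noise variance
  pred1 <- fit_predict_age(X[tr, ], age[tr], X[tr[3], , drop = FALSE], seed = 5)
  expect_lt(abs(pred1 - age[tr[3]]), 0.05)

  # constant training target
  predc <- fit_predict_age(X[tr, ], rep(7.5, 80), X[te, ], seed = 5)
  expect_equal(predc, rep(7.5, 20), tolerance = 1e-6)

  # refusal below 20 training subjects; non-finite input
  expect_error(fit_predict_age(X[1:10, ], age[1:10], X[te, ]), "20")
  Xb <- X[tr, ]; Xb[1, 1] <- NA
  expect_error(fit_predict_age(Xb, age[tr], X[te, ]), "finite")
  # zero-variance feature dropped with a warning
  Xz <- cbind(X[tr, ], 1)
  expect_warning(fit_predict_age(Xz, age[tr], cbind(X[te, ], 1), seed = 5),
                 "zero-variance")
})

test_that("LDA separates separated classes and is calibrated on null data", {
  set.seed(10)
  n <- 200
  # two clusters 10 sigma apart
  cls <- rep(c("F", "M"), each = n / 2)
  X <- matrix(rnorm(n * 2), n)
  X[cls == "M", 1] <- X[cls == "M", 1] + 10
  out <- fit_predict_sex(X, cls, X)
  expect_equal(mean(out$labels == cls), 1)
  expect_true(all(abs(rowSums(out$posterior) - 1) < 1e-12))

  # identical class distributions: accuracy near 1/2
  Xn <- matrix(rnorm(400 * 2), 400)
  cln <- rep(c("F", "M"), 200)
  te <- 201:400
  outn <- fit_predict_sex(Xn[1:200, ], cln[1:200], Xn[te, ])
  acc <- mean(outn$labels == cln[te])
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 200) + 1e-9)

  expect_error(fit_predict_sex(X[cls == "F", ], cls[cls == "F"], X), "both classes")
})

test_that("ill-conditioned pooled covariance falls back to shrinkage LDA", {
  set.seed(11)
  n <- 60
  x <- rnorm(n)
  X <- cbind(x, x, rnorm(n))   # exactly collinear features
  cls <- rep(c("F", "M"), n / 2)
  X[cls == "M", 3] <- X[cls == "M", 3] + 3
  out <- fit_predict_sex(X, cls, X)
  expect_gt(mean(out$labels == cls), 0.8)
  expect_true(all(abs(rowSums(out$posterior) - 1) < 1e-12))
})

test_that("site ANOVA matches the textbook oracle and handles edge cases", {
  set.seed(12)
  err <- c(rnorm(10, 1), rnorm(12, 1.5), rnorm(9, 0.8))
  site <- rep(c("a", "b", "c"), c(10, 12, 9))
  rep_obj <- list(predictions = data.frame(
    error = err, site = site, true_age = 10, predicted_age = 10 + err,
    true_sex = "F", predicted_sex = "F", stringsAsFactors = FALSE))
  got <- site_anova(rep_obj)
  want <- oracle_anova(abs(err), site)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$df1, length(unique(site)) - 1)
  expect_equal(got$df2, length(err) - length(unique(site)))

  # identical group means and variances -> F ~ 0
  e0 <- rep(c(1, 2, 3), times = 3)
  rep0 <- list(predictions = data.frame(
    error = e0, site = rep(c("a", "b", "c"), each = 3), stringsAsFactors = FALSE))
  expect_lt(site_anova(rep0)$F, 1e-20)

  # sites with < 2 subjects are excluded with a warning
  rep1 <- list(predictions = data.frame(
    error = c(err, 5), site = c(site, "lonely"), stringsAsFactors = FALSE))
  expect_warning(got1 <- site_anova(rep1), "lonely")
  expect_equal(got1$F, want$F, tolerance = 1e-10)
})

test_that("binned metrics partition by age order into near-equal bins", {
  set.seed(13)
  n <- 100
  pr <- data.frame(subject_id = sprintf("s%03d", 1:n), fold = 1,
                   true_age = runif(n, 3, 21), stringsAsFactors = FALSE)
  pr$predicted_age <- pr$true_age       # perfect predictions
  pr$error <- 0
  pr$true_sex <- sample(c("F", "M"), n, TRUE)
  pr$predicted_sex <- pr$true_sex
  rep_obj <- list(predictions = pr, sex_levels = c("F", "M"))
  b <- binned_metrics(rep_obj, 10)
  expect_equal(b$n, rep(10, 10))
  expect_equal(b$mae, rep(0, 10))
  expect_equal(b$accuracy, rep(1, 10))
  # ordered bins: max age in bin b <= min age in bin b+1
  ord <- order(pr$true_age)
  for (k in 1:9) {
    top <- max(pr$true_age[ord[((k - 1) * 10 + 1):(k * 10)]])
    bot <- min(pr$true_age[ord[(k * 10 + 1):((k + 1) * 10)]])
    expect_lte(top, bot)
  }
  # uneven division: sizes differ by at most 1
  b2 <- binned_metrics(list(predictions = pr[1:97, ], sex_levels = c("F", "M")), 10)
  expect_true(all(abs(b2$n - 9.7) <= 1))
  expect_equal(sum(b2$n), 97)
  expect_error(binned_metrics(list(predictions = pr[1:5, ], sex_levels = c("F", "M")), 10),
               "fewer")
})

test_that("cognition regression identities hold", {
  set.seed(14)
  n <- 300
  tab <- data.frame(subject_id = sprintf("s%03d", 1:n), age = runif(n, 3, 21),
                    sex = sample(c("F", "M"), n, TRUE), site = "a",
                    ses = rnorm(n), stringsAsFactors = FALSE)
  err <- rnorm(n)
  # covariate made exactly orthogonal to the error so stage-1
  # residualization leaves the linear relation untouched
  tab$ses <- residuals(lm(tab$ses ~ err))
  tab$score_exact <- 0.3 * err                       # exactly linear in error
  tab$score_null <- rnorm(n)
  tab <- subject_table(tab, c("F", "M"))
  rep_obj <- list(predictions = data.frame(subject_id = tab$subject_id, error = err,
                                           stringsAsFactors = FALSE),
                  sex_levels = c("F", "M"))
  res <- error_cognition_regression(rep_obj, tab, c("score_exact", "score_null"),
                                    covariates = c("ses"))
  expect_equal(res$r_squared[res$score == "score_exact"], 1, tolerance = 1e-6)
  # R^2 equals the squared Pearson correlation of the stage-2 variables
  resid1 <- residuals(lm(tab$score_null ~ tab$ses))
  expect_equal(res$r_squared[res$score == "score_null"],
               cor(resid1, err)^2, tolerance = 1e-12)
  expect_equal(res$df1, c(1, 1))
  expect_equal(res$df2, c(n - 2, n - 2))
  expect_equal(res$p_adjusted, pmin(1, res$p * 2), tolerance = 1e-12)
})

test_that("null cognition-regression p-values are approximately uniform", {
  set.seed(15)
  n <- 200
  reps <- 50
  pvals <- replicate(reps, {
    tab <- subject_table(data.frame(
      subject_id = sprintf("s%03d", 1:n), age = runif(n, 3, 21),
      sex = sample(c("F", "M"), n, TRUE), site = "a",
      ses = rnorm(n), score = rnorm(n), stringsAsFactors = FALSE), c("F", "M"))
    rep_obj <- list(predictions = data.frame(subject_id = tab$subject_id,
                                             error = rnorm(n),
                                             stringsAsFactors = FALSE),
                    sex_levels = c("F", "M"))
    error_cognition_regression(rep_obj, tab, "score", covariates = "ses")$p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
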