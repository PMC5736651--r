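#' Assign cross-validation folds
#'
#' Stratifies by sex and age decile (default), so each fold mirrors the
#' cohort's composition; plain random folds are available.  Every fold's
#' training set must contain both sexes; if not, the stratification is
#' re-randomized once before failing.
#'
#' @param table a \code{subject_table}.
#' @param n_folds number of folds.
#' @param stratified stratify by sex x age-decile.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..n_folds) per subject.
#' @export
make_folds <- function(table, n_folds = 10, stratified = TRUE, seed = 1L) {
  n <- nrow(table)
  if (n < n_folds) stopf("fewer subjects (%d) than folds (%d)", n, n_folds)
  draw <- function(s) {
    with_seed(s, {
      folds <- integer(n)
      if (stratified) {
        dec <- cut(rank(table$age, ties.method = "first"),
                   breaks = max(1L, min(10L, floor(n / n_folds))),
                   labels = FALSE)
        strata <- interaction(table$sex, dec, drop = TRUE)
        counter <- 0L
        for (s_lab in levels(strata)) {
          idx <- sample(which(strata == s_lab))
          folds[idx] <- ((counter + seq_along(idx) - 1L) %% n_folds) + 1L
          counter <- counter + length(idx)
        }
      } else {
        folds <- sample(rep_len(seq_len(n_folds), n))
      }
      folds
    })
  }
  ok <- function(folds) {
    all(vapply(seq_len(n_folds), function(f) {
      length(unique(table$sex[folds != f])) == 2L
    }, logical(1)))
  }
  folds <- draw(seed)
  if (!ok(folds)) {
    folds <- draw(seed + 1L)
    if (!ok(folds)) stopf("a fold's training set has a single sex class; cohort too unbalanced")
  }
  folds
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs the internal validation protocol: per fold, the entire pipeline
#' (scale correction, SVD, supervised graph, reconstruction weights, NPE,
#' rotation, GP and LDA) is refit on the training subjects only; the held
#' out 10\% are projected onto the training manifold and their age and sex
#' predicted.  Pooled out-of-fold predictions give the mean absolute error
#' (MAE), Pearson correlation between chronological and predicted age,
#' and sex classification accuracy, plus per-age-bin and per-site tables
#' and a site ANOVA on absolute error.
#'
#' @param table a \code{subject_table}.
#' @param matrices named list of \code{metric_matrix} objects.
#' @param config an \code{npe_config}.
#' @param folds optional precomputed fold assignment (integer vector).
#' @return object of class \code{evaluation_report}.
#' @export
crossval_evaluate <- function(table, matrices, config = npe_config(), folds = NULL) {
  joined <- join_cohort(table, matrices)
  table <- joined$table
  matrices <- joined$matrices
  n <- nrow(table)
  if (is.null(folds)) {
    folds <- make_folds(table, config$n_folds, config$stratified_folds,
                        config$random_seed)
  }
  if (length(folds) != n) stopf("fold assignment length differs from cohort size")
  n_folds <- max(folds)
  pred_age <- rep(NA_real_, n)
  pred_sex <- rep(NA_character_, n)
  p_second <- rep(NA_real_, n)
  fingerprints <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (!length(te)) next
    tab_tr <- subject_table(as.data.frame(table[tr, , drop = FALSE]),
                            sex_levels = attr(table, "sex_levels"))
    mats_tr <- lapply(matrices, function(m) {
      metric_matrix(m$metric, m$values[tr, , drop = FALSE], tab_tr$subject_id,
                    m$features, global_covariate = m$global_covariate)
    })
    tab_te <- subject_table(as.data.frame(table[te, , drop = FALSE]),
                            sex_levels = attr(table, "sex_levels"))
    mats_te <- lapply(matrices, function(m) {
      metric_matrix(m$metric, m$values[te, , drop = FALSE], tab_te$subject_id,
                    m$features, global_covariate = m$global_covariate)
    })
    fold_seed <- (config$random_seed * 1009L + f) %% .Machine$integer.max
    model <- npe_fit(tab_tr, mats_tr, config, seed = fold_seed)
    fingerprints[[f]] <- fingerprint_fit(model)
    pr <- npe_predict(model, mats_te, table = tab_te)
    pred_age[te] <- pr$age
    pred_sex[te] <- pr$sex
    lv2 <- model$sex_levels[2]
    p_second[te] <- pr$posterior[, lv2]
  }
  lv <- attr(table, "sex_levels")
  predictions <- data.frame(
    subject_id = table$subject_id, fold = folds,
    true_age = table$age, predicted_age = pred_age,
    error = pred_age - table$age,
    true_sex = table$sex, predicted_sex = pred_sex,
    p_second_level = p_second,
    site = table$site, stringsAsFactors = FALSE)
  report <- structure(list(
    predictions = predictions,
    mae = mean(abs(predictions$error)),
    pearson_r = stats::cor(predictions$predicted_age, predictions$true_age),
    accuracy = mean(predictions$predicted_sex == predictions$true_sex),
    sex_levels = lv,
    n = n, n_folds = n_folds,
    fingerprints = fingerprints,
    config = config), class = "evaluation_report")
  report$bins <- binned_metrics(report)
  report$site_table <- site_metrics(report)
  report$site_anova <- site_anova(report)
  report
}

#' Per-age-bin accuracy table
#'
#' Orders subjects by age (ties by smaller index) and partitions them into
#' approximately equal-sized bins; reports per-bin n, mean age, MAE, male
#' count and sex classification accuracy.
#'
#' @param report an \code{evaluation_report}.
#' @param n_bins number of bins (default 10).
#' @return data frame with one row per bin.
#' @export
binned_metrics <- function(report, n_bins = 10) {
  pr <- report$predictions
  n <- nrow(pr)
  if (n < n_bins) stopf("fewer subjects (%d) than bins (%d)", n, n_bins)
  ord <- order(pr$true_age, seq_len(n))
  edges <- round(seq(0, n, length.out = n_bins + 1))
  male_level <- male_level_of(report$sex_levels)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- ord[(edges[b] + 1):edges[b + 1]]
    data.frame(bin = b, n = length(idx),
               mean_age = mean(pr$true_age[idx]),
               mae = mean(abs(pr$error[idx])),
               n_male = sum(pr$true_sex[idx] == male_level),
               accuracy = mean(pr$predicted_sex[idx] == pr$true_sex[idx]))
  }))
  rownames(out) <- NULL
  out
}

male_level_of <- function(levels) {
  hit <- grepl("^m(ale)?$", levels, ignore.case = TRUE)
  if (any(hit)) levels[hit][1] else levels[2]
}

# Per-site MAE and accuracy.
site_metrics <- function(report) {
  pr <- report$predictions
  out <- do.call(rbind, lapply(sort(unique(pr$site)), function(s) {
    idx <- pr$site == s
    data.frame(site = s, n = sum(idx), mae = mean(abs(pr$error[idx])),
               accuracy = mean(pr$predicted_sex[idx] == pr$true_sex[idx]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of absolute age-prediction error across sites
#'
#' Tests whether acquisition site associates with absolute error.  Sites
#' with fewer than 2 subjects are excluded with a warning.
#'
#' @param report an \code{evaluation_report}.
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
site_anova <- function(report) {
  pr <- report$predictions
  tab <- table(pr$site)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warnf("excluding site(s) with <2 subjects from ANOVA: %s",
          paste(small, collapse = ", "))
    pr <- pr[!pr$site %in% small, , drop = FALSE]
  }
  if (length(unique(pr$site)) < 2L)
    return(list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_, p = NA_real_))
  fit <- stats::lm(abs(error) ~ factor(site), data = pr)
  av <- stats::anova(fit)
  list(F = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2], p = av$`Pr(>F)`[1])
}

#' Associations between predicted-age error and cognitive scores
#'
#' Two-stage analysis: each cognitive score is first residualized on the
#' supplied covariates (OLS), then regressed on the predicted-age error
#' (the brain-age gap).  Per score: R-squared, F with df (1, n-2), and p,
#' with a Bonferroni-adjusted significance column across scores (the
#' adjustment method is configurable).
#'
#' @param report an \code{evaluation_report}.
#' @param table \code{subject_table} holding the scores and covariates.
#' @param scores character vector of score column names.
#' @param covariates character vector of covariate column names (e.g. age,
#'   sex code, socioeconomic status, ancestry factor).
#' @param adjust multiple-comparison method (default "bonferroni").
#' @return data frame with one row per score; the number of subjects
#'   dropped for missing data is in \code{attr(x, "n_dropped")}.
#' @export
error_cognition_regression <- function(report, table, scores, covariates,
                                       adjust = "bonferroni") {
  pr <- report$predictions
  df <- merge(pr[, c("subject_id", "error")], as.data.frame(table),
              by = "subject_id", sort = FALSE)
  df$.sex_code <- ifelse(df$sex == report$sex_levels[1], -1, 1)
  covariates <- vapply(covariates, function(cv) {
    if (cv == "sex") ".sex_code" else cv
  }, character(1))
  need <- c("error", covariates, scores)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  complete <- stats::complete.cases(df[, need, drop = FALSE])
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  Xc <- as.matrix(df[, covariates, drop = FALSE])
  out <- do.call(rbind, lapply(scores, function(sc) {
    resid1 <- stats::residuals(stats::lm(df[[sc]] ~ Xc))
    fit2 <- stats::lm(resid1 ~ df$error)
    sm <- summary(fit2)
    Fst <- sm$fstatistic
    data.frame(score = sc, r_squared = sm$r.squared,
               F = unname(Fst[1]), df1 = unname(Fst[2]), df2 = unname(Fst[3]),
               p = stats::pf(Fst[1], Fst[2], Fst[3], lower.tail = FALSE),
               n = nrow(df), stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adjusted < 0.05
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write an evaluation report as JSON (plus a per-subject TSV)
#'
#' The JSON report is deterministic for a given configuration and seed:
#' it carries no timestamps.
#'
#' @param report an \code{evaluation_report}.
#' @param path output JSON path.
#' @param predictions_path optional TSV path for per-subject predictions.
#' @export
write_report <- function(report, path, predictions_path = NULL) {
  body <- list(
    n = report$n, n_folds = report$n_folds,
    mae = report$mae, pearson_r = report$pearson_r, accuracy = report$accuracy,
    sex_levels = report$sex_levels,
    site_anova = report$site_anova,
    bins = report$bins,
    site_table = report$site_table,
    config = unclass(report$config),
    predictions = report$predictions)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(predictions_path)) {
    out <- report$predictions
    for (cn in names(out)) if (is.numeric(out[[cn]])) out[[cn]] <- fmt_num(out[[cn]])
    utils::write.table(out, predictions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: n=%d, %d folds\n", x$n, x$n_folds))
  cat(sprintf("  age:  MAE = %.3f y, Pearson r = %.3f\n", x$mae, x$pearson_r))
  cat(sprintf("  sex:  accuracy = %.1f%%\n", 100 * x$accuracy))
  if (!is.null(x$site_anova) && is.finite(x$site_anova$F))
    cat(sprintf("  site ANOVA: F(%d,%d) = %.2f, p = %.3g\n",
                x$site_anova$df1, x$site_anova$df2, x$site_anova$F, x$site_anova$p))
  invisible(x)
}
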