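#' Fit the full supervised NPE model on a cohort
#'
#' Runs, per metric: optional global-scale correction, mean-centring +
#' SVD reduction, supervised neighbour-graph construction (image and age
#' similarity, sex-match and site-mismatch masks), locally linear
#' reconstruction weights, the NPE eigenproblem, and the age/sex axis
#' rotation.  Per-metric coordinates are concatenated and used to train
#' the GP age regressor and LDA sex classifier.  Every statistic is
#' fitted on the supplied subjects only, so the function can be applied
#' per training fold without leakage.
#'
#' @param table a \code{subject_table}.
#' @param matrices named list of \code{metric_matrix} objects in the same
#'   subject order as \code{table} (use \code{join_cohort} first).
#' @param config an \code{npe_config}.
#' @param seed seed for the GP restarts; defaults to
#'   \code{config$random_seed}.
#' @return object of class \code{npe_fit}.
#' @export
npe_fit <- function(table, matrices, config = npe_config(), seed = NULL) {
  seed <- seed %||% config$random_seed
  keep <- intersect(METRICS, names(matrices))
  if (!length(keep)) stopf("matrices must be named by metric (volume/thickness/area)")
  matrices <- matrices[keep]
  for (m in matrices) {
    if (!identical(m$subjects, table$subject_id))
      stopf("%s matrix subject order differs from table; run join_cohort() first", m$metric)
  }
  age <- table$age
  sx <- sex_code(table)
  a_sim <- age_similarity(table, config$age_bandwidth)
  fits <- list()
  blocks <- list()
  for (m in matrices) {
    scale <- NULL
    mm <- m
    if (config$global_scale_correction) {
      scale <- fit_scale_correction(mm, table, method = config$scale_method)
      mm <- apply_scale_correction(mm, scale, table)
    }
    red <- fit_svd(mm, config$variance_retained)
    Xr <- transform_svd(mm, red)
    rownames(Xr) <- table$subject_id
    A <- image_similarity(Xr, config$image_bandwidth)
    graph <- tryCatch({
      Am <- apply_constraints(A, table, config$use_site_constraint)
      combine_and_select(Am, a_sim, config$k, config$combination_mode, config$lambda)
    }, error = function(e) {
      if (config$use_site_constraint && grepl("no eligible neighbours", conditionMessage(e))) {
        warnf("%s: site constraint starved a neighbour row; retrying without it", m$metric)
        Am <- apply_constraints(A, table, use_site = FALSE)
        combine_and_select(Am, a_sim, config$k, config$combination_mode, config$lambda)
      } else stop(e)
    })
    W <- compute_reconstruction_weights(Xr, graph, config$ridge)
    mod <- fit_npe(Xr, W, config$d)
    mod$svd <- red
    rot <- NULL
    Yb <- mod$Y
    if (config$rotate_axes && config$d >= 2L) {
      rot <- tryCatch(fit_axis_rotation(mod$Y, age, sx), error = function(e) NULL)
      if (!is.null(rot)) Yb <- apply_rotation(mod$Y, rot)
    }
    mod$rotation <- rot
    rownames(Yb) <- table$subject_id
    fits[[m$metric]] <- list(scale = scale, svd = red, npe = mod, rotation = rot)
    blocks[[m$metric]] <- Yb
  }
  coords <- do.call(cbind, lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]; colnames(b) <- paste0(nm, ".", seq_len(ncol(b))); b
  }))
  rownames(coords) <- table$subject_id
  joint <- concatenate_and_pca(blocks)
  gp_keep <- apply(coords, 2L, stats::sd) > 1e-12
  gp <- gp_fit(coords[, gp_keep, drop = FALSE], age,
               restarts = config$gp_restarts, seed = seed)
  lda <- lda_fit(coords, factor(table$sex, levels = attr(table, "sex_levels")))
  structure(list(metrics = fits, coords = coords, joint = joint,
                 gp = gp, gp_keep = gp_keep, lda = lda,
                 sex_levels = attr(table, "sex_levels"),
                 config = config, subjects = table$subject_id),
            class = "npe_fit")
}

#' Project new subjects through a fitted model and predict age and sex
#'
#' @param model an \code{npe_fit}.
#' @param matrices named list of \code{metric_matrix} objects covering the
#'   model's metrics, identical subject order across metrics.
#' @param table optional \code{subject_table} for the new subjects;
#'   required when the model uses global-scale correction (it supplies the
#'   covariates).
#' @return list with \code{coords} (m x 3d), \code{age} (predicted years),
#'   \code{sex} (predicted labels), \code{posterior} (class
#'   probabilities).
#' @export
npe_predict <- function(model, matrices, table = NULL) {
  keep <- names(model$metrics)
  miss <- setdiff(keep, names(matrices))
  if (length(miss)) stopf("missing metric matrices: %s", paste(miss, collapse = ", "))
  subj <- matrices[[keep[1]]]$subjects
  blocks <- list()
  for (nm in keep) {
    m <- matrices[[nm]]
    if (!identical(m$subjects, subj)) stopf("subject order differs between metric matrices")
    fit <- model$metrics[[nm]]
    if (!is.null(fit$scale)) {
      if (is.null(table)) stopf("model uses scale correction; supply the subject table")
      if (!identical(table$subject_id, subj)) stopf("table order differs from matrices")
      m <- apply_scale_correction(m, fit$scale, table)
    }
    Yb <- transform_npe(m, fit$npe)
    if (!is.null(fit$rotation)) Yb <- apply_rotation(Yb, fit$rotation)
    colnames(Yb) <- paste0(nm, ".", seq_len(ncol(Yb)))
    blocks[[nm]] <- Yb
  }
  coords <- do.call(cbind, blocks)
  rownames(coords) <- subj
  age <- gp_predict(model$gp, coords[, model$gp_keep, drop = FALSE])
  cls <- lda_predict(model$lda, coords)
  list(coords = coords, age = age, sex = cls$labels, posterior = cls$posterior)
}

# Deterministic numeric fingerprint of every fitted (training-side)
# parameter; used by the leakage-guard tests.
fingerprint_fit <- function(model) {
  num <- function(x) if (is.null(x)) 0 else sum(as.numeric(x)) + sum(as.numeric(x)^2)
  out <- c()
  for (nm in names(model$metrics)) {
    f <- model$metrics[[nm]]
    out <- c(out,
             num(f$svd$mean), num(f$svd$basis), num(f$svd$singular_values),
             num(f$scale$slope), num(f$scale$intercept),
             num(f$npe$P), num(f$npe$eigenvalues), num(f$rotation$R))
  }
  gp <- model$gp
  out <- c(out, num(gp$ell2), num(gp$sf2), num(gp$sn2), num(gp$alpha), num(gp$ym))
  if (model$lda$kind == "mass") {
    out <- c(out, num(model$lda$fit$means), num(model$lda$fit$scaling),
             num(model$lda$fit$prior))
  } else {
    out <- c(out, num(model$lda$mu), num(model$lda$Sinv), num(model$lda$priors))
  }
  unname(out)
}

# ---- model archive (JSON, text-only) --------------------------------------

serialize_lda <- function(l) {
  if (l$kind == "mass") {
    f <- l$fit
    list(kind = "mass", keep = l$keep, levels = l$levels,
         prior = as.numeric(f$prior), counts = as.numeric(f$counts),
         means = pack_matrix(f$means), scaling = pack_matrix(as.matrix(f$scaling)),
         lev = f$lev, N = f$N, svd = as.numeric(f$svd))
  } else {
    list(kind = "shrinkage", keep = l$keep, levels = l$levels,
         mu = pack_matrix(l$mu), Sinv = pack_matrix(l$Sinv),
         priors = l$priors, shrinkage = l$shrinkage)
  }
}

deserialize_lda <- function(s) {
  if (s$kind == "mass") {
    fit <- structure(list(prior = stats::setNames(as.numeric(s$prior), s$lev),
                          counts = stats::setNames(as.numeric(s$counts), s$lev),
                          means = unpack_matrix(s$means),
                          scaling = unpack_matrix(s$scaling),
                          lev = as.character(s$lev), svd = as.numeric(s$svd),
                          N = as.integer(s$N), call = quote(lda())),
                     class = "lda")
    structure(list(kind = "mass", keep = as.logical(unlist(s$keep)),
                   levels = as.character(s$levels), fit = fit, shrinkage = 0),
              class = "sex_classifier")
  } else {
    structure(list(kind = "shrinkage", keep = as.logical(unlist(s$keep)),
                   levels = as.character(s$levels), mu = unpack_matrix(s$mu),
                   Sinv = unpack_matrix(s$Sinv), priors = as.numeric(unlist(s$priors)),
                   shrinkage = as.numeric(s$shrinkage)),
              class = "sex_classifier")
  }
}

#' Serialize a fitted model to a JSON archive
#'
#' The archive holds the configuration, per-metric SVD bases and
#' projections, rotations, scale corrections, predictor parameters and the
#' sex coding — everything \code{npe_predict} needs, in plain text at full
#' precision.
#'
#' @param model an \code{npe_fit}.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  pack_gp <- function(gp) {
    if (isTRUE(gp$constant)) {
      list(constant = TRUE, ym = gp$ym, xm = as.numeric(gp$xm), xs = as.numeric(gp$xs))
    } else {
      list(constant = FALSE, Xs = pack_matrix(gp$Xs), xm = as.numeric(gp$xm),
           xs = as.numeric(gp$xs), ym = gp$ym, ell2 = gp$ell2, sf2 = gp$sf2,
           sn2 = gp$sn2, alpha = as.numeric(gp$alpha))
    }
  }
  arc <- list(
    package = "npemorph", format = 1L,
    config = unclass(model$config),
    sex_levels = model$sex_levels,
    subjects = model$subjects,
    gp_keep = as.logical(model$gp_keep),
    gp = pack_gp(model$gp),
    lda = serialize_lda(model$lda),
    metrics = lapply(model$metrics, function(f) {
      list(
        scale = if (is.null(f$scale)) NULL else list(
          metric = f$scale$metric, covariate = f$scale$covariate,
          method = f$scale$method, intercept = as.numeric(f$scale$intercept),
          slope = as.numeric(f$scale$slope), covariate_mean = f$scale$covariate_mean,
          features = f$scale$features, n_fit = f$scale$n_fit),
        svd = list(mean = as.numeric(f$svd$mean), basis = pack_matrix(f$svd$basis),
                   singular_values = as.numeric(f$svd$singular_values),
                   variance_fraction_achieved = f$svd$variance_fraction_achieved,
                   rank = f$svd$rank, n_fit = f$svd$n_fit),
        P = pack_matrix(f$npe$P), Y = pack_matrix(f$npe$Y),
        eigenvalues = as.numeric(f$npe$eigenvalues), eps = f$npe$eps,
        rotation = if (is.null(f$rotation)) NULL else
          list(R = pack_matrix(f$rotation$R), achieved = as.numeric(f$rotation$achieved)))
    }))
  jsonlite::write_json(arc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a serialized model archive
#'
#' @param path archive path written by \code{write_model}.
#' @return an \code{npe_fit} (without the training coordinate cache).
#' @export
read_model <- function(path) {
  arc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  cfg <- do.call(npe_config, arc$config[intersect(names(arc$config),
                                                  names(formals(npe_config)))])
  gp <- if (isTRUE(arc$gp$constant)) {
    structure(list(constant = TRUE, ym = arc$gp$ym, xm = as.numeric(arc$gp$xm),
                   xs = as.numeric(arc$gp$xs)), class = "gp_model")
  } else {
    structure(list(constant = FALSE, Xs = unpack_matrix(arc$gp$Xs),
                   xm = as.numeric(arc$gp$xm), xs = as.numeric(arc$gp$xs),
                   ym = arc$gp$ym, ell2 = arc$gp$ell2, sf2 = arc$gp$sf2,
                   sn2 = arc$gp$sn2, alpha = as.numeric(arc$gp$alpha)),
              class = "gp_model")
  }
  metrics <- lapply(arc$metrics, function(f) {
    red <- structure(list(mean = as.numeric(f$svd$mean), basis = unpack_matrix(f$svd$basis),
                          singular_values = as.numeric(f$svd$singular_values),
                          variance_fraction_achieved = f$svd$variance_fraction_achieved,
                          rank = f$svd$rank, n_fit = f$svd$n_fit),
                     class = "svd_reduction")
    npe <- structure(list(P = unpack_matrix(f$P), Y = unpack_matrix(f$Y),
                          eigenvalues = as.numeric(f$eigenvalues), eps = f$eps,
                          svd = red, rotation = NULL),
                     class = "npe_model")
    rot <- if (!is.null(f$rotation)) {
      structure(list(R = unpack_matrix(f$rotation$R),
                     achieved = as.numeric(f$rotation$achieved)),
                class = "axis_rotation")
    }
    npe$rotation <- rot
    scale <- if (!is.null(f$scale)) {
      structure(list(metric = f$scale$metric, covariate = f$scale$covariate,
                     method = f$scale$method,
                     intercept = as.numeric(f$scale$intercept),
                     slope = as.numeric(f$scale$slope),
                     covariate_mean = f$scale$covariate_mean,
                     features = as.character(unlist(f$scale$features)),
                     n_fit = f$scale$n_fit),
                class = "scale_correction")
    }
    list(scale = scale, svd = red, npe = npe, rotation = rot)
  })
  structure(list(metrics = metrics, coords = NULL, joint = NULL,
                 gp = gp, gp_keep = as.logical(unlist(arc$gp_keep)),
                 lda = deserialize_lda(arc$lda),
                 sex_levels = as.character(unlist(arc$sex_levels)),
                 config = cfg, subjects = as.character(unlist(arc$subjects))),
            class = "npe_fit")
}

#' @export
print.npe_fit <- function(x, ...) {
  cat(sprintf("npe_fit: metrics [%s], %d training subjects, d=%d per metric\n",
              paste(names(x$metrics), collapse = ", "),
              length(x$subjects), x$config$d))
  invisible(x)
}
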