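NTCB_SCORES <- c("flanker", "attention", "picture_sequence_memory",
                 "list_sorting", "picture_vocabulary", "reading",
                 "card_sorting", "pattern_comparison")

#' Specification for a synthetic multi-site developmental cohort
#'
#' The generator emulates the statistical structure of a developmental
#' morphometry cohort without any image geometry: per metric, each
#' subject's feature row is
#' \deqn{x_i = g_i (\mu + age_i \beta_{age} u_{age} + s_i \beta_{sex}
#'   u_{sex} + \sum_l z_{il} v_l) + \delta_{site(i)} + \epsilon}
#' with spatially smooth pattern vectors (moving-average over the feature
#' index standing in for the smoothed maps), a multiplicative global
#' scale \eqn{g_i = 1 + \gamma_{age}(age_i - 12) + \gamma_{sex} s_i +
#' \epsilon_g} from which the global covariates (icv, total_area,
#' mean_thickness) are derived, additive site offsets, latent nuisance
#' components, and i.i.d. Gaussian residual noise.  Sex enters the global
#' scale for volume and area (male brains are larger throughout
#' development) but the spatial pattern for thickness, so global-scale
#' correction removes most sex signal from volume/area while sparing
#' thickness.
#'
#' Cognitive scores depend on age, sex and socioeconomic status plus
#' independent noise — null association with the brain patterns by
#' default.
#'
#' @param n_subjects cohort size.
#' @param age_range years, default 3-21.
#' @param sex_balance probability of the second sex level ("M").
#' @param sex_levels declared coding, first level coded -1.
#' @param n_sites number of acquisition sites.
#' @param n_features named feature counts per metric.
#' @param smooth_window moving-average window (features) for pattern
#'   smoothness.
#' @param beta_age,beta_sex per-metric pattern effect sizes (feature units
#'   per year / per sex code, along unit-norm patterns).
#' @param gamma_age,gamma_sex,sigma_g global-scale model coefficients
#'   (per year, per sex code) and residual SD.
#' @param site_sd per-feature SD of the additive site offset patterns.
#' @param sigma_noise residual noise SD per feature.
#' @param n_latent,latent_scale nuisance components: count and pattern
#'   norm.
#' @param baseline,baseline_sd per-metric mean level and the SD of the
#'   smooth baseline pattern around it.
#' @param icv_scale,area_scale,thickness_scale map the latent scale g to
#'   covariate units (mm^3, mm^2, mm).
#' @param cog_coef list of coefficients (age, sex, ses) shared by all
#'   cognitive scores; \code{cog_noise_sd} their independent noise.
#' @param cog_noise_sd noise SD of cognitive scores.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class \code{generator_spec}.
#' @export
generator_spec <- function(n_subjects = 600,
                           age_range = c(3, 21),
                           sex_balance = 0.5,
                           sex_levels = c("F", "M"),
                           n_sites = 4,
                           n_features = c(volume = 400, thickness = 400, area = 400),
                           smooth_window = 15,
                           beta_age = c(volume = 0.18, thickness = 0.18, area = 0.18),
                           beta_sex = c(volume = 0.05, thickness = 0.27, area = 0.05),
                           gamma_age = 0.01,
                           gamma_sex = c(volume = 0.02, thickness = 0, area = 0.02),
                           sigma_g = 0.02,
                           site_sd = 0.035,
                           sigma_noise = 0.1,
                           n_latent = 4,
                           latent_scale = 0.35,
                           baseline = c(volume = 0, thickness = 2.5, area = 1),
                           baseline_sd = 0.5,
                           icv_scale = 1.4e6,
                           area_scale = 1.8e5,
                           thickness_scale = 2.5,
                           cog_coef = list(age = 0.5, sex = 0.3, ses = 0.4),
                           cog_noise_sd = 1,
                           seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
               sex_balance = sex_balance, sex_levels = as.character(sex_levels),
               n_sites = as.integer(n_sites),
               n_features = full_metric_vec(n_features),
               smooth_window = as.integer(smooth_window),
               beta_age = full_metric_vec(beta_age),
               beta_sex = full_metric_vec(beta_sex),
               gamma_age = gamma_age, gamma_sex = full_metric_vec(gamma_sex),
               sigma_g = sigma_g, site_sd = site_sd, sigma_noise = sigma_noise,
               n_latent = as.integer(n_latent), latent_scale = latent_scale,
               baseline = full_metric_vec(baseline), baseline_sd = baseline_sd,
               icv_scale = icv_scale, area_scale = area_scale,
               thickness_scale = thickness_scale,
               cog_coef = cog_coef, cog_noise_sd = cog_noise_sd,
               seed = as.integer(seed))
  validate_generator_spec(spec)
  structure(spec, class = "generator_spec")
}

full_metric_vec <- function(v) {
  if (is.null(names(v))) names(v) <- METRICS[seq_along(v)]
  out <- v[METRICS]
  names(out) <- METRICS
  if (anyNA(out)) stopf("per-metric vector must name volume, thickness and area")
  out
}

validate_generator_spec <- function(spec) {
  if (spec$n_subjects < 4L) stopf("n_subjects must be >= 4")
  if (diff(spec$age_range) <= 0) stopf("age_range must be increasing")
  if (spec$age_range[1] <= 0) stopf("ages must be positive")
  if (!(spec$sex_balance > 0 && spec$sex_balance < 1)) stopf("sex_balance must be in (0,1)")
  if (length(spec$sex_levels) != 2L) stopf("sex_levels must have 2 entries")
  if (spec$n_sites < 1L) stopf("n_sites must be >= 1")
  if (any(spec$n_features < 2)) stopf("each metric needs >= 2 features")
  if (any(c(spec$sigma_g, spec$site_sd, spec$sigma_noise, spec$cog_noise_sd) < 0))
    stopf("all noise scales must be >= 0")
  if (spec$n_latent < 0L) stopf("n_latent must be >= 0")
  invisible(spec)
}

#' The committed benchmark cohort specification
#'
#' The default generator parameters ARE the benchmark: n = 600 subjects,
#' three metrics of 400 features, 4 sites, ages 3-21, and noise calibrated
#' by construction so that an oracle linear model reading the true latent
#' scores achieves an age MAE around 0.5 years and the Bayes sex accuracy
#' is around 97\%.
#'
#' @param seed integer seed.
#' @return a \code{generator_spec}.
#' @export
default_recovery_spec <- function(seed = 1L) generator_spec(seed = seed)

#' Serialize / read a generator spec as JSON
#' @param spec a \code{generator_spec}.
#' @param path file path.
#' @export
write_generator_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$cog_coef <- as.list(raw$cog_coef)
  do.call(generator_spec, raw[intersect(names(raw), names(formals(generator_spec)))])
}

# Smooth unit-variance pattern over the feature index: white noise passed
# through a circular moving average, then rescaled to SD 1.
smooth_pattern <- function(D, window) {
  x <- stats::rnorm(D)
  # short feature axes get a narrower window (a circular average over the
  # whole axis would be constant)
  window <- max(1L, min(window, D %/% 2L))
  if (window > 1L) {
    x <- as.numeric(stats::filter(x, rep(1 / window, window), circular = TRUE))
  }
  x / stats::sd(x)
}

unit_pattern <- function(D, window) {
  p <- smooth_pattern(D, window)
  p / sqrt(sum(p^2))
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec a \code{generator_spec}.
#' @return list with \code{table} (a \code{subject_table}),
#'   \code{matrices} (named list of three \code{metric_matrix} blocks),
#'   \code{truth} (pattern vectors, latent scores, true global scales and
#'   data-derived oracle scores), and the \code{spec}.
#' @export
generate_cohort <- function(spec) {
  validate_generator_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sx <- ifelse(stats::runif(n) < spec$sex_balance, 1, -1)
    if (length(unique(sx)) == 1L) sx[1:2] <- c(-1, 1)  # degenerate tiny draws
    site <- sample(seq_len(spec$n_sites), n, replace = TRUE)
    ses <- stats::rnorm(n)
    gaf <- stats::rnorm(n)
    eps_g <- stats::rnorm(n, 0, spec$sigma_g)
    age_c <- age - mean(spec$age_range)

    g <- sapply(METRICS, function(m) {
      1 + spec$gamma_age * age_c + spec$gamma_sex[[m]] * sx + eps_g
    })
    if (any(g <= 0)) stopf("global scale model produced non-positive scales; reduce gamma/sigma_g")

    z <- if (spec$n_latent > 0) matrix(stats::rnorm(n * spec$n_latent), n) else
      matrix(0, n, 0)

    truth <- list(u_age = list(), u_sex = list(), v = list(), mu = list(),
                  site_offsets = list(), z = z, g = g,
                  oracle_age_scores = matrix(NA_real_, n, 3,
                                             dimnames = list(NULL, METRICS)),
                  oracle_sex_scores = matrix(NA_real_, n, 3,
                                             dimnames = list(NULL, METRICS)))
    ids <- sprintf("s%04d", seq_len(n))
    matrices <- list()
    for (m in METRICS) {
      D <- spec$n_features[[m]]
      u_age <- unit_pattern(D, spec$smooth_window)
      u_sex <- unit_pattern(D, spec$smooth_window)
      mu <- spec$baseline[[m]] + spec$baseline_sd * smooth_pattern(D, spec$smooth_window)
      V <- if (spec$n_latent > 0) {
        vapply(seq_len(spec$n_latent),
               function(l) spec$latent_scale * unit_pattern(D, spec$smooth_window),
               numeric(D))
      } else matrix(0, D, 0)
      site_off <- vapply(seq_len(spec$n_sites),
                         function(s) spec$site_sd * smooth_pattern(D, spec$smooth_window),
                         numeric(D))
      signal <- matrix(mu, n, D, byrow = TRUE) +
        outer(age * spec$beta_age[[m]], u_age) +
        outer(sx * spec$beta_sex[[m]], u_sex) +
        z %*% t(V)
      X <- signal * g[, m] + t(site_off)[site, , drop = FALSE] +
        matrix(stats::rnorm(n * D, 0, spec$sigma_noise), n, D)
      matrices[[m]] <- metric_matrix(m, X, ids)
      truth$u_age[[m]] <- u_age
      truth$u_sex[[m]] <- u_sex
      truth$v[[m]] <- V
      truth$mu[[m]] <- mu
      truth$site_offsets[[m]] <- site_off
      descaled <- sweep(X / g[, m], 2L, mu)
      truth$oracle_age_scores[, m] <- descaled %*% u_age
      truth$oracle_sex_scores[, m] <- descaled %*% u_sex
    }
    cog <- sapply(NTCB_SCORES, function(s) {
      spec$cog_coef$age * scale(age)[, 1] + spec$cog_coef$sex * sx +
        spec$cog_coef$ses * ses + stats::rnorm(n, 0, spec$cog_noise_sd)
    })
    df <- data.frame(subject_id = ids, age = age,
                     sex = ifelse(sx < 0, spec$sex_levels[1], spec$sex_levels[2]),
                     site = paste0("site", site),
                     icv = spec$icv_scale * g[, "volume"],
                     total_area = spec$area_scale * g[, "area"],
                     mean_thickness = spec$thickness_scale * g[, "thickness"],
                     ses = ses, gaf = gaf,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(cog))
    table <- subject_table(df, sex_levels = spec$sex_levels)
    list(table = table, matrices = matrices, truth = truth, spec = spec)
  })
}

#' Write a generated cohort to disk in the canonical text formats
#'
#' Writes \code{subjects.tsv}, one \code{<metric>.tsv} per metric, the
#' spec as \code{spec.json} and the ground truth as \code{truth.json}.
#'
#' @param cohort output of \code{generate_cohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_subject_table(cohort$table, file.path(dir, "subjects.tsv"))
  for (m in names(cohort$matrices)) {
    write_metric_matrix(cohort$matrices[[m]], file.path(dir, paste0(m, ".tsv")))
  }
  write_generator_spec(cohort$spec, file.path(dir, "spec.json"))
  tr <- cohort$truth
  arc <- list(u_age = tr$u_age, u_sex = tr$u_sex,
              mu = tr$mu, g = pack_matrix(tr$g), z = pack_matrix(tr$z),
              oracle_age_scores = pack_matrix(tr$oracle_age_scores),
              oracle_sex_scores = pack_matrix(tr$oracle_sex_scores))
  jsonlite::write_json(arc, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
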