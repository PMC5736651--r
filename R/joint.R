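#' Orthogonal rotation aligning manifold axes with age and sex
#'
#' Finds a d x d orthogonal matrix R such that the first rotated axis has
#' maximal absolute correlation with age and the second has maximal
#' absolute correlation with sex subject to orthogonality to the first
#' (the sex least-squares direction is projected off axis 1 and
#' renormalized).  Remaining columns complete an orthonormal basis by
#' Gram-Schmidt over the canonical axes, smallest index first.  Signs are
#' fixed so both target correlations are positive.
#'
#' The age direction is exact: the unit vector maximizing |corr(Y r, age)|
#' is proportional to the least-squares coefficients of age on Y.
#'
#' @param Y n x d coordinate matrix, d >= 2.
#' @param age ages in years (non-constant).
#' @param sex -1/+1 sex codes (non-constant).
#' @return object of class \code{axis_rotation}: \code{R} and the achieved
#'   correlations on the fitting subjects.
#' @export
fit_axis_rotation <- function(Y, age, sex) {
  Y <- as.matrix(Y)
  d <- ncol(Y)
  if (d < 2L) stopf("axis rotation needs d >= 2")
  if (stats::sd(age) == 0) stopf("age is constant; rotation target undefined")
  if (stats::sd(sex) == 0) stopf("sex is constant; rotation target undefined")
  S <- stats::cov(Y)
  S <- S + diag(1e-12 * mean(diag(S)), d)
  b1 <- solve(S, stats::cov(Y, age))
  r1 <- b1 / sqrt(sum(b1^2))
  b2 <- solve(S, stats::cov(Y, sex))
  r2 <- b2 - sum(b2 * r1) * r1
  nr2 <- sqrt(sum(r2^2))
  if (nr2 < 1e-10 * sqrt(sum(b2^2)))
    stopf("sex direction is parallel to the age direction; rotation undefined")
  r2 <- r2 / nr2
  R <- cbind(as.vector(r1), as.vector(r2))
  for (j in seq_len(d)) {
    if (ncol(R) == d) break
    e <- numeric(d); e[j] <- 1
    u <- e - R %*% crossprod(R, e)
    nu <- sqrt(sum(u^2))
    if (nu > 1e-8) R <- cbind(R, u / nu)
  }
  if (ncol(R) != d) stopf("failed to complete an orthonormal basis")
  c1 <- stats::cor(Y %*% R[, 1], age)
  if (c1 < 0) { R[, 1] <- -R[, 1]; c1 <- -c1 }
  c2 <- stats::cor(Y %*% R[, 2], sex)
  if (c2 < 0) { R[, 2] <- -R[, 2]; c2 <- -c2 }
  structure(list(R = R, achieved = c(age = c1, sex = c2)),
            class = "axis_rotation")
}

#' Apply an axis rotation to coordinates
#'
#' @param Y n x d coordinates.
#' @param rotation an \code{axis_rotation}.
#' @return rotated coordinates \code{Y \%*\% R}.
#' @export
apply_rotation <- function(Y, rotation) {
  as.matrix(Y) %*% rotation$R
}

#' Concatenate per-metric coordinates and compute the joint PCA
#'
#' Assembles \code{Y_c = (Y_v, Y_t, Y_a)} (blocks ordered volume,
#' thickness, area; absent metrics are skipped) and computes PCA on the
#' column-centred concatenation, components sorted by variance with a
#' deterministic sign (largest-magnitude loading positive).
#'
#' @param blocks named list of n x d coordinate matrices, names among
#'   "volume", "thickness", "area"; identical subject (row) order, checked
#'   via row names when present.
#' @return object of class \code{joint_coordinates}: \code{Y_c},
#'   \code{scores}, \code{loadings}, \code{center}, \code{sdev},
#'   \code{block} labels mapping columns to metrics.
#' @export
concatenate_and_pca <- function(blocks) {
  keep <- intersect(METRICS, names(blocks))
  if (!length(keep)) stopf("no metric blocks supplied")
  blocks <- blocks[keep]
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1L) stopf("blocks have different numbers of subjects")
  rn <- lapply(blocks, rownames)
  rn <- rn[!vapply(rn, is.null, logical(1))]
  if (length(rn) > 1L && !all(vapply(rn[-1], identical, logical(1), rn[[1]])))
    stopf("subject order differs between metric blocks")
  labels <- rep(keep, vapply(blocks, ncol, integer(1)))
  Yc <- do.call(cbind, lapply(blocks, as.matrix))
  colnames(Yc) <- paste0(labels, ".", unlist(lapply(blocks, function(b) seq_len(ncol(b)))))
  if (length(rn)) rownames(Yc) <- rn[[1]]
  pc <- stats::prcomp(Yc, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(Y_c = Yc, scores = pc$x, loadings = pc$rotation,
                 center = pc$center, sdev = pc$sdev, block = labels),
            class = "joint_coordinates")
}

#' Export per-subject joint coordinates as a long table
#'
#' @param joint a \code{joint_coordinates}.
#' @param path optional TSV output path.
#' @return data frame (subject_id, block, axis, value).
#' @export
joint_coordinates_table <- function(joint, path = NULL) {
  Yc <- joint$Y_c
  ids <- rownames(Yc) %||% as.character(seq_len(nrow(Yc)))
  axis_within <- stats::ave(seq_along(joint$block), joint$block, FUN = seq_along)
  df <- do.call(rbind, lapply(seq_len(ncol(Yc)), function(jj) {
    data.frame(subject_id = ids, block = joint$block[jj], axis = axis_within[jj],
               value = Yc[, jj], stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    out <- df
    out$value <- fmt_num(out$value)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
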