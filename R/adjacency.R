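similarity_matrix <- function(values, bandwidth, kind) {
  structure(list(values = values, bandwidth = bandwidth, kind = kind),
            class = "similarity_matrix")
}

sim_values <- function(x) if (inherits(x, "similarity_matrix")) x$values else as.matrix(x)

#' Gaussian image-similarity matrix
#'
#' \eqn{A_{ij} = \exp(-\|x_i - x_j\|^2 / \sigma^2)} on the SVD-reduced
#' rows.  With \code{bandwidth = "auto"}, \eqn{\sigma^2} is the median of
#' the nonzero squared pairwise distances, so a pair at exactly the median
#' squared distance has similarity \eqn{e^{-1}}.
#'
#' @param Xr reduced rows (n x q), n >= 2.
#' @param bandwidth numeric sigma, or \code{"auto"} (median heuristic).
#' @return a \code{similarity_matrix} (symmetric, entries in [0, 1]).
#' @export
image_similarity <- function(Xr, bandwidth = "auto") {
  Xr <- as.matrix(Xr)
  if (nrow(Xr) < 2L) stopf("need at least 2 subjects")
  D2 <- as.matrix(stats::dist(Xr))^2
  if (identical(bandwidth, "auto")) {
    nz <- D2[upper.tri(D2)]
    nz <- nz[nz > 0]
    if (!length(nz))
      stopf("all rows identical: automatic image bandwidth undefined")
    sigma2 <- stats::median(nz)
  } else {
    sigma2 <- as.numeric(bandwidth)^2
    if (!is.finite(sigma2) || sigma2 <= 0) stopf("image bandwidth must be positive")
  }
  V <- exp(-D2 / sigma2)
  dimnames(V) <- list(rownames(Xr), rownames(Xr))
  similarity_matrix(V, sqrt(sigma2), "image")
}

#' Gaussian age-similarity matrix
#'
#' \eqn{a_{ij} = \exp(-(age_i - age_j)^2 / \tau^2)}.  With
#' \code{bandwidth = "auto"}, \eqn{\tau} is the median nonzero absolute
#' pairwise age difference.
#'
#' @param table a \code{subject_table}.
#' @param bandwidth numeric tau in years, or \code{"auto"}.
#' @return a \code{similarity_matrix}.
#' @export
age_similarity <- function(table, bandwidth = "auto") {
  age <- table$age
  Dage <- abs(outer(age, age, "-"))
  if (identical(bandwidth, "auto")) {
    nz <- Dage[upper.tri(Dage)]
    nz <- nz[nz > 0]
    if (!length(nz)) stopf("all ages equal: automatic age bandwidth undefined")
    tau <- stats::median(nz)
  } else {
    tau <- as.numeric(bandwidth)
    if (!is.finite(tau) || tau <= 0) stopf("age bandwidth must be positive")
  }
  V <- exp(-(Dage / tau)^2)
  dimnames(V) <- list(table$subject_id, table$subject_id)
  similarity_matrix(V, tau, "age")
}

#' Apply supervised constraints to an image-similarity matrix
#'
#' Zeroes entries between subjects of different sex (neighbours must be
#' sex-matched) and, when \code{use_site} is on, between subjects scanned
#' at the same site (neighbours must come from different scanners, which
#' discourages site-driven similarity).  The diagonal is zeroed: a subject
#' is never its own neighbour.
#'
#' @param A an image \code{similarity_matrix}.
#' @param table a \code{subject_table} in matching order.
#' @param use_site apply the site-mismatch constraint.
#' @return a \code{similarity_matrix} whose \code{eligible} attribute
#'   records the surviving (unmasked) pairs.
#' @export
apply_constraints <- function(A, table, use_site = TRUE) {
  V <- sim_values(A)
  n <- nrow(V)
  if (n != nrow(table)) stopf("similarity matrix and table sizes differ")
  eligible <- outer(table$sex, table$sex, "==")
  if (use_site) eligible <- eligible & outer(table$site, table$site, "!=")
  diag(eligible) <- FALSE
  V[!eligible] <- 0
  out <- similarity_matrix(V, if (inherits(A, "similarity_matrix")) A$bandwidth else NA_real_,
                           "image_masked")
  attr(out, "eligible") <- eligible
  attr(out, "masks") <- c(sex = TRUE, site = isTRUE(use_site))
  out
}

#' Combine similarities and select k nearest neighbours per subject
#'
#' The combined score is the elementwise product of masked image
#' similarity and age similarity (default), or the convex combination
#' \code{lambda * A + (1 - lambda) * a} with the image masks re-applied.
#' Per row, the k largest strictly-positive scores are selected; ties are
#' broken by smaller subject index.  Rows with fewer than k eligible
#' neighbours are flagged short rather than failing the run.
#'
#' @param A_masked output of \code{apply_constraints}.
#' @param a an age \code{similarity_matrix}.
#' @param k neighbours per subject (>= 1).
#' @param mode \code{"product"} or \code{"weighted_sum"}.
#' @param lambda image-similarity weight for \code{"weighted_sum"}.
#' @return object of class \code{neighbour_graph}: per-subject ordered
#'   neighbour indices and combined scores.
#' @export
combine_and_select <- function(A_masked, a, k, mode = c("product", "weighted_sum"),
                               lambda = 0.5) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  Av <- sim_values(A_masked)
  av <- sim_values(a)
  if (!all(dim(Av) == dim(av))) stopf("similarity matrices have different sizes")
  eligible <- attr(A_masked, "eligible")
  if (is.null(eligible)) {
    eligible <- matrix(TRUE, nrow(Av), ncol(Av))
    diag(eligible) <- FALSE
  }
  C <- switch(mode,
              product = Av * av,
              weighted_sum = {
                W <- lambda * Av + (1 - lambda) * av
                W[!eligible] <- 0   # masks re-applied to the sum
                W
              })
  diag(C) <- 0
  n <- nrow(C)
  ids <- rownames(Av) %||% as.character(seq_len(n))
  masks <- attr(A_masked, "masks") %||% c(sex = NA, site = NA)
  neighbours <- vector("list", n)
  scores <- vector("list", n)
  short <- logical(n)
  for (i in seq_len(n)) {
    cand <- which(C[i, ] > 0 & eligible[i, ])
    if (!length(cand)) {
      stopf("subject '%s' has no eligible neighbours under active masks (%s)",
            ids[i], paste(names(masks)[which(masks %in% TRUE)], collapse = " + "))
    }
    ord <- cand[order(-C[i, cand], cand)]  # descending score, smaller index on ties
    take <- seq_len(min(k, length(ord)))
    neighbours[[i]] <- ord[take]
    scores[[i]] <- C[i, ord[take]]
    short[i] <- length(ord) < k
  }
  if (any(short))
    warnf("%d subject(s) have fewer than k=%d eligible neighbours (flagged short)",
          sum(short), k)
  structure(list(neighbours = neighbours, scores = scores, short = short,
                 k = k, mode = mode, lambda = lambda,
                 masks = masks, subject_ids = ids),
            class = "neighbour_graph")
}

#' Export a neighbour graph as an edge list
#'
#' @param graph a \code{neighbour_graph}.
#' @param path optional TSV path; when given the edge list is written there.
#' @return data frame (subject_id, neighbour_id, rank, combined_score).
#' @export
neighbour_graph_edges <- function(graph, path = NULL) {
  ids <- graph$subject_ids
  df <- do.call(rbind, lapply(seq_along(graph$neighbours), function(i) {
    nb <- graph$neighbours[[i]]
    data.frame(subject_id = ids[i], neighbour_id = ids[nb],
               rank = seq_along(nb), combined_score = graph$scores[[i]],
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    out <- df
    out$combined_score <- fmt_num(out$combined_score)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
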