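METRICS <- c("volume", "thickness", "area")

#' Default global covariate column for a metric
#'
#' Tissue volume is corrected for intracranial volume, surface area for
#' total surface area, and cortical thickness for mean cortical thickness.
#'
#' @param metric one of "volume", "thickness", "area".
#' @return covariate column name in the subject table.
#' @export
default_covariate <- function(metric) {
  switch(match.arg(metric, METRICS),
         volume = "icv", thickness = "mean_thickness", area = "total_area")
}

#' Construct a metric matrix
#'
#' One subjects-by-features block of morphometric data (e.g. voxel-wise
#' log-Jacobian tissue volume, vertex-wise cortical thickness or area).
#' The high-dimensional regime (more features than subjects) is expected.
#'
#' @param metric one of "volume", "thickness", "area".
#' @param values numeric matrix, n_subjects x n_features; all finite.
#' @param subjects character vector of subject ids (row order).
#' @param features character vector of feature ids; defaults to existing
#'   column names or \code{f1..fD}.
#' @param global_covariate subject-table column used for global-scale
#'   correction of this metric; defaults per \code{default_covariate}.
#' @return object of class \code{metric_matrix}.
#' @export
metric_matrix <- function(metric, values, subjects, features = NULL,
                          global_covariate = NULL) {
  metric <- match.arg(metric, METRICS)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  subjects <- as.character(subjects)
  if (length(subjects) != nrow(values))
    stopf("subjects (%d) must match matrix rows (%d)", length(subjects), nrow(values))
  if (anyDuplicated(subjects)) stopf("duplicate subject ids in metric matrix")
  if (is.null(features)) features <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  features <- as.character(features)
  if (length(features) != ncol(values))
    stopf("features (%d) must match matrix columns (%d)", length(features), ncol(values))
  if (!all(is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stopf("non-finite value in %s matrix at (row %d, column %d) [subject %s, feature %s]",
          metric, idx[1], idx[2], subjects[idx[1]], features[idx[2]])
  }
  dimnames(values) <- list(subjects, features)
  structure(list(metric = metric, subjects = subjects, features = features,
                 values = values,
                 global_covariate = global_covariate %||% default_covariate(metric)),
            class = "metric_matrix")
}

#' Read a metric matrix from delimited text
#'
#' First column is \code{subject_id}, remaining columns are features.  If a
#' \code{subject_table} is supplied, rows are reordered to the table's
#' order; subjects present in only one of the two inputs are reported in
#' \code{attr(x, "join_report")} and excluded from the joined cohort.
#'
#' @param path file path (tab- or comma-delimited, detected from header).
#' @inheritParams metric_matrix
#' @param subjects optional \code{subject_table} to join against.
#' @param mask optional logical or integer vector selecting feature columns
#'   to retain (a feature-inclusion mask); recorded in the result.
#' @return a \code{metric_matrix}.
#' @export
read_metric_matrix <- function(path, metric, subjects = NULL, mask = NULL,
                               global_covariate = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (names(raw)[1] != "subject_id")
    stopf("first column must be 'subject_id' (got '%s')", names(raw)[1])
  ids <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (!all(is.finite(vals))) {
    idx <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stopf("non-finite value at (row %d, column %d) in %s", idx[1], idx[2], path)
  }
  feats <- colnames(vals)
  if (!is.null(mask)) {
    vals <- vals[, mask, drop = FALSE]
    feats <- colnames(vals)
  }
  m <- metric_matrix(metric, vals, ids, feats, global_covariate = global_covariate)
  attr(m, "mask") <- mask
  if (!is.null(subjects)) m <- join_metric(m, subjects)
  m
}

# Reorder a metric matrix to subject-table order, dropping (and reporting)
# subjects present on only one side.  Order-stable and idempotent.
join_metric <- function(m, table) {
  common <- intersect(table$subject_id, m$subjects)
  if (!length(common)) stopf("no subjects shared between table and %s matrix", m$metric)
  only_table <- setdiff(table$subject_id, m$subjects)
  only_matrix <- setdiff(m$subjects, table$subject_id)
  ord <- table$subject_id[table$subject_id %in% common]
  out <- metric_matrix(m$metric, m$values[match(ord, m$subjects), , drop = FALSE],
                       ord, m$features, global_covariate = m$global_covariate)
  attr(out, "join_report") <- list(only_in_table = only_table,
                                   only_in_matrix = only_matrix)
  if (length(only_table) || length(only_matrix))
    warnf("%s matrix join: %d subject(s) only in table, %d only in matrix; excluded",
          m$metric, length(only_table), length(only_matrix))
  out
}

#' Join a subject table with one or more metric matrices
#'
#' Restricts every input to the common subject set, in table order.
#'
#' @param table a \code{subject_table}.
#' @param matrices named list of \code{metric_matrix} objects.
#' @return list with elements \code{table}, \code{matrices},
#'   \code{dropped} (ids excluded from the joined cohort).
#' @export
join_cohort <- function(table, matrices) {
  common <- Reduce(intersect, c(list(table$subject_id),
                                lapply(matrices, `[[`, "subjects")))
  if (!length(common)) stopf("no subjects shared across all inputs")
  dropped <- setdiff(unique(c(table$subject_id,
                              unlist(lapply(matrices, `[[`, "subjects")))), common)
  tab <- table[table$subject_id %in% common, , drop = FALSE]
  tab <- subject_table(as.data.frame(tab), sex_levels = attr(table, "sex_levels"))
  mats <- lapply(matrices, function(m) {
    metric_matrix(m$metric, m$values[match(tab$subject_id, m$subjects), , drop = FALSE],
                  tab$subject_id, m$features, global_covariate = m$global_covariate)
  })
  list(table = tab, matrices = mats, dropped = dropped)
}

#' Write a metric matrix as canonical tab-delimited text
#'
#' @param m a \code{metric_matrix}.
#' @param path output path.
#' @export
write_metric_matrix <- function(m, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  cat(paste(c("subject_id", m$features), collapse = "\t"), "\n", file = con, sep = "")
  body <- vapply(seq_along(m$subjects), function(i) {
    paste(c(m$subjects[i], fmt_num(m$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat(sprintf("metric_matrix '%s': %d subjects x %d features (covariate: %s)\n",
              x$metric, nrow(x$values), ncol(x$values), x$global_covariate))
  invisible(x)
}
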