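#' Construct a validated subject table
#'
#' A subject table carries per-subject attributes driving supervision and
#' evaluation: a unique \code{subject_id}, \code{age} in years, a two-level
#' \code{sex} label, an acquisition \code{site}, and optional numeric
#' columns (global covariates \code{icv}, \code{total_area},
#' \code{mean_thickness}; cognitive scores; demographic covariates).
#'
#' Sex is coded internally as -1/+1 in the order of \code{sex_levels}
#' (first declared level -1), so the sign conventions of downstream axis
#' rotations are reproducible.
#'
#' @param df data frame with at least subject_id, age, sex, site.
#' @param sex_levels character(2): the declared sex coding, e.g.
#'   \code{c("F", "M")}.  \code{NULL} infers the two observed levels in
#'   sorted order.
#' @return object of class \code{subject_table} (a data frame) with
#'   attributes \code{sex_levels} and \code{load_report}.
#' @export
subject_table <- function(df, sex_levels = NULL) {
  req <- c("subject_id", "age", "sex", "site")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$sex <- as.character(df$sex)
  df$site <- as.character(df$site)
  df$age <- as.numeric(df$age)

  report <- list(dropped = data.frame(subject_id = character(), reason = character(),
                                      stringsAsFactors = FALSE),
                 incomplete_optional = character())

  # rows missing a required field are rejected, with a report
  bad <- is.na(df$subject_id) | df$subject_id == "" |
    is.na(df$age) | is.na(df$sex) | df$sex == "" |
    is.na(df$site)
  if (any(bad)) {
    report$dropped <- data.frame(
      subject_id = ifelse(is.na(df$subject_id), "<missing id>", df$subject_id)[bad],
      reason = "missing required field", stringsAsFactors = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stopf("no valid subjects remain after validation")

  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) stopf("duplicate subject_id: %s", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stopf("age must be finite and > 0 for all subjects")
  if (any(df$site == "")) stopf("site labels must be non-empty")

  obs <- sort(unique(df$sex))
  if (is.null(sex_levels)) sex_levels <- obs
  sex_levels <- as.character(sex_levels)
  if (length(sex_levels) != 2L)
    stopf("sex coding must declare exactly 2 levels (got %d)", length(sex_levels))
  unknown <- setdiff(obs, sex_levels)
  if (length(unknown))
    stopf("sex has more than 2 levels / undeclared level(s): %s",
          paste(unknown, collapse = ", "))

  # optional numeric columns must be fully present or are flagged absent
  opt <- setdiff(names(df), req)
  for (cn in opt) {
    v <- df[[cn]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      report$incomplete_optional <- c(report$incomplete_optional, cn)
      df[[cn]] <- NULL
    } else {
      df[[cn]] <- v
    }
  }
  if (length(report$incomplete_optional))
    warnf("optional column(s) with partial missingness flagged absent: %s",
          paste(report$incomplete_optional, collapse = ", "))

  rownames(df) <- NULL
  structure(df, sex_levels = sex_levels, load_report = report,
            class = c("subject_table", "data.frame"))
}

#' Read a subject metadata table from delimited text
#'
#' The delimiter (tab or comma) is detected from the header row.  Numeric
#' parsing is strict: a value such as \code{"12,3"} is an error, never a
#' silent coercion.
#'
#' @param path file path.
#' @inheritParams subject_table
#' @return a \code{subject_table}; dropped rows are listed in
#'   \code{attr(x, "load_report")}.
#' @export
read_subject_table <- function(path, sex_levels = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  req <- c("subject_id", "age", "sex", "site")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  raw$age <- parse_num_strict(raw$age, "age")
  for (cn in setdiff(names(raw), c("subject_id", "sex", "site", "age"))) {
    raw[[cn]] <- parse_num_strict(raw[[cn]], cn)
  }
  subject_table(raw, sex_levels = sex_levels)
}

#' Write a subject table as canonical tab-delimited text
#'
#' UTF-8, '.' decimal, full precision: a write/read round trip reproduces
#' values exactly.
#'
#' @param x a \code{subject_table}.
#' @param path output path.
#' @export
write_subject_table <- function(x, path) {
  out <- as.data.frame(x)
  for (cn in names(out)) if (is.numeric(out[[cn]])) out[[cn]] <- fmt_num(out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Sex codes (-1/+1) in declaration order
#'
#' @param table a \code{subject_table}.
#' @return numeric vector: -1 for the first declared level, +1 for the
#'   second.
#' @export
sex_code <- function(table) {
  lv <- attr(table, "sex_levels")
  ifelse(table$sex == lv[1], -1, 1)
}

#' @export
print.subject_table <- function(x, ...) {
  lv <- attr(x, "sex_levels")
  cat(sprintf("subject_table: %d subjects, %d sites, sex coding %s=-1 / %s=+1\n",
              nrow(x), length(unique(x$site)), lv[1], lv[2]))
  cat(sprintf("  age %.2f-%.2f y; columns: %s\n", min(x$age), max(x$age),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
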