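`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the previous RNG state so
#' that seeded internals never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Full-precision decimal rendering used by all text writers so that a
# write/read round trip reproduces doubles exactly.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Strict numeric parser: empty/NA -> NA, anything else that does not parse
# as a '.'-decimal number is a hard error (no locale-dependent coercion).
parse_num_strict <- function(x, what) {
  x <- trimws(x)
  miss <- is.na(x) | x == "" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    stopf("column '%s': value '%s' is not a valid number", what, x[which(bad)[1]])
  }
  out
}

# Serialize a matrix to a JSON-friendly list and back (row-major data).
pack_matrix <- function(m) {
  list(dim = dim(m), dimnames = dimnames(m), data = as.vector(t(m)))
}

unpack_matrix <- function(p) {
  d <- as.integer(unlist(p$dim))
  m <- matrix(as.numeric(unlist(p$data)), nrow = d[1], ncol = d[2], byrow = TRUE)
  dn <- p$dimnames
  if (!is.null(dn) && length(dn) == 2) {
    dimnames(m) <- lapply(dn, function(v) if (length(v)) as.character(unlist(v)) else NULL)
  }
  m
}

# Minimal structured logger: timestamped lines to a connection or stderr.
npe_log <- function(msg, ..., level = "INFO", file = NULL) {
  line <- sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(msg, ...))
  if (is.null(file)) message(line) else cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}
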