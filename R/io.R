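## File I/O: lifetime data files and critical-value table round trips.

#' Read lifetimes from a plain-text file
#'
#' Parses a file of positive lifetimes (whitespace-, newline- or
#' comma-separated; lines starting with `#` are comments) into a
#' [censored_sample()].  The file carries only the observed values;
#' censoring is metadata supplied through `n`.
#'
#' @param path file path.
#' @param n total items on test; defaults to the number of values read.
#' @param r optional observed count; must equal the number of values in the
#'   file (the file holds exactly the observed values) and is accepted for
#'   explicitness.
#' @return a [censored_sample()].
#' @examples
#' f <- tempfile(); writeLines(c("# demo", "1.0 2.0", "3.0"), f)
#' read_lifetimes(f, n = 5)
#' @export
read_lifetimes <- function(path, n = NULL, r = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  values <- numeric(0)
  for (i in which(keep)) {
    tokens <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    parsed <- suppressWarnings(as.numeric(tokens))
    if (any(is.na(parsed)))
      stop(sprintf("parse error at line %d of '%s': '%s'", i, path,
                   tokens[which(is.na(parsed))[1]]), call. = FALSE)
    values <- c(values, parsed)
  }
  if (!length(values)) stop("no data values in '", path, "'", call. = FALSE)
  if (!is.null(r) && r != length(values))
    stop(sprintf("r = %d but the file holds %d observed values", r,
                 length(values)), call. = FALSE)
  censored_sample(values, n = if (is.null(n)) length(values) else n)
}

#' Write or read a critical-value table
#'
#' `write_cv_table()` stores a [cr_critical_tables()] result as CSV
#' (columns `statistic`, `n`, `r`, `gamma`, `critical_value`) with a JSON
#' metadata sidecar (`<path>.meta.json`) carrying the case, generating
#' parameters, reps, seed and quantile convention.  `read_cv_table()`
#' restores both; if the sidecar is missing the table is loaded anyway with
#' a warning.
#'
#' @param table a `"cr_cv_table"` data frame.
#' @param path CSV file path.
#' @return `write_cv_table()` returns `path` invisibly; `read_cv_table()`
#'   returns the table with metadata attributes restored.
#' @examples
#' tab <- cr_critical_tables(sizes = data.frame(n = 5, r = 5),
#'                           case = "beta_known", reps = 100, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_cv_table(tab, f)
#' identical(read_cv_table(f)$critical_value, tab$critical_value)
#' @export
write_cv_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(as.data.frame(table)[c("statistic", "n", "r", "gamma",
                                   "critical_value")],
            path, row.names = FALSE, quote = FALSE)
  meta <- attributes(table)[c("case", "alpha", "beta", "reps", "seed",
                              "convention")]
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cv_table
#' @export
read_cv_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("statistic", "n", "r", "gamma", "critical_value")
  if (!all(need %in% names(tab)))
    stop("malformed critical-value CSV: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    warning("metadata sidecar missing for '", path, "'", call. = FALSE)
  }
  out <- structure(tab, class = c("cr_cv_table", "data.frame"))
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  out
}
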