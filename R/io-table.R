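#' Read and write feature-by-sample tables
#'
#' Tab-separated tables with a header row and feature ids in the first
#' column. Numeric values round-trip losslessly to at least 12 significant
#' digits (values are written with 15 significant digits). Ragged rows raise
#' a format error.
#'
#' @param path file path
#' @return for `readSampleTable`, a numeric matrix with feature row names and
#'   unique sample column names
#' @examples
#' m <- matrix(c(0.1234567890123, 2), 1, 2,
#'             dimnames = list("tx1", c("s1", "s2")))
#' f <- tempfile(fileext = ".tsv")
#' writeSampleTable(m, f)
#' stopifnot(identical(readSampleTable(f)["tx1", "s1"], 0.1234567890123))
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty table file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1)
    stop("ragged rows in ", path, ": line ",
         which(ncols != ncols[1])[1], " has ", ncols[ncols != ncols[1]][1],
         " fields, expected ", ncols[1])
  header <- parts[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) stop("duplicated column labels in ", path)
  body <- parts[-1]
  ids <- vapply(body, `[[`, "", 1L)
  vals <- vapply(body, function(p) as.numeric(p[-1]),
                 numeric(length(samples)))
  m <- if (length(body)) t(matrix(vals, nrow = length(samples)))
       else matrix(numeric(), 0, length(samples))
  dimnames(m) <- list(ids, samples)
  m
}

#' @rdname readSampleTable
#' @param table numeric matrix (or data.frame coercible to one) with row and
#'   column names; negative entries are rejected
#' @param idColumn header label for the feature-id column
#' @export
writeSampleTable <- function(table, path, idColumn = "feature_id") {
  m <- as.matrix(table)
  if (any(m < 0, na.rm = TRUE)) stop("sample tables must be non-negative")
  if (is.null(colnames(m))) stop("'table' must have column names")
  header <- paste(c(idColumn, colnames(m)), collapse = "\t")
  rows <- character(nrow(m))
  if (nrow(m)) {
    txt <- format(m, digits = 15, trim = TRUE, scientific = NA)
    txt[is.na(m)] <- "NA"
    rows <- paste(rownames(m), apply(txt, 1, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
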