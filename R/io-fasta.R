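#' Read a FASTA file
#'
#' Minimal strict FASTA reader for the references this pipeline consumes.
#' Sequences are uppercased and `U` is transliterated to `T`; record order is
#' preserved. Malformed input (sequence data before the first header, a
#' header with an empty id, or a record with no sequence) raises an error
#' naming the offending line.
#'
#' @param path file path
#' @return named character vector of sequences (names = record ids, the first
#'   whitespace-delimited token of each header)
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGU"), f)
#' readFasta(f)   # c(x = "ACGT")
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  ids <- character()
  seqs <- character()
  headerLine <- integer()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      id <- strsplit(trimws(substring(ln, 2)), "[[:space:]]+")[[1]][1]
      if (is.na(id) || !nzchar(id))
        stop("malformed FASTA header (empty id) at line ", i, " of ", path)
      ids <- c(ids, id)
      headerLine <- c(headerLine, i)
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      if (is.null(cur))
        stop("sequence data before any FASTA header at line ", i, " of ", path)
      chunk <- gsub("[[:space:]]", "", ln)
      if (grepl("[^A-Za-z*-]", chunk))
        stop("invalid sequence characters at line ", i, " of ", path)
      seqs[cur] <- paste0(seqs[cur], chunk)
    }
  }
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record '", ids[which(empty)[1]], "' (header at line ",
         headerLine[which(empty)[1]], ") of ", path)
  out <- toupper(chartr("Uu", "Tt", seqs))
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line-wrap width (default 60)
#' @return `path`, invisibly
#' @export
writeFasta <- function(seqs, path, width = 60) {
  if (length(seqs) && is.null(names(seqs)))
    stop("'seqs' must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
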