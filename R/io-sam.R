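.QUERY_OPS <- c("M", "I", "S", "=", "X")
.REF_OPS <- c("M", "D", "N", "=", "X")

# parse a vector of CIGAR strings into lists of (lengths, ops)
.parseCigars <- function(cigars) {
  toks <- regmatches(cigars, gregexpr("[0-9]+[MIDNSHP=X]", cigars))
  bad <- vapply(toks, function(t) sum(nchar(t)), 1L) != nchar(cigars)
  if (any(bad))
    stop("malformed CIGAR string: ", cigars[which(bad)[1]])
  lapply(toks, function(t) {
    list(len = as.integer(sub("[MIDNSHP=X]$", "", t)),
         op = substring(t, nchar(t), nchar(t)))
  })
}

.cigarWidth <- function(parsed, ops) {
  vapply(parsed, function(p) sum(p$len[p$op %in% ops]), 0L)
}

# width over a vector of CIGAR strings, parsing each distinct string once
.cigarWidths <- function(cigars, ops) {
  u <- unique(cigars)
  w <- .cigarWidth(.parseCigars(u), ops)
  w[match(cigars, u)]
}

#' Read alignment records from a text SAM file
#'
#' Parses the subset of SAM this pipeline relies on: headerless access to
#' primary alignments with CIGAR and (optionally) MD tags, in reference or
#' transcript coordinates. Unmapped (flag 0x4), secondary (0x100) and
#' supplementary (0x800) records are skipped. Reverse-strand records (0x10)
#' are rejected with an error: alignments in transcript/mature-tRNA space are
#' sense by construction.
#'
#' @param path SAM file path
#' @return data.frame with columns `read_id`, `flag`, `ref_id`, `ref_start`
#'   (1-based leftmost), `cigar`, `md` (NA when the tag is absent), `seq`
#'   (NA when "*") and `seq_len`
#' @export
readSamRecords <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  if (!length(body)) return(.emptySamFrame())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM record (fewer than 11 fields) at line ", body[which(nf < 11)[1]])
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  keep <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L
  fields <- fields[keep]
  flag <- flag[keep]
  if (!length(fields)) return(.emptySamFrame())
  readId <- vapply(fields, `[[`, "", 1L)
  rev <- bitwAnd(flag, 16L) != 0L
  if (any(rev))
    stop("reverse-strand alignment not supported in transcript space; read(s): ",
         paste(utils::head(readId[rev], 5), collapse = ", "))
  md <- vapply(fields, function(f) {
    tag <- grep("^MD:Z:", f[-(1:11)], value = TRUE)
    if (length(tag)) substring(tag[1], 6) else NA_character_
  }, "")
  seqs <- vapply(fields, `[[`, "", 10L)
  seqs[seqs == "*"] <- NA_character_
  cigar <- vapply(fields, `[[`, "", 6L)
  qlen <- .cigarWidths(cigar, .QUERY_OPS)
  badLen <- !is.na(seqs) & nchar(seqs) != qlen
  if (any(badLen))
    stop("CIGAR query length disagrees with SEQ for read(s): ",
         paste(utils::head(readId[badLen], 5), collapse = ", "))
  data.frame(
    read_id = readId,
    flag = flag,
    ref_id = vapply(fields, `[[`, "", 3L),
    ref_start = as.integer(vapply(fields, `[[`, "", 4L)),
    cigar = cigar,
    md = md,
    seq = seqs,
    seq_len = qlen,
    stringsAsFactors = FALSE)
}

.emptySamFrame <- function() {
  data.frame(read_id = character(), flag = integer(), ref_id = character(),
             ref_start = integer(), cigar = character(), md = character(),
             seq = character(), seq_len = integer(), stringsAsFactors = FALSE)
}

#' Write alignment records as text SAM
#'
#' Emits a minimal valid SAM file (HD and SQ header lines, then one record
#' per row) that round-trips through [readSamRecords()].
#'
#' @param records data.frame in the layout produced by [readSamRecords()]
#'   (`flag`, `seq` and `md` optional)
#' @param refLengths named integer vector of reference lengths for the SQ
#'   header lines
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSamRecords <- function(records, refLengths, path) {
  if (is.null(names(refLengths)))
    stop("'refLengths' must be named by reference id")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(refLengths), "\tLN:", refLengths))
  n <- nrow(records)
  flag <- if ("flag" %in% names(records)) records$flag else rep(0L, n)
  seqs <- if ("seq" %in% names(records)) records$seq else rep(NA_character_, n)
  seqs[is.na(seqs)] <- "*"
  lines <- paste(records$read_id, flag, records$ref_id, records$ref_start,
                 255L, records$cigar, "*", 0L, 0L, seqs, "*", sep = "\t")
  if ("md" %in% names(records)) {
    hasMd <- !is.na(records$md)
    lines[hasMd] <- paste0(lines[hasMd], "\tMD:Z:", records$md[hasMd])
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
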