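#' Collapse identical tRNA genes into single reference entries
#'
#' Genes with byte-identical mature sequences are merged into one entry (the
#' first gene encountered provides the retained identity); the returned
#' mapping records which original gene collapsed into which entry and the
#' multiplicity of each collapsed entry.
#'
#' @param reference a [TrnaReference-class]
#' @return list with elements `reference` (collapsed [TrnaReference-class])
#'   and `mapping` (data.frame `gene_id`, `collapsed_id`, `multiplicity`)
#' @export
collapseReference <- function(reference) {
  stopifnot(is(reference, "TrnaReference"))
  seqs <- refSequences(reference)
  anno <- refAnno(reference)
  first <- !duplicated(seqs)
  collapsedId <- anno$gene_id[first][match(seqs, seqs[first])]
  mult <- table(collapsedId)
  mapping <- data.frame(gene_id = anno$gene_id,
                        collapsed_id = collapsedId,
                        multiplicity = as.integer(mult[collapsedId]),
                        stringsAsFactors = FALSE)
  keep <- which(first)
  collapsed <- new("TrnaReference", sequences = seqs[keep],
                   anno = anno[keep, , drop = FALSE])
  list(reference = collapsed, mapping = mapping)
}

#' Count reads per isodecoder and per anticodon group
#'
#' Each retained (primary, mapped) read increments exactly one isodecoder;
#' isodecoder counts are summed over genes sharing an (amino acid, anticodon)
#' pair to give anticodon-level counts. RPM = count x 10^6 / total assigned
#' reads, so RPM sums to 10^6 over the reference whenever at least one read
#' is assigned. Reads referencing a gene absent from the reference are
#' counted under `unassigned` with a warning and excluded from RPM totals.
#'
#' @param reads alignment records ([readSamRecords()] layout)
#' @param reference the collapsed [TrnaReference-class]
#' @return list with data.frames `isodecoder` (`gene_id`, `anticodon_group`,
#'   `count`, `rpm`) and `anticodon` (`anticodon_group`, `count`, `rpm`),
#'   plus `unassigned` (count)
#' @export
countReads <- function(reads, reference) {
  stopifnot(is(reference, "TrnaReference"))
  ids <- geneIds(reference)
  known <- reads$ref_id %in% ids
  nUnassigned <- sum(!known)
  if (nUnassigned > 0)
    warning(nUnassigned, " read(s) reference unknown gene(s); counted as unassigned")
  counts <- table(factor(reads$ref_id[known], levels = ids))
  total <- sum(counts)
  rpm <- if (total > 0) as.numeric(counts) * 1e6 / total else rep(0, length(ids))
  anno <- refAnno(reference)
  group <- paste(anno$amino_acid, anno$anticodon, sep = "-")
  iso <- data.frame(gene_id = ids, anticodon_group = group,
                    count = as.integer(counts), rpm = rpm,
                    stringsAsFactors = FALSE)
  ac <- stats::aggregate(cbind(count, rpm) ~ anticodon_group, data = iso, sum)
  ac$count <- as.integer(ac$count)
  list(isodecoder = iso, anticodon = ac, unassigned = nUnassigned)
}

# Walk one CIGAR/MD pair and return the variant events it encodes.
# Returns list(mismatch, insertion, deletion (ref positions), refEnd) or
# throws a condition describing the inconsistency.
.alignmentEvents <- function(refStart, cigarParsed, md) {
  op <- cigarParsed$op
  len <- cigarParsed$len
  refTypes <- character(0)  # "M"/"D" per reference-consuming position
  insAnchor <- integer(0)
  refPos <- refStart
  for (k in seq_along(op)) {
    o <- op[k]
    if (o %in% c("M", "=", "X")) {
      refTypes <- c(refTypes, rep("M", len[k]))
      refPos <- refPos + len[k]
    } else if (o %in% c("D", "N")) {
      refTypes <- c(refTypes, rep("D", len[k]))
      refPos <- refPos + len[k]
    } else if (o == "I") {
      insAnchor <- c(insAnchor, rep(refPos - 1L, 1L))  # one event per I op
    }  # S/H/P consume no reference and carry no events here
  }
  refCoords <- seq.int(refStart, length.out = length(refTypes))
  toks <- regmatches(md, gregexpr("\\^[A-Za-z]+|[A-Za-z]|[0-9]+", md))[[1]]
  if (sum(nchar(toks)) != nchar(md))
    stop("unparseable MD tag '", md, "'", call. = FALSE)
  i <- 1L
  mism <- integer(0)
  dels <- integer(0)
  for (t in toks) {
    if (startsWith(t, "^")) {
      w <- nchar(t) - 1L
      idx <- seq.int(i, length.out = w)
      if (i + w - 1L > length(refTypes) || any(refTypes[idx] != "D"))
        stop("MD deletion does not match CIGAR", call. = FALSE)
      dels <- c(dels, refCoords[idx])
      i <- i + w
    } else if (grepl("^[0-9]+$", t)) {
      w <- as.integer(t)
      if (w > 0L) {
        idx <- seq.int(i, length.out = w)
        if (i + w - 1L > length(refTypes) || any(refTypes[idx] != "M"))
          stop("MD match run overruns CIGAR", call. = FALSE)
        i <- i + w
      }
    } else {
      if (i > length(refTypes) || refTypes[i] != "M")
        stop("MD mismatch does not fall on an aligned base", call. = FALSE)
      mism <- c(mism, refCoords[i])
      i <- i + 1L
    }
  }
  if (i != length(refTypes) + 1L)
    stop("MD covers ", i - 1L, " reference bases, CIGAR consumes ",
         length(refTypes), call. = FALSE)
  list(mismatch = mism, insertion = insAnchor, deletion = dels,
       refEnd = if (length(refCoords)) refCoords[length(refCoords)] else refStart - 1L)
}

#' Per-position variant profile of a tRNA gene
#'
#' Implements the four-way variant tabulation read out from CIGAR and MD
#' tags: mismatches are located by walking the MD tag against the
#' reference-consuming CIGAR operations; deletions are counted at each
#' deleted reference position; each insertion is assigned to the reference
#' position immediately 5' of the insertion point; and a read whose 5'-most
#' aligned position p is internal (p > 1) contributes one RT-stop event at
#' p. Fractions use the total reads assigned to the gene as denominator.
#' Reads with a missing MD tag raise an error; reads whose MD and CIGAR are
#' inconsistent are skipped, excluded from the denominator and reported in
#' the profile's QC slots.
#'
#' @param reads alignment records for this gene
#' @param refLength reference length L in nt
#' @param geneId gene id (defaults to the records' `ref_id`)
#' @return a [VariantProfile-class]
#' @export
variantProfile <- function(reads, refLength, geneId = NULL) {
  if (is.null(geneId))
    geneId <- if (nrow(reads)) reads$ref_id[1] else NA_character_
  if (nrow(reads) && !all(reads$ref_id == geneId))
    stop("reads for multiple genes passed to variantProfile")
  counts <- matrix(0, nrow = refLength, ncol = 4,
                   dimnames = list(NULL, c("mismatch", "insertion",
                                           "deletion", "stop")))
  if (nrow(reads) && anyNA(reads$md))
    stop("MD tag required for variant calling; missing for read(s): ",
         paste(utils::head(reads$read_id[is.na(reads$md)], 5), collapse = ", "))
  nTotal <- 0
  skipped <- character(0)
  if (nrow(reads)) {
    key <- paste(reads$ref_start, reads$cigar, reads$md, sep = "\r")
    firstIdx <- which(!duplicated(key))
    weight <- table(key)[key[firstIdx]]
    parsed <- .parseCigars(reads$cigar[firstIdx])
    for (j in seq_along(firstIdx)) {
      i <- firstIdx[j]
      w <- as.numeric(weight[j])
      evs <- tryCatch(
        .alignmentEvents(reads$ref_start[i], parsed[[j]], reads$md[i]),
        error = function(e) e)
      if (inherits(evs, "error")) {
        dup <- key == key[i]
        skipped <- c(skipped, reads$read_id[dup])
        next
      }
      nTotal <- nTotal + w
      for (p in evs$mismatch) counts[p, "mismatch"] <- counts[p, "mismatch"] + w
      for (p in evs$deletion) counts[p, "deletion"] <- counts[p, "deletion"] + w
      for (p in evs$insertion)
        if (p >= 1) counts[p, "insertion"] <- counts[p, "insertion"] + w
      if (reads$ref_start[i] > 1)
        counts[reads$ref_start[i], "stop"] <- counts[reads$ref_start[i], "stop"] + w
    }
  }
  new("VariantProfile", geneId = geneId, counts = counts, nTotal = nTotal,
      nSkipped = length(skipped), skippedIds = skipped)
}

#' Per-position read depth of a tRNA gene
#'
#' Depth d(p) counts reads whose alignment spans position p (positions
#' deleted from a read are still spanned by it).
#'
#' @param reads alignment records for one gene
#' @param refLength reference length in nt
#' @return numeric vector of length `refLength`
#' @export
depthProfile <- function(reads, refLength) {
  if (!nrow(reads)) return(numeric(refLength))
  refWidth <- .cigarWidths(reads$cigar, .REF_OPS)
  starts <- reads$ref_start
  ends <- pmin(starts + refWidth - 1L, refLength)
  add <- tabulate(starts, nbins = refLength + 1L)
  sub <- tabulate(ends + 1L, nbins = refLength + 1L)
  as.numeric(cumsum(add - sub)[seq_len(refLength)])
}

#' Between-condition per-position depth ratio
#'
#' Replicate depth vectors are averaged arithmetically within each condition
#' and the ratio of the averages is reported; positions with zero average
#' depth in the denominator condition are reported as `NA` (missing), never
#' infinite.
#'
#' @param profilesA,profilesB lists of equal-length depth vectors
#'   (replicates of condition A and condition B)
#' @return numeric vector R(p) = mean depth A / mean depth B
#' @export
ratioProfile <- function(profilesA, profilesB) {
  lens <- lengths(c(profilesA, profilesB))
  if (length(unique(lens)) != 1)
    stop("all replicate depth profiles must have the same length")
  a <- Reduce(`+`, profilesA) / length(profilesA)
  b <- Reduce(`+`, profilesB) / length(profilesB)
  r <- ifelse(b > 0, a / b, NA_real_)
  r
}
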