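#' Trimmed footprint coverage over a CDS
#'
#' Each read contributes +1 coverage over its aligned span minus `trim5`
#' leading and `trim3` trailing nucleotides (trimming smooths ribosome
#' density profiles). Reads whose trimmed span is empty are discarded and
#' counted; spans extending beyond the CDS are clipped to it with a warning
#' counter. The coverage is normalized to the CDS mean, so the normalized
#' density rho averages exactly 1 over the CDS whenever any coverage exists.
#'
#' @param reads alignment records in CDS coordinates for one transcript
#' @param cdsLen CDS length in nt
#' @param trim5,trim3 trim lengths in nt (defaults 9 and 12)
#' @return list: `coverage`, `rho` (= coverage / mean), `meanCov`,
#'   `readsAssigned` (reads assigned to the CDS before trim-discard),
#'   `nDiscarded`, `nClipped`
#' @export
trimAndCover <- function(reads, cdsLen, trim5 = 9, trim3 = 12) {
  nAssigned <- nrow(reads)
  cov <- numeric(cdsLen)
  nDiscarded <- 0L
  nClipped <- 0L
  if (nAssigned) {
    refWidth <- .cigarWidths(reads$cigar, .REF_OPS)
    start <- reads$ref_start
    end <- start + refWidth - 1L
    ts <- start + trim5
    te <- end - trim3
    nClipped <- sum(start < 1L | end > cdsLen)
    ts <- pmax(ts, 1L)
    te <- pmin(te, cdsLen)
    keep <- ts <= te
    nDiscarded <- sum(!keep)
    add <- tabulate(ts[keep], nbins = cdsLen + 1L)
    sub <- tabulate(te[keep] + 1L, nbins = cdsLen + 1L)
    cov <- cumsum(add - sub)[seq_len(cdsLen)]
  }
  m <- mean(cov)
  list(coverage = cov, rho = if (m > 0) cov / m else rep(NA_real_, cdsLen),
       meanCov = m, readsAssigned = nAssigned, nDiscarded = nDiscarded,
       nClipped = nClipped)
}

#' Trimmed coverage for a set of CDSs
#'
#' Splits alignment records by reference id and runs [trimAndCover()] per
#' CDS (CDSs without reads get zero coverage).
#'
#' @param reads alignment records in CDS coordinates
#' @param cdsLens named integer vector of CDS lengths
#' @inheritParams trimAndCover
#' @return named list of [trimAndCover()] results
#' @export
trimCoverageSet <- function(reads, cdsLens, trim5 = 9, trim3 = 12) {
  if (is.null(names(cdsLens))) stop("'cdsLens' must be named")
  byRef <- split(seq_len(nrow(reads)), reads$ref_id)
  out <- lapply(names(cdsLens), function(id) {
    idx <- byRef[[id]]
    sub <- if (is.null(idx)) reads[0, , drop = FALSE]
           else reads[idx, , drop = FALSE]
    trimAndCover(sub, cdsLens[[id]], trim5, trim3)
  })
  names(out) <- names(cdsLens)
  out
}

#' Filter CDSs by read density
#'
#' A CDS is retained iff its assigned (untrimmed) read count is at least
#' `minDensity` reads per codon, i.e. `readsAssigned / (cdsLen / 3) >=
#' minDensity`.
#'
#' @param covSet named list from [trimCoverageSet()]
#' @param cdsLens named integer vector of CDS lengths (nt)
#' @param minDensity minimum reads per codon (default 1)
#' @return character vector of retained CDS ids
#' @export
filterCds <- function(covSet, cdsLens, minDensity = 1) {
  ids <- names(covSet)
  reads <- vapply(covSet, `[[`, 0, "readsAssigned")
  codons <- cdsLens[ids] / 3
  ids[codons > 0 & reads / codons >= minDensity]
}

#' Windowed per-codon ribosome pause scores
#'
#' For every occurrence of a codon at CDS positions `[p, p + 2]`, the
#' normalized footprint density is summed over the 100-nt window formed by
#' the 50 nt upstream (`[p - 50, p - 1]`) and 50 nt downstream
#' (`[p + 3, p + 52]`) of the codon -- the codon itself is excluded, giving
#' exactly 100 density values. Occurrences whose window would extend past
#' the CDS are skipped (not zero-padded), so the footprint numerator and the
#' RNA-seq denominator are accumulated over identical supports. The pause
#' score of a codon is the ratio of the summed footprint density to the
#' summed RNA-seq density over all kept occurrences across all retained
#' CDSs (ratio of sums, robust to zero-coverage windows).
#'
#' @param fpCov,rnaCov named lists from [trimCoverageSet()] for footprints
#'   and matched RNA-seq (processed with identical trimming)
#' @param cdsSet named character vector of CDS sequences
#' @param cdsLens named integer vector of CDS lengths; defaults to
#'   `nchar(cdsSet)`
#' @param window flank width in nt (default 50)
#' @param minDensity reads-per-codon filter applied to both libraries; the
#'   intersection of retained CDSs is used
#' @return data.frame `codon` (RNA alphabet, 61 sense codons),
#'   `n_occurrences`, `numerator`, `denominator`, `score` (`NA` where the
#'   denominator is 0 or no occurrence was kept)
#' @export
pauseScores <- function(fpCov, rnaCov, cdsSet, cdsLens = NULL, window = 50,
                        minDensity = 1) {
  if (is.null(cdsLens))
    cdsLens <- stats::setNames(nchar(cdsSet), names(cdsSet))
  retained <- intersect(filterCds(fpCov, cdsLens, minDensity),
                        filterCds(rnaCov, cdsLens, minDensity))
  retained <- retained[vapply(fpCov[retained], `[[`, 0, "meanCov") > 0 &
                       vapply(rnaCov[retained], `[[`, 0, "meanCov") > 0]
  sense <- senseCodons("DNA")
  num <- den <- occ <- stats::setNames(numeric(length(sense)), sense)
  for (id in retained) {
    seqc <- cdsSet[[id]]
    L <- cdsLens[[id]]
    pos <- seq(1, L - 2, by = 3)
    codons <- substring(seqc, pos, pos + 2)
    ok <- pos - window >= 1 & pos + 2 + window <= L
    if (!any(ok)) next
    Sf <- c(0, cumsum(fpCov[[id]]$rho))
    Sr <- c(0, cumsum(rnaCov[[id]]$rho))
    p <- pos[ok]
    wf <- (Sf[p] - Sf[p - window]) + (Sf[p + 3 + window] - Sf[p + 3])
    wr <- (Sr[p] - Sr[p - window]) + (Sr[p + 3 + window] - Sr[p + 3])
    cc <- codons[ok]
    keep <- cc %in% sense
    if (!any(keep)) next
    nf <- tapply(wf[keep], cc[keep], sum)
    nr <- tapply(wr[keep], cc[keep], sum)
    no <- table(cc[keep])
    num[names(nf)] <- num[names(nf)] + nf
    den[names(nr)] <- den[names(nr)] + nr
    occ[names(no)] <- occ[names(no)] + no
  }
  score <- ifelse(occ > 0 & den > 0, num / den, NA_real_)
  data.frame(codon = codonToRna(sense), n_occurrences = as.integer(occ),
             numerator = unname(num), denominator = unname(den),
             score = unname(score), stringsAsFactors = FALSE)
}

#' Average pause scores over biological replicates
#'
#' Replicates are processed independently and averaged at the score level.
#'
#' @param tables list of data.frames from [pauseScores()]
#' @return data.frame `codon`, one `score_<i>` column per replicate, `mean`
#' @export
averagePauseScores <- function(tables) {
  stopifnot(length(tables) >= 1)
  out <- data.frame(codon = tables[[1]]$codon, stringsAsFactors = FALSE)
  for (i in seq_along(tables)) {
    if (!identical(tables[[i]]$codon, out$codon))
      stop("replicate pause tables must cover the same codons in order")
    out[[paste0("score_", i)]] <- tables[[i]]$score
  }
  out$mean <- rowMeans(as.matrix(out[, -1, drop = FALSE]))
  out
}

#' Ribosome density (translational-efficiency proxy)
#'
#' RD = footprint FPKM over the CDS divided by RNA-seq FPKM over the
#' transcript, with FPKM = reads x 10^9 / (length x total assigned reads).
#' RD is missing where the RNA FPKM is 0.
#'
#' @param fpCounts,rnaCounts named read-count vectors (footprints assigned
#'   to CDSs; RNA reads assigned to transcripts)
#' @param cdsLens,txLens named length vectors (nt)
#' @return data.frame `transcript_id`, `fp_fpkm`, `rna_fpkm`, `rd`
#' @export
ribosomeDensity <- function(fpCounts, rnaCounts, cdsLens, txLens) {
  ids <- intersect(names(fpCounts), names(rnaCounts))
  fpTotal <- sum(fpCounts)
  rnaTotal <- sum(rnaCounts)
  if (fpTotal <= 0 || rnaTotal <= 0) stop("total read counts must be positive")
  fpF <- fpCounts[ids] * 1e9 / (cdsLens[ids] * fpTotal)
  rnaF <- rnaCounts[ids] * 1e9 / (txLens[ids] * rnaTotal)
  data.frame(transcript_id = ids, fp_fpkm = unname(fpF),
             rna_fpkm = unname(rnaF),
             rd = unname(ifelse(rnaF > 0, fpF / rnaF, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Simulate ribosome footprints and matched RNA-seq over a CDS set
#'
#' Footprint 5' positions are sampled with probability proportional to the
#' dwell multiplier of the codon at the center of the read's trimmed span,
#' so slowly decoded codons accumulate footprint density. Matched RNA-seq
#' reads are sampled uniformly over the CDS regardless of dwell. All reads
#' are perfect-match (`<len>M`).
#'
#' @param cdsSet named character vector of CDS sequences
#' @param spec a [PauseSpec-class]
#' @param matchedRna also simulate the uniform RNA-seq library (default
#'   `TRUE`)
#' @return list with alignment-record data.frames `footprints` and `rna`
#'   (`NULL` when `matchedRna = FALSE`)
#' @export
simulateProfiling <- function(cdsSet, spec, matchedRna = TRUE) {
  stopifnot(is(spec, "PauseSpec"))
  len <- spec@readLength
  dwellOf <- function(codon) {
    d <- spec@dwell[codon]
    ifelse(is.na(d), 1, d)
  }
  centerOffset <- spec@trim5 + (len - spec@trim5 - spec@trim3 - 1) %/% 2
  n <- spec@readsPerTranscript
  fpStart <- rnaStart <- vector("list", length(cdsSet))
  withr::with_seed(spec@seed, {
    for (i in seq_along(cdsSet)) {
      L <- nchar(cdsSet[[i]])
      nPos <- L - len + 1L
      if (nPos < 1L) next
      starts <- seq_len(nPos)
      codonStart <- ((starts + centerOffset - 1L) %/% 3L) * 3L + 1L
      w <- dwellOf(substring(cdsSet[[i]], codonStart, codonStart + 2L))
      fpStart[[i]] <- sample(starts, n, replace = TRUE, prob = w)
      if (matchedRna) rnaStart[[i]] <- sample(starts, n, replace = TRUE)
    }
  })
  flat <- function(startList, tag) {
    kept <- which(!vapply(startList, is.null, TRUE))
    refId <- rep(names(cdsSet)[kept], vapply(startList[kept], length, 0L))
    data.frame(
      read_id = paste0(refId, ".", tag, sequence(vapply(startList[kept],
                                                        length, 0L))),
      flag = 0L, ref_id = refId, ref_start = unlist(startList[kept]),
      cigar = paste0(len, "M"), md = as.character(len), seq = NA_character_,
      seq_len = len, stringsAsFactors = FALSE)
  }
  list(footprints = flat(fpStart, "fp"),
       rna = if (matchedRna) flat(rnaStart, "rna") else NULL)
}
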