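#' @import methods
NULL

#' Collapsed mature tRNA reference
#'
#' Holds CCA-less mature tRNA sequences (5'->3', DNA alphabet) together with
#' their gene annotation: amino acid (3-letter code), anticodon and isodecoder
#' index. The triple (amino acid, anticodon, isodecoder index) is unique
#' within a reference, gene ids are unique, and sequence lengths are
#' constrained to the mature-tRNA range of 60--100 nt.
#'
#' @slot sequences named character vector of sequences (names = gene ids)
#' @slot anno data.frame with columns `gene_id`, `amino_acid`, `anticodon`,
#'   `isodecoder_index`
#' @export
setClass("TrnaReference",
  slots = c(sequences = "character", anno = "data.frame"))

setValidity("TrnaReference", function(object) {
  a <- object@anno
  s <- object@sequences
  msgs <- character()
  need <- c("gene_id", "amino_acid", "anticodon", "isodecoder_index")
  if (!all(need %in% names(a)))
    return(paste("anno must have columns", paste(need, collapse = ", ")))
  if (length(s) != nrow(a) || !identical(names(s), a$gene_id))
    msgs <- c(msgs, "sequence names must equal anno$gene_id, in order")
  if (anyDuplicated(a$gene_id))
    msgs <- c(msgs, "duplicated gene_id")
  if (any(grepl("[^ACGT]", s)))
    msgs <- c(msgs, "sequences must be over {A,C,G,T}")
  if (length(s) && (any(nchar(s) < 60L) || any(nchar(s) > 100L)))
    msgs <- c(msgs, "sequence lengths must lie in [60, 100]")
  key <- paste(a$amino_acid, a$anticodon, a$isodecoder_index)
  if (anyDuplicated(key))
    msgs <- c(msgs, "(amino_acid, anticodon, isodecoder_index) must be unique")
  if (nrow(a) && any(a$isodecoder_index < 1))
    msgs <- c(msgs, "isodecoder_index must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a tRNA reference
#'
#' @param aminoAcid character vector of 3-letter amino-acid codes (e.g. "Phe")
#' @param anticodon character vector of anticodon 3-mers (RNA or DNA alphabet;
#'   stored as given, uppercased)
#' @param isodecoderIndex positive integer vector
#' @param sequence mature CCA-less tRNA sequences, 5'->3'; `U` is
#'   transliterated to `T`
#' @param geneId optional explicit gene ids; defaults to
#'   `"<aminoAcid>-<anticodon>-<isodecoderIndex>"`
#' @return a [TrnaReference-class] object
#' @examples
#' ref <- TrnaReference("Phe", "GAA", 1,
#'   paste(rep("GCGGATTTAGCTCAGTTGGGAGAGCGCCAGACTGAAGATCTGGAGGTCCTGTG", 2),
#'         collapse = ""))
#' geneIds(ref)
#' @export
TrnaReference <- function(aminoAcid, anticodon, isodecoderIndex, sequence,
                          geneId = NULL) {
  sequence <- toupper(chartr("Uu", "Tt", sequence))
  anticodon <- toupper(anticodon)
  if (is.null(geneId))
    geneId <- paste(aminoAcid, anticodon, isodecoderIndex, sep = "-")
  anno <- data.frame(gene_id = as.character(geneId),
                     amino_acid = as.character(aminoAcid),
                     anticodon = anticodon,
                     isodecoder_index = as.integer(isodecoderIndex),
                     stringsAsFactors = FALSE)
  names(sequence) <- anno$gene_id
  new("TrnaReference", sequences = sequence, anno = anno)
}

#' @describeIn TrnaReference gene ids, in reference order
#' @param x a `TrnaReference`
#' @export
geneIds <- function(x) x@anno$gene_id

#' @describeIn TrnaReference named character vector of sequences
#' @export
refSequences <- function(x) x@sequences

#' @describeIn TrnaReference annotation data.frame
#' @export
refAnno <- function(x) x@anno

setMethod("show", "TrnaReference", function(object) {
  cat("TrnaReference with", nrow(object@anno), "genes,",
      length(unique(paste(object@anno$amino_acid, object@anno$anticodon))),
      "anticodon groups\n")
  if (nrow(object@anno))
    cat("  ", paste(utils::head(object@anno$gene_id, 6), collapse = ", "),
        if (nrow(object@anno) > 6) "..." else "", "\n")
})

setMethod("length", "TrnaReference", function(x) length(x@sequences))

#' Per-position modification signature of one tRNA
#'
#' Event probabilities read out by reverse transcription over a modified
#' tRNA: per reference position, the probability of a misincorporation
#' (mismatch), a 1-nt insertion (anchored 3' of the position), a 1-nt
#' deletion, and of RT termination such that the read's 5' end falls at that
#' position. A 5' end at position 1 is a full-length read, so `stop[1]` must
#' be 0, and the stop probabilities must sum to at most 1 (the remainder is
#' the full-length probability).
#'
#' @slot mismatch,insertion,deletion,stop numeric vectors of equal length
#'   (one entry per reference position), values in `[0, 1]`
#' @export
setClass("ModificationProfile",
  slots = c(mismatch = "numeric", insertion = "numeric",
            deletion = "numeric", stop = "numeric"))

setValidity("ModificationProfile", function(object) {
  L <- length(object@mismatch)
  p <- c(object@mismatch, object@insertion, object@deletion, object@stop)
  if (length(object@insertion) != L || length(object@deletion) != L ||
      length(object@stop) != L)
    return("all four probability vectors must have equal length")
  if (any(p < 0) || any(p > 1))
    return("probabilities must lie in [0, 1]")
  if (L > 0 && object@stop[1] != 0)
    return("stop[1] must be 0 (a 5' end at position 1 is full length)")
  if (sum(object@stop) > 1 + 1e-12)
    return("stop probabilities must sum to <= 1")
  TRUE
})

.expandProb <- function(x, len, what) {
  if (is.null(x)) return(numeric(len))
  if (is.null(names(x))) {
    if (length(x) != len)
      stop("unnamed '", what, "' must have length ", len, call. = FALSE)
    return(as.numeric(x))
  }
  out <- numeric(len)
  pos <- as.integer(names(x))
  if (anyNA(pos) || any(pos < 1) || any(pos > len))
    stop("named positions in '", what, "' out of range", call. = FALSE)
  out[pos] <- as.numeric(x)
  out
}

#' Construct a modification profile
#'
#' Probability arguments may be full-length vectors or named numerics whose
#' names are 1-based positions (e.g. `stop = c("38" = 0.4)`); unspecified
#' positions are 0.
#'
#' @param length reference length in nt
#' @param mismatch,insertion,deletion,stop per-position event probabilities
#' @return a [ModificationProfile-class]
#' @examples
#' modificationProfile(76, mismatch = c("37" = 0.3), stop = c("38" = 0.4))
#' @export
modificationProfile <- function(length, mismatch = NULL, insertion = NULL,
                                deletion = NULL, stop = NULL) {
  new("ModificationProfile",
      mismatch = .expandProb(mismatch, length, "mismatch"),
      insertion = .expandProb(insertion, length, "insertion"),
      deletion = .expandProb(deletion, length, "deletion"),
      stop = .expandProb(stop, length, "stop"))
}

setMethod("length", "ModificationProfile", function(x) length(x@mismatch))

setMethod("show", "ModificationProfile", function(object) {
  nz <- function(v) sum(v > 0)
  cat("ModificationProfile over", length(object), "positions:",
      nz(object@mismatch), "mismatch,", nz(object@insertion), "insertion,",
      nz(object@deletion), "deletion,", nz(object@stop), "stop sites\n")
})

#' Per-position variant profile of one tRNA gene
#'
#' Counts of the four read-out variant classes at each position of the
#' collapsed mature reference: mismatches, insertions (anchored to the
#' reference base 5' of the insertion point), deletions, and RT stop events
#' (reads whose 5'-most aligned position is internal, i.e. > 1). `nTotal` is
#' the number of reads assigned to the gene and is the denominator of the
#' variant fractions; reads skipped for malformed CIGAR/MD are excluded from
#' `nTotal` and tallied in `nSkipped`.
#'
#' @slot geneId gene id
#' @slot counts integer-valued matrix, positions x
#'   c(mismatch, insertion, deletion, stop)
#' @slot nTotal reads assigned (denominator of fractions)
#' @slot nSkipped reads skipped for malformed tags
#' @slot skippedIds ids of skipped reads
#' @export
setClass("VariantProfile",
  slots = c(geneId = "character", counts = "matrix", nTotal = "numeric",
            nSkipped = "numeric", skippedIds = "character"))

setValidity("VariantProfile", function(object) {
  cn <- c("mismatch", "insertion", "deletion", "stop")
  if (!identical(colnames(object@counts), cn))
    return("counts must have columns mismatch, insertion, deletion, stop")
  if (any(object@counts < 0))
    return("counts must be non-negative")
  if (nrow(object@counts) && object@counts[1, "stop"] != 0)
    return("no stop events may be recorded at position 1")
  if (any(object@counts > object@nTotal))
    return("per-position event counts cannot exceed nTotal")
  TRUE
})

#' @describeIn VariantProfile combined per-position variant fraction
#'   f(p) = (mismatch + insertion + deletion + stop)(p) / nTotal
#' @param x a `VariantProfile`
#' @export
variantFractions <- function(x) {
  stopifnot(is(x, "VariantProfile"))
  if (x@nTotal == 0) return(numeric(nrow(x@counts)))
  rowSums(x@counts) / x@nTotal
}

#' @describeIn VariantProfile the positions x event-type count matrix
#' @export
variantCounts <- function(x) x@counts

setMethod("show", "VariantProfile", function(object) {
  f <- variantFractions(object)
  cat("VariantProfile for", object@geneId, "-", nrow(object@counts),
      "positions,", object@nTotal, "reads")
  if (object@nSkipped > 0) cat(" (", object@nSkipped, " skipped)", sep = "")
  cat("; max fraction", format(if (length(f)) max(f) else 0, digits = 3), "\n")
})

#' Specification of a synthetic mRNA decay time course
#'
#' Generative parameters for a pulse-chase metabolic-labeling experiment:
#' per-transcript true half-lives, chase timepoints (hours, starting at 0),
#' multiplicative lognormal measurement noise (sdlog), and the mass fraction
#' of the constant spike-in pool at time 0.
#'
#' @slot halfLives per-transcript true half-lives, hours (> 0)
#' @slot timepoints strictly increasing, starting at 0
#' @slot noiseSd sdlog of the multiplicative lognormal noise
#' @slot spikeMassFraction spike share of the labeled pool at t = 0
#' @slot seed integer seed used by [simulateDecayCourse()]
#' @export
setClass("DecaySpec",
  slots = c(halfLives = "numeric", timepoints = "numeric", noiseSd = "numeric",
            spikeMassFraction = "numeric", seed = "numeric"))

setValidity("DecaySpec", function(object) {
  if (any(object@halfLives <= 0)) return("half-lives must be > 0")
  tp <- object@timepoints
  if (length(tp) < 2 || tp[1] != 0 || any(diff(tp) <= 0))
    return("timepoints must be strictly increasing and start at 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@spikeMassFraction <= 0 || object@spikeMassFraction >= 1)
    return("spikeMassFraction must lie in (0, 1)")
  TRUE
})

#' Construct a decay-course specification
#'
#' @param halfLives numeric vector of true half-lives (hours); its length sets
#'   the number of transcripts
#' @param timepoints chase timepoints in hours (default `c(0, 1, 2, 4, 6)`)
#' @param noiseSd sdlog of multiplicative lognormal noise (default 0.2)
#' @param spikeMassFraction spike-in share of the labeled RNA pool at t = 0
#'   (default 0.01)
#' @param seed integer seed
#' @return a [DecaySpec-class]
#' @export
decaySpec <- function(halfLives, timepoints = c(0, 1, 2, 4, 6),
                      noiseSd = 0.2, spikeMassFraction = 0.01, seed = 0) {
  new("DecaySpec", halfLives = as.numeric(halfLives),
      timepoints = as.numeric(timepoints), noiseSd = noiseSd,
      spikeMassFraction = spikeMassFraction, seed = seed)
}

setMethod("show", "DecaySpec", function(object) {
  cat("DecaySpec:", length(object@halfLives), "transcripts, timepoints (h):",
      paste(object@timepoints, collapse = ", "),
      "| noise sdlog", object@noiseSd,
      "| spike mass fraction", object@spikeMassFraction, "\n")
})

#' Spike-in-containing decay time course
#'
#' Raw FPKM trajectories (transcripts x timepoints) together with per-sample
#' spike-in read counts for the two constant-mass spike features ("Luc",
#' "LYSa") and per-sample total mapped reads. The spike fraction of sample j
#' is `mean(reads_Luc, reads_LYSa) / total_reads_j`.
#'
#' @slot fpkm numeric matrix, transcripts x timepoints (colnames = hours)
#' @slot timepoints hours, including 0
#' @slot spikeReads matrix with rows "Luc" and "LYSa", one column per sample
#' @slot totalReads per-sample total mapped reads
#' @export
setClass("DecayCourse",
  slots = c(fpkm = "matrix", timepoints = "numeric",
            spikeReads = "matrix", totalReads = "numeric"))

setValidity("DecayCourse", function(object) {
  J <- length(object@timepoints)
  if (ncol(object@fpkm) != J) return("fpkm must have one column per timepoint")
  if (!0 %in% object@timepoints) return("timepoints must include 0")
  if (!identical(rownames(object@spikeReads), c("Luc", "LYSa")))
    return("spikeReads must have rows 'Luc' and 'LYSa'")
  if (ncol(object@spikeReads) != J || length(object@totalReads) != J)
    return("spikeReads/totalReads must match the number of timepoints")
  if (any(object@fpkm < 0)) return("FPKM values must be non-negative")
  if (any(object@spikeReads < 0) || any(object@totalReads <= 0))
    return("spike/total read counts must be non-negative/positive")
  s <- colMeans(object@spikeReads) / object@totalReads
  if (any(s >= 1))
    return("spike fractions must be < 1")
  TRUE
})

#' @describeIn DecayCourse per-sample spike fraction
#'   s_j = mean(reads_Luc, reads_LYSa) / total_reads_j
#' @param x a `DecayCourse`
#' @export
spikeFraction <- function(x) {
  stopifnot(is(x, "DecayCourse"))
  colMeans(x@spikeReads) / x@totalReads
}

#' @describeIn DecayCourse the raw FPKM matrix
#' @export
rawFpkm <- function(x) x@fpkm

#' @describeIn DecayCourse chase timepoints in hours
#' @export
courseTimepoints <- function(x) x@timepoints

setMethod("show", "DecayCourse", function(object) {
  cat("DecayCourse:", nrow(object@fpkm), "transcripts x",
      length(object@timepoints), "timepoints (",
      paste(object@timepoints, collapse = ", "), "h ); spike fractions",
      paste(signif(spikeFraction(object), 3), collapse = ", "), "\n")
})

#' Specification of codon-dependent ribosome dwell for synthetic profiling
#'
#' @slot dwell named numeric vector of dwell multipliers per DNA codon;
#'   codons absent from the vector have multiplier 1
#' @slot readLength footprint read length (nt)
#' @slot readsPerTranscript footprints sampled per CDS
#' @slot trim5,trim3 trim lengths (nt) defining the trimmed span used to
#'   weight footprint placement
#' @slot seed integer seed
#' @export
setClass("PauseSpec",
  slots = c(dwell = "numeric", readLength = "numeric",
            readsPerTranscript = "numeric", trim5 = "numeric",
            trim3 = "numeric", seed = "numeric"))

setValidity("PauseSpec", function(object) {
  if (any(object@dwell < 0)) return("dwell multipliers must be >= 0")
  if (length(object@dwell) && is.null(names(object@dwell)))
    return("dwell must be a named vector (names = DNA codons)")
  if (object@readLength < object@trim5 + object@trim3 + 1)
    return("readLength must be >= trim5 + trim3 + 1")
  if (object@readsPerTranscript < 1)
    return("readsPerTranscript must be >= 1")
  TRUE
})

#' Construct a pause specification
#'
#' @param dwell named numeric vector of dwell multipliers (names are codons in
#'   RNA or DNA alphabet); unnamed codons default to 1
#' @param readLength footprint length in nt (default 30, the typical MNase
#'   footprint)
#' @param readsPerTranscript footprints per CDS (default 100)
#' @param trim5,trim3 5'/3' trim in nt (defaults 9 and 12)
#' @param seed integer seed
#' @return a [PauseSpec-class]
#' @export
pauseSpec <- function(dwell = numeric(), readLength = 30,
                      readsPerTranscript = 100, trim5 = 9, trim3 = 12,
                      seed = 0) {
  if (length(dwell)) names(dwell) <- codonToDna(names(dwell))
  new("PauseSpec", dwell = dwell, readLength = readLength,
      readsPerTranscript = readsPerTranscript, trim5 = trim5, trim3 = trim3,
      seed = seed)
}

setMethod("show", "PauseSpec", function(object) {
  cat("PauseSpec:", object@readLength, "nt footprints, trim",
      object@trim5, "/", object@trim3, ",", object@readsPerTranscript,
      "reads per transcript;", length(object@dwell),
      "codon(s) with non-default dwell\n")
})
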