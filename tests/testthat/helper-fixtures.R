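# Deterministic fixtures shared across test files. Everything is generated
# in code; nothing is read from disk.

randomTrnaSequence <- function(len = 76, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

testReference <- function() {
  TrnaReference(
    aminoAcid = c("Phe", "Phe", "Lys", "His"),
    anticodon = c("GAA", "GAA", "TTT", "GTG"),
    isodecoderIndex = c(1L, 2L, 1L, 1L),
    sequence = c(randomTrnaSequence(76, 11), randomTrnaSequence(76, 12),
                 randomTrnaSequence(74, 13), randomTrnaSequence(72, 14)))
}

# hand-built perfect full-length alignment records for a gene of length L
fullLengthReads <- function(n, geneId, L, prefix = "r") {
  data.frame(read_id = paste0(prefix, seq_len(n)), flag = 0L,
             ref_id = geneId, ref_start = 1L, cigar = paste0(L, "M"),
             md = as.character(L), seq = NA_character_, seq_len = L,
             stringsAsFactors = FALSE)
}

# alignment records starting at an internal 5' end (RT fall-off reads)
stopReads <- function(n, geneId, L, at, prefix = "s") {
  span <- L - at + 1L
  data.frame(read_id = paste0(prefix, seq_len(n)), flag = 0L,
             ref_id = geneId, ref_start = at, cigar = paste0(span, "M"),
             md = as.character(span), seq = NA_character_, seq_len = span,
             stringsAsFactors = FALSE)
}

# a modification profile with events scattered over several positions
richProfile <- function(L) {
  modificationProfile(L,
    mismatch = stats::setNames(c(0.15, 0.05, 0.2), c(20, 37, 58)),
    insertion = stats::setNames(c(0.08), c(25)),
    deletion = stats::setNames(c(0.07), c(48)),
    stop = stats::setNames(c(0.15, 0.1), c(30, 38)))
}
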