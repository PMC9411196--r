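# Independent brute-force oracles. Each re-derives a quantity from first
# principles with a deliberately naive implementation, sharing no code with
# the package internals it checks.

# Enumerate the variant events of one read by expanding the CIGAR base by
# base and scanning the MD tag character by character.
naiveReadEvents <- function(refStart, cigar, md) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  refpos <- refStart
  alignedType <- character(0)   # per reference-consuming base: "M" or "D"
  alignedPos <- integer(0)
  insertionAt <- integer(0)
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("M", "=", "X")) {
      for (j in seq_len(lens[k])) {
        alignedType <- c(alignedType, "M"); alignedPos <- c(alignedPos, refpos)
        refpos <- refpos + 1L
      }
    } else if (ops[k] %in% c("D", "N")) {
      for (j in seq_len(lens[k])) {
        alignedType <- c(alignedType, "D"); alignedPos <- c(alignedPos, refpos)
        refpos <- refpos + 1L
      }
    } else if (ops[k] == "I") {
      insertionAt <- c(insertionAt, refpos - 1L)  # one event per I op
    }
  }
  # character-by-character MD scan
  chars <- strsplit(md, "")[[1]]
  i <- 1L          # cursor into chars
  a <- 1L          # cursor into aligned positions
  mismatchAt <- integer(0)
  deletionAt <- integer(0)
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("[0-9]", ch)) {
      num <- ""
      while (i <= length(chars) && grepl("[0-9]", chars[i])) {
        num <- paste0(num, chars[i]); i <- i + 1L
      }
      a <- a + as.integer(num)
    } else if (ch == "^") {
      i <- i + 1L
      while (i <= length(chars) && grepl("[A-Z]", chars[i])) {
        stopifnot(alignedType[a] == "D")
        deletionAt <- c(deletionAt, alignedPos[a])
        a <- a + 1L; i <- i + 1L
      }
    } else {
      stopifnot(alignedType[a] == "M")
      mismatchAt <- c(mismatchAt, alignedPos[a])
      a <- a + 1L; i <- i + 1L
    }
  }
  stopifnot(a == length(alignedPos) + 1L)
  list(mismatch = mismatchAt, insertion = insertionAt, deletion = deletionAt,
       stop = if (refStart > 1L) refStart else integer(0))
}

# Tally naive per-read events into a positions x 4 count matrix.
naiveVariantCounts <- function(reads, L) {
  counts <- matrix(0, L, 4,
                   dimnames = list(NULL, c("mismatch", "insertion",
                                           "deletion", "stop")))
  for (i in seq_len(nrow(reads))) {
    ev <- naiveReadEvents(reads$ref_start[i], reads$cigar[i], reads$md[i])
    for (p in ev$mismatch) counts[p, "mismatch"] <- counts[p, "mismatch"] + 1
    for (p in ev$insertion) counts[p, "insertion"] <- counts[p, "insertion"] + 1
    for (p in ev$deletion) counts[p, "deletion"] <- counts[p, "deletion"] + 1
    for (p in ev$stop) counts[p, "stop"] <- counts[p, "stop"] + 1
  }
  counts
}

# Pearson correlation from the raw sum formula.
sigmaPearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Kruskal-Wallis H from ranks, with the standard tie correction.
rankSumH <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  tie <- table(values)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Naive per-occurrence window enumeration of pause scores.
naivePauseScores <- function(fpCov, rnaCov, cdsSet, cdsLens, window = 50,
                             minDensity = 1) {
  densityOk <- function(covSet, id)
    covSet[[id]]$readsAssigned / (cdsLens[[id]] / 3) >= minDensity
  num <- den <- list()
  for (id in names(cdsSet)) {
    if (!densityOk(fpCov, id) || !densityOk(rnaCov, id)) next
    if (fpCov[[id]]$meanCov == 0 || rnaCov[[id]]$meanCov == 0) next
    L <- cdsLens[[id]]
    for (p in seq(1, L - 2, by = 3)) {
      cdn <- substr(cdsSet[[id]], p, p + 2)
      if (cdn %in% c("TAA", "TAG", "TGA")) next
      if (p - window < 1 || p + 2 + window > L) next
      win <- c((p - window):(p - 1), (p + 3):(p + 2 + window))
      num[[cdn]] <- c(num[[cdn]], sum(fpCov[[id]]$rho[win]))
      den[[cdn]] <- c(den[[cdn]], sum(rnaCov[[id]]$rho[win]))
    }
  }
  codons <- sort(names(num))
  data.frame(codon = codonToRna(codons),
             score = vapply(codons, function(cdn)
               sum(num[[cdn]]) / sum(den[[cdn]]), 0),
             stringsAsFactors = FALSE)
}

# Least-squares exponential fit (for contrast with the LAD estimator).
leastSquaresHalfLife <- function(y, tt, minHalfLife = 0.1) {
  kMax <- log(2) / minHalfLife
  o <- stats::optimize(function(k) sum((y - exp(-k * tt))^2), c(0, kMax))
  log(2) / max(o$minimum, 1e-12)
}
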