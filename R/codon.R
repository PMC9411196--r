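#' Per-transcript codon counts and length-normalized frequencies
#'
#' Codons are counted in-frame (window 3, step 3) over the full CDS with
#' `Biostrings::oligonucleotideFrequency`. CDSs that do not start with ATG,
#' or whose length is not a multiple of 3, are excluded and logged.
#' `codonFrequencies` divides by the total codon count of the CDS (the
#' terminal stop codon is part of the denominator) and reports only the 61
#' sense-codon columns, so row sums are at most 1.
#'
#' @param cdsSet named character vector of CDS sequences (DNA alphabet)
#' @return matrix (transcripts x codons, DNA column names) with the excluded
#'   transcripts in `attr(, "excluded")` (data.frame `transcript_id`,
#'   `reason`)
#' @examples
#' codonFrequencies(c(tx1 = "ATGTTT"))[, c("ATG", "TTT")]
#' @export
codonCounts <- function(cdsSet) {
  if (length(cdsSet) && is.null(names(cdsSet)))
    stop("'cdsSet' must be named by transcript id")
  cdsSet <- toupper(chartr("Uu", "Tt", cdsSet))
  badLen <- nchar(cdsSet) %% 3 != 0 | nchar(cdsSet) == 0
  if (any(badLen))
    warning(sum(badLen), " CDS(s) with length not a multiple of 3 excluded")
  badStart <- !badLen & substr(cdsSet, 1, 3) != "ATG"
  excluded <- data.frame(
    transcript_id = names(cdsSet)[badLen | badStart],
    reason = c(rep("length", sum(badLen)), rep("start", sum(badStart))),
    stringsAsFactors = FALSE)
  keep <- !(badLen | badStart)
  kept <- cdsSet[keep]
  counts <- if (length(kept))
    Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(kept),
                                         width = 3, step = 3)
  else matrix(0L, 0, 64, dimnames = list(NULL, .allCodons()))
  counts <- counts[, sort(colnames(counts)), drop = FALSE]
  rownames(counts) <- names(kept)
  attr(counts, "excluded") <- excluded
  counts
}

#' @rdname codonCounts
#' @export
codonFrequencies <- function(cdsSet) {
  counts <- codonCounts(cdsSet)
  total <- rowSums(counts)
  freq <- counts[, senseCodons("DNA"), drop = FALSE] / total
  if (nrow(freq) == 0) freq <- freq[, , drop = FALSE]
  attr(freq, "excluded") <- attr(counts, "excluded")
  freq
}

#' Codon Stabilization Coefficients
#'
#' The CSC of a codon is the Pearson correlation, across transcripts,
#' between transcript half-life and the codon's length-normalized frequency.
#' Negative values mark destabilizing (non-optimal) codons, positive values
#' stabilizing (optimal) ones. Transcripts are matched by id between the
#' frequency matrix and the half-life table; half-lives must be positive
#' (censored half-lives enter at their capped value). Codons whose frequency
#' has zero variance over the used transcripts yield a missing CSC with a
#' warning, never an NaN propagated silently.
#'
#' @param freq matrix from [codonFrequencies()]
#' @param halfLives data.frame with columns `transcript_id` and `half_life`
#'   (as produced by [fitHalfLives()]), or a named numeric vector
#' @return data.frame `codon` (RNA alphabet), `csc`, `n`
#' @export
computeCsc <- function(freq, halfLives) {
  if (!is.data.frame(halfLives))
    halfLives <- data.frame(transcript_id = names(halfLives),
                            half_life = as.numeric(halfLives))
  halfLives <- halfLives[halfLives$half_life > 0, , drop = FALSE]
  ids <- intersect(rownames(freq), halfLives$transcript_id)
  if (length(ids) < 3)
    stop("need at least 3 transcripts common to 'freq' and 'halfLives'")
  f <- freq[ids, , drop = FALSE]
  h <- halfLives$half_life[match(ids, halfLives$transcript_id)]
  if (stats::var(h) == 0) {
    warning("half-lives have zero variance; all CSC values missing")
    csc <- rep(NA_real_, ncol(f))
  } else {
    v <- apply(f, 2, stats::var)
    csc <- rep(NA_real_, ncol(f))
    csc[v > 0] <- as.numeric(stats::cor(h, f[, v > 0, drop = FALSE]))
    if (any(v == 0))
      warning(sum(v == 0), " codon(s) with zero-variance frequency; CSC missing")
  }
  data.frame(codon = codonToRna(colnames(f)), csc = csc, n = length(ids),
             stringsAsFactors = FALSE)
}

#' Synonymous codon bias per transcript
#'
#' For a focal/partner synonymous pair (e.g. UUU vs UUC, AAA vs AAG) the
#' bias is `b = n_focal / (n_focal + n_partner)`; transcripts in which
#' neither codon occurs are reported missing.
#'
#' @param cdsSet named character vector of CDS sequences
#' @param focal,partner codons (RNA or DNA alphabet); must be distinct sense
#'   codons
#' @return data.frame `transcript_id`, `n_focal`, `n_partner`, `bias`
#' @export
codonBias <- function(cdsSet, focal = "UUU", partner = "UUC") {
  fd <- codonToDna(toupper(focal)); pd <- codonToDna(toupper(partner))
  if (!.isSenseCodon(fd) || !.isSenseCodon(pd))
    stop("focal and partner must be sense codons")
  if (fd == pd) stop("focal and partner must differ")
  counts <- codonCounts(cdsSet)
  nf <- counts[, fd]; np <- counts[, pd]
  b <- ifelse(nf + np > 0, nf / (nf + np), NA_real_)
  data.frame(transcript_id = rownames(counts), n_focal = as.integer(nf),
             n_partner = as.integer(np), bias = b, stringsAsFactors = FALSE)
}

# Kruskal-Wallis H with the standard tie correction; the degenerate case in
# which every response value is identical is defined as H = 0, p = 1.
.kruskal <- function(values, groups) {
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p.value = 1,
                df = nlevels(droplevels(groups)) - 1L))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}

#' Bin transcripts by codon bias and test half-life differences
#'
#' Transcripts with a defined bias are split into `nBins` equal-count
#' (quantile) bins; tied bias values stay in one bin, so bin counts may be
#' unequal (and fewer than `nBins` bins may result under heavy ties).
#' Half-life differences across bins are assessed with the Kruskal-Wallis
#' rank test (standard tie correction, chi-square approximation with
#' #bins - 1 degrees of freedom).
#'
#' @param bias data.frame from [codonBias()]
#' @param halfLives data.frame with `transcript_id`, `half_life`, or named
#'   numeric vector
#' @param nBins number of quantile bins (default 5)
#' @return list: `bins` (data.frame `bin`, `lower`, `upper`, `n`, `q25`,
#'   `median`, `q75`), `statistic` (H), `df`, `p.value`, `n`
#' @export
binAndTest <- function(bias, halfLives, nBins = 5) {
  if (!is.data.frame(halfLives))
    halfLives <- data.frame(transcript_id = names(halfLives),
                            half_life = as.numeric(halfLives))
  d <- merge(bias[!is.na(bias$bias), c("transcript_id", "bias")],
             halfLives[, c("transcript_id", "half_life")],
             by = "transcript_id")
  if (nrow(d) < nBins)
    stop("fewer transcripts with defined bias (", nrow(d),
         ") than bins (", nBins, ")")
  breaks <- unique(stats::quantile(d$bias, probs = seq(0, 1, length.out = nBins + 1),
                                   names = FALSE))
  if (length(breaks) < 2) breaks <- c(breaks, breaks + 1e-9)
  grp <- cut(d$bias, breaks, include.lowest = TRUE)
  kw <- .kruskal(d$half_life, grp)
  q <- function(v, p) unname(stats::quantile(v, p))
  bins <- do.call(rbind, lapply(levels(grp), function(g) {
    v <- d$half_life[grp == g]
    data.frame(bin = g, n = length(v),
               q25 = q(v, .25), median = q(v, .5), q75 = q(v, .75))
  }))
  bins$lower <- breaks[-length(breaks)]
  bins$upper <- breaks[-1]
  bins <- bins[, c("bin", "lower", "upper", "n", "q25", "median", "q75")]
  list(bins = bins, statistic = kw$statistic, df = kw$df,
       p.value = kw$p.value, n = nrow(d))
}

#' Simulate a CDS set with a designed codon-to-half-life link
#'
#' Generates `n` coding sequences (ATG start, random sense-codon body, stop
#' codon, length a multiple of 3) in which the frequency of one designated
#' codon varies across transcripts, and assigns true half-lives
#' `intercept + slope * frequency + noise`. This is the ground-truth
#' construction used to verify that the designated codon's CSC recovers the
#' designed sign and magnitude ordering.
#'
#' @param n number of transcripts
#' @param lengthRange 2-vector: min/max CDS length in codons (including the
#'   start and stop codon)
#' @param codon the designated codon (RNA or DNA alphabet; sense codon)
#' @param slope,intercept half-life link coefficients (hours per unit
#'   frequency; hours)
#' @param noiseSd additive Gaussian noise on half-lives (hours)
#' @param maxTargetProb upper bound of the per-transcript target-codon usage
#'   probability (default 0.12)
#' @param seed integer seed
#' @return list with `cds` (named character vector) and `halfLives`
#'   (data.frame `transcript_id`, `half_life`, `target_freq`)
#' @export
simulateCdsSet <- function(n, lengthRange = c(80, 150), codon = "UUU",
                           slope = 10, intercept = 2, noiseSd = 0,
                           maxTargetProb = 0.12, seed = 0) {
  target <- codonToDna(toupper(codon))
  if (!.isSenseCodon(target)) stop("designated codon must be a sense codon")
  if (n == 0)
    return(list(cds = stats::setNames(character(0), character(0)),
                halfLives = data.frame(transcript_id = character(),
                                       half_life = numeric(),
                                       target_freq = numeric())))
  others <- setdiff(senseCodons("DNA"), c(target, "ATG"))
  withr::with_seed(seed, {
    nCodons <- sample(seq(lengthRange[1], lengthRange[2]), n, replace = TRUE)
    p <- stats::runif(n, 0, maxTargetProb)
    cds <- character(n)
    freq <- numeric(n)
    for (i in seq_len(n)) {
      body <- nCodons[i] - 2L
      isTarget <- stats::runif(body) < p[i]
      codons <- ifelse(isTarget, target,
                       others[sample.int(length(others), body, replace = TRUE)])
      cds[i] <- paste0("ATG", paste(codons, collapse = ""),
                       .STOP_CODONS[sample.int(3, 1)])
      freq[i] <- (sum(isTarget) + (target == "ATG")) / nCodons[i]
    }
    noise <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
  })
  halfLife <- pmax(intercept + slope * freq + noise, 0.05)
  ids <- sprintf("cds%05d", seq_len(n))
  names(cds) <- ids
  list(cds = cds,
       halfLives = data.frame(transcript_id = ids, half_life = halfLife,
                              target_freq = freq, stringsAsFactors = FALSE))
}
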