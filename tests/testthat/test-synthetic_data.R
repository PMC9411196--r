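test_that("all-zero profile yields only perfect full-length reads", {
  ref <- testReference()
  g <- geneIds(ref)[1]
  prof <- stats::setNames(list(modificationProfile(76)), g)
  reads <- simulateTrnaAlignments(ref, prof, 50, seed = 1)
  expect_true(all(reads$ref_start == 1))
  expect_true(all(reads$cigar == "76M"))
  expect_true(all(reads$md == "76"))
  expect_true(all(reads$seq == refSequences(ref)[[g]]))
})

test_that("a forced RT stop places every 5' end at the stop position", {
  ref <- testReference()
  g <- geneIds(ref)[1]
  prof <- stats::setNames(list(modificationProfile(76, stop = c("38" = 1))), g)
  reads <- simulateTrnaAlignments(ref, prof, 40, seed = 2)
  expect_true(all(reads$ref_start == 38))
  expect_true(all(reads$cigar == "39M"))
})

test_that("generators are pure functions of (spec, seed)", {
  ref <- testReference()
  prof <- stats::setNames(list(richProfile(76)), geneIds(ref)[1])
  r1 <- simulateTrnaAlignments(ref, prof, 300, seed = 5)
  r2 <- simulateTrnaAlignments(ref, prof, 300, seed = 5)
  expect_identical(r1, r2)
  r3 <- simulateTrnaAlignments(ref, prof, 300, seed = 6)
  expect_false(identical(r1, r3))

  spec <- decaySpec(c(1, 2, 3), noiseSd = 0.3, seed = 9)
  expect_identical(rawFpkm(simulateDecayCourse(spec)),
                   rawFpkm(simulateDecayCourse(spec)))

  sim1 <- simulateCdsSet(20, seed = 4)
  sim2 <- simulateCdsSet(20, seed = 4)
  expect_identical(sim1, sim2)

  ps <- pauseSpec(dwell = c(AAA = 2), readsPerTranscript = 50, seed = 3)
  expect_identical(simulateProfiling(sim1$cds, ps),
                   simulateProfiling(sim1$cds, ps))
})

test_that("simulated event frequencies converge to spec probabilities", {
  # binomial oracle: recovered fractions within 3 SE at depth 10,000
  ref <- testReference()
  g <- geneIds(ref)[1]
  n <- 10000
  # the only stop site (20) lies 5' of every other event site, so all reads
  # cover positions 37/45/58 regardless of fall-off
  prof <- stats::setNames(list(modificationProfile(76,
    mismatch = c("37" = 0.3), insertion = c("45" = 0.1),
    deletion = c("58" = 0.12), stop = c("20" = 0.2))), g)
  reads <- simulateTrnaAlignments(ref, prof, n, seed = 7)
  counts <- naiveVariantCounts(reads, 76)
  se <- function(p, m) 3 * sqrt(p * (1 - p) / m)
  expect_lt(abs(counts[37, "mismatch"] / n - 0.3), se(0.3, n))
  expect_lt(abs(counts[45, "insertion"] / n - 0.1), se(0.1, n))
  expect_lt(abs(counts[58, "deletion"] / n - 0.12), se(0.12, n))
  expect_lt(abs(counts[20, "stop"] / n - 0.2), se(0.2, n))
})

test_that("mixture draws follow the mixing fraction", {
  ref <- testReference()
  g <- geneIds(ref)[1]
  a <- modificationProfile(76, stop = c("38" = 0.8))
  b <- modificationProfile(76)
  mix <- simulateMixture(ref, g, a, b, fractionA = 0.5, nReads = 10000,
                         seed = 3)
  frac <- mean(mix$ref_start == 38)
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  # fractionA = 1 reduces to profile A alone
  pure <- simulateMixture(ref, g, a, b, fractionA = 1, nReads = 2000, seed = 4)
  expect_lt(abs(mean(pure$ref_start == 38) - 0.8),
            3 * sqrt(0.8 * 0.2 / 2000))
  expect_error(simulateMixture(ref, g, a, b, 1.2, 10), "fractionA")
})

test_that("zero-noise decay courses invert exactly under spike normalization", {
  spec <- decaySpec(halfLives = c(1, 2), timepoints = c(0, 1, 2, 4, 6),
                    noiseSd = 0, seed = 10)
  y <- spikeNormalize(simulateDecayCourse(spec))
  expect_equal(unname(y[1, ]), 2^(-c(0, 1, 2, 4, 6) / 1), tolerance = 1e-6)
  expect_equal(unname(y[2, ]), 2^(-c(0, 1, 2, 4, 6) / 2), tolerance = 1e-6)
})

test_that("non-decaying transcripts keep the spike fraction constant", {
  spec <- decaySpec(halfLives = rep(Inf, 5), noiseSd = 0, seed = 2)
  course <- simulateDecayCourse(spec)
  s <- spikeFraction(course)
  expect_equal(max(s), min(s), tolerance = 1e-12)
})

test_that("CDS simulator respects composition constraints and the designed link", {
  sim <- simulateCdsSet(40, lengthRange = c(60, 90), codon = "UUU",
                        slope = 12, intercept = 2, noiseSd = 0, seed = 8)
  expect_true(all(substr(sim$cds, 1, 3) == "ATG"))
  expect_true(all(nchar(sim$cds) %% 3 == 0))
  last <- substring(sim$cds, nchar(sim$cds) - 2, nchar(sim$cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  # zero noise: half-life is an exact affine function of the codon frequency
  freq <- codonFrequencies(sim$cds)[, "TTT"]
  expect_equal(sigmaPearson(sim$halfLives$half_life, unname(freq)), 1,
               tolerance = 1e-12)
  empty <- simulateCdsSet(0)
  expect_length(empty$cds, 0)
  expect_identical(nrow(empty$halfLives), 0L)
})

test_that("footprint placement follows dwell weights; RNA stays uniform", {
  # footprint length 24 makes the trimmed span exactly one codon, so the
  # sampling-weight oracle is exact: central-base coverage at enhanced
  # codons sits at delta x background
  sim <- simulateCdsSet(30, lengthRange = c(120, 150), codon = "CTG",
                        slope = 0, seed = 6)
  cds <- sim$cds
  lens <- stats::setNames(nchar(cds), names(cds))
  spec <- pauseSpec(dwell = c(AAA = 3), readLength = 24,
                    readsPerTranscript = 3000, seed = 13)
  pr <- simulateProfiling(cds, spec)
  fpCov <- trimCoverageSet(pr$footprints, lens)
  rnaCov <- trimCoverageSet(pr$rna, lens)
  covAt <- function(covSet, which = "AAA") {
    hit <- bg <- numeric(0)
    for (id in names(cds)) {
      L <- lens[[id]]
      pos <- seq(1, L - 2, 3)
      codons <- substring(cds[[id]], pos, pos + 2)
      center <- pos + 1
      inner <- center > 24 & center < L - 24   # avoid edge falloff
      hit <- c(hit, covSet[[id]]$coverage[center[inner & codons == which]])
      bg <- c(bg, covSet[[id]]$coverage[center[inner & codons != which]])
    }
    mean(hit) / mean(bg)
  }
  expect_equal(covAt(fpCov), 3, tolerance = 0.1)
  expect_equal(covAt(rnaCov), 1, tolerance = 0.1)
})
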