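mkRead <- function(id, refId, start, len) {
  data.frame(read_id = id, flag = 0L, ref_id = refId, ref_start = start,
             cigar = paste0(len, "M"), md = as.character(len),
             seq = NA_character_, seq_len = len, stringsAsFactors = FALSE)
}

test_that("trimming removes 9 nt from the 5' and 12 nt from the 3' end", {
  r <- mkRead("r1", "cds", 100, 30)  # aligned span [100, 129]
  tc <- trimAndCover(r, 300)
  covered <- which(tc$coverage > 0)
  expect_identical(covered, 109:117)  # 9 nt
  # a 21-nt read has an empty trimmed span and is discarded
  tc2 <- trimAndCover(mkRead("r2", "cds", 100, 21), 300)
  expect_identical(tc2$nDiscarded, 1L)
  expect_true(all(tc2$coverage == 0))
  expect_identical(tc2$readsAssigned, 1L)
  # reads beyond the CDS bounds are clipped and counted
  tc3 <- trimAndCover(mkRead("r3", "cds", 290, 30), 300)
  expect_identical(tc3$nClipped, 1L)
  expect_identical(which(tc3$coverage > 0), 299:300)
})

test_that("uniform tiling gives interior normalized density exactly 1", {
  L <- 300
  reads <- do.call(rbind, lapply(1:(L - 29), function(s)
    mkRead(paste0("t", s), "cds", s, 30)))
  tc <- trimAndCover(reads, L)
  interior <- 30:(L - 30)
  expect_equal(tc$rho[interior] / tc$rho[interior][1],
               rep(1, length(interior)), tolerance = 1e-12)
  expect_equal(mean(tc$rho), 1, tolerance = 1e-12)
})

test_that("the CDS density filter applies its >= 1 read/codon boundary", {
  L <- 180  # 60 codons
  cov59 <- trimAndCover(do.call(rbind, lapply(1:59, function(i)
    mkRead(paste0("a", i), "c1", 1 + (i %% 100), 30))), L)
  cov60 <- trimAndCover(do.call(rbind, lapply(1:60, function(i)
    mkRead(paste0("b", i), "c2", 1 + (i %% 100), 30))), L)
  covSet <- list(c1 = cov59, c2 = cov60,
                 c3 = trimAndCover(mkRead("x", "c3", 1, 30)[0, ], L))
  lens <- c(c1 = L, c2 = L, c3 = L)
  expect_identical(filterCds(covSet, lens), "c2")
})

test_that("pause scores self-normalize to exactly 1", {
  sim <- simulateCdsSet(15, lengthRange = c(110, 140), codon = "CTG",
                        slope = 0, seed = 9)
  lens <- stats::setNames(nchar(sim$cds), names(sim$cds))
  pr <- simulateProfiling(sim$cds, pauseSpec(dwell = c(AAA = 2),
                                             readsPerTranscript = 400,
                                             seed = 2))
  cov <- trimCoverageSet(pr$footprints, lens)
  ps <- pauseScores(cov, cov, sim$cds, lens)
  kept <- !is.na(ps$score)
  expect_true(any(kept))
  expect_true(all(ps$score[kept] == 1))
})

test_that("pause scores equal the naive window-enumeration oracle", {
  sim <- simulateCdsSet(20, lengthRange = c(105, 160), codon = "GGA",
                        slope = 0, seed = 14)
  lens <- stats::setNames(nchar(sim$cds), names(sim$cds))
  pr <- simulateProfiling(sim$cds,
                          pauseSpec(dwell = c(TTT = 3, GAA = 0.5),
                                    readsPerTranscript = 300, seed = 5))
  fp <- trimCoverageSet(pr$footprints, lens)
  rna <- trimCoverageSet(pr$rna, lens)
  ps <- pauseScores(fp, rna, sim$cds, lens)
  oracle <- naivePauseScores(fp, rna, sim$cds, lens)
  shared <- intersect(oracle$codon, ps$codon[!is.na(ps$score)])
  expect_gt(length(shared), 30)
  expect_equal(ps$score[match(shared, ps$codon)],
               oracle$score[match(shared, oracle$codon)], tolerance = 1e-9)
})

test_that("occurrences too close to the CDS ends are skipped, not padded", {
  # one CDS whose only AAA codons sit within 50 nt of the ends
  body <- strrep("GGC", 60)
  cds <- c(only = paste0("ATG", "AAA", substr(body, 1, 168), "AAA", "TAA"))
  lens <- stats::setNames(nchar(cds), names(cds))
  reads <- do.call(rbind, lapply(seq(1, nchar(cds) - 29), function(s)
    mkRead(paste0("r", s), "only", s, 30)))
  cov <- trimCoverageSet(reads, lens)
  ps <- pauseScores(cov, cov, cds, lens)
  expect_true(is.na(ps$score[ps$codon == "AAA"]))
  expect_identical(ps$n_occurrences[ps$codon == "AAA"], 0L)
})

test_that("replicate pause scores average arithmetically", {
  t1 <- data.frame(codon = c("AAA", "UUU"), n_occurrences = 1L,
                   numerator = 1, denominator = 1, score = c(1.2, 0.8))
  t2 <- data.frame(codon = c("AAA", "UUU"), n_occurrences = 1L,
                   numerator = 1, denominator = 1, score = c(1.4, 1.0))
  avg <- averagePauseScores(list(t1, t2))
  expect_equal(avg$mean, c(1.3, 0.9))
})

test_that("ribosome density follows the FPKM ratio definition", {
  rd <- ribosomeDensity(c(tx1 = 200, tx2 = 100), c(tx1 = 100, tx2 = 200),
                        cdsLens = c(tx1 = 1000, tx2 = 2000),
                        txLens = c(tx1 = 2000, tx2 = 2000))
  # fp reads 200 on a 1 kb CDS vs rna reads 100 on the 2 kb transcript,
  # equal totals (300 each) -> RD = (200/1) / (100/2) = 4
  expect_equal(rd$rd[rd$transcript_id == "tx1"], 4)
  expect_equal(rd$rd[rd$transcript_id == "tx2"], 0.5)
  rd0 <- ribosomeDensity(c(a = 5, b = 5), c(a = 0, b = 10),
                         c(a = 300, b = 300), c(a = 600, b = 600))
  expect_true(is.na(rd0$rd[rd0$transcript_id == "a"]))
})

test_that("designed dwell multipliers rank-order recovered pause scores", {
  dw <- c(GAA = 0.25, CCA = 0.5, GGC = 1.5, AAA = 2, TTT = 4)
  sim <- simulateCdsSet(120, lengthRange = c(150, 200), codon = "CTG",
                        slope = 0, seed = 5)
  lens <- stats::setNames(nchar(sim$cds), names(sim$cds))
  pr <- simulateProfiling(sim$cds, pauseSpec(dwell = dw,
                                             readsPerTranscript = 2000,
                                             seed = 11))
  fp <- trimCoverageSet(pr$footprints, lens)
  rna <- trimCoverageSet(pr$rna, lens)
  ps <- pauseScores(fp, rna, sim$cds, lens)
  sc <- ps$score[match(codonToRna(names(dw)), ps$codon)]
  expect_gte(cor(dw, sc, method = "spearman"), 0.9)
})
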