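test_that("codon frequencies follow the window-3/step-3 definition", {
  f <- codonFrequencies(c(t1 = "ATGTTT"))
  expect_equal(unname(f["t1", "ATG"]), 0.5)
  expect_equal(unname(f["t1", "TTT"]), 0.5)
  expect_true(all(f["t1", setdiff(colnames(f), c("ATG", "TTT"))] == 0))
  # the stop codon counts in the denominator but is not a column
  f2 <- codonFrequencies(c(t2 = "ATGAAATAA"))
  expect_equal(unname(f2["t2", "ATG"]), 1 / 3)
  expect_equal(unname(f2["t2", "AAA"]), 1 / 3)
  expect_false("TAA" %in% colnames(f2))
  expect_equal(unname(rowSums(f2)), 2 / 3)
  # non-ATG start is excluded and logged
  f3 <- codonFrequencies(c(bad = "TTGAAATAA", ok = "ATGTAA"))
  expect_identical(rownames(f3), "ok")
  expect_identical(attr(f3, "excluded")$transcript_id, "bad")
  expect_warning(codonFrequencies(c(r = "ATGTT")), "multiple of 3")
})

test_that("CSC equals a from-definition Pearson oracle on random inputs", {
  withr::with_seed(41, {
    freq <- matrix(runif(50 * 61), 50, 61,
                   dimnames = list(sprintf("t%02d", 1:50), senseCodons("DNA")))
    th <- runif(50, 0.3, 8)
  })
  csc <- computeCsc(freq, stats::setNames(th, rownames(freq)))
  for (j in seq_len(61)) {
    expect_equal(csc$csc[j], sigmaPearson(th, freq[, j]), tolerance = 1e-12)
  }
  expect_true(all(abs(csc$csc) <= 1))
  expect_true(all(csc$n == 50))
})

test_that("degenerate CSC inputs give missing values, never NaN", {
  freq <- matrix(c(0.1, 0.2, 0.3, 0.4, 0, 0, 0, 0), 4, 2,
                 dimnames = list(paste0("t", 1:4), c("TTT", "AAA")))
  th <- stats::setNames(1:4, rownames(freq))
  expect_warning(csc <- computeCsc(freq, th), "zero-variance")
  expect_equal(csc$csc[csc$codon == "UUU"], 1, tolerance = 1e-12)
  expect_true(is.na(csc$csc[csc$codon == "AAA"]))
  expect_warning(cscFlat <- computeCsc(freq, stats::setNames(rep(2, 4),
                                                             rownames(freq))),
                 "zero variance")
  expect_true(all(is.na(cscFlat$csc)))
  expect_error(computeCsc(freq[1:2, ], th), "at least 3")
})

test_that("CSC is invariant under affine rescaling of half-lives", {
  withr::with_seed(4, {
    freq <- matrix(runif(30 * 61), 30, 61,
                   dimnames = list(paste0("t", 1:30), senseCodons("DNA")))
    th <- runif(30, 1, 6)
  })
  a <- computeCsc(freq, stats::setNames(th, rownames(freq)))
  b <- computeCsc(freq, stats::setNames(3 * th + 1, rownames(freq)))
  expect_equal(a$csc, b$csc, tolerance = 1e-12)
})

test_that("codon bias follows its focal/(focal+partner) definition", {
  cds <- c(x = paste0("ATG", strrep("TTT", 3), "TTC", "TAA"),
           y = paste0("ATG", strrep("TTT", 5), "TAA"),
           z = "ATGAAATAA")
  b <- codonBias(cds, "UUU", "UUC")
  expect_equal(b$bias[b$transcript_id == "x"], 0.75)
  expect_equal(b$bias[b$transcript_id == "y"], 1)
  expect_true(is.na(b$bias[b$transcript_id == "z"]))
  expect_error(codonBias(cds, "UAA", "UUC"), "sense")
  expect_error(codonBias(cds, "UUU", "UUU"), "differ")
})

test_that("quantile binning partitions defined-bias transcripts and the rank
           test matches its from-definition oracle", {
  # small exact case: three clean groups
  bias <- data.frame(transcript_id = paste0("t", 1:9),
                     bias = rep(c(0.1, 0.5, 0.9), each = 3))
  th <- stats::setNames(1:9, paste0("t", 1:9))
  out <- binAndTest(bias, th, nBins = 3)
  expect_identical(sum(out$bins$n), 9L)
  expect_equal(out$statistic, rankSumH(1:9, rep(1:3, each = 3)),
               tolerance = 1e-12)
  expect_equal(out$statistic, 7.2, tolerance = 1e-12)
  expect_equal(out$p.value, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # all half-lives equal: H = 0, p = 1 by convention
  flat <- binAndTest(bias, stats::setNames(rep(2, 9), paste0("t", 1:9)),
                     nBins = 3)
  expect_identical(flat$statistic, 0)
  expect_identical(flat$p.value, 1)
  expect_error(binAndTest(bias[1:3, ], th, nBins = 5), "fewer")
})

test_that("bin counts sum to the transcripts with defined bias", {
  withr::with_seed(12, {
    n <- 500L
    bias <- data.frame(transcript_id = sprintf("t%03d", 1:n),
                       bias = c(runif(n - 50), rep(NA, 50)))
    th <- stats::setNames(rexp(n, 1 / 3), bias$transcript_id)
  })
  out <- binAndTest(bias, th, nBins = 5)
  expect_identical(sum(out$bins$n), n - 50L)
})

test_that("a designed bias-to-decay link is detected by the binned rank test", {
  # stronger decay at high bias; n = 2000 transcripts per seed
  pvals <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      b <- runif(2000)
      th <- pmax(3 - 1.2 * b + rnorm(2000, 0, 0.8), 0.1)
    })
    bias <- data.frame(transcript_id = sprintf("t%04d", 1:2000), bias = b)
    binAndTest(bias, stats::setNames(th, bias$transcript_id))$p.value
  }, 0)
  expect_gte(mean(pvals < 0.01), 0.95)
})

test_that("the designed codon attains the extreme CSC of the designed sign", {
  hits <- vapply(1:30, function(s) {
    sim <- simulateCdsSet(300, lengthRange = c(80, 120), codon = "UUU",
                          slope = 10, intercept = 2, noiseSd = 0.2,
                          seed = 3000 + s)
    csc <- computeCsc(codonFrequencies(sim$cds), sim$halfLives)
    csc$codon[which.max(csc$csc)] == "UUU" & csc$csc[csc$codon == "UUU"] > 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # with zero noise the designed correlation is perfect
  sim0 <- simulateCdsSet(100, codon = "GCU", slope = 6, noiseSd = 0, seed = 77)
  csc0 <- computeCsc(codonFrequencies(sim0$cds), sim0$halfLives)
  expect_equal(csc0$csc[csc0$codon == "GCU"], 1, tolerance = 1e-12)
})
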