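# Fixed 4-gene demonstration tRNA reference: two anticodon-loop-modified
# focal genes (Phe-GAA, Lys-TTT) and two control genes (His-GTG, Leu-CAG).
# Sequences are arbitrary but fixed 76-mers with the anticodon placed at
# positions 34-36.
.demoTrnaReference <- function() {
  body <- function(anticodon, salt) {
    withr::with_seed(salt, {
      s <- sample(.BASES, 76, replace = TRUE)
      s[34:36] <- strsplit(anticodon, "")[[1]]
      paste(s, collapse = "")
    })
  }
  TrnaReference(
    aminoAcid = c("Phe", "Lys", "His", "Leu"),
    anticodon = c("GAA", "TTT", "GTG", "CAG"),
    isodecoderIndex = c(1L, 1L, 1L, 1L),
    sequence = c(body("GAA", 101), body("TTT", 102),
                 body("GTG", 103), body("CAG", 104)))
}

#' Demonstration run configuration
#'
#' Builds the configuration of the end-to-end synthetic study: two
#' conditions ("progenitor", in which the focal tRNAs are modified, and
#' "differentiated", in which they are hypomodified), two replicates each.
#' Every analysis tunable carries its standard default (trim 9/12 nt, 50-nt
#' pause window, 5 bias bins, 6 h half-life cap, FPKM >= 1 at 0 h, 1 read
#' per codon, 100 reads minimum for variant-profile emission). All
#' randomness derives from `seed`.
#'
#' @param seed integer master seed (default 0)
#' @param nTranscripts transcripts in the decay/CSC stage (default 2000)
#' @param nProfilingTranscripts CDS subset used for ribosome profiling
#'   (default 300)
#' @param trnaReads tRNA-seq reads per gene per replicate (default 10000)
#' @param fpReadsPerTranscript footprints per CDS per replicate (default 200,
#'   comfortably above the 1-read-per-codon retention filter for the CDS
#'   lengths simulated)
#' @return a named list of class `RunConfig`
#' @export
demoRunConfig <- function(seed = 0, nTranscripts = 2000,
                          nProfilingTranscripts = 300, trnaReads = 10000,
                          fpReadsPerTranscript = 200) {
  structure(list(
    seed = as.integer(seed),
    conditions = c("progenitor", "differentiated"),
    replicates = 2L,
    trna = list(
      n_reads = as.integer(trnaReads),
      focal_genes = c("Phe-GAA-1", "Lys-TTT-1"),
      # modified state: strong RT stop at 38 + misincorporation at 37
      stop_prob = c(progenitor = 0.5, differentiated = 0.1),
      mismatch_prob = c(progenitor = 0.25, differentiated = 0.05),
      stop_position = 38L, mismatch_position = 37L,
      min_reads = 100L),
    decay = list(
      n_transcripts = as.integer(nTranscripts),
      timepoints = c(0, 1, 2, 4, 6),
      noise_sd = 0.2,
      spike_mass_fraction = 0.01,
      cap_hours = 6,
      min_fpkm0 = 1,
      focal_codon = "UUU",
      partner_codon = "UUC",
      # half-life link: the focal codon stabilizes in progenitors and
      # destabilizes in differentiated cells (optimality flip)
      slope = c(progenitor = 8, differentiated = -8),
      intercept = 2.5,
      link_noise_sd = 0.2,
      bins = 5L),
    profiling = list(
      n_transcripts = as.integer(nProfilingTranscripts),
      reads_per_transcript = as.integer(fpReadsPerTranscript),
      read_length = 30L, trim5 = 9L, trim3 = 12L, window = 50L,
      min_density = 1,
      dwell = c(progenitor = 1, differentiated = 2.5))),
    class = "RunConfig")
}

#' Read and write run configurations
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path YAML file path
#' @return for `readRunConfig`, a `RunConfig` list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  for (f in c("trna", "decay", "profiling"))
    for (nm in names(cfg[[f]]))
      if (is.list(cfg[[f]][[nm]])) cfg[[f]][[nm]] <- unlist(cfg[[f]][[nm]])
  structure(cfg, class = "RunConfig")
}

#' @rdname readRunConfig
#' @param config a `RunConfig` list
#' @export
writeRunConfig <- function(config, path) {
  # named atomic vectors become YAML maps so their names survive the trip
  mapify <- function(x) {
    if (is.list(x)) lapply(x, mapify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(mapify(unclass(config)), path, precision = 15)
  invisible(path)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the end-to-end synthetic two-condition study
#'
#' Simulates and analyzes the full synthetic experiment defined by a
#' `RunConfig`: (1) tRNA-seq with condition-dependent anticodon-loop
#' modification signatures, variant profiles, read counts and the
#' between-condition depth ratio; (2) a spike-in decay course whose
#' half-lives are linked to the focal codon's frequency with a
#' condition-dependent sign, half-life fitting, CSC, and codon-bias binning
#' with the Kruskal-Wallis test; (3) ribosome profiling with
#' condition-dependent dwell at the focal codon and windowed pause scores.
#' All outputs are written as TSV plus a machine-readable JSON summary;
#' runs are deterministic given the config seed (repeated runs are
#' byte-identical).
#'
#' @param config a `RunConfig` from [demoRunConfig()] or [readRunConfig()]
#' @param outDir output directory (created if needed)
#' @return invisibly, a list with the principal per-condition results
#'   (`csc`, `pause`, `bins`, `depthRatio`, `halfLives`)
#' @export
runPipeline <- function(config, outDir) {
  if (!inherits(config, "RunConfig") && !is.list(config))
    stop("'config' must be a RunConfig")
  for (f in c("seed", "conditions", "replicates", "trna", "decay", "profiling"))
    if (is.null(config[[f]]))
      stop("config is missing required field '", f, "'")
  if (missing(outDir) || is.null(outDir))
    stop("'outDir' is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  conds <- config$conditions
  reps <- seq_len(config$replicates)

  ## ---- tRNA modification stage -------------------------------------------
  trnaOut <- .stage("trna", {
    ref <- .demoTrnaReference()
    tc <- config$trna
    profiles <- lapply(stats::setNames(conds, conds), function(cond) {
      p <- lapply(stats::setNames(tc$focal_genes, tc$focal_genes),
        function(g) modificationProfile(
          nchar(refSequences(ref)[[g]]),
          mismatch = stats::setNames(tc$mismatch_prob[[cond]],
                                     tc$mismatch_position),
          stop = stats::setNames(tc$stop_prob[[cond]], tc$stop_position)))
      ctrl <- setdiff(geneIds(ref), tc$focal_genes)
      p[ctrl] <- lapply(ctrl, function(g)
        modificationProfile(nchar(refSequences(ref)[[g]])))
      p
    })
    depth <- list()
    vp <- list()
    countsTabs <- list()
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      for (r in reps) {
        reads <- simulateTrnaAlignments(ref, profiles[[cond]], tc$n_reads,
                                        seed = seed + 1000L * ci + r)
        key <- paste(cond, r, sep = "_")
        countsTabs[[key]] <- countReads(reads, ref)
        for (g in tc$focal_genes) {
          sub <- reads[reads$ref_id == g, , drop = FALSE]
          L <- nchar(refSequences(ref)[[g]])
          depth[[g]][[cond]][[r]] <- depthProfile(sub, L)
          if (nrow(sub) >= tc$min_reads)
            vp[[paste(g, key, sep = "_")]] <- variantProfile(sub, L, g)
        }
      }
    }
    iso <- do.call(cbind, lapply(countsTabs, function(x)
      stats::setNames(x$isodecoder$count, x$isodecoder$gene_id)))
    writeSampleTable(iso, file.path(outDir, "counts_isodecoder.tsv"),
                     idColumn = "gene_id")
    for (nm in names(vp)) {
      m <- cbind(variantCounts(vp[[nm]]),
                 fraction = variantFractions(vp[[nm]]))
      rownames(m) <- seq_len(nrow(m))
      writeSampleTable(m, file.path(outDir, paste0("variants_", nm, ".tsv")),
                       idColumn = "position")
    }
    ratio <- lapply(stats::setNames(tc$focal_genes, tc$focal_genes),
      function(g) ratioProfile(depth[[g]][[conds[1]]],
                               depth[[g]][[conds[2]]]))
    rm <- do.call(cbind, ratio)
    rownames(rm) <- seq_len(nrow(rm))
    writeSampleTable(rm, file.path(outDir, "depth_ratio.tsv"),
                     idColumn = "position")
    list(variantProfiles = vp, depthRatio = ratio)
  })

  ## ---- decay / CSC stage --------------------------------------------------
  decayOut <- .stage("decay", {
    dc <- config$decay
    cdsSets <- lapply(stats::setNames(conds, conds), function(cond)
      simulateCdsSet(dc$n_transcripts, codon = dc$focal_codon,
                     slope = dc$slope[[cond]], intercept = dc$intercept,
                     noiseSd = dc$link_noise_sd, seed = seed + 77L))
    res <- list()
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      cset <- cdsSets[[cond]]
      spec <- decaySpec(cset$halfLives$half_life,
                        timepoints = dc$timepoints, noiseSd = dc$noise_sd,
                        spikeMassFraction = dc$spike_mass_fraction,
                        seed = seed + 500L + ci)
      course <- simulateDecayCourse(spec)
      rownames(course@fpkm) <- cset$halfLives$transcript_id
      y <- spikeNormalize(course)
      keep <- filterTranscripts(course, minFpkm0 = dc$min_fpkm0)$retained
      fits <- fitHalfLives(y[keep, , drop = FALSE], dc$timepoints,
                           capHours = dc$cap_hours)
      freq <- codonFrequencies(cset$cds)
      csc <- computeCsc(freq, fits)
      bias <- codonBias(cset$cds, dc$focal_codon, dc$partner_codon)
      bt <- binAndTest(bias, fits, nBins = dc$bins)
      utils::write.table(fits, file.path(outDir,
        paste0("half_lives_", cond, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(csc, file.path(outDir, paste0("csc_", cond, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(bt$bins, file.path(outDir,
        paste0("bins_", cond, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
      res[[cond]] <- list(fits = fits, csc = csc, binTest = bt,
                          cds = cset$cds)
    }
    res
  })

  ## ---- ribosome profiling stage ------------------------------------------
  pauseOut <- .stage("profiling", {
    pc <- config$profiling
    focalDna <- codonToDna(config$decay$focal_codon)
    cds <- decayOut[[conds[1]]]$cds[seq_len(min(pc$n_transcripts,
                                                length(decayOut[[conds[1]]]$cds)))]
    res <- list()
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      repTabs <- list()
      for (r in reps) {
        spec <- pauseSpec(
          dwell = stats::setNames(pc$dwell[[cond]], focalDna),
          readLength = pc$read_length,
          readsPerTranscript = pc$reads_per_transcript,
          trim5 = pc$trim5, trim3 = pc$trim3,
          seed = seed + 9000L + 10L * ci + r)
        sim <- simulateProfiling(cds, spec)
        lens <- stats::setNames(nchar(cds), names(cds))
        fpCov <- trimCoverageSet(sim$footprints, lens, pc$trim5, pc$trim3)
        rnaCov <- trimCoverageSet(sim$rna, lens, pc$trim5, pc$trim3)
        repTabs[[r]] <- pauseScores(fpCov, rnaCov, cds, lens,
                                    window = pc$window,
                                    minDensity = pc$min_density)
      }
      avg <- averagePauseScores(repTabs)
      utils::write.table(avg, file.path(outDir,
        paste0("pause_scores_", cond, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
      res[[cond]] <- avg
    }
    res
  })

  ## ---- summary ------------------------------------------------------------
  focal <- config$decay$focal_codon
  summary <- list(
    package_version = as.character(utils::packageVersion("codonDecay")),
    seed = seed,
    parameters = unclass(config),
    focal_codon = focal,
    csc_focal = lapply(decayOut, function(x)
      x$csc$csc[x$csc$codon == focal]),
    pause_focal = lapply(pauseOut, function(x)
      x$mean[x$codon == focal]),
    bin_test_p = lapply(decayOut, function(x) x$binTest$p.value))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE),
             file.path(outDir, "summary.json"))
  invisible(list(csc = lapply(decayOut, `[[`, "csc"),
                 pause = pauseOut,
                 bins = lapply(decayOut, `[[`, "binTest"),
                 depthRatio = trnaOut$depthRatio,
                 halfLives = lapply(decayOut, `[[`, "fits")))
}
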