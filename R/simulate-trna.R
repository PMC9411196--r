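# Assemble one aligned read from its drawn events.
#
# A QuantM-seq style read runs from its (possibly internal) 5' end `start`
# to the 3' end of the reference (position L). Events:
#   del: integer positions deleted from the read
#   mis: named character vector, names = positions, values = read base
#   ins: named character vector, names = anchor positions (base inserted
#        immediately 3' of the anchor), values = inserted base
# Deletion and mismatch are mutually exclusive at a position (resolved by
# the caller); an insertion may share its anchor with either. Returns
# list(cigar, md, seq).
.buildRead <- function(start, refBases, del = integer(0),
                       mis = character(0), ins = character(0)) {
  L <- length(refBases)
  items <- data.frame(
    pos = c(del, as.integer(names(mis)), as.integer(names(ins))),
    type = rep(c("D", "X", "I"), c(length(del), length(mis), length(ins))),
    base = c(rep(NA_character_, length(del)), unname(mis), unname(ins)),
    stringsAsFactors = FALSE)
  # at equal positions a deletion/mismatch precedes an insertion (anchored 3')
  items <- items[order(items$pos, match(items$type, c("D", "X", "I"))), ]

  cigOp <- character(0); cigLen <- integer(0)
  addOp <- function(op, len) {
    if (len == 0L) return()
    k <- length(cigOp)
    if (k && cigOp[k] == op) cigLen[k] <<- cigLen[k] + len
    else { cigOp[k + 1L] <<- op; cigLen[k + 1L] <<- len }
  }
  mdParts <- character(0)
  mdGap <- 0L
  lastWasDel <- FALSE
  flushMd <- function() {
    mdParts[length(mdParts) + 1L] <<- as.character(mdGap)
    mdGap <<- 0L
  }
  seqParts <- character(0)
  cur <- start  # next unaccounted reference position
  for (i in seq_len(nrow(items))) {
    p <- items$pos[i]; ty <- items$type[i]
    gap <- p - cur
    if (ty == "I") gap <- gap + 1L  # anchor base itself is a match
    if (gap > 0L) {
      addOp("M", gap)
      mdGap <- mdGap + gap
      seqParts <- c(seqParts, paste(refBases[cur:(cur + gap - 1L)], collapse = ""))
      cur <- cur + gap
      lastWasDel <- FALSE
    }
    if (ty == "D") {
      addOp("D", 1L)
      if (lastWasDel && mdGap == 0L) {
        mdParts[length(mdParts)] <- paste0(mdParts[length(mdParts)], refBases[p])
      } else {
        flushMd()
        mdParts[length(mdParts) + 1L] <- paste0("^", refBases[p])
      }
      cur <- cur + 1L
      lastWasDel <- TRUE
    } else if (ty == "X") {
      addOp("M", 1L)
      flushMd()
      mdParts[length(mdParts) + 1L] <- refBases[p]
      seqParts <- c(seqParts, items$base[i])
      cur <- cur + 1L
      lastWasDel <- FALSE
    } else {
      addOp("I", 1L)
      seqParts <- c(seqParts, items$base[i])
      lastWasDel <- FALSE
    }
  }
  if (cur <= L) {
    addOp("M", L - cur + 1L)
    mdGap <- mdGap + (L - cur + 1L)
    seqParts <- c(seqParts, paste(refBases[cur:L], collapse = ""))
  }
  flushMd()
  list(cigar = paste0(cigLen, cigOp, collapse = ""),
       md = paste(mdParts, collapse = ""),
       seq = paste(seqParts, collapse = ""))
}

.otherBase <- function(base, u) .BASES[-match(base, .BASES)][ceiling(u * 3)]

# Simulate reads for a single gene; returns a data.frame of SAM-style records.
.simulateGeneReads <- function(geneId, refSeq, profile, nReads, idPrefix) {
  L <- nchar(refSeq)
  if (length(profile) != L)
    stop("profile length (", length(profile), ") does not match reference '",
         geneId, "' length (", L, ")")
  refBases <- strsplit(refSeq, "")[[1]]
  pFull <- 1 - sum(profile@stop)
  start <- sample.int(L, nReads, replace = TRUE,
                      prob = c(pFull, profile@stop[-1]))
  # event draws per position with non-zero probability, for covering reads
  ev <- list()
  for (q in which(profile@mismatch > 0)) {
    idx <- which(start <= q)
    hit <- idx[stats::runif(length(idx)) < profile@mismatch[q]]
    if (length(hit))
      ev[[length(ev) + 1L]] <- data.frame(
        read = hit, pos = q, type = "X",
        base = .otherBase(refBases[q], stats::runif(length(hit))))
  }
  for (q in which(profile@deletion > 0)) {
    idx <- which(start <= q)
    hit <- idx[stats::runif(length(idx)) < profile@deletion[q]]
    if (length(hit))
      ev[[length(ev) + 1L]] <- data.frame(read = hit, pos = q, type = "D",
                                          base = NA_character_)
  }
  for (q in which(profile@insertion > 0)) {
    idx <- which(start <= q)
    hit <- idx[stats::runif(length(idx)) < profile@insertion[q]]
    if (length(hit))
      ev[[length(ev) + 1L]] <- data.frame(
        read = hit, pos = q, type = "I",
        base = .BASES[ceiling(stats::runif(length(hit)) * 4)])
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(read = integer(), pos = integer(), type = character(),
               base = character())
  # a deletion suppresses a mismatch drawn at the same covered position
  if (nrow(events)) {
    delKey <- with(events[events$type == "D", ], paste(read, pos))
    drop <- events$type == "X" & paste(events$read, events$pos) %in% delKey
    events <- events[!drop, , drop = FALSE]
  }

  cigar <- md <- seqs <- character(nReads)
  plain <- setdiff(seq_len(nReads), unique(events$read))
  if (length(plain)) {
    span <- L - start[plain] + 1L
    cigar[plain] <- paste0(span, "M")
    md[plain] <- as.character(span)
    seqs[plain] <- substring(refSeq, start[plain], L)
  }
  if (nrow(events)) {
    byRead <- split(events, events$read)
    for (nm in names(byRead)) {
      e <- byRead[[nm]]
      i <- as.integer(nm)
      mis <- e$base[e$type == "X"]; names(mis) <- e$pos[e$type == "X"]
      ins <- e$base[e$type == "I"]; names(ins) <- e$pos[e$type == "I"]
      r <- .buildRead(start[i], refBases, del = e$pos[e$type == "D"],
                      mis = mis, ins = ins)
      cigar[i] <- r$cigar; md[i] <- r$md; seqs[i] <- r$seq
    }
  }
  data.frame(read_id = paste0(idPrefix, seq_len(nReads)),
             flag = 0L, ref_id = geneId, ref_start = start,
             cigar = cigar, md = md, seq = seqs, seq_len = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Simulate tRNA-seq alignments with modification signatures
#'
#' For each read, an RT-stop position is drawn from the profile's stop
#' distribution (or full length with the remaining probability); the read
#' then spans from that 5' end to the reference 3' end, and mismatch /
#' 1-nt-insertion / 1-nt-deletion events are drawn independently at each
#' covered position. The emitted CIGAR and MD strings encode exactly the
#' drawn events, and seeded runs are bit-reproducible.
#'
#' @param reference a [TrnaReference-class]
#' @param profiles named list of [ModificationProfile-class], keyed by gene id
#'   (keys must exist in the reference)
#' @param nReads reads per gene; a scalar or a vector named by gene id
#' @param seed integer seed
#' @return data.frame of alignment records (see [readSamRecords()] layout)
#' @seealso [writeSamRecords()] to emit SAM text, [variantProfile()] to
#'   recover the signatures
#' @export
simulateTrnaAlignments <- function(reference, profiles, nReads, seed = 0) {
  stopifnot(is(reference, "TrnaReference"))
  if (any(nReads <= 0)) stop("nReads must be positive")
  ids <- names(profiles)
  if (is.null(ids) || !all(ids %in% geneIds(reference)))
    stop("profiles must be keyed by gene ids present in the reference")
  n <- if (length(nReads) == 1) stats::setNames(rep(nReads, length(ids)), ids)
       else if (is.null(names(nReads)) && length(nReads) == length(ids))
         stats::setNames(nReads, ids)
       else nReads[ids]
  if (anyNA(n)) stop("nReads must cover every profiled gene")
  withr::with_seed(seed, {
    out <- lapply(ids, function(g)
      .simulateGeneReads(g, refSequences(reference)[[g]], profiles[[g]],
                         n[[g]], paste0(g, ".r")))
    do.call(rbind, out)
  })
}

#' Simulate a two-population mixture of tRNA reads
#'
#' Emulates a dilution series mixing RNA from a modified and an unmodified
#' population: each read is drawn from `profileA` with probability
#' `fractionA` and from `profileB` otherwise, so every per-position event
#' fraction is linear in the mixing fraction in expectation.
#'
#' @param reference a [TrnaReference-class] (the profiled gene's reference)
#' @param geneId gene to simulate
#' @param profileA,profileB [ModificationProfile-class] objects
#' @param fractionA mixing fraction in `[0, 1]`
#' @param nReads total reads
#' @param seed integer seed
#' @return data.frame of alignment records
#' @export
simulateMixture <- function(reference, geneId, profileA, profileB, fractionA,
                            nReads, seed = 0) {
  if (fractionA < 0 || fractionA > 1) stop("fractionA must lie in [0, 1]")
  if (nReads <= 0) stop("nReads must be positive")
  withr::with_seed(seed, {
    nA <- stats::rbinom(1, nReads, fractionA)
    refSeq <- refSequences(reference)[[geneId]]
    parts <- list()
    if (nA > 0)
      parts$a <- .simulateGeneReads(geneId, refSeq, profileA, nA,
                                    paste0(geneId, ".a"))
    if (nReads - nA > 0)
      parts$b <- .simulateGeneReads(geneId, refSeq, profileB, nReads - nA,
                                    paste0(geneId, ".b"))
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  })
}
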