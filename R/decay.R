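#' Simulate a spike-in-normalized decay time course
#'
#' Emulates a pulse-chase metabolic-labeling experiment. Labeled transcript
#' mass decays as `exp(-ln2 t / T1/2)` with multiplicative lognormal noise;
#' the spike-in pool ("Luc" + "LYSa") has constant absolute mass across
#' timepoints. Reported FPKM is each transcript's share of the combined
#' (cellular + spike) pool scaled to FPKM units, so later timepoints carry
#' inflated spike fractions -- exactly the pool-shrinkage distortion that
#' [spikeNormalize()] must undo. Spike and total read counts are emitted as
#' real-valued expected read masses so that zero-noise courses invert
#' exactly.
#'
#' @param spec a [DecaySpec-class]
#' @return a [DecayCourse-class]
#' @export
simulateDecayCourse <- function(spec) {
  stopifnot(is(spec, "DecaySpec"))
  n <- length(spec@halfLives)
  tp <- spec@timepoints
  J <- length(tp)
  withr::with_seed(spec@seed, {
    base <- stats::rlnorm(n, meanlog = log(30), sdlog = 1.2)
    decay <- outer(spec@halfLives, tp, function(Th, t) 2^(-t / Th))
    # measurement noise applies to the chase samples; the 0 h sample is the
    # reference every trajectory is normalized to (y at 0 h is exactly 1)
    noise <- matrix(1, n, J)
    if (spec@noiseSd > 0 && J > 1)
      noise[, -1] <- stats::rlnorm(n * (J - 1), 0, spec@noiseSd)
    mass <- base * decay * noise
  })
  spikeMass <- spec@spikeMassFraction / (1 - spec@spikeMassFraction) *
    sum(base)
  pool <- colSums(mass) + spikeMass
  fpkm <- sweep(mass, 2, pool, "/") * 1e6
  ids <- sprintf("tx%05d", seq_len(n))
  dimnames(fpkm) <- list(ids, as.character(tp))
  totalReads <- rep(2e7, J)
  spikeReads <- rbind(Luc = totalReads * (spikeMass / 2) / pool,
                      LYSa = totalReads * (spikeMass / 2) / pool)
  colnames(spikeReads) <- as.character(tp)
  new("DecayCourse", fpkm = fpkm, timepoints = tp, spikeReads = spikeReads,
      totalReads = totalReads)
}

#' Spike-in normalization of a decay course
#'
#' Divides each sample's FPKM by its spike fraction `s_j = mean(reads_Luc,
#' reads_LYSa) / total_reads_j` and then renormalizes every trajectory to
#' its 0 h value, so `y[, "0"] == 1` exactly for all transcripts.
#'
#' @param course a [DecayCourse-class]
#' @return numeric matrix y (transcripts x timepoints, colnames = hours)
#' @export
spikeNormalize <- function(course) {
  stopifnot(is(course, "DecayCourse"))
  zero <- colSums(course@spikeReads) == 0
  if (any(zero)) {
    lab <- colnames(course@spikeReads)
    if (is.null(lab)) lab <- as.character(course@timepoints)
    stop("zero spike-in reads in sample(s): ",
         paste(lab[zero], collapse = ", "))
  }
  s <- spikeFraction(course)
  norm <- sweep(rawFpkm(course), 2, s, "/")
  t0 <- which(course@timepoints == 0)
  y <- norm / norm[, t0]
  y
}

#' Filter transcripts before half-life fitting
#'
#' A transcript is excluded if its raw FPKM at 0 h is below `minFpkm0`
#' (rule A) or if its raw FPKM is zero at both 1 h and 2 h (rule B); by
#' default the union of the two rules is applied. The conjunctive reading
#' (both conditions required) is selectable for sensitivity analysis.
#'
#' @param course a [DecayCourse-class] whose timepoints include 0, 1 and 2 h
#' @param mode `"union"` (default: excluded if A or B) or `"conjunctive"`
#'   (excluded only if A and B)
#' @param minFpkm0 rule-A threshold on 0 h FPKM (default 1)
#' @param earlyHours the two early chase timepoints of rule B (default 1, 2)
#' @return list with `retained` (character ids) and `log` (data.frame
#'   `transcript_id`, `rule` for each exclusion)
#' @export
filterTranscripts <- function(course, mode = c("union", "conjunctive"),
                              minFpkm0 = 1, earlyHours = c(1, 2)) {
  mode <- match.arg(mode)
  stopifnot(is(course, "DecayCourse"))
  tp <- course@timepoints
  if (!all(c(0, earlyHours) %in% tp))
    stop("course must contain the 0 h and early (", paste(earlyHours,
         collapse = ", "), " h) timepoints")
  f <- rawFpkm(course)
  a <- f[, match(0, tp)] < minFpkm0
  b <- rowSums(f[, match(earlyHours, tp), drop = FALSE] == 0) ==
    length(earlyHours)
  excl <- if (mode == "union") a | b else a & b
  rule <- ifelse(a & b, "A+B", ifelse(a, "A", "B"))
  list(retained = rownames(f)[!excl],
       log = data.frame(transcript_id = rownames(f)[excl],
                        rule = rule[excl], stringsAsFactors = FALSE))
}

.goldenMin <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2) }
  }
  if (f1 <= f2) c(k = c1, obj = f1) else c(k = c2, obj = f2)
}

#' Least-absolute-deviations exponential half-life fit
#'
#' Fits `y(t) = exp(-k t)` (amplitude fixed at 1, since trajectories are
#' normalized to their 0 h value) by minimizing the sum of absolute
#' deviations over a dense grid on `k` in `[0, ln2 / minHalfLife]` followed
#' by golden-section refinement to `|dk| < 1e-6`. The objective is evaluated
#' on the linear scale, so zero observations are admissible. Ties on the
#' grid resolve to the smallest `k` (longest half-life). Half-lives longer
#' than `capHours` are censored and reported at the cap.
#'
#' With `freeAmplitude = TRUE` a two-parameter fit `y(t) = A exp(-k t)` is
#' used: for fixed `k` the LAD-optimal amplitude is a weighted median,
#' computed exactly inside the same grid/golden search.
#'
#' @param y normalized trajectory (y at 0 h must be 1); `NA` values are
#'   dropped from the objective
#' @param timepoints hours, same length as `y`, including 0
#' @param capHours censoring cap (default 6)
#' @param minHalfLife shortest resolvable half-life, sets the upper bound of
#'   the `k` grid (default 0.1 h)
#' @param gridSize number of grid points (default 512)
#' @param freeAmplitude fit a free amplitude (default `FALSE`)
#' @return one-row data.frame: `k` (1/h), `half_life` (h, capped),
#'   `censored`, `objective`, `n_points`, `amplitude`
#' @examples
#' fitHalfLife(c(1, .5, .25, .0625, .015625), c(0, 1, 2, 4, 6))$half_life
#' @export
fitHalfLife <- function(y, timepoints, capHours = 6, minHalfLife = 0.1,
                        gridSize = 512, freeAmplitude = FALSE) {
  if (length(y) != length(timepoints))
    stop("y and timepoints must have equal length")
  if (!0 %in% timepoints[!is.na(y)])
    stop("trajectory is missing its 0 h observation")
  keep <- !is.na(y)
  y <- y[keep]; tt <- timepoints[keep]
  if (length(y) < 3)
    stop("fewer than 3 usable points in trajectory")
  if (sum(tt > 0) < 1) stop("no usable post-chase points")
  kMax <- log(2) / minHalfLife
  grid <- seq(0, kMax, length.out = gridSize)
  amp <- function(k) {
    if (!freeAmplitude) return(1)
    g <- exp(-k * tt)
    o <- order(y / g)
    w <- g[o] / sum(g)
    (y / g)[o][which(cumsum(w) >= 0.5)[1]]  # weighted median
  }
  obj <- function(k) {
    A <- amp(k)
    sum(abs(y - A * exp(-k * tt)))
  }
  vals <- vapply(grid, obj, 0)
  i <- which.min(vals)  # first minimum = smallest k on ties
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, gridSize)]
  ref <- .goldenMin(obj, lo, hi)
  if (ref[["obj"]] < vals[i] ||
      (ref[["obj"]] == vals[i] && ref[["k"]] < grid[i])) {
    k <- ref[["k"]]; o <- ref[["obj"]]
  } else {
    k <- grid[i]; o <- vals[i]
  }
  rawT <- if (k > 0) log(2) / k else Inf
  censored <- rawT > capHours
  data.frame(k = k, half_life = min(rawT, capHours), censored = censored,
             objective = o, n_points = length(y), amplitude = amp(k))
}

#' Fit half-lives for a matrix of normalized trajectories
#'
#' Applies [fitHalfLife()] row-wise. Transcripts with fewer than 3 usable
#' points (or a missing 0 h value) are excluded and reported in the
#' `excluded` attribute rather than fitted.
#'
#' @param y matrix from [spikeNormalize()] (transcripts x timepoints,
#'   colnames = hours)
#' @param timepoints hours; defaults to `as.numeric(colnames(y))`
#' @inheritParams fitHalfLife
#' @return data.frame with one row per fitted transcript (`transcript_id`,
#'   `k`, `half_life`, `censored`, `objective`, `n_points`); excluded ids in
#'   `attr(, "excluded")`
#' @export
fitHalfLives <- function(y, timepoints = NULL, capHours = 6,
                         minHalfLife = 0.1, gridSize = 512,
                         freeAmplitude = FALSE) {
  if (is.null(timepoints)) timepoints <- as.numeric(colnames(y))
  if (anyNA(timepoints)) stop("timepoints could not be inferred from colnames")
  fits <- vector("list", nrow(y))
  excluded <- character(0)
  for (i in seq_len(nrow(y))) {
    fit <- tryCatch(
      fitHalfLife(y[i, ], timepoints, capHours, minHalfLife, gridSize,
                  freeAmplitude),
      error = function(e) NULL)
    if (is.null(fit)) excluded <- c(excluded, rownames(y)[i])
    else fits[[i]] <- cbind(transcript_id = rownames(y)[i], fit)
  }
  out <- do.call(rbind, fits[!vapply(fits, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(transcript_id = character(), k = numeric(),
                      half_life = numeric(), censored = logical(),
                      objective = numeric(), n_points = integer(),
                      amplitude = numeric())
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
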