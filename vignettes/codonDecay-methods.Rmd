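---
title: "Models and methods behind codonDecay"
author: "codonDecay authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind codonDecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonDecay)
```

## The scientific problem

Decoding speed is not uniform across codons: it depends on the abundance
and, critically, the modification state of the cognate tRNAs. Because a
hesitating ribosome is recognized by the mRNA degradation machinery, codon
composition feeds back on transcript stability — codon optimality-mediated
mRNA decay (CO-MD). When a cell type carries hypomodified anticodon loops on
specific tRNAs (for example Phe-GAA and Lys-UUU in differentiating glia),
their cognate codons can flip from stabilizing to destabilizing, ribosomes
dwell longer on them, and transcripts enriched in those codons decay
faster.

codonDecay implements the complete computational chain needed to observe
this axis: (1) tRNA modification read-out from sequencing alignments,
(2) spike-in-normalized mRNA half-life estimation from metabolic-labeling
time courses, (3) Codon Stabilization Coefficients and synonymous
codon-bias binning, and (4) windowed per-codon ribosome pause scores. A
matched set of seeded generators emulates each experiment so every stage is
testable end to end without external data.

## tRNA modification read-out

Reverse transcription across a modified nucleotide either misreads it
(mismatch, 1-nt insertion or deletion in the read) or aborts, leaving a
read whose 5' end is internal to the mature tRNA. `variantProfile()`
tabulates the four event classes per reference position by walking the MD
tag against the reference-consuming CIGAR operations:

* mismatches at the reference coordinate the MD tag names;
* deletions at each deleted reference position;
* insertions at the reference base immediately 5' of the insertion point
  (one event per insertion operation);
* one RT-stop event at the read's 5'-most aligned position `p` whenever
  `p > 1`.

The variant fraction `f(p)` divides the summed event counts by the total
reads assigned to the gene, not by per-position coverage: stop events at
`p` are contributed by reads that do not cover positions 5' of `p`, so a
coverage denominator would be ill-defined for the combined fraction. When
a recovered *event probability* is compared against a generative truth, the
natural denominator differs by event type — reads covering the position for
mismatch/indel events (use `depthProfile()`), all assigned reads for stop
events — and the tests make exactly that distinction. Positions are plain
1-based indices along the collapsed mature reference; no structural
(Sprinzl-style) numbering is attempted.

Reads with unparseable or inconsistent CIGAR/MD pairs are skipped, excluded
from the denominator, and reported in the profile's QC slots; a missing MD
tag is an error because without it mismatches cannot be located at all.

The simulator (`simulateTrnaAlignments()`) draws, per read, first an
RT-stop position from the per-position stop distribution (the remaining
mass is full length), then independent per-covered-position mismatch /
1-nt insertion / 1-nt deletion events, and emits CIGAR/MD strings that
encode exactly the drawn events. RT stop and miscoding are drawn
independently — the two observable signatures are produced separately, with
no joint modification model. When a deletion and a mismatch are drawn at
the same position the deletion wins, since a deleted base cannot also
mismatch. `simulateMixture()` mixes two profiles read-by-read, which makes
every event fraction linear in the mixing fraction in expectation — the
in-silico analogue of a dilution series of modified and unmodified RNA.

## Half-life estimation

The decay experiment measures FPKM trajectories over a chase (default
timepoints 0, 1, 2, 4, 6 h) in a *shrinking* labeled RNA pool. Because a
constant mass of labeled spike-in RNA (two features, "Luc" and "LYSa") is
added to every sample, the spike share of each library measures the
inverse pool size: dividing FPKM by the spike fraction
`s_j = mean(reads_Luc, reads_LYSa) / total_reads_j` restores abundances on
a common absolute scale, and dividing by the 0 h value gives trajectories
with `y(0) = 1` exactly.

Transcripts are filtered before fitting: raw FPKM below 1 at 0 h, or zero
FPKM at both 1 h and 2 h, excludes a transcript (the union of the two
rules; the conjunctive reading is selectable via `mode = "conjunctive"`,
but it would retain transcripts whose 0 h value cannot anchor the
normalization, which is why the union is the default).

`fitHalfLife()` estimates the decay rate by least absolute deviations:

$$\hat k = \arg\min_{k \ge 0} \sum_j \lvert y_j - e^{-k t_j} \rvert,
\qquad T_{1/2} = \ln 2 / \hat k .$$

Numerical choices:

* the objective is evaluated on the **linear** scale — LAD on logs is
  undefined at `y = 0`, and genuine zero FPKM values at late timepoints
  are retained;
* the amplitude is fixed at 1 because trajectories are normalized to 0 h;
  a free-amplitude variant (`freeAmplitude = TRUE`) solves the inner LAD
  amplitude problem exactly as a weighted median, for sensitivity
  analyses;
* the search runs a 512-point grid on `k` in `[0, ln 2 / 0.1]` (shortest
  resolvable half-life 0.1 h) followed by golden-section refinement to
  `|Δk| < 10^{-6}`; grid ties resolve to the smallest `k`, i.e. the
  longest (most conservative) half-life;
* half-lives above 6 h are censored at 6 h — the chase simply does not
  constrain slower decay — and flagged;
* missing timepoints are dropped from the objective; trajectories with
  fewer than three usable points are excluded and logged.

The generator (`simulateDecayCourse()`) decays per-transcript mass as
`exp(-ln2 · t / T½)`, keeps the spike mass constant, and reports each
feature's share of the combined pool in FPKM units — precisely the
distortion the spike normalization must undo. Two conventions deserve
justification. First, multiplicative lognormal measurement noise (default
sdlog 0.2) is applied to the chase samples; the 0 h sample is the
noise-free reference. This matches the definition of the normalized
trajectory (`y(0) = 1` exactly): a noisy anchor would act as a common
scale error on every later ratio and would be indistinguishable from a
rate shift for a fixed-amplitude estimator. Second, spike and total read
counts are emitted as real-valued expected read masses rather than
Poisson-rounded integers, so zero-noise courses invert exactly to their
closed-form trajectories — convenient for verification and irrelevant at
realistic depths (the rounding error at 2×10^7 total reads is below
10^-5). The spike mass is 1% of the labeled pool at 0 h, a typical
magnitude for an enriched-pool spike-in.

## Codon statistics

Codon frequencies are counted in-frame (window 3, step 3, via
`Biostrings::oligonucleotideFrequency`) over CDSs that start with ATG and
have length divisible by 3; the count is divided by the *total* codon
count, so the terminal stop codon is in the denominator while only the 61
sense codons are reported. The Codon Stabilization Coefficient of a codon
is the Pearson correlation between its frequency and transcript half-life
across transcripts; censored half-lives enter at their 6 h face value
(they carry real ordering information, and excluding them is available for
sensitivity analysis by filtering the half-life table first). Zero-variance
columns yield missing CSCs with a warning rather than NaNs.

Synonymous codon bias, `b = n_focal / (n_focal + n_partner)` (e.g.
UUU/(UUU+UUC)), is binned into 5 equal-count (quantile) bins by default;
tied bias values stay in a single bin, so counts can be unequal under heavy
ties. Five bins places roughly 1,600–1,750 transcripts per bin on an
8,000-transcript half-life set, matching the granularity typical of such
analyses; the count is configurable and the realized bin boundaries are
always reported. Differences in half-life across bins are tested with the
Kruskal–Wallis rank test (standard tie correction, chi-square
approximation). One degenerate case is defined explicitly: if every
half-life is identical the test reports `H = 0, p = 1`, since the tie
correction denominator vanishes there.

Codons are matched against DNA CDS sequences internally and reported in
the RNA alphabet (UUU, not TTT) in all user-facing tables; `codonToRna()`
and `codonToDna()` are the fixed bijection at that boundary.

## Ribosome pause scores

Footprint reads (MNase-protected, typically 30 nt) are trimmed by 9 nt
from the 5' end and 12 nt from the 3' end to smooth the density profile,
accumulated into per-CDS coverage, and normalized to the CDS mean, giving
a density `ρ` with mean exactly 1 per retained CDS. CDSs with fewer than 1
assigned (untrimmed) read per codon are discarded.

For every occurrence of a codon at positions `[p, p+2]`, the 50 nt on
either side — `[p-50, p-1]` and `[p+3, p+52]`, excluding the codon itself,
exactly 100 density values — are summed. Occurrences whose window would
cross a CDS boundary are skipped rather than zero-padded, keeping the
footprint numerator and the RNA-seq denominator (processed with identical
trimming and normalization) over identical supports. The pause score is
the ratio of summed footprint density to summed RNA density over all kept
occurrences (ratio of sums, robust to zero-coverage windows; per-occurrence
ratio averaging is the obvious alternative but divides by noisy
denominators). Replicates are scored independently and averaged at the
score level. No A-/P-site offsetting is attempted: MNase footprints do not
support reliable site assignment, so coverage is positional only — which
is exactly why the windowed score is used in the first place.

The generator samples footprint 5' ends with probability proportional to
the dwell multiplier of the codon at the *center of the trimmed span*.
With the default 30-nt footprints the 9-nt trimmed span smooths each
pause over neighbouring codons, as real footprints do; with 24-nt reads
the trimmed span is a single codon and the sampling weights are exactly
recoverable from central-base coverage, which is how the generator itself
is verified. Matched RNA-seq reads are uniform regardless of dwell.

Ribosome density (RD), a translational-efficiency proxy, is footprint
FPKM over the CDS divided by RNA FPKM over the transcript, with
`FPKM = reads × 10^9 / (length × total)`; RD is missing when the RNA FPKM
is zero.

## The end-to-end synthetic study

`runPipeline(demoRunConfig(seed), outDir)` simulates and analyzes a
two-condition experiment ("progenitor" vs "differentiated") built to carry
the expected biological contrasts:

* the focal tRNAs (Phe-GAA, Lys-UUU) carry a strong RT-stop/mismatch
  signature in progenitors (stop 0.5, mismatch 0.25 at the anticodon loop)
  that is much weaker in differentiated cells (0.1 / 0.05) — so the
  progenitor/differentiated depth ratio drops 5' of the modified site;
* half-lives are linked to the focal codon's frequency with slope +8 h per
  unit frequency in progenitors and −8 in differentiated cells
  (an optimality flip), around a 2.5 h intercept with 0.2 h noise;
* ribosome dwell at the focal codon is 2.5× in differentiated cells.

Problem sizes are 2,000 transcripts for the decay/CSC stage, a
300-transcript subset at 200 footprints per transcript for profiling, and
10,000 tRNA reads per gene per replicate, with two replicates per
condition — large enough that every designed contrast is comfortably
resolved, small enough that the full demo runs in well under a minute on
one CPU. All randomness flows from the single config seed, and repeated
runs are byte-identical (the JSON summary deliberately contains no
timestamps).

## What the generators do and do not emulate

The simulators reproduce the *statistical structure* the analyses rely on:
modification-dependent mismatch and 5'-truncation signatures with exact
CIGAR/MD encoding, exponential decay against a constant spike mass with
multiplicative noise, codon-dependent footprint placement with uniform
matched RNA. They do not model base-call qualities, ligation or PCR bias,
multi-mapping between near-identical tRNA genes, positional library
artifacts, or UTRs (alignments are in CDS coordinates; genome-to-transcript
projection is out of scope). Passing the recovery tests therefore
demonstrates that the estimators are correct and well-calibrated under the
assumed error model — not that they are immune to every artifact of real
libraries, which is what the spike-ins, matched RNA normalization and
replicate averaging are there to absorb.

## Known limitations

* Variant fractions are additive over the four event classes; a read
  contributes at most one event per class per position, but classes are
  not mutually exclusive, so `f(p)` is an event rate, not a read fraction.
* The LAD fit assumes a single-exponential decay with unit amplitude;
  biphasic decay or incomplete labeling would bias half-lives (the
  free-amplitude flag is a partial diagnostic).
* Pause scores are positional, not site-resolved: a pause shows up in the
  100-nt window of *nearby* occurrences too, which dilutes but does not
  reorder strong signals.
* The Kruskal–Wallis chi-square approximation assumes reasonably filled
  bins; with very few transcripts per bin an exact test would be needed.
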