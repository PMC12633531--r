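---
title: "Methods: detecting, timing and attributing kataegis"
author: "kataegisStorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, timing and attributing kataegis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The phenomenon and the model

Kataegis is focal hypermutation of a tumour genome: a burst of closely
spaced somatic single-nucleotide variants (SNVs), typically C-to-T and
C-to-G changes in a TpC context, produced in one action of an APOBEC3
cytidine deaminase on transiently exposed single-stranded DNA. In a
"rainfall" plot of inter-mutational distance (IMD) against genomic
position, a kataegis event appears as a run of points several orders of
magnitude below the background band.

The pipeline implements five analysis layers on top of that definition:

1. **Detection** — per chromosome, the sorted SNV positions give
   `imd[i] = pos[i+1] - pos[i]`. The log10 IMD sequence is segmented by
   exact penalized least squares (piecewise constant fitting, PCF), each
   raw distance is replaced by its segment mean, and every maximal run of
   consecutive adjusted distances below `dMax` with at least `kmin`
   member SNVs becomes an event.
2. **Evolutionary timing** — each SNV is placed in a tumour-evolution
   epoch from its cancer cell fraction (CCF), mutation multiplicity and
   local allele-specific copy number; events are refined into per-epoch
   "evolutionary kataegis" subsets that must re-pass the detection
   criteria.
3. **APOBEC attribution** — each event's mutated-cytosine motif counts
   (C, TCW, YTCW, RTCW; W = A/T, Y = C/T, R = A/G, the mutated C central
   and pyrimidine-normalized across strands) are compared with the
   sample's non-clustered SNVs by a one-sided Fisher test, adjusted for
   motif accessibility in the ±20 bp sequence context; enriched events
   are sub-attributed to APOBEC3A (YTCW skew) or APOBEC3B (RTCW skew).
4. **SV proximity** — each event's distance to the nearest structural
   variant breakend is compared with a null built from 1,000 pseudo
   events per real event (same span, centred on random non-clustered
   SNVs of the same sample), binned into log-spaced distance bins;
   rank-based empirical p-values per bin classify events as
   SV-associated (enriched bins) or SV-independent (sparse bins).
5. **Cohort statistics** — burden outlier exclusion (z > 3, single
   pass), Wilcoxon and Fisher group comparisons with
   Benjamini–Hochberg (BH) FDR adjustment, driver co-occurrence,
   negative-binomial burden regression with log(1+x)-transformed skewed
   covariates, and Kaplan–Meier/log-rank survival stratification.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `kmin` | 4 | SNVs | minimum members per event |
| `dMax` | 1000 | bp | adjusted-IMD calling threshold |
| `pcfGamma` | 25 | noise variances | per-segment PCF penalty |
| `flank` | 20 | bp/side | motif accessibility window (41-mer) |
| `nSim` | 1000 | draws | pseudo events per real event |
| `distanceBinEdges` | 0,1k,10k,0.1M,1M,10M,100M,Inf | bp | proximity bins |
| `outlierZ` | 3 | z | burden outlier exclusion |
| `alpha` | 0.05 | — | FDR level of every test family |
| `clonalCcfThreshold` | 0.9 | CCF | clonal/subclonal cut |
| `burdenSplit` | 1 | events | survival burden stratification |

The threshold pair (`kmin`, `dMax`) is deliberately fixed for all
samples; `expectedImdDiagnostic(n, L) = L/n` is reported per sample so
users can confirm that 1 kb sits far below each sample's random
expectation (about 1 Mb at typical prostate-tumour burdens).

# Numerical choices

**Exact segmentation.** `pcfSegment()` minimizes
`sum of within-segment squared error + gamma × (number of segments)` by
an O(n²) dynamic program, so results are exactly reproducible and can be
verified against exhaustive enumeration (the test suite does this for
all inputs up to n = 12). Ties are broken toward fewer segments, then
earlier segment starts; empty input returns an empty segmentation.

**Penalty units.** The penalty is counted in units of noise variance,
the convention of the standard PCF implementations this field uses. For
a locally Poisson background the sd of log10 spacings is rate-free,
`pi/sqrt(6)/ln 10 ≈ 0.557`, so log10 IMDs are scaled by that constant
before segmentation. A data-driven robust estimate was rejected: it is
contaminated precisely on kataegis-dense chromosomes, where half the
spacings belong to clusters.

**Adjusted distance.** `adjustedImd()` supports the arithmetic segment
mean (its own default) and the back-transformed mean of log distances
(geometric mean). Calling uses the geometric mean: segmentation is
performed in log space, and the arithmetic mean lets a single
background-scale gap that the optimizer attached to a cluster segment
drag the whole event above `dMax` (measured cost: about 6% of planted
events lost at default conditions). With the geometric mean the event
survives; as a guard against the converse failure — smoothing bridging
two clusters across one background-scale gap — candidate runs are split
at any raw gap of 10 × `dMax` or more, since SNVs ten kilobases apart
are not part of one focal cluster. At segment ties (all gaps equal) the geometric mean
returns the common value exactly, keeping the strict `< dMax` boundary
behaviour exact at, e.g., a uniform 999/1000 bp spacing.

**Epoch rules.** Subclonal if CCF < 0.9 (point estimate; no interval
machinery). Clonal SNVs on a gained segment (major copy number ≥ 2) are
early if multiplicity ≥ 2 (the mutation preceded the gain) and late if
multiplicity 1; copy-neutral loci give `clonal_unspecified`. Missing
annotations give `unknown`, which is excluded from all proportions.
Within-subset distances during refinement are raw successive distances:
PCF is meaningless at event-sized n.

**Accessibility-adjusted Fisher table.** The 2×2 table rescales the
*background* TCW count by
`a = (ctx_tcw_ev/ctx_c_ev)/(ctx_tcw_bg/ctx_c_bg)`, clamped into the
background total. Rescaling the event side instead is an equally
defensible construction; raw counts are always emitted so either can be
recomputed. Context windows are merged (`IRanges::reduce`) before motif
counting so dense clusters do not double-count; N-containing contexts
are dropped and reported.

**Rank p-values are discrete.** The proximity p-value
`(1 + #{sim ≥ obs})/(nSim + 1)` is a discrete probability integral
transform: it is uniform only up to jumps the size of the null count
pmf. In sparse bins (0–1 kb under no coupling, where the expected count
is ~0) the p-value mass sits at 1 by construction, and *any* faithful
implementation fails a Kolmogorov–Smirnov uniformity check there. The
calibration experiment therefore pools roughly 300 events per replicate
cohort and applies the KS check (99% band, 200 replicates) to the
0.1–1 Mb bin, where null counts are approximately Binomial(300, 0.55)
and the discreteness gap (max pmf ≈ 0.05) is well inside the band.

**Degenerate inputs.** Chromosomes with fewer than two SNVs are skipped;
duplicate records are collapsed by the readers and duplicate positions
by the caller (an IMD of zero would break the log transform); samples
with no non-clustered SNVs are excluded from the simulation null with a
log line; zero-variance burden vectors flag no outliers; events with no
cytosine mutations get p = 1 and a note rather than an error.

# What the synthetic cohort generator emulates

`generateCohort()` produces, deterministically from one seed: an i.i.d.
uniform reference genome (default 3 × 50 Mb); background SNVs at 1/Mb
with uniform substitutions; planted kataegis in 40% of samples (median
two events per positive, at most 13; median six members over a median
2.7 kb span) whose members sit on genuine TCW occurrences of the
reference with probability `apobecOmega = 0.9`, strand-coordinated with
probability 0.9, substituted C>T or C>G; SV breakend pairs (40 per
sample, five classes, 10% chromothripsis-flagged) with a configurable
fraction of events anchored within 10 kb of a breakpoint; a two-state
clonal/subclonal CCF architecture (subclonal CCF 0.4, Gaussian
observation noise sd 0.05, whole-chromosome 2+1 gains on 30% of
chromosomes timing early/late clonal mutations); and a clinical table
with ancestry, ISUP grade group, PSA, age and follow-up.

Planted events satisfy the kataegis spacing definition by construction
(every member gap < 1 kb): a "truth" event that does not meet the
phenomenon's definition would make recovery scores meaningless. The
fully-clonal refinement identity check sets the CCF observation noise to
zero, because with noise sd 0.05 a 0.9 threshold mislabels ~2% of truly
clonal mutations — a property of thresholded noisy CCFs, not of the
refinement logic under test.

The generator does **not** emulate: replication timing or expression
covariates of mutation rate, trinucleotide composition of a real genome
(its TCW availability among cytosines is the i.i.d. value 1/8, versus
~0.07–0.1 genome-wide in human), clustered non-kataegis mutation classes
(doublets, omikli), subclonal CCF mixtures with more than one subclone,
or read-level artefacts. Passing tests therefore demonstrate the
correctness and calibration of the algorithms under the stated
statistical structure, not performance on real tumour genomes.

# Problem sizes used by the test and acceptance runs

Detection recovery uses one 20-sample cohort on the 3 × 50 Mb genome
with planted events of ≥ 5 SNVs spanning ≤ 2.5 kb. Attribution power
uses ~100 six-member events (ω = 0.9) and the null error rate ~500
unbiased events. Proximity calibration uses 200 replicate cohorts of
~300 events each (`nSim` = 1000); the coupled condition uses
`couplingRho` = 0.8 at 10 kb. NB-regression coverage uses 200 replicates
of n = 500. The acceptance script runs the full pipeline twice on the
default 20-sample configuration and checks byte-identity of every
emitted table.

# Known limitations

* The early/late/unspecified epoch rules are standard multiplicity-based
  timing; pipelines with CCF confidence intervals or multi-clone
  deconvolution will disagree near the threshold.
* The accessibility adjustment enters through a rescaled background
  count rounded to an integer; for very small backgrounds the rounding
  granularity is visible in the odds ratio.
* Whether the rank test should be one-sided per direction or a single
  two-sided rank is ambiguous; both directions' p-values are emitted and
  BH-adjusted separately.
* The run-splitting constant (10 × `dMax`) is a heuristic guard against
  segment absorption; events genuinely spanning ≥ 10 kb internal gaps
  are out of the model's scope.
* Hooks exist for additional per-event candidate filters beyond the
  (`kmin`, `dMax`) rule, but none are applied by default.
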