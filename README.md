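# kataegisStorm

Kataegis — from the Greek for *thunderstorm* — is focal hypermutation of
a tumour genome: a burst of closely spaced somatic single-nucleotide
variants (SNVs), usually C>T/C>G changes in a TpC context, left by a
single action of an APOBEC3 cytidine deaminase on exposed single-stranded
DNA. In prostate cancer these events are rare but informative: they track
genomic instability, cluster near structural-variant (SV) breakpoints,
and carry prognostic signal.

`kataegisStorm` is an R package for whole-genome analysts who want a
tested, deterministic, end-to-end kataegis pipeline:

* **Detection.** Inter-mutational distances (IMD) per chromosome are
  segmented on the log10 scale by *exact* piecewise constant fitting
  (penalized least squares solved by dynamic programming), raw distances
  are replaced by segment means, and every maximal run of adjusted
  distances below 1 kb with ≥ 4 SNVs is an event:
  `min_seg Σ_seg Σ_i (v_i − mean_seg)² + γ·|segments|`, γ = 25 in units
  of the background noise variance.
* **Evolutionary timing.** SNVs are assigned to clonal (early / late /
  unspecified) or subclonal epochs from CCF, multiplicity and
  allele-specific copy number; events are refined into per-epoch
  evolutionary kataegis.
* **APOBEC attribution.** Accessibility-adjusted one-sided Fisher tests
  on mutated-cytosine TCW counts against the sample's non-clustered
  SNVs; enriched events are sub-attributed to APOBEC3A (YTCW) or
  APOBEC3B (RTCW), all FDR-adjusted (Benjamini–Hochberg).
* **SV proximity.** A simulation null of 1,000 pseudo events per real
  event (same span, centred on random non-clustered SNVs) yields
  rank-based p-values on log-spaced distance bins; events in enriched
  bins are SV-associated, in sparse bins SV-independent.
* **Cohort statistics.** Burden outlier exclusion (z > 3), Wilcoxon /
  Fisher comparisons, driver co-occurrence, negative-binomial burden
  regression, Kaplan–Meier / log-rank survival stratification.
* **Synthetic cohorts.** A fully deterministic generator plants kataegis
  with known truth labels (APOBEC bias, SV coupling, clonality) on a
  random reference, so every stage is testable without access-controlled
  patient data.

## Worked example

```r
library(kataegisStorm)

cfg    <- simConfig(nSamples = 4, chromLengths = c(chr1 = 2e6, chr2 = 2e6),
                    backgroundRate = 5, nSvs = 6, seed = 7)
cohort <- generateCohort(cfg)
events <- callKataegis(snvTable(cohort), detectionParams(), cohort@genome)
events
#> KataegisEvents: 2 event(s) in 1 sample(s)
#>   median n_snv 5, median span 1.71 kb
#>   params: kmin=4, dMax=1000 bp, gamma=25
scoreDetection(events, truthEvents(cohort))[1:2]
#> $sensitivity  [1] 0.5
#> $precision    [1] 1
```

(The deliberately tiny 2 Mb toy genome above makes some planted clusters
genuinely borderline; at the default 3 × 50 Mb study scale sensitivity
and precision both exceed 0.95 — the acceptance suite verifies this.)

The whole pipeline, driven by one config and one seed:

```r
runPipeline(list(seed = 17), "out/")   # simulate → detect → time →
                                       # apobec → svprox → report
jsonlite::read_json("out/summary.json")
```

`out/` then contains `events_final.tsv` (one row per event with epoch,
APOBEC class and SV class), `proximity.tsv` (per-group bin tests),
`cohort.tsv`, the comparison/regression/survival tables, and a
`manifest.json` with per-stage checksums; re-running with the same
config skips up-to-date stages and byte-identically reproduces every
table.

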