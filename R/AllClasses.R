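#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Reference genome container
#'
#' Wraps a named [Biostrings::DNAStringSet] and provides bounds-checked
#' sequence access. Chromosome order is the order of appearance in the set
#' and defines the sort order used throughout the package.
#'
#' @slot seq a named `DNAStringSet`, one entry per chromosome.
#' @slot cache an environment used for lazily computed per-genome indices
#'   (e.g. TCW site positions used by the synthetic generator).
#' @export
setClass("GenomeRef",
  representation(seq = "DNAStringSet", cache = "environment"))

setValidity("GenomeRef", function(object) {
  nm <- names(object@seq)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("all chromosomes must be named")
  if (anyDuplicated(nm)) return("chromosome names must be unique")
  if (any(Biostrings::width(object@seq) < 1L))
    return("chromosome lengths must be positive")
  TRUE
})

#' Construct a GenomeRef
#'
#' @param seq a named `DNAStringSet` or named character vector of sequences.
#' @return a [GenomeRef-class] object.
#' @export
#' @examples
#' g <- GenomeRef(c(chr1 = "ACGTACGTAC"))
#' chromLengths(g)
GenomeRef <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
  new("GenomeRef", seq = seq, cache = new.env(parent = emptyenv()))
}

#' Detection and analysis parameters
#'
#' Holds every tunable threshold of the pipeline. Defaults implement the
#' standard calling rule: at least `kmin = 4` SNVs whose PCF-adjusted
#' inter-mutational distances are all below `dMax = 1000` bp, with the
#' segmentation penalty `pcfGamma = 25` applied to log10 distances.
#'
#' @slot kmin minimum SNVs per event (>= 2).
#' @slot dMax adjusted inter-mutational distance threshold in bp.
#' @slot pcfGamma per-segment penalty of the exact PCF segmentation.
#' @slot flank bp of sequence context per side used for motif accessibility.
#' @slot nSim number of pseudo-events per real event in the SV null.
#' @slot distanceBinEdges strictly increasing log-spaced bin edges in bp.
#' @slot burdenSplit kataegis-count cut used for survival stratification.
#' @slot outlierZ z-score threshold for burden outlier exclusion.
#' @slot alpha FDR level for all test families.
#' @slot clonalCcfThreshold CCF below which an SNV is called subclonal.
#' @slot imdAdjust how the segment mean is back-substituted for raw
#'   distances: `"geometric"` (back-transform of the mean log10 distance,
#'   robust to a single large gap joining a cluster segment; the calling
#'   default) or `"arithmetic"`.
#' @slot rngSeed integer seed for the simulation null.
#' @export
setClass("DetectionParams",
  representation(kmin = "numeric", dMax = "numeric", pcfGamma = "numeric",
                 flank = "numeric", nSim = "numeric",
                 distanceBinEdges = "numeric", burdenSplit = "numeric",
                 outlierZ = "numeric", alpha = "numeric",
                 clonalCcfThreshold = "numeric", imdAdjust = "character",
                 rngSeed = "numeric"),
  prototype(kmin = 4, dMax = 1000, pcfGamma = 25, flank = 20, nSim = 1000,
            distanceBinEdges = c(0, 1e3, 1e4, 1e5, 1e6, 1e7, 1e8, Inf),
            burdenSplit = 1, outlierZ = 3, alpha = 0.05,
            clonalCcfThreshold = 0.9, imdAdjust = "geometric",
            rngSeed = 1))

setValidity("DetectionParams", function(object) {
  if (object@kmin < 2) return("kmin must be >= 2")
  if (object@dMax <= 0) return("dMax must be positive")
  if (object@pcfGamma <= 0) return("pcfGamma must be positive")
  if (any(diff(object@distanceBinEdges) <= 0))
    return("distanceBinEdges must be strictly increasing")
  if (object@distanceBinEdges[1] != 0)
    return("first distance bin edge must be 0")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  if (!object@imdAdjust %in% c("geometric", "arithmetic"))
    return("imdAdjust must be 'geometric' or 'arithmetic'")
  TRUE
})

#' @rdname DetectionParams-class
#' @param ... slot values overriding the defaults.
#' @return a `DetectionParams` object.
#' @export
#' @examples
#' detectionParams(pcfGamma = 25, kmin = 4)
detectionParams <- function(...) new("DetectionParams", ...)

#' Called kataegis events
#'
#' Container for the event table produced by [callKataegis()] and annotated
#' by the downstream stages (epoch refinement, APOBEC attribution,
#' SV-proximity classification), together with the parameters used.
#'
#' @slot events a data.frame with one row per event; `member_pos` is a
#'   list-column of member SNV positions.
#' @slot params the [DetectionParams-class] used for calling.
#' @export
setClass("KataegisEvents",
  representation(events = "data.frame", params = "DetectionParams"))

setValidity("KataegisEvents", function(object) {
  ev <- object@events
  need <- c("event_id", "sample_id", "chrom", "start", "end", "n_snv",
            "span", "max_adjusted_imd")
  miss <- setdiff(need, names(ev))
  if (length(miss)) return(paste("events missing column(s):",
                                 paste(miss, collapse = ", ")))
  if (nrow(ev)) {
    if (any(ev$n_snv < object@params@kmin))
      return("every event must have n_snv >= kmin")
    if (any(ev$max_adjusted_imd >= object@params@dMax))
      return("every event must have max_adjusted_imd < dMax")
    if (any(ev$end < ev$start)) return("event end must be >= start")
  }
  TRUE
})

#' SV-proximity simulation null for one patient group
#'
#' Observed and simulated event-to-breakpoint distance bin counts with
#' rank-based empirical p-values in both directions.
#'
#' @slot group group label (ancestry x risk).
#' @slot edges distance bin edges (bp, last edge `Inf`).
#' @slot observed integer observed count per bin.
#' @slot simCounts nSim x nBins matrix of pseudo-event counts.
#' @slot pEnrich,pSparse empirical p-values per bin.
#' @slot fdrEnrich,fdrSparse BH-adjusted p-values (across bins and groups).
#' @slot binClass per-bin label: enriched, sparse or neither.
#' @export
setClass("ProximityNull",
  representation(group = "character", edges = "numeric",
                 observed = "numeric", simCounts = "matrix",
                 pEnrich = "numeric", pSparse = "numeric",
                 fdrEnrich = "numeric", fdrSparse = "numeric",
                 binClass = "character"))

setValidity("ProximityNull", function(object) {
  nb <- length(object@edges) - 1L
  if (length(object@observed) != nb) return("observed length != bin count")
  if (ncol(object@simCounts) != nb) return("simCounts ncol != bin count")
  if (nrow(object@simCounts) &&
      any(rowSums(object@simCounts) != sum(object@observed)))
    return("each simulation replicate must conserve the event total")
  if (any(object@pEnrich <= 0 | object@pEnrich > 1, na.rm = TRUE))
    return("pEnrich out of (0,1]")
  TRUE
})

#' Synthetic cohort configuration
#'
#' Defines the statistical structure of a generated cohort: background SNV
#' rate, planted kataegis clusters with APOBEC strand-coordinated TCW bias,
#' SV breakpoints with a configurable kataegis-coupling fraction, a
#' two-cluster clonal/subclonal CCF architecture, and clinical covariates.
#' Defaults reflect the characteristics of primary prostate tumour genomes:
#' roughly 1 SNV/Mb background, events with a median of six SNVs over a
#' median span of 2.7 kb, a per-positive burden with median two events
#' (at most 13), and a predominantly clonal architecture.
#'
#' @slot nSamples number of tumours.
#' @slot chromLengths named chromosome lengths in bp.
#' @slot backgroundRate background SNVs per Mb.
#' @slot kataegisPrevalence fraction of samples carrying >= 1 event.
#' @slot eventsPerPositiveP geometric success probability for the
#'   per-positive event count (truncated at `eventsPerPositiveMax`).
#' @slot eventsPerPositiveMax maximum events per sample.
#' @slot snvsPerEventMin,snvsPerEventMedian member-count distribution:
#'   `min + Poisson(median - min)`.
#' @slot eventSpanMedian,eventSpanSdlog log-normal event span (bp).
#' @slot eventSpanMax optional hard cap on the span (NA = no cap beyond the
#'   detectability cap `0.9 * dMax * (n - 1)`).
#' @slot apobecOmega probability a member SNV is planted at a TCW site.
#' @slot strandCoordination probability all TCW members of an event share
#'   one strand.
#' @slot nSvs SV breakend pairs per sample.
#' @slot couplingRho fraction of events anchored within `couplingD` of a
#'   breakpoint.
#' @slot couplingD coupling distance in bp.
#' @slot minEventSeparation minimum distance between planted events.
#' @slot clonalFraction clonal fraction of background SNVs.
#' @slot eventClonalFraction clonal fraction of planted events (per event).
#' @slot subclonalCcf true CCF of subclonal mutations.
#' @slot ccfNoiseSd Gaussian sd of observed CCF around the truth.
#' @slot purity tumour purity.
#' @slot gainedFraction fraction of chromosomes with a 2+1 gain.
#' @slot chromothripsisFraction fraction of SV pairs flagged chromothriptic.
#' @slot svClassProbs named sampling weights over DEL/DUP/INV/TRA/OTHER.
#' @slot ancestryMix named sampling weights over AFR/EUR/ASI.
#' @slot seed integer seed; the whole cohort is a pure function of
#'   (config, seed).
#' @export
setClass("SimConfig",
  representation(nSamples = "numeric", chromLengths = "numeric",
                 backgroundRate = "numeric", kataegisPrevalence = "numeric",
                 eventsPerPositiveP = "numeric", eventsPerPositiveMax = "numeric",
                 snvsPerEventMin = "numeric", snvsPerEventMedian = "numeric",
                 eventSpanMedian = "numeric", eventSpanSdlog = "numeric",
                 eventSpanMax = "numeric",
                 apobecOmega = "numeric", strandCoordination = "numeric",
                 nSvs = "numeric", couplingRho = "numeric",
                 couplingD = "numeric", minEventSeparation = "numeric",
                 clonalFraction = "numeric", eventClonalFraction = "numeric",
                 subclonalCcf = "numeric", ccfNoiseSd = "numeric",
                 purity = "numeric", gainedFraction = "numeric",
                 chromothripsisFraction = "numeric", svClassProbs = "numeric",
                 ancestryMix = "numeric", seed = "numeric"),
  prototype(nSamples = 20, chromLengths = c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7),
            backgroundRate = 1, kataegisPrevalence = 0.4,
            eventsPerPositiveP = 0.35, eventsPerPositiveMax = 13,
            snvsPerEventMin = 4, snvsPerEventMedian = 6,
            eventSpanMedian = 2700, eventSpanSdlog = 0.4,
            eventSpanMax = NA_real_,
            apobecOmega = 0.9, strandCoordination = 0.9,
            nSvs = 40, couplingRho = 0.4, couplingD = 1e4,
            minEventSeparation = 1e4,
            clonalFraction = 0.68, eventClonalFraction = 0.65,
            subclonalCcf = 0.4, ccfNoiseSd = 0.05,
            purity = 0.7, gainedFraction = 0.3,
            chromothripsisFraction = 0.1,
            svClassProbs = c(DEL = 0.3, DUP = 0.2, INV = 0.2, TRA = 0.2,
                             OTHER = 0.1),
            ancestryMix = c(AFR = 0.5, EUR = 0.3, ASI = 0.2),
            seed = 1))

setValidity("SimConfig", function(object) {
  pr <- c(object@kataegisPrevalence, object@apobecOmega,
          object@strandCoordination, object@couplingRho,
          object@clonalFraction, object@eventClonalFraction,
          object@subclonalCcf, object@gainedFraction,
          object@chromothripsisFraction)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0,1]")
  if (any(object@chromLengths <= 0)) return("chromosome lengths must be > 0")
  if (is.null(names(object@chromLengths))) return("chromLengths must be named")
  if (object@snvsPerEventMin < 2)
    return("snvsPerEventMin must be >= 2 (sub-threshold clusters allowed)")
  if (object@purity <= 0 || object@purity > 1) return("purity must be in (0,1]")
  TRUE
})

#' @rdname SimConfig-class
#' @param ... slot values overriding the defaults.
#' @return a `SimConfig` object.
#' @export
#' @examples
#' simConfig(nSamples = 5, couplingRho = 0)
simConfig <- function(...) new("SimConfig", ...)

#' A generated synthetic cohort with ground truth
#'
#' @slot genome the [GenomeRef-class] the cohort was simulated on.
#' @slot snvs SNV table (sample_id, chrom, pos, ref, alt, ccf, multiplicity,
#'   plus truth columns `truth_clonal`, `truth_kataegis`).
#' @slot svs SV breakend-pair table (BEDPE-like, 0-based starts).
#' @slot cn copy-number segment table.
#' @slot purity per-sample purity table.
#' @slot clinical clinical table (ancestry, risk, ISUP GG, PSA, age,
#'   follow-up, BCR/metastasis flags).
#' @slot truthEvents planted event table with epoch/APOBEC/coupling labels.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SyntheticCohort",
  representation(genome = "GenomeRef", snvs = "data.frame",
                 svs = "data.frame", cn = "data.frame",
                 purity = "data.frame", clinical = "data.frame",
                 truthEvents = "data.frame", config = "SimConfig"))
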