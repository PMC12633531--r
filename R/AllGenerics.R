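#' @include AllClasses.R
NULL

#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setGeneric("refSequence",
           function(x, chrom, start, end) standardGeneric("refSequence"))

#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @export
setGeneric("detParams", function(x) standardGeneric("detParams"))

#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @export
setGeneric("snvTable", function(x) standardGeneric("snvTable"))

#' Chromosome names of a reference
#' @param x a `GenomeRef`.
#' @return character vector in reference order.
#' @export
setMethod("chromNames", "GenomeRef", function(x) names(x@seq))

#' Chromosome lengths of a reference
#' @param x a `GenomeRef`.
#' @return named integer vector of lengths (bp).
#' @export
setMethod("chromLengths", "GenomeRef", function(x) {
  stats::setNames(Biostrings::width(x@seq), names(x@seq))
})

#' Extract reference sequence
#'
#' Bounds-checked 1-based inclusive sequence access; the returned string has
#' exactly `end - start + 1` characters.
#'
#' @param x a `GenomeRef`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return an uppercase character string over A/C/G/T/N.
#' @export
setMethod("refSequence", "GenomeRef", function(x, chrom, start, end) {
  len <- chromLengths(x)
  if (!chrom %in% names(len)) stop("unknown chromosome: ", chrom)
  if (start < 1L || end > len[[chrom]] || start > end)
    stop(sprintf("interval %s:%d-%d outside chromosome bounds (1-%d)",
                 chrom, start, end, len[[chrom]]))
  as.character(Biostrings::subseq(x@seq[[chrom]], start, end))
})

setMethod("show", "GenomeRef", function(object) {
  len <- chromLengths(object)
  cat(sprintf("GenomeRef with %d chromosome(s), %.2f Mb total\n",
              length(len), sum(len) / 1e6))
  cat("  ", paste(sprintf("%s (%.1f Mb)", names(len), len / 1e6),
                  collapse = ", "), "\n")
})

#' Event table of a KataegisEvents object
#' @param x a `KataegisEvents`.
#' @return the event data.frame.
#' @export
setMethod("eventTable", "KataegisEvents", function(x) x@events)

#' Number of called events
#' @param x a `KataegisEvents`.
#' @return integer event count.
#' @export
setMethod("nEvents", "KataegisEvents", function(x) nrow(x@events))

#' Parameters used for calling
#' @param x a `KataegisEvents`.
#' @return the `DetectionParams`.
#' @export
setMethod("detParams", "KataegisEvents", function(x) x@params)

setMethod("show", "KataegisEvents", function(object) {
  ev <- object@events
  cat(sprintf("KataegisEvents: %d event(s) in %d sample(s)\n",
              nrow(ev), length(unique(ev$sample_id))))
  if (nrow(ev)) {
    cat(sprintf("  median n_snv %.0f, median span %.2f kb\n",
                stats::median(ev$n_snv), stats::median(ev$span) / 1000))
    if ("apobec_enriched" %in% names(ev) && any(!is.na(ev$apobec_enriched)))
      cat(sprintf("  APOBEC-enriched: %d\n",
                  sum(ev$apobec_enriched, na.rm = TRUE)))
    if ("sv_class" %in% names(ev) && any(!is.na(ev$sv_class)))
      cat(sprintf("  SV-associated: %d, SV-independent: %d\n",
                  sum(ev$sv_class == "SV_associated", na.rm = TRUE),
                  sum(ev$sv_class == "SV_independent", na.rm = TRUE)))
  }
  cat(sprintf("  params: kmin=%d, dMax=%g bp, gamma=%g\n",
              as.integer(object@params@kmin), object@params@dMax,
              object@params@pcfGamma))
})

setMethod("show", "ProximityNull", function(object) {
  cat(sprintf("ProximityNull for group '%s': %d events, %d simulations\n",
              object@group, sum(object@observed), nrow(object@simCounts)))
  lab <- .binLabels(object@edges)
  for (i in seq_along(object@observed)) {
    cat(sprintf("  %-12s obs=%4d  pEnrich=%.4g  pSparse=%.4g  [%s]\n",
                lab[i], object@observed[i], object@pEnrich[i],
                object@pSparse[i], object@binClass[i]))
  }
})

#' Planted truth events of a synthetic cohort
#' @param x a `SyntheticCohort`.
#' @return data.frame of planted events.
#' @export
setMethod("truthEvents", "SyntheticCohort", function(x) x@truthEvents)

#' SNV table of a synthetic cohort
#' @param x a `SyntheticCohort`.
#' @return data.frame of SNVs with truth annotations.
#' @export
setMethod("snvTable", "SyntheticCohort", function(x) x@snvs)

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(paste0("SyntheticCohort: %d sample(s), %d SNV(s), ",
                     "%d planted event(s)\n"),
              length(unique(object@clinical$sample_id)),
              nrow(object@snvs), nrow(object@truthEvents)))
  show(object@genome)
})
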