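#' @include AllClasses.R detect.R
NULL

#' Assign SNVs to evolutionary epochs
#'
#' Point-estimate timing from cancer cell fraction, multiplicity and local
#' copy number: an SNV is `subclonal` when its CCF falls below
#' `clonalCcfThreshold`; otherwise it is clonal and sub-labelled
#' `clonal_early` when the locus is gained (major copy number >= 2) and
#' the mutation sits on multiple copies (multiplicity >= 2, i.e. it
#' preceded the gain), `clonal_late` when gained but single-copy, and
#' `clonal_unspecified` when the locus is copy-neutral (no timing signal).
#' Missing CCF or multiplicity yields `unknown`.
#'
#' @param ccf cancer cell fraction in `[0,1]` (NA allowed).
#' @param multiplicity mutation copy count (NA allowed).
#' @param majorCn,minorCn allele-specific copy number of the locus.
#' @param clonalCcfThreshold clonal/subclonal CCF cut (default 0.9).
#' @return character vector of epoch labels.
#' @export
#' @examples
#' assignEpoch(1.0, 2, 2, 1)  # clonal_early
#' assignEpoch(1.0, 1, 1, 1)  # clonal_unspecified
assignEpoch <- function(ccf, multiplicity, majorCn, minorCn,
                        clonalCcfThreshold = 0.9) {
  n <- max(length(ccf), length(multiplicity), length(majorCn))
  ccf <- rep_len(ccf, n); multiplicity <- rep_len(multiplicity, n)
  majorCn <- rep_len(majorCn, n); minorCn <- rep_len(minorCn, n)
  out <- rep("unknown", n)
  known <- !is.na(ccf) & !is.na(multiplicity) & !is.na(majorCn)
  sub <- known & ccf < clonalCcfThreshold
  out[sub] <- "subclonal"
  clonal <- known & !sub
  gained <- clonal & majorCn >= 2
  out[gained & multiplicity >= 2] <- "clonal_early"
  out[gained & multiplicity == 1] <- "clonal_late"
  out[clonal & majorCn < 2] <- "clonal_unspecified"
  out
}

#' Annotate an SNV table with epochs from copy-number segments
#'
#' Maps each SNV onto its overlapping copy-number segment (per sample and
#' chromosome) and applies [assignEpoch()]. SNVs with no overlapping
#' segment, or missing CCF/multiplicity, get epoch `unknown` and are
#' excluded from downstream proportions; their count is logged.
#'
#' @param snvs SNV table with `ccf` and `multiplicity` columns.
#' @param cn copy-number segment table ([readCnSegments()] format).
#' @param clonalCcfThreshold CCF cut, default 0.9.
#' @return the SNV table with `major_cn`, `minor_cn` and `epoch` columns.
#' @export
annotateEpochs <- function(snvs, cn, clonalCcfThreshold = 0.9) {
  snvs$major_cn <- NA_real_
  snvs$minor_cn <- NA_real_
  key <- paste(snvs$sample_id, snvs$chrom)
  for (k in unique(key)) {
    idx <- which(key == k)
    seg <- cn[paste(cn$sample_id, cn$chrom) == k, , drop = FALSE]
    if (nrow(seg) == 0L) next
    seg <- seg[order(seg$start), , drop = FALSE]
    hit <- findInterval(snvs$pos[idx], seg$start)
    ok <- hit >= 1L & snvs$pos[idx] <= seg$end[pmax(hit, 1L)]
    snvs$major_cn[idx[ok]] <- seg$major_cn[hit[ok]]
    snvs$minor_cn[idx[ok]] <- seg$minor_cn[hit[ok]]
  }
  snvs$epoch <- assignEpoch(snvs$ccf, snvs$multiplicity, snvs$major_cn,
                            snvs$minor_cn, clonalCcfThreshold)
  nUnk <- sum(snvs$epoch == "unknown")
  if (nUnk) message(nUnk, " SNV(s) with epoch 'unknown' ",
                    "(missing timing annotations or CN segment)")
  snvs
}

#' Estimate mutation multiplicity from VAF
#'
#' Helper for inputs that carry variant allele fractions instead of
#' pre-computed multiplicities:
#' `round(vaf * (purity * cnTotal + 2 * (1 - purity)) / purity)`, floored
#' at 1.
#'
#' @param vaf variant allele fraction.
#' @param purity tumour purity in (0,1].
#' @param cnTotal total local copy number (major + minor).
#' @return integer multiplicities.
#' @export
multiplicityFromVaf <- function(vaf, purity, cnTotal) {
  pmax(1L, as.integer(round(vaf * (purity * cnTotal + 2 * (1 - purity)) /
                              purity)))
}

#' Refine kataegis events into per-epoch evolutionary events
#'
#' Kataegic SNVs arise together in one mutational burst, so an event whose
#' members straddle epochs is re-examined one epoch at a time: member SNVs
#' are grouped by epoch label (members with epoch `unknown` are set
#' aside), and each group is re-tested against the detection criteria —
#' at least `kmin` members and all successive within-group distances below
#' `dMax`. Within-group distances are raw (PCF is not re-run on
#' event-sized subsets). Passing groups become evolutionary kataegis
#' events.
#'
#' @param events a [KataegisEvents-class].
#' @param snvs epoch-annotated SNV table ([annotateEpochs()]).
#' @param params the [DetectionParams-class]; defaults to the calling
#'   parameters stored in `events`.
#' @return data.frame with parent_id, epoch, n_snv, start, end and a
#'   `member_pos` list-column; zero rows when nothing passes.
#' @export
refineEvents <- function(events, snvs, params = NULL) {
  params <- params %||% detParams(events)
  ev <- eventTable(events)
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    mem <- snvs[snvs$sample_id == ev$sample_id[i] &
                  snvs$chrom == ev$chrom[i] &
                  snvs$pos %in% ev$member_pos[[i]], , drop = FALSE]
    mem <- mem[order(mem$pos), , drop = FALSE]
    for (ep in setdiff(unique(mem$epoch), "unknown")) {
      pos <- mem$pos[mem$epoch == ep]
      if (length(pos) < params@kmin) next
      if (any(diff(pos) >= params@dMax)) next
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = ev$event_id[i], sample_id = ev$sample_id[i],
        chrom = ev$chrom[i], epoch = ep, n_snv = length(pos),
        start = pos[1], end = pos[length(pos)], stringsAsFactors = FALSE)
      rows[[length(rows)]]$member_pos <- list(pos)
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(parent_id = character(), sample_id = character(),
               chrom = character(), epoch = character(), n_snv = integer(),
               start = integer(), end = integer(), member_pos = I(list()),
               stringsAsFactors = FALSE)
  }
}

#' Per-sample clonal proportions of kataegic versus genome-wide SNVs
#'
#' For every sample with at least one kataegis event: the fraction of
#' kataegic SNVs with a clonal epoch and the fraction of all timed SNVs
#' with a clonal epoch (epoch `unknown` excluded from both denominators),
#' compared across samples with a paired two-sided Wilcoxon signed-rank
#' test.
#'
#' @param snvs epoch-annotated SNV table.
#' @param events a [KataegisEvents-class].
#' @return list with `perSample` (sample_id, kataegis_clonal_frac,
#'   genomewide_clonal_frac), `medians` and the paired `p` value.
#' @export
epochProportions <- function(snvs, events) {
  ev <- eventTable(events)
  if (is.null(snvs$epoch)) stop("snvs must carry an epoch column; ",
                                "run annotateEpochs() first")
  epoch <- ifelse(is.na(snvs$epoch), "unknown", snvs$epoch)
  clonal <- startsWith(epoch, "clonal")
  timed <- epoch != "unknown"
  inEvent <- rep(FALSE, nrow(snvs))
  for (i in seq_len(nrow(ev))) {
    inEvent <- inEvent | (snvs$sample_id == ev$sample_id[i] &
                            snvs$chrom == ev$chrom[i] &
                            snvs$pos >= ev$start[i] & snvs$pos <= ev$end[i])
  }
  per <- lapply(unique(ev$sample_id), function(sid) {
    sel <- snvs$sample_id == sid & timed
    kat <- sel & inEvent
    data.frame(sample_id = sid,
               kataegis_clonal_frac =
                 if (any(kat)) mean(clonal[kat]) else NA_real_,
               genomewide_clonal_frac =
                 if (any(sel)) mean(clonal[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(sample_id = character(), kataegis_clonal_frac = numeric(),
               genomewide_clonal_frac = numeric())
  ok <- stats::complete.cases(per)
  p <- if (sum(ok) >= 1L &&
           any(per$kataegis_clonal_frac[ok] != per$genomewide_clonal_frac[ok])) {
    suppressWarnings(stats::wilcox.test(per$kataegis_clonal_frac[ok],
                                        per$genomewide_clonal_frac[ok],
                                        paired = TRUE))$p.value
  } else 1
  list(perSample = per,
       medians = c(kataegis = stats::median(per$kataegis_clonal_frac[ok]),
                   genomewide = stats::median(per$genomewide_clonal_frac[ok])),
       p = p)
}
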