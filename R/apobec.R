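#' @include AllClasses.R detect.R
NULL

# IUPAC conventions used throughout: W = A/T, Y = C/T (pyrimidine),
# R = A/G (purine). The mutated base of the TCW motif is the central C,
# pyrimidine-normalized across strands.

#' Pyrimidine-normalize a substitution and its sequence context
#'
#' Mutations at purine reference bases (G, A) are reported on the opposite
#' strand: the substitution and its flanking window are
#' reverse-complemented so the reported reference base is C or T. Windows
#' running off a chromosome end are truncated and flagged.
#'
#' @param genome a [GenomeRef-class].
#' @param chrom,pos site (1-based).
#' @param ref,alt observed alleles on the plus strand.
#' @param flank bases of context per side (default 20).
#' @return list with `ref`, `alt`, `context` (character, mutated base at
#'   position `offset`), `offset`, and `truncated`.
#' @export
normalizeStrand <- function(genome, chrom, pos, ref, alt, flank = 20) {
  len <- chromLengths(genome)[[chrom]]
  a <- max(1L, pos - flank); b <- min(len, pos + flank)
  win <- refSequence(genome, chrom, a, b)
  offset <- pos - a + 1L
  truncated <- (a > pos - flank) || (b < pos + flank)
  if (ref %in% c("G", "A")) {
    win <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
    offset <- nchar(win) - offset + 1L
    ref <- unname(.complementBase(ref)); alt <- unname(.complementBase(alt))
  }
  list(ref = ref, alt = alt, context = win, offset = offset,
       truncated = truncated)
}

# per-site normalized context bases: prev2, prev1, next1 relative to the
# pyrimidine-normalized orientation; NA when off-chromosome
.normalizedContextBases <- function(snvs, genome) {
  len <- chromLengths(genome)
  getBase <- function(chrom, p) {
    ok <- p >= 1L & p <= len[chrom]
    out <- rep(NA_character_, length(p))
    for (i in which(ok)) out[i] <- refSequence(genome, chrom[i], p[i], p[i])
    out
  }
  plusPrev1 <- getBase(snvs$chrom, snvs$pos - 1L)
  plusNext1 <- getBase(snvs$chrom, snvs$pos + 1L)
  plusPrev2 <- getBase(snvs$chrom, snvs$pos - 2L)
  plusNext2 <- getBase(snvs$chrom, snvs$pos + 2L)
  flip <- snvs$ref %in% c("G", "A")
  data.frame(
    ref = ifelse(flip, .complementBase(snvs$ref), snvs$ref),
    prev1 = ifelse(flip, .complementBase(plusNext1), plusPrev1),
    next1 = ifelse(flip, .complementBase(plusPrev1), plusNext1),
    prev2 = ifelse(flip, .complementBase(plusNext2), plusPrev2),
    stringsAsFactors = FALSE)
}

#' Count mutated and accessible APOBEC motifs for an SNV set
#'
#' Mutation counts are taken over pyrimidine-normalized cytosine mutations:
#' `mut_c` counts mutated cytosines, `mut_tcw` those in a TCW trinucleotide
#' context, and `mut_ytcw`/`mut_rtcw` split TCW by the preceding
#' pyrimidine/purine (the A3A and A3B tetranucleotide preferences).
#' Context (accessibility) counts are motif occurrences, both strands
#' pyrimidine-normalized, within the union of the per-SNV +/- `flank`
#' windows; overlapping windows are merged before counting so dense
#' clusters are not double-counted. Contexts containing N are dropped and
#' reported in `n_dropped`.
#'
#' @param snvs SNV table (one set: an event's members or a sample's
#'   non-clustered background).
#' @param genome a [GenomeRef-class].
#' @param flank bp of context per side (default 20).
#' @return a list of class `MotifCounts` with fields mut_c, mut_tcw,
#'   mut_ytcw, mut_rtcw, ctx_c, ctx_tcw, ctx_ytcw, ctx_rtcw, n_dropped.
#' @export
countMotifs <- function(snvs, genome, flank = 20) {
  stopifnot(nrow(snvs) >= 1L)
  ctxb <- .normalizedContextBases(snvs, genome)
  isC <- ctxb$ref == "C"
  hasN <- (!is.na(ctxb$prev1) & ctxb$prev1 == "N") |
    (!is.na(ctxb$next1) & ctxb$next1 == "N") |
    (!is.na(ctxb$prev2) & ctxb$prev2 == "N")
  tcw <- isC & !hasN & !is.na(ctxb$prev1) & !is.na(ctxb$next1) &
    ctxb$prev1 == "T" & ctxb$next1 %in% c("A", "T")
  ytcw <- tcw & !is.na(ctxb$prev2) & ctxb$prev2 %in% c("C", "T")
  rtcw <- tcw & !is.na(ctxb$prev2) & ctxb$prev2 %in% c("A", "G")

  # merged accessibility windows
  len <- chromLengths(genome)
  seqs <- Biostrings::DNAStringSet()
  for (ch in unique(snvs$chrom)) {
    p <- snvs$pos[snvs$chrom == ch]
    ir <- IRanges::reduce(IRanges::IRanges(pmax(1L, p - flank),
                                           pmin(len[[ch]], p + flank)))
    seqs <- c(seqs, Biostrings::DNAStringSet(
      Biostrings::Views(genome@seq[[ch]], ir)))
  }
  cnt <- function(pat) sum(Biostrings::vcountPattern(pat, seqs, fixed = FALSE))
  lf <- Biostrings::letterFrequency(seqs, c("C", "G"))
  out <- list(
    mut_c = sum(isC & !hasN),
    mut_tcw = sum(tcw),
    mut_ytcw = sum(ytcw),
    mut_rtcw = sum(rtcw),
    ctx_c = sum(lf),
    ctx_tcw = cnt("TCW") + cnt("WGA"),
    ctx_ytcw = cnt("YTCW") + cnt("WGAR"),
    ctx_rtcw = cnt("RTCW") + cnt("WGAY"),
    n_dropped = sum(isC & hasN))
  class(out) <- "MotifCounts"
  out
}

#' Accessibility-adjusted APOBEC enrichment test for one event
#'
#' One-sided Fisher exact test comparing the TCW fraction of an event's
#' mutated cytosines against the sample's non-clustered background,
#' adjusted for motif accessibility: the background TCW count is rescaled
#' by `a = (ctx_tcw_ev / ctx_c_ev) / (ctx_tcw_bg / ctx_c_bg)` (clamped so
#' the rescaled count stays within the background total) before building
#' the 2x2 table `[[mut_tcw_ev, mut_c_ev - mut_tcw_ev], [b_tcw,
#' mut_c_bg - b_tcw]]`. Raw counts are always returned so alternative
#' table constructions can be recomputed.
#'
#' @param eventCounts,backgroundCounts `MotifCounts` from [countMotifs()].
#' @return list with `table`, `odds_ratio`, `p`, `accessibility`, `note`.
#' @export
apobecEnrichmentTest <- function(eventCounts, backgroundCounts) {
  ec <- eventCounts; bc <- backgroundCounts
  if (ec$mut_c == 0L) {
    return(list(table = matrix(0, 2, 2), odds_ratio = NA_real_, p = 1,
                accessibility = NA_real_, note = "no cytosine mutations"))
  }
  if (bc$mut_c < 1L) {
    return(list(table = matrix(0, 2, 2), odds_ratio = NA_real_, p = 1,
                accessibility = NA_real_,
                note = "no background cytosine mutations"))
  }
  a <- if (ec$ctx_c > 0 && bc$ctx_tcw > 0 && bc$ctx_c > 0)
    (ec$ctx_tcw / ec$ctx_c) / (bc$ctx_tcw / bc$ctx_c) else 1
  bTcw <- min(bc$mut_c, max(0L, round(bc$mut_tcw * a)))
  tab <- matrix(c(ec$mut_tcw, ec$mut_c - ec$mut_tcw,
                  bTcw, bc$mut_c - bTcw), nrow = 2, byrow = TRUE,
                dimnames = list(c("event", "background"),
                                c("TCW", "otherC")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       accessibility = a, note = NA_character_)
}

#' A3A/A3B sub-attribution p-values for one event
#'
#' Two one-sided Fisher tests on `[[mut_ytcw, mut_rtcw], [ctx_ytcw,
#' ctx_rtcw]]`: skew of the mutated TCW toward YTCW relative to its
#' accessibility supports APOBEC3A, toward RTCW supports APOBEC3B.
#'
#' @param counts `MotifCounts` of an APOBEC-enriched event.
#' @return named numeric: `p_a3a`, `p_a3b` (both 1 when `mut_tcw` is 0).
#' @export
classifyA3 <- function(counts) {
  if (counts$mut_tcw == 0L) return(c(p_a3a = 1, p_a3b = 1))
  tab <- matrix(c(counts$mut_ytcw, counts$mut_rtcw,
                  counts$ctx_ytcw, counts$ctx_rtcw), nrow = 2, byrow = TRUE)
  c(p_a3a = stats::fisher.test(tab, alternative = "greater")$p.value,
    p_a3b = stats::fisher.test(tab, alternative = "less")$p.value)
}

#' Attribute kataegis events to APOBEC and its A3A/A3B arms
#'
#' For every sample: the non-clustered background is the sample's SNVs
#' outside all called events. Each event gets the accessibility-adjusted
#' enrichment test against that background; `apobec_enriched` is decided
#' at `alpha` after BH adjustment across all events in the run. Enriched
#' events are sub-attributed: YTCW and RTCW one-sided tests, BH-adjusted
#' across enriched events per arm; exactly one significant arm names the
#' enzyme, both or neither is `ambiguous`, non-enriched events are `none`.
#'
#' @param events a [KataegisEvents-class].
#' @param snvs the SNV table used for calling.
#' @param genome a [GenomeRef-class].
#' @param params a [DetectionParams-class] (flank, alpha).
#' @return the [KataegisEvents-class] with columns apobec_p, apobec_fdr,
#'   apobec_or, apobec_enriched, a3_class (and the member motif counts
#'   mut_c, mut_tcw, mut_ytcw, mut_rtcw) appended to the event table.
#' @export
attributeApobec <- function(events, snvs, genome, params = NULL) {
  params <- params %||% detParams(events)
  ev <- eventTable(events)
  n <- nrow(ev)
  ev$apobec_p <- rep(NA_real_, n); ev$apobec_or <- rep(NA_real_, n)
  ev$mut_c <- rep(NA_integer_, n); ev$mut_tcw <- rep(NA_integer_, n)
  ev$mut_ytcw <- rep(NA_integer_, n); ev$mut_rtcw <- rep(NA_integer_, n)
  pa3a <- rep(NA_real_, n); pa3b <- rep(NA_real_, n)
  if (n == 0L) {
    ev$apobec_fdr <- numeric(0); ev$apobec_enriched <- logical(0)
    ev$a3_class <- character(0)
    return(new("KataegisEvents", events = ev, params = params))
  }
  bgCache <- list()
  for (sid in unique(ev$sample_id)) {
    s <- snvs[snvs$sample_id == sid, , drop = FALSE]
    inEvent <- rep(FALSE, nrow(s))
    for (i in which(ev$sample_id == sid))
      inEvent <- inEvent | (s$chrom == ev$chrom[i] & s$pos >= ev$start[i] &
                              s$pos <= ev$end[i])
    bg <- s[!inEvent, , drop = FALSE]
    bgCache[[sid]] <- if (nrow(bg)) countMotifs(bg, genome, params@flank)
                      else NULL
  }
  for (i in seq_len(n)) {
    s <- snvs[snvs$sample_id == ev$sample_id[i] &
                snvs$chrom == ev$chrom[i] &
                snvs$pos %in% ev$member_pos[[i]], , drop = FALSE]
    ec <- countMotifs(s, genome, params@flank)
    ev$mut_c[i] <- ec$mut_c; ev$mut_tcw[i] <- ec$mut_tcw
    ev$mut_ytcw[i] <- ec$mut_ytcw; ev$mut_rtcw[i] <- ec$mut_rtcw
    bc <- bgCache[[ev$sample_id[i]]]
    if (is.null(bc)) {
      ev$apobec_p[i] <- 1
      next
    }
    res <- apobecEnrichmentTest(ec, bc)
    ev$apobec_p[i] <- res$p; ev$apobec_or[i] <- res$odds_ratio
    if (is.na(res$note)) {
      pp <- classifyA3(ec)
      pa3a[i] <- pp["p_a3a"]; pa3b[i] <- pp["p_a3b"]
    }
  }
  ev$apobec_fdr <- stats::p.adjust(ev$apobec_p, method = "BH")
  ev$apobec_enriched <- ev$apobec_fdr < params@alpha &
    (!is.na(ev$apobec_or) & ev$apobec_or > 1)
  ev$a3_class <- rep("none", n)
  enr <- which(ev$apobec_enriched & !is.na(pa3a) & ev$mut_tcw >= 1L)
  if (length(enr)) {
    fa <- stats::p.adjust(pa3a[enr], method = "BH")
    fb <- stats::p.adjust(pa3b[enr], method = "BH")
    sa <- fa < params@alpha; sb <- fb < params@alpha
    ev$a3_class[enr] <- ifelse(sa & !sb, "A3A",
                        ifelse(sb & !sa, "A3B", "ambiguous"))
  }
  ev$a3_class[ev$apobec_enriched & ev$mut_tcw == 0L] <- "none"
  new("KataegisEvents", events = ev, params = params)
}
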