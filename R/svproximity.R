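#' @include AllClasses.R detect.R
NULL

.binLabels <- function(edges) {
  lab <- character(length(edges) - 1L)
  fmt <- function(x) {
    if (!is.finite(x)) return("Inf")
    if (x >= 1e6) paste0(x / 1e6, "Mb") else if (x >= 1e3) paste0(x / 1e3, "kb")
    else paste0(x, "bp")
  }
  for (i in seq_along(lab)) {
    lab[i] <- if (is.finite(edges[i + 1L]))
      paste0(fmt(edges[i]), "-", fmt(edges[i + 1L]))
    else paste0(">", fmt(edges[i]))
  }
  lab
}

# nearest-breakend distance from intervals to sorted positions, vectorized;
# 0 when a breakend falls inside the interval, Inf when the chromosome has
# no breakend
.intervalDistance <- function(start, end, bkpos) {
  n <- length(start)
  if (length(bkpos) == 0L) return(rep(Inf, n))
  bkpos <- sort(bkpos)
  iEnd <- findInterval(end, bkpos)           # last bk <= end
  iBefore <- findInterval(start - 1L, bkpos) # last bk < start
  inside <- iEnd > iBefore
  dLeft <- ifelse(iBefore >= 1L, start - bkpos[pmax(iBefore, 1L)], Inf)
  dRight <- ifelse(iEnd < length(bkpos), bkpos[pmin(iEnd + 1L, length(bkpos))] - end,
                   Inf)
  ifelse(inside, 0, pmin(dLeft, dRight))
}

#' Distance from kataegis events to the nearest SV breakpoint
#'
#' 0 when any breakend lies within the event interval; otherwise the
#' minimum over same-chromosome breakends of the gap to the nearer event
#' edge; `Inf` when the chromosome carries no breakend (binned into the
#' final "beyond" bin downstream).
#'
#' @param events a [KataegisEvents-class] or event/interval data.frame
#'   (sample_id, chrom, start, end).
#' @param breakends breakend table ([readSvBedpe()] format).
#' @return numeric distances in bp, one per event.
#' @export
eventSvDistance <- function(events, breakends) {
  ev <- if (is(events, "KataegisEvents")) eventTable(events) else events
  d <- rep(Inf, nrow(ev))
  key <- paste(ev$sample_id, ev$chrom)
  for (k in unique(key)) {
    idx <- which(key == k)
    bk <- breakends$pos[paste(breakends$sample_id, breakends$chrom) == k]
    d[idx] <- .intervalDistance(ev$start[idx], ev$end[idx], bk)
  }
  d
}

#' Simulate pseudo kataegis events
#'
#' For each real event, draws `nSim` positions uniformly with replacement
#' from the sample's non-clustered SNVs and centres an interval of the
#' event's span on each; intervals are truncated at chromosome ends.
#' Replicate `j` of the group-level null pools the `j`-th pseudo interval
#' of every event.
#'
#' @param events a [KataegisEvents-class] or event data.frame.
#' @param snvs the sample-annotated SNV table (all samples).
#' @param genome a [GenomeRef-class] (for chromosome lengths).
#' @param nSim pseudo events per real event (default 1000).
#' @param seed integer seed making the draw reproducible.
#' @return data.frame with event_id, sim_index, sample_id, chrom, start,
#'   end. Events of samples with no non-clustered SNV are excluded with a
#'   message.
#' @export
simulatePseudoEvents <- function(events, snvs, genome, nSim = 1000,
                                 seed = 1) {
  ev <- if (is(events, "KataegisEvents")) eventTable(events) else events
  len <- chromLengths(genome)
  set.seed(seed)
  inEvent <- rep(FALSE, nrow(snvs))
  for (i in seq_len(nrow(ev)))
    inEvent <- inEvent | (snvs$sample_id == ev$sample_id[i] &
                            snvs$chrom == ev$chrom[i] &
                            snvs$pos >= ev$start[i] & snvs$pos <= ev$end[i])
  pools <- split(snvs[!inEvent, c("chrom", "pos")], snvs$sample_id[!inEvent])
  out <- vector("list", nrow(ev))
  dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    pool <- pools[[ev$sample_id[i]]]
    if (is.null(pool) || nrow(pool) == 0L) {
      dropped <- dropped + 1L
      next
    }
    pick <- sample.int(nrow(pool), nSim, replace = TRUE)
    span <- ev$end[i] - ev$start[i]
    centre <- pool$pos[pick]
    half <- span %/% 2L
    st <- centre - half
    en <- st + span
    chromLen <- len[pool$chrom[pick]]
    out[[i]] <- data.frame(event_id = ev$event_id[i], sim_index = seq_len(nSim),
                           sample_id = ev$sample_id[i],
                           chrom = pool$chrom[pick],
                           start = pmax(1L, st),
                           end = pmin(as.integer(chromLen), en),
                           stringsAsFactors = FALSE)
  }
  if (dropped) message(dropped,
                       " event(s) without non-clustered SNVs excluded ",
                       "from the simulation null")
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) do.call(rbind, out) else
    data.frame(event_id = character(), sim_index = integer(),
               sample_id = character(), chrom = character(),
               start = integer(), end = integer())
}

#' Bin distances into log-spaced bins
#'
#' Bin `i` holds distances `edge[i] <= d < edge[i+1]`; `Inf` (no
#' same-chromosome breakpoint) and distances at or beyond the last finite
#' edge fall into the final bin, keeping the bins exhaustive.
#'
#' @param d numeric distances (may contain `Inf`).
#' @param edges strictly increasing edges starting at 0 (last may be
#'   `Inf`).
#' @return integer counts, one per bin; sums to `length(d)`.
#' @export
#' @examples
#' binDistances(c(0, 999, 1000), c(0, 1e3, 1e4, Inf))
binDistances <- function(d, edges) {
  if (any(d < 0)) stop("internal error: negative distance")
  if (any(diff(edges) <= 0) || edges[1] != 0)
    stop("edges must be strictly increasing and start at 0")
  nb <- length(edges) - 1L
  idx <- pmin(findInterval(d, edges), nb)
  tabulate(idx, nbins = nb)
}

#' Rank-based enrichment/sparsity test of SV proximity per patient group
#'
#' Per group: observed distance-bin counts of the real events versus the
#' `nSim` pooled pseudo replicates. Empirical p-values use the +1 rank
#' correction (`p` in `[1/(nSim+1), 1]`): enrichment counts replicates
#' with a bin count at least the observed one, sparsity those at most the
#' observed one. BH adjustment runs across bins x groups separately per
#' direction; a bin is `enriched` or `sparse` when the respective FDR is
#' below `alpha` (enrichment wins, with a message, if both directions
#' pass).
#'
#' @param events a [KataegisEvents-class] or event data.frame.
#' @param pseudo pseudo-event table from [simulatePseudoEvents()].
#' @param breakends breakend table.
#' @param groups named character vector mapping sample_id to group label
#'   (e.g. ancestry x risk); unnamed scalar applies one group to all.
#' @param params a [DetectionParams-class] (bin edges, alpha).
#' @return named list of [ProximityNull-class], one per group.
#' @export
proximityTest <- function(events, pseudo, breakends, groups = "all",
                          params = detectionParams()) {
  ev <- if (is(events, "KataegisEvents")) eventTable(events) else events
  if (length(groups) == 1L && is.null(names(groups))) {
    groups <- stats::setNames(rep(groups, length(unique(ev$sample_id))),
                              unique(ev$sample_id))
  }
  ev$group <- unname(groups[ev$sample_id])
  edges <- params@distanceBinEdges
  nb <- length(edges) - 1L
  nSim <- max(pseudo$sim_index %||% 0L, 0L)
  ev$dist <- eventSvDistance(ev, breakends)
  pseudo$dist <- eventSvDistance(
    data.frame(sample_id = pseudo$sample_id, chrom = pseudo$chrom,
               start = pseudo$start, end = pseudo$end), breakends)
  pseudo$group <- unname(groups[pseudo$sample_id])
  res <- list()
  for (g in sort(unique(ev$group))) {
    evG <- ev[ev$group == g & ev$event_id %in% pseudo$event_id, , drop = FALSE]
    if (nrow(evG) == 0L) next
    obs <- binDistances(evG$dist, edges)
    ps <- pseudo[pseudo$group == g, , drop = FALSE]
    binIdx <- pmin(findInterval(ps$dist, edges), nb)
    sim <- matrix(0L, nrow = nSim, ncol = nb)
    tab <- table(factor(ps$sim_index, levels = seq_len(nSim)),
                 factor(binIdx, levels = seq_len(nb)))
    sim[] <- as.integer(tab)
    pE <- pS <- numeric(nb)
    for (b in seq_len(nb)) {
      pE[b] <- (1 + sum(sim[, b] >= obs[b])) / (nSim + 1)
      pS[b] <- (1 + sum(sim[, b] <= obs[b])) / (nSim + 1)
    }
    res[[g]] <- new("ProximityNull", group = g, edges = edges,
                    observed = as.numeric(obs), simCounts = sim,
                    pEnrich = pE, pSparse = pS,
                    fdrEnrich = rep(NA_real_, nb),
                    fdrSparse = rep(NA_real_, nb),
                    binClass = rep("neither", nb))
  }
  if (length(res) == 0L) return(res)
  allE <- unlist(lapply(res, function(x) x@pEnrich))
  allS <- unlist(lapply(res, function(x) x@pSparse))
  fE <- stats::p.adjust(allE, method = "BH")
  fS <- stats::p.adjust(allS, method = "BH")
  off <- 0L
  for (g in names(res)) {
    idx <- off + seq_len(nb); off <- off + nb
    res[[g]]@fdrEnrich <- fE[idx]
    res[[g]]@fdrSparse <- fS[idx]
    cls <- rep("neither", nb)
    cls[res[[g]]@fdrSparse < params@alpha] <- "sparse"
    both <- res[[g]]@fdrEnrich < params@alpha & res[[g]]@fdrSparse < params@alpha
    if (any(both)) message("bin(s) significant in both directions in group ",
                           g, "; labelled enriched")
    cls[res[[g]]@fdrEnrich < params@alpha] <- "enriched"
    res[[g]]@binClass <- cls
  }
  res
}

#' Classify events as SV-associated or SV-independent
#'
#' An event whose breakpoint distance falls into a bin flagged `enriched`
#' for its group becomes `SV_associated`; a `sparse` bin gives
#' `SV_independent`; anything else stays `unclassified`.
#'
#' @param events a [KataegisEvents-class].
#' @param nulls list of [ProximityNull-class] from [proximityTest()].
#' @param breakends breakend table.
#' @param groups sample-to-group mapping as in [proximityTest()].
#' @return the [KataegisEvents-class] with `sv_distance` and `sv_class`
#'   columns filled in.
#' @export
classifyEventsByBin <- function(events, nulls, breakends, groups = "all") {
  ev <- eventTable(events)
  if (length(groups) == 1L && is.null(names(groups))) {
    groups <- stats::setNames(rep(groups, length(unique(ev$sample_id))),
                              unique(ev$sample_id))
  }
  ev$sv_distance <- eventSvDistance(ev, breakends)
  ev$sv_class <- rep("unclassified", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    g <- unname(groups[ev$sample_id[i]])
    if (!g %in% names(nulls)) next
    nl <- nulls[[g]]
    b <- min(findInterval(ev$sv_distance[i], nl@edges),
             length(nl@edges) - 1L)
    ev$sv_class[i] <- switch(nl@binClass[b], enriched = "SV_associated",
                             sparse = "SV_independent", "unclassified")
  }
  new("KataegisEvents", events = ev, params = detParams(events))
}

#' Per-SV-type proximity Fisher tests
#'
#' For each SV class (and for the chromothripsis flag as its own
#' category): a two-sided Fisher test on breakend counts cross-classified
#' as within `window` of any same-sample event versus not, and this type
#' versus the others, BH-adjusted across types. Direction is reported as
#' the odds ratio (Haldane-corrected when a margin is zero).
#'
#' @param events a [KataegisEvents-class] or event data.frame.
#' @param breakends breakend table with sv_class and chromothripsis_flag.
#' @param window proximity window in bp (default 10 kb).
#' @return data.frame with type, near counts, p, fdr, odds_ratio,
#'   direction.
#' @export
svTypeProximity <- function(events, breakends, window = 1e4) {
  ev <- if (is(events, "KataegisEvents")) eventTable(events) else events
  near <- rep(FALSE, nrow(breakends))
  key <- paste(breakends$sample_id, breakends$chrom)
  for (k in unique(key)) {
    idx <- which(key == k)
    evK <- ev[paste(ev$sample_id, ev$chrom) == k, , drop = FALSE]
    if (nrow(evK) == 0L) next
    for (i in seq_len(nrow(evK))) {
      near[idx] <- near[idx] |
        (breakends$pos[idx] >= evK$start[i] - window &
           breakends$pos[idx] <= evK$end[i] + window)
    }
  }
  cats <- list()
  for (t in intersect(.SV_CLASSES, unique(breakends$sv_class)))
    cats[[t]] <- breakends$sv_class == t
  if (any(breakends$chromothripsis_flag))
    cats[["chromothripsis"]] <- breakends$chromothripsis_flag
  rows <- lapply(names(cats), function(t) {
    isT <- cats[[t]]
    tab <- matrix(c(sum(near & isT), sum(near & !isT),
                    sum(!near & isT), sum(!near & !isT)), 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    or <- .oddsRatio(tab)
    data.frame(type = t, n_near = tab[1, 1], n_far = tab[2, 1], p = p,
               odds_ratio = or,
               direction = ifelse(or > 1, "enriched", "depleted"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
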