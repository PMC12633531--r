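#' @include AllClasses.R AllGenerics.R io.R
NULL

#' Inter-mutational distances per chromosome
#'
#' For each sample and each chromosome carrying at least two SNVs, computes
#' the successive distances `imd[i] = pos[i+1] - pos[i]`. Input must be
#' sorted with duplicate positions already collapsed (the reader's
#' contract); violations are an internal error.
#'
#' @param snvs SNV table (one or more samples).
#' @param genome optional [GenomeRef-class] fixing chromosome order.
#' @return a list of IMD series; each element has fields `sample_id`,
#'   `chrom`, `positions` and `imd`.
#' @export
# collapse records sharing a genomic position (multi-allelic splits),
# keeping the first: an IMD of zero would break the log transform
.collapsePositions <- function(snvs) {
  snvs[!duplicated(paste(snvs$sample_id, snvs$chrom, snvs$pos)), ,
       drop = FALSE]
}

computeImd <- function(snvs, genome = NULL) {
  lev <- .chromLevels(snvs$chrom, genome)
  out <- list()
  for (sid in unique(snvs$sample_id)) {
    s <- snvs[snvs$sample_id == sid, , drop = FALSE]
    for (ch in lev[lev %in% s$chrom]) {
      pos <- s$pos[s$chrom == ch]
      if (is.unsorted(pos, strictly = FALSE))
        stop("internal error: SNVs not sorted for ", sid, " ", ch)
      if (anyDuplicated(pos))
        stop("internal error: duplicate positions for ", sid, " ", ch)
      if (length(pos) < 2L) next
      out[[length(out) + 1L]] <- list(sample_id = sid, chrom = ch,
                                      positions = pos, imd = diff(pos))
    }
  }
  out
}

#' Exact piecewise-constant-fitting segmentation
#'
#' Finds the segmentation of a numeric sequence minimizing
#' `sum over segments of within-segment squared error + gamma * (number of
#' segments)`, by exact dynamic programming in O(n^2). Ties are broken in
#' favour of fewer segments, then earlier segment starts. For kataegis
#' detection the input is log10 inter-mutational distance (the rainfall
#' convention).
#'
#' @param values finite numeric vector.
#' @param gamma positive per-segment penalty.
#' @return a data.frame with 1-based inclusive `start`, `end` indices and
#'   the segment `mean`; zero rows for empty input.
#' @export
#' @examples
#' pcfSegment(c(1, 1, 1, 5, 5, 5), gamma = 0.5)
pcfSegment <- function(values, gamma) {
  stopifnot(is.numeric(values), gamma > 0)
  n <- length(values)
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(), mean = numeric()))
  if (any(!is.finite(values))) stop("values must be finite")
  cs <- c(0, cumsum(values))
  cs2 <- c(0, cumsum(values^2))
  # sse of segment i..j from prefix sums (clamped against fp cancellation)
  sse <- function(i, j) {
    s <- cs[j + 1L] - cs[i]
    max(0, (cs2[j + 1L] - cs2[i]) - s * s / (j - i + 1L))
  }
  cost <- c(0, rep(Inf, n))      # cost[j+1]: best cost of prefix 1..j
  nseg <- c(0L, rep(0L, n))
  prev <- rep(0L, n + 1L)
  tol <- 1e-9
  for (j in seq_len(n)) {
    best <- Inf; bestSeg <- 0L; bestI <- 1L
    for (i in seq_len(j)) {
      cand <- cost[i] + sse(i, j) + gamma
      candSeg <- nseg[i] + 1L
      better <- cand < best - tol ||
        (cand < best + tol && (candSeg < bestSeg ||
                               (candSeg == bestSeg && i < bestI)))
      if (better) { best <- cand; bestSeg <- candSeg; bestI <- i }
    }
    cost[j + 1L] <- best
    nseg[j + 1L] <- bestSeg
    prev[j + 1L] <- bestI
  }
  starts <- integer(0); ends <- integer(0)
  j <- n
  while (j > 0L) {
    i <- prev[j + 1L]
    starts <- c(i, starts); ends <- c(j, ends)
    j <- i - 1L
  }
  data.frame(start = starts, end = ends,
             mean = vapply(seq_along(starts), function(k)
               (cs[ends[k] + 1L] - cs[starts[k]]) / (ends[k] - starts[k] + 1L),
               numeric(1)))
}

#' PCF-adjusted inter-mutational distances
#'
#' Replaces each raw distance by the segment mean of the raw distances,
#' expressed in bp because the calling threshold is stated in bp. Segment
#' membership comes from segmenting log10 distances; the substituted
#' value is either the arithmetic mean of the raw distances (this
#' function's default) or their geometric mean (the back-transform of the
#' mean log10 distance, which [callKataegis()] uses by default since it
#' is not dominated by a single large gap that the segmentation attached
#' to a cluster).
#'
#' @param imd raw inter-mutational distances (bp).
#' @param segments segmentation from [pcfSegment()] covering
#'   `seq_along(imd)`.
#' @param method `"arithmetic"` or `"geometric"`.
#' @return numeric vector of adjusted distances, same length as `imd`.
#' @export
adjustedImd <- function(imd, segments,
                        method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (length(imd) == 0L) return(numeric(0))
  if (nrow(segments) == 0L || segments$start[1] != 1L ||
      segments$end[nrow(segments)] != length(imd) ||
      (nrow(segments) > 1L &&
       any(segments$start[-1] != segments$end[-nrow(segments)] + 1L)))
    stop("segments must partition the distance index range")
  adj <- numeric(length(imd))
  for (k in seq_len(nrow(segments))) {
    idx <- segments$start[k]:segments$end[k]
    adj[idx] <- if (method == "arithmetic") mean(imd[idx])
    else if (min(imd[idx]) == max(imd[idx])) imd[idx][1]  # exact at ties
    else exp(mean(log(imd[idx])))
  }
  adj
}

#' Expected inter-mutational distance diagnostic
#'
#' The per-sample random expectation `L / n`: the mean distance between
#' successive mutations were the sample's `n` SNVs scattered uniformly over
#' a genome of length `L`. Reported alongside the fixed calling threshold
#' so users can confirm the threshold sits far below the random
#' expectation for every sample.
#'
#' @param nSnvs SNV count (>= 1).
#' @param genomeLength total genome length in bp.
#' @return expected distance in bp.
#' @export
#' @examples
#' expectedImdDiagnostic(3000, 3e9)  # 1 Mb
expectedImdDiagnostic <- function(nSnvs, genomeLength) {
  if (any(nSnvs < 1)) stop("nSnvs must be >= 1")
  genomeLength / nSnvs
}

#' Call kataegis events
#'
#' Per sample and chromosome: compute inter-mutational distances, segment
#' log10 distances by exact PCF, substitute segment means for raw
#' distances, then call every maximal run of consecutive adjusted
#' distances all below `dMax` whose SNV count (run length + 1) reaches
#' `kmin`. Events are maximal by construction; start/end are the first and
#' last member SNV positions. Runs are additionally split at raw gaps an
#' order of magnitude above `dMax` before the `kmin` filter: smoothing in
#' log space can absorb a background-scale gap between two tight
#' clusters (or next to one), and SNVs ten kilobases apart are not part
#' of one focal cluster.
#'
#' Following the convention of standard PCF implementations, the penalty
#' is counted in units of noise variance: log10 distances are scaled by
#' the noise sd of the background mutation process before segmentation.
#' Background spacings are locally exponential, and the sd of the log10
#' of an exponential is rate-free (`pi / sqrt(6) / ln 10`, about 0.557),
#' so a single constant calibrates `pcfGamma = 25` across mutation rates
#' without being contaminated by the clusters themselves. Segment
#' boundaries are then applied to the raw bp distances.
#'
#' @param snvs sorted SNV table (one or more samples).
#' @param params a [DetectionParams-class].
#' @param genome optional [GenomeRef-class].
#' @return a [KataegisEvents-class]; zero-row table when nothing is called.
#' @export
callKataegis <- function(snvs, params = detectionParams(), genome = NULL) {
  series <- computeImd(.collapsePositions(snvs), genome)
  rows <- list()
  for (s in series) {
    if (length(s$positions) < params@kmin) next
    v <- log10(s$imd)
    sigma <- pi / sqrt(6) / log(10)  # sd of log10 exponential spacings
    segs <- pcfSegment(v / sigma, params@pcfGamma)
    adj <- adjustedImd(s$imd, segs, params@imdAdjust)
    gapCut <- 10 * params@dMax
    r <- rle(adj < params@dMax & s$imd < gapCut)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    for (k in which(r$values & r$lengths >= params@kmin - 1L)) {
      a <- startIdx[k]; b <- endIdx[k]     # run over imd indices a..b
      members <- s$positions[a:(b + 1L)]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, chrom = s$chrom,
        start = members[1], end = members[length(members)],
        n_snv = length(members), span = members[length(members)] - members[1],
        max_adjusted_imd = max(adj[a:b]),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$member_pos <- list(members)
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), n_snv = integer(),
               span = integer(), max_adjusted_imd = numeric(),
               member_pos = I(list()), stringsAsFactors = FALSE)
  ev <- cbind(event_id = if (nrow(ev))
    sprintf("%s_%s_%d", ev$sample_id, ev$chrom, ev$start) else character(0),
    ev, stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  new("KataegisEvents", events = ev, params = params)
}

#' Rainfall plot data
#'
#' Positions, log10 inter-mutational distance (of each SNV to its
#' predecessor) and a flag marking membership in a called event; the
#' standard rainfall-plot export.
#'
#' @param snvs sorted SNV table.
#' @param events a [KataegisEvents-class] called on the same SNVs.
#' @param genome optional [GenomeRef-class].
#' @return data.frame with sample_id, chrom, pos, log10_imd, in_event.
#' @export
rainfallData <- function(snvs, events, genome = NULL) {
  series <- computeImd(.collapsePositions(snvs), genome)
  ev <- eventTable(events)
  out <- lapply(series, function(s) {
    inEv <- rep(FALSE, length(s$positions) - 1L)
    sel <- ev$sample_id == s$sample_id & ev$chrom == s$chrom
    for (i in which(sel))
      inEv <- inEv | (s$positions[-1L] >= ev$start[i] &
                        s$positions[-1L] <= ev$end[i])
    data.frame(sample_id = s$sample_id, chrom = s$chrom,
               pos = s$positions[-1L], log10_imd = log10(s$imd),
               in_event = inEv, stringsAsFactors = FALSE)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), chrom = character(), pos = integer(),
               log10_imd = numeric(), in_event = logical())
}

#' Score detection against planted truth
#'
#' A called event recovers a truth event when the two intervals overlap
#' reciprocally (each covering at least `minOverlap` of the other, and at
#' least one base either way). Sensitivity is the fraction of truth
#' events recovered; precision the fraction of called events matching
#' some truth event.
#'
#' @param events a [KataegisEvents-class] or event data.frame.
#' @param truth truth event table (sample_id, chrom, start, end).
#' @param minOverlap reciprocal overlap fraction; the default 0 requires
#'   any mutual overlap.
#' @return list with sensitivity, precision, nCalled, nTruth.
#' @export
scoreDetection <- function(events, truth, minOverlap = 0) {
  ev <- if (is(events, "KataegisEvents")) eventTable(events) else events
  recovered <- rep(FALSE, nrow(truth))
  matched <- rep(FALSE, nrow(ev))
  for (i in seq_len(nrow(truth))) {
    cand <- which(ev$sample_id == truth$sample_id[i] &
                    ev$chrom == truth$chrom[i])
    for (j in cand) {
      ov <- min(ev$end[j], truth$end[i]) - max(ev$start[j], truth$start[i]) + 1
      wTr <- truth$end[i] - truth$start[i] + 1
      wEv <- ev$end[j] - ev$start[j] + 1
      if (ov >= max(1, minOverlap * wTr) && ov >= max(1, minOverlap * wEv)) {
        recovered[i] <- TRUE
        matched[j] <- TRUE
      }
    }
  }
  list(sensitivity = if (nrow(truth)) mean(recovered) else NA_real_,
       precision = if (nrow(ev)) mean(matched) else NA_real_,
       nCalled = nrow(ev), nTruth = nrow(truth))
}
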