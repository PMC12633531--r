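#' @include AllClasses.R io.R
NULL

# fraction of cytosines sitting in a TCW context on an i.i.d. uniform
# genome: P(prev = T) * P(next in {A,T}) = 1/4 * 1/2
.UNIFORM_TCW_FRACTION <- 1 / 8

#' Generate an i.i.d. random reference genome
#'
#' Uniform A/C/G/T sequence per chromosome, fully determined by the
#' config seed (salted with "reference" so the cohort draw stream is
#' independent).
#'
#' @param config a [SimConfig-class].
#' @return a [GenomeRef-class].
#' @export
generateReference <- function(config) {
  set.seed(saltSeed(config@seed, "reference"))
  bases <- charToRaw("ACGT")
  seqs <- lapply(config@chromLengths, function(L)
    rawToChar(sample(bases, L, replace = TRUE)))
  GenomeRef(Biostrings::DNAStringSet(unlist(seqs)))
}

# lazily computed, cached positions of the mutable C of every TCW motif,
# per chromosome and strand ("plus": TCW on plus strand, "minus": TCW on
# the minus strand, i.e. WGA on plus; position is always plus-strand)
.tcwSites <- function(genome) {
  if (!is.null(genome@cache$tcw)) return(genome@cache$tcw)
  out <- lapply(seq_along(genome@seq), function(i) {
    s <- genome@seq[[i]]
    list(plus = Biostrings::start(
           Biostrings::matchPattern("TCW", s, fixed = FALSE)) + 1L,
         minus = Biostrings::start(
           Biostrings::matchPattern("WGA", s, fixed = FALSE)) + 1L)
  })
  names(out) <- names(genome@seq)
  genome@cache$tcw <- out
  out
}

# last index with v[i] <= x on a sorted vector; O(log n) without the
# full-vector coercion/sortedness scan findInterval performs per call
.bsearchLE <- function(v, x) {
  lo <- 0L; hi <- length(v)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (v[mid] <= x) lo <- mid else hi <- mid - 1L
  }
  lo
}

.refBasesAt <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    out[idx] <- as.character(Biostrings::extractAt(
      genome@seq[[ch]], IRanges::IRanges(pos[idx], pos[idx])))
  }
  out
}

.randomAlt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
         character(1), USE.NAMES = FALSE)
}

.simulateSvPairs <- function(config, sampleId) {
  len <- config@chromLengths
  n <- config@nSvs
  if (n == 0L) {
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      name = character(), score = numeric(),
                      strand1 = character(), strand2 = character(),
                      sv_class = character(), chromothripsis = logical()))
  }
  cls <- sample(names(config@svClassProbs), n, replace = TRUE,
                prob = config@svClassProbs)
  if (length(len) < 2L) cls[cls == "TRA"] <- "OTHER"  # TRA needs two chroms
  chrom1 <- sample(names(len), n, replace = TRUE, prob = len)
  pos1 <- vapply(chrom1, function(ch) sample.int(len[[ch]], 1L), integer(1))
  chrom2 <- chrom1; pos2 <- integer(n)
  for (i in seq_len(n)) {
    if (cls[i] == "TRA") {
      chrom2[i] <- sample(setdiff(names(len), chrom1[i]), 1L)
      pos2[i] <- sample.int(len[[chrom2[i]]], 1L)
    } else {
      size <- max(1000L, as.integer(round(stats::rlnorm(1, log(1e5), 1))))
      pos2[i] <- min(len[[chrom1[i]]], pos1[i] + size)
    }
  }
  data.frame(chrom1 = chrom1, start1 = pos1 - 1L, end1 = pos1,
             chrom2 = chrom2, start2 = pos2 - 1L, end2 = pos2,
             name = sprintf("%s_sv%03d", sampleId, seq_len(n)),
             score = 0, strand1 = "+", strand2 = "-",
             sv_class = cls,
             chromothripsis = stats::runif(n) < config@chromothripsisFraction,
             stringsAsFactors = FALSE)
}

# plant the members of one event inside [winStart, winEnd] on `chrom`;
# APOBEC members are placed on real TCW occurrences of the random
# reference (context accessibility stays honest), the rest uniformly.
# Planted events satisfy the kataegis spacing definition by construction:
# every successive member gap stays below 1 kb (redrawn, then snapped to
# an even grid as a last resort), so a truth event is a genuine cluster.
.MAX_MEMBER_GAP <- 1000

.plantMembers <- function(config, genome, tcw, chrom, winStart, winEnd, n) {
  drawOnce <- function(targets = NULL) {
    isTcw <- stats::runif(n) < config@apobecOmega
    coordinated <- stats::runif(1) < config@strandCoordination
    eventStrand <- sample(c("plus", "minus"), 1L)
    pos <- integer(0); ref <- character(0); alt <- character(0)
    nTcw <- sum(isTcw)
    if (nTcw > 0L) {
      strands <- if (coordinated) rep(eventStrand, nTcw)
                 else sample(c("plus", "minus"), nTcw, replace = TRUE)
      for (st in unique(strands)) {
        need <- sum(strands == st)
        sites <- tcw[[chrom]][[st]]
        lo <- .bsearchLE(sites, winStart - 1L) + 1L
        hi <- .bsearchLE(sites, winEnd)
        avail <- if (hi >= lo) sites[lo:hi] else integer(0)
        take <- min(need, length(avail))
        if (take > 0L) {
          p <- if (is.null(targets)) {
            sort(avail[sample.int(length(avail), take)])
          } else {
            # snap evenly spaced targets to their nearest motif site
            unique(vapply(targets[seq_len(take)], function(tg)
              avail[which.min(abs(avail - tg))], numeric(1)))
          }
          take <- length(p)
          # C>T (SBS2-like) or C>G (SBS13-like) on the TCW strand
          sub <- sample(c("T", "G"), take, replace = TRUE,
                        prob = c(0.55, 0.45))
          if (st == "plus") {
            pos <- c(pos, p); ref <- c(ref, rep("C", take))
            alt <- c(alt, sub)
          } else {
            pos <- c(pos, p); ref <- c(ref, rep("G", take))
            alt <- c(alt, unname(.complementBase(sub)))
          }
        }
      }
    }
    nFlat <- n - length(pos)
    if (nFlat > 0L) {
      p <- if (is.null(targets)) sample(winStart:winEnd, nFlat)
           else utils::tail(targets, nFlat)
      r <- .refBasesAt(genome, rep(chrom, nFlat), p)
      pos <- c(pos, p); ref <- c(ref, r); alt <- c(alt, .randomAlt(r))
    }
    keep <- !duplicated(pos)
    ord <- order(pos[keep])
    data.frame(chrom = chrom, pos = as.integer(pos[keep][ord]),
               ref = ref[keep][ord], alt = alt[keep][ord],
               stringsAsFactors = FALSE)
  }
  for (attempt in 1:30) {
    mem <- drawOnce()
    if (nrow(mem) == n &&
        (n == 1L || max(diff(mem$pos)) < .MAX_MEMBER_GAP)) return(mem)
  }
  targets <- as.integer(round(seq(winStart, winEnd, length.out = n)))
  drawOnce(targets = targets)
}

.observedCcf <- function(truthCcf, sd) {
  pmin(1, pmax(0.01, truthCcf + stats::rnorm(length(truthCcf), 0, sd)))
}

#' Generate one synthetic tumour sample
#'
#' Draws, in order: whole-chromosome copy-number states, SV breakend
#' pairs, planted kataegis events (anchored near a breakpoint with
#' probability `couplingRho`, members APOBEC-biased to TCW sites with
#' probability `apobecOmega`), and uniform background SNVs at
#' `backgroundRate` per Mb; then assigns clonality (CCF/multiplicity)
#' per event and per background SNV. Uses the calling R random stream:
#' seed management belongs to [generateCohort()].
#'
#' @param config a [SimConfig-class].
#' @param genome a [GenomeRef-class] from [generateReference()].
#' @param sampleId sample identifier.
#' @param positive force kataegis positivity (default: Bernoulli
#'   `kataegisPrevalence`).
#' @return list with snvs, svPairs, cn, truthEvents.
#' @export
generateSample <- function(config, genome, sampleId,
                           positive = NULL) {
  len <- config@chromLengths
  if (any(config@eventSpanMedian > len))
    stop("event span exceeds a chromosome length: infeasible config")
  tcw <- .tcwSites(genome)
  gained <- stats::runif(length(len)) < config@gainedFraction
  names(gained) <- names(len)
  cn <- data.frame(sample_id = sampleId, chrom = names(len), start = 1L,
                   end = unname(len),
                   major_cn = ifelse(gained, 2L, 1L), minor_cn = 1L,
                   stringsAsFactors = FALSE)
  svPairs <- .simulateSvPairs(config, sampleId)
  breakends <- .breakendsFromPairs(svPairs, sampleId)

  if (is.null(positive))
    positive <- stats::runif(1) < config@kataegisPrevalence
  nEvents <- if (positive)
    min(config@eventsPerPositiveMax,
        stats::rgeom(1, config@eventsPerPositiveP) + 1L) else 0L

  evRows <- list(); evSnvs <- list()
  accepted <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
  for (e in seq_len(nEvents)) {
    n <- config@snvsPerEventMin +
      stats::rpois(1, max(0, config@snvsPerEventMedian - config@snvsPerEventMin))
    span <- stats::rlnorm(1, log(config@eventSpanMedian), config@eventSpanSdlog)
    cap <- 900 * (n - 1L)   # keeps planted clusters within the kataegis regime
    if (!is.na(config@eventSpanMax)) cap <- min(cap, config@eventSpanMax)
    span <- as.integer(round(max(min(span, cap), 30 * n)))
    placed <- FALSE
    for (try in 1:50) {
      coupled <- stats::runif(1) < config@couplingRho && nrow(breakends) > 0L
      if (coupled) {
        b <- breakends[sample.int(nrow(breakends), 1L), ]
        ch <- b$chrom
        centre <- b$pos + as.integer(round(stats::runif(1, -config@couplingD,
                                                        config@couplingD)))
      } else {
        ch <- sample(names(len), 1L, prob = len)
        centre <- sample.int(len[[ch]], 1L)
      }
      winStart <- max(1L, centre - span %/% 2L)
      winEnd <- winStart + span
      if (winEnd > len[[ch]]) {
        winEnd <- len[[ch]]; winStart <- max(1L, winEnd - span)
      }
      near <- accepted$chrom == ch &
        (pmin(accepted$end, winEnd) - pmax(accepted$start, winStart) >
           -config@minEventSeparation)
      if (!any(near)) { placed <- TRUE; break }
    }
    if (!placed) next
    mem <- .plantMembers(config, genome, tcw, ch, winStart, winEnd, n)
    if (nrow(mem) < config@snvsPerEventMin) next
    accepted <- rbind(accepted,
                      data.frame(chrom = ch, start = winStart, end = winEnd))
    clonal <- stats::runif(1) < config@eventClonalFraction
    epoch <- if (!clonal) "subclonal"
    else if (gained[[ch]]) sample(c("clonal_early", "clonal_late"), 1L)
    else "clonal_unspecified"
    mult <- if (epoch == "clonal_early") 2L else 1L
    ccfTruth <- if (clonal) 1 else config@subclonalCcf
    mem$sample_id <- sampleId
    mem$ccf <- .observedCcf(rep(ccfTruth, nrow(mem)), config@ccfNoiseSd)
    mem$multiplicity <- mult
    mem$truth_clonal <- clonal
    mem$truth_kataegis <- TRUE
    evSnvs[[length(evSnvs) + 1L]] <- mem
    evRows[[length(evRows) + 1L]] <- local({
      r <- data.frame(sample_id = sampleId, chrom = ch,
                      start = min(mem$pos), end = max(mem$pos),
                      n_snv = nrow(mem), epoch = epoch,
                      omega = config@apobecOmega,
                      apobec_flag = config@apobecOmega > .UNIFORM_TCW_FRACTION,
                      coupled_flag = coupled, stringsAsFactors = FALSE)
      r$member_pos <- list(mem$pos)
      r
    })
  }

  nBg <- stats::rpois(1, config@backgroundRate * sum(len) / 1e6)
  bg <- if (nBg > 0L) {
    ch <- sample(names(len), nBg, replace = TRUE, prob = len)
    p <- vapply(ch, function(x) sample.int(len[[x]], 1L), integer(1))
    r <- .refBasesAt(genome, ch, p)
    clonal <- stats::runif(nBg) < config@clonalFraction
    onGained <- gained[ch]
    early <- clonal & onGained & stats::runif(nBg) < 0.5
    data.frame(sample_id = sampleId, chrom = ch, pos = p, ref = r,
               alt = .randomAlt(r),
               ccf = .observedCcf(ifelse(clonal, 1, config@subclonalCcf),
                                  config@ccfNoiseSd),
               multiplicity = ifelse(early, 2L, 1L),
               truth_clonal = clonal, truth_kataegis = FALSE,
               stringsAsFactors = FALSE)
  } else NULL
  snvs <- do.call(rbind, c(evSnvs, list(bg)))
  if (is.null(snvs))
    snvs <- data.frame(sample_id = character(), chrom = character(),
                       pos = integer(), ref = character(), alt = character(),
                       ccf = numeric(), multiplicity = integer(),
                       truth_clonal = logical(), truth_kataegis = logical(),
                       stringsAsFactors = FALSE)
  snvs <- snvs[, c("sample_id", "chrom", "pos", "ref", "alt", "ccf",
                   "multiplicity", "truth_clonal", "truth_kataegis")]
  snvs$epoch <- NA_character_
  key <- paste(snvs$chrom, snvs$pos)
  snvs <- snvs[!duplicated(key), , drop = FALSE]
  ci <- match(snvs$chrom, names(len))
  snvs <- snvs[order(ci, snvs$pos), , drop = FALSE]
  rownames(snvs) <- NULL
  truth <- if (length(evRows)) do.call(rbind, evRows) else
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), n_snv = integer(),
               epoch = character(), omega = numeric(),
               apobec_flag = logical(), coupled_flag = logical(),
               member_pos = I(list()), stringsAsFactors = FALSE)
  list(snvs = snvs, svPairs = svPairs, cn = cn, truthEvents = truth)
}

.simulateClinical <- function(config, sampleIds) {
  n <- length(sampleIds)
  isup <- sample(1:5, n, replace = TRUE, prob = c(0.10, 0.15, 0.25, 0.30, 0.20))
  data.frame(
    sample_id = sampleIds,
    ancestry = sample(names(config@ancestryMix), n, replace = TRUE,
                      prob = config@ancestryMix),
    risk = ifelse(isup <= 2, "LR", "HR"),
    isup_gg = isup,
    psa = round(stats::rlnorm(n, log(15), 0.9), 1),
    age = as.integer(round(stats::rnorm(n, 65, 8))),
    followup_days = as.integer(round(stats::runif(n, 500, 3000))),
    bcr_flag = stats::runif(n) < 0.30,
    metastasis_flag = stats::runif(n) < 0.15,
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Builds the reference, then every sample, then the clinical table, all
#' deterministically from `config@seed`: identical config and seed give
#' identical cohorts (and, through [emitCohort()], byte-identical files).
#'
#' @param config a [SimConfig-class].
#' @param genome optional pre-built [GenomeRef-class] for the same config
#'   (saves regenerating the reference across replicate cohorts; the
#'   cohort draw stream is unaffected).
#' @return a [SyntheticCohort-class].
#' @export
generateCohort <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- generateReference(config)
  set.seed(saltSeed(config@seed, "cohort"))
  ids <- sprintf("S%03d", seq_len(config@nSamples))
  samples <- lapply(ids, function(sid)
    generateSample(config, genome, sid))
  snvs <- do.call(rbind, lapply(samples, `[[`, "snvs"))
  cn <- do.call(rbind, lapply(samples, `[[`, "cn"))
  truth <- do.call(rbind, lapply(samples, `[[`, "truthEvents"))
  svPairs <- do.call(rbind, lapply(seq_along(ids), function(i) {
    sp <- samples[[i]]$svPairs
    if (nrow(sp)) sp$sample_id <- ids[i] else sp$sample_id <- character(0)
    sp
  }))
  clinical <- .simulateClinical(config, ids)
  purity <- data.frame(sample_id = ids, purity = config@purity,
                       stringsAsFactors = FALSE)
  rownames(snvs) <- rownames(cn) <- rownames(truth) <- rownames(svPairs) <- NULL
  new("SyntheticCohort", genome = genome, snvs = snvs, svs = svPairs,
      cn = cn, purity = purity, clinical = clinical, truthEvents = truth,
      config = config)
}

#' Breakend table of a synthetic cohort
#'
#' @param cohort a [SyntheticCohort-class].
#' @return breakend data.frame in [readSvBedpe()] format.
#' @export
cohortBreakends <- function(cohort) {
  sp <- cohort@svs
  out <- lapply(unique(sp$sample_id), function(sid)
    .breakendsFromPairs(sp[sp$sample_id == sid, , drop = FALSE], sid))
  if (length(out)) do.call(rbind, out) else
    .breakendsFromPairs(sp, "none")
}

#' Write a synthetic cohort to disk
#'
#' One VCF and one BEDPE per sample, cohort-level CN/purity/clinical TSVs,
#' the reference FASTA and a truth JSON indexing every planted object.
#' All files parse back losslessly through the package readers.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
emitCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastaRef(cohort@genome, file.path(dir, "reference.fa"))
  for (sid in unique(cohort@clinical$sample_id)) {
    s <- cohort@snvs[cohort@snvs$sample_id == sid, , drop = FALSE]
    writeSnvsVcf(s, file.path(dir, paste0(sid, ".vcf")), cohort@genome)
    writeSvBedpe(cohort@svs[cohort@svs$sample_id == sid, , drop = FALSE],
                 file.path(dir, paste0(sid, ".bedpe")))
  }
  utils::write.table(cohort@cn, file.path(dir, "cn_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort@purity, file.path(dir, "purity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort@clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort@truthEvents
  truthList <- list(
    n_events = nrow(truth),
    events = lapply(seq_len(nrow(truth)), function(i) list(
      sample_id = truth$sample_id[i], chrom = truth$chrom[i],
      start = truth$start[i], end = truth$end[i], n_snv = truth$n_snv[i],
      epoch = truth$epoch[i], omega = truth$omega[i],
      apobec_flag = truth$apobec_flag[i],
      coupled_flag = truth$coupled_flag[i],
      member_pos = truth$member_pos[[i]])),
    snv_truth = list(
      n_snvs = nrow(cohort@snvs),
      n_clonal = sum(cohort@snvs$truth_clonal),
      n_kataegic = sum(cohort@snvs$truth_kataegis)))
  jsonlite::write_json(truthList, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
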