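mkBreakends <- function(pos, chrom = "chr1", sample_id = "S1",
                        sv_class = "DEL", ct = FALSE) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             sv_class = sv_class, chromothripsis_flag = ct,
             mate_chrom = chrom, mate_pos = as.integer(pos),
             bk_id = sprintf("bk%03d", seq_along(pos)),
             mate_id = sprintf("bk%03d", seq_along(pos)),
             stringsAsFactors = FALSE)
}

mkEvents <- function(start, end, chrom = "chr1", sample_id = "S1") {
  data.frame(event_id = sprintf("%s_%s_%d", sample_id, chrom, start),
             sample_id = sample_id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("event-to-breakpoint distance handles containment and absence", {
  bk <- mkBreakends(c(11000, 15000))
  expect_equal(eventSvDistance(mkEvents(10000, 12000), bk), 0)
  expect_equal(eventSvDistance(mkEvents(10000, 12000),
                               mkBreakends(15000)), 3000)
  expect_equal(eventSvDistance(mkEvents(10000, 12000),
                               mkBreakends(8000)), 2000)
  # no breakend on the chromosome
  expect_equal(eventSvDistance(mkEvents(10000, 12000,
                                        chrom = "chr2"), bk), Inf)
})

test_that("interval distances equal the brute-force pairwise minimum", {
  set.seed(61)
  ev <- mkEvents(start = sort(sample.int(1e6, 100)), end = 0)
  ev$end <- ev$start + sample(100:5000, 100, TRUE)
  bk <- mkBreakends(sample.int(1.1e6, 40))
  d <- eventSvDistance(ev, bk)
  for (i in seq_len(nrow(ev))) {
    gaps <- pmax(0, pmax(ev$start[i] - bk$pos, bk$pos - ev$end[i]))
    expect_equal(d[i], min(gaps))
  }
})

test_that("distance binning uses half-open log-spaced bins exhaustively", {
  edges <- c(0, 1e3, 1e4, 1e5, 1e6, 1e7, 1e8, Inf)
  expect_equal(binDistances(c(0, 999, 1000), c(0, 1e3, 1e4, Inf)),
               c(2L, 1L, 0L))
  expect_equal(binDistances(rep(Inf, 5), edges)[7], 5L)
  expect_error(binDistances(-1, edges), "negative")

  set.seed(66)
  d <- c(10^runif(1e4, 0, 8.5), rep(Inf, 17))
  counts <- binDistances(d, edges)
  expect_equal(sum(counts), length(d))
  oracle <- vapply(seq_len(7), function(b)
    sum(d >= edges[b] & (d < edges[b + 1] | b == 7)), integer(1))
  expect_equal(counts, oracle)
})

test_that("pseudo events preserve span, centre on the pool and reproduce", {
  g <- GenomeRef(c(chr1 = strrep("ACGT", 25000)))  # 100 kb
  ev <- mkEvents(50000, 52000)
  # degenerate pool: exactly one non-clustered SNV
  snvs <- rbind(snvsAt(c(50100, 50500, 51000, 51500)), snvsAt(20000))
  ps <- simulatePseudoEvents(ev, snvs, g, nSim = 200, seed = 4)
  expect_equal(nrow(ps), 200L)
  expect_true(all(ps$start == 20000 - 1000))
  expect_true(all(ps$end - ps$start == 2000))

  # larger pool: spans preserved except at chromosome-end clipping
  snvs2 <- rbind(snvsAt(seq(500, 99500, by = 500)))
  ps2 <- simulatePseudoEvents(ev, snvs2, g, nSim = 500, seed = 9)
  unclipped <- ps2$start > 1 & ps2$end < 1e5
  expect_true(all((ps2$end - ps2$start)[unclipped] == 2000))
  expect_gt(mean(unclipped), 0.95)
  ps3 <- simulatePseudoEvents(ev, snvs2, g, nSim = 500, seed = 9)
  expect_identical(ps2, ps3)

  # no pool at all: event excluded with a message
  expect_message(
    ps4 <- simulatePseudoEvents(ev, snvsAt(c(50100, 50500, 51000, 51500)),
                                g, nSim = 10, seed = 1),
    "excluded")
  expect_equal(nrow(ps4), 0L)
})

test_that("rank p-values hit the +1 formula at the extremes", {
  g <- GenomeRef(c(chr1 = strrep("ACGT", 250000)))  # 1 Mb
  params <- detectionParams(nSim = 1000)
  # event sits on a breakpoint; the SNV pool is far away, so no pseudo
  # replicate can reach the first bin
  ev <- mkEvents(500000, 500400)
  bk <- mkBreakends(500200)
  pool <- snvsAt(seq(700000, 990000, by = 1000))
  snvs <- rbind(snvsAt(seq(500000, 500400, by = 100)), pool)
  ps <- simulatePseudoEvents(ev, snvs, g, nSim = 1000, seed = 2)
  nulls <- proximityTest(ev, ps, bk, groups = "all", params = params)
  x <- nulls[["all"]]
  expect_equal(x@pEnrich[1], 1 / 1001)
  expect_equal(sum(x@observed), 1)
  expect_true(all(rowSums(x@simCounts) == 1))
  expect_true(all(x@pEnrich >= 1 / 1001 & x@pEnrich <= 1))

  # degenerate pool: one non-clustered SNV that itself sits on a
  # breakpoint, so every pseudo replicate ties with the observed bin
  snvs2 <- rbind(snvsAt(seq(500000, 500400, by = 100)), snvsAt(600000))
  bk2 <- mkBreakends(c(500200, 600000))
  ps2 <- simulatePseudoEvents(ev, snvs2, g, nSim = 100, seed = 3)
  nulls2 <- proximityTest(ev, ps2, bk2, groups = "all",
                          params = detectionParams(nSim = 100))
  expect_equal(nulls2[["all"]]@pEnrich, rep(1, 7))
  expect_equal(nulls2[["all"]]@pSparse, rep(1, 7))
})

test_that("bin classes translate into SV-associated/independent calls", {
  params <- detectionParams()
  edges <- params@distanceBinEdges
  nl <- new("ProximityNull", group = "all", edges = edges,
            observed = c(3, 1, 0, 0, 0, 0, 1), simCounts = matrix(0, 0, 7),
            pEnrich = rep(1, 7), pSparse = rep(1, 7),
            fdrEnrich = rep(1, 7), fdrSparse = rep(1, 7),
            binClass = c("enriched", "enriched", rep("neither", 4),
                         "sparse"))
  ev <- mkEvents(c(10000, 200000, 900000), c(12000, 201000, 901000),
                 chrom = c("chr1", "chr1", "chr2"))
  ev$n_snv <- 5L; ev$span <- ev$end - ev$start
  ev$max_adjusted_imd <- 500; ev$event_id <- paste0("e", 1:3)
  evObj <- new("KataegisEvents", events = ev, params = params)
  bk <- mkBreakends(c(11500, 195000))   # distances: 0, 5000, none (Inf)
  out <- eventTable(classifyEventsByBin(evObj, list(all = nl), bk, "all"))
  expect_equal(out$sv_class,
               c("SV_associated", "SV_associated", "SV_independent"))
  expect_equal(out$sv_distance, c(0, 5000, Inf))
})

test_that("per-type proximity tests match the Fisher oracle", {
  ev <- mkEvents(100000, 102000)
  ev$n_snv <- 4L
  near <- mkBreakends(seq(95000, 107000, by = 1000), sv_class = "DEL")
  far <- mkBreakends(seq(500000, 519000, by = 1000), sv_class = "TRA")
  far$bk_id <- paste0("f", seq_len(nrow(far)))
  res <- svTypeProximity(ev, rbind(near, far), window = 1e4)
  del <- res[res$type == "DEL", ]
  expect_equal(del$direction, "enriched")
  # oracle on the same table: [[near DEL, near other],[far DEL, far other]]
  expect_equal(del$p, fisherOracleTwoSided(13, 0, 0, 20))
  expect_equal(res$fdr, p.adjust(res$p, "BH"))

  # proportionally identical near/far composition: odds ratio about 1
  bkA <- mkBreakends(c(99000, 101000, 300000, 400000), sv_class = "DEL")
  bkB <- mkBreakends(c(98000, 103000, 350000, 450000), sv_class = "INV")
  bkB$bk_id <- paste0("i", 1:4)
  res2 <- svTypeProximity(ev, rbind(bkA, bkB), window = 1e4)
  expect_true(all(abs(log(res2$odds_ratio)) < 1e-9))
  expect_true(all(res2$p == 1))
})

test_that("chromothripsis-flagged breakends get their own category", {
  ev <- mkEvents(100000, 102000)
  bk <- mkBreakends(c(99000, 101000, 500000, 600000), sv_class = "DEL",
                    ct = c(TRUE, TRUE, FALSE, FALSE))
  res <- svTypeProximity(ev, bk, window = 1e4)
  expect_true("chromothripsis" %in% res$type)
  expect_equal(res$direction[res$type == "chromothripsis"], "enriched")
})

test_that("near-bin enrichment p-values fall as planted coupling rises", {
  g <- fixture("proxGenome", function()
    generateReference(simConfig(chromLengths = c(chr1 = 2e7, chr2 = 2e7),
                                seed = 515)))
  medP <- function(rho, seeds) {
    p <- vapply(seeds, function(s) {
      cfg <- simConfig(nSamples = 10, chromLengths = chromLengths(g),
                       kataegisPrevalence = 1, eventsPerPositiveP = 0.2,
                       couplingRho = rho, seed = s)
      co <- generateCohort(cfg, genome = g)
      evT <- eventsFromTruth(truthEvents(co))
      ps <- simulatePseudoEvents(evT, snvTable(co), g, nSim = 300,
                                 seed = s + 1)
      nulls <- proximityTest(evT, ps, cohortBreakends(co), "all",
                             detectionParams(nSim = 300))
      nulls[["all"]]@pEnrich[1]
    }, numeric(1))
    median(p)
  }
  seeds <- 1400 + 1:12
  p0 <- medP(0, seeds); p4 <- medP(0.4, seeds); p8 <- medP(0.8, seeds)
  expect_gt(p0, p4)
  expect_gte(p4, p8)
  expect_lt(p8, 0.05)
})
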