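test_that("epoch assignment follows the multiplicity rules", {
  # copy-neutral clonal mutations carry no early/late signal
  expect_equal(assignEpoch(1.0, 1, 1, 1), "clonal_unspecified")
  # gained locus: multiplicity 2 preceded the gain, multiplicity 1 followed
  expect_equal(assignEpoch(1.0, 2, 2, 1), "clonal_early")
  expect_equal(assignEpoch(1.0, 1, 2, 1), "clonal_late")
  expect_equal(assignEpoch(0.4, 1, 1, 1), "subclonal")
  expect_equal(assignEpoch(NA, 1, 1, 1), "unknown")
  expect_equal(assignEpoch(1.0, NA, 2, 1), "unknown")
})

test_that("a CCF-0.4 subclone is labelled subclonal despite noise", {
  set.seed(14)
  ccf <- pmin(1, pmax(0.01, rnorm(5000, 0.4, 0.05)))
  lab <- assignEpoch(ccf, rep(1, 5000), rep(1, 5000), rep(1, 5000),
                     clonalCcfThreshold = 0.9)
  expect_gte(mean(lab == "subclonal"), 0.99)
})

test_that("epoch annotation maps SNVs onto their CN segment", {
  snvs <- snvsAt(c(100, 900, 2500))
  snvs$ccf <- 1; snvs$multiplicity <- c(2L, 1L, 1L)
  cn <- data.frame(sample_id = "S1", chrom = "chr1",
                   start = c(1, 1001), end = c(1000, 3000),
                   major_cn = c(2, 1), minor_cn = 1)
  out <- annotateEpochs(snvs, cn)
  expect_equal(out$epoch, c("clonal_early", "clonal_late",
                            "clonal_unspecified"))
  # no overlapping segment -> unknown, logged
  snvs2 <- snvsAt(500, chrom = "chr9")
  snvs2$ccf <- 1; snvs2$multiplicity <- 1L
  expect_message(out2 <- annotateEpochs(snvs2, cn), "unknown")
  expect_equal(out2$epoch, "unknown")
})

test_that("multiplicity from VAF follows the purity-scaled rounding", {
  # clonal het SNV in a diploid tumour at purity 0.8: vaf ~ 0.4
  expect_equal(multiplicityFromVaf(0.4, 0.8, 2), 1L)
  # mutation on both copies of a gain
  expect_equal(multiplicityFromVaf(0.55, 0.8, 3), 2L)
  expect_equal(multiplicityFromVaf(0.05, 0.8, 2), 1L)  # floored at 1
})

test_that("refinement keeps epoch-pure subsets that re-pass the criteria", {
  mkSnvs <- function(pos, epoch) {
    s <- snvsAt(pos)
    s$epoch <- epoch
    s
  }
  params <- detectionParams()
  # all members one epoch: the event survives unchanged
  pos <- seq(1000, by = 100, length.out = 6)
  tr <- data.frame(sample_id = "S1", chrom = "chr1", start = min(pos),
                   end = max(pos), n_snv = 6)
  tr$member_pos <- list(pos)
  evo <- refineEvents(eventsFromTruth(tr), mkSnvs(pos, "clonal_early"))
  expect_equal(nrow(evo), 1L)
  expect_equal(evo$epoch, "clonal_early")
  expect_equal(evo$n_snv, 6L)

  # 3 clonal + 3 subclonal: both subsets fall below kmin
  evo <- refineEvents(eventsFromTruth(tr),
                      mkSnvs(pos, rep(c("clonal_late", "subclonal"), 3)))
  expect_equal(nrow(evo), 0L)

  # 5 clonal spaced 200 bp interleaved with 4 subclonal spaced 400 bp
  clonalPos <- seq(1000, by = 200, length.out = 5)
  subPos <- seq(1100, by = 400, length.out = 4)   # within-subset gaps 400
  allPos <- sort(c(clonalPos, subPos))
  epochs <- ifelse(allPos %in% clonalPos, "clonal_unspecified", "subclonal")
  tr2 <- data.frame(sample_id = "S1", chrom = "chr1", start = min(allPos),
                    end = max(allPos), n_snv = 9)
  tr2$member_pos <- list(allPos)
  evo <- refineEvents(eventsFromTruth(tr2), mkSnvs(allPos, epochs))
  expect_equal(nrow(evo), 2L)
  expect_setequal(evo$epoch, c("clonal_unspecified", "subclonal"))
  expect_equal(sort(evo$n_snv), c(4L, 5L))
  # subsets never overlap and never invent members
  expect_true(all(unlist(evo$member_pos) %in% allPos))
  expect_equal(anyDuplicated(unlist(evo$member_pos)), 0L)
})

test_that("a within-subset gap at dMax disqualifies the subset", {
  pos <- c(seq(1000, by = 100, length.out = 4), 10000)
  s <- snvsAt(pos); s$epoch <- "subclonal"
  tr <- data.frame(sample_id = "S1", chrom = "chr1", start = min(pos),
                   end = max(pos), n_snv = 5)
  tr$member_pos <- list(pos)
  evo <- refineEvents(eventsFromTruth(tr), s)
  expect_equal(nrow(evo), 0L)
})

test_that("epoch labels partition timed SNVs (count conservation)", {
  co <- defaultCohort()
  snvs <- annotateEpochs(snvTable(co), co@cn)
  counts <- table(factor(snvs$epoch,
                         c("clonal_early", "clonal_late",
                           "clonal_unspecified", "subclonal", "unknown")))
  expect_equal(sum(counts), nrow(snvs))
  expect_equal(sum(counts[1:4]),
               sum(!is.na(snvs$ccf) & !is.na(snvs$multiplicity)))
})

test_that("clonal proportions compare kataegic to genome-wide SNVs", {
  # degenerate all-clonal case: both medians 100%, p = 1
  pos <- c(seq(1000, by = 100, length.out = 5), 50000, 90000)
  s <- snvsAt(pos)
  s$epoch <- "clonal_unspecified"
  tr <- data.frame(sample_id = "S1", chrom = "chr1", start = 1000,
                   end = 1400, n_snv = 5)
  tr$member_pos <- list(pos[1:5])
  res <- epochProportions(s, eventsFromTruth(tr))
  expect_equal(unname(res$medians), c(1, 1))
  expect_equal(res$p, 1)

  # hand-built three-sample table: medians match spreadsheet arithmetic
  mk <- function(sid, kat, bgClonalN, bgSubN) {
    katPos <- seq(1000, by = 100, length.out = 5)
    bgPos <- seq(2e5, by = 1e4, length.out = bgClonalN + bgSubN)
    s <- snvsAt(c(katPos, bgPos), sample_id = sid)
    s$epoch <- c(rep(ifelse(kat, "clonal_late", "subclonal"), 5),
                 rep("clonal_late", bgClonalN), rep("subclonal", bgSubN))
    s
  }
  s3 <- rbind(mk("A", TRUE, 6, 4), mk("B", TRUE, 2, 8), mk("C", FALSE, 5, 5))
  tr3 <- data.frame(sample_id = c("A", "B", "C"), chrom = "chr1",
                    start = 1000, end = 1400, n_snv = 5)
  tr3$member_pos <- rep(list(seq(1000, by = 100, length.out = 5)), 3)
  res <- epochProportions(s3, eventsFromTruth(tr3))
  # per-sample genome-wide clonal fractions: (5+6)/15, (5+2)/15, 5/15
  expect_equal(sort(res$perSample$genomewide_clonal_frac),
               sort(c(11 / 15, 7 / 15, 5 / 15)))
  expect_equal(res$perSample$kataegis_clonal_frac[
    res$perSample$sample_id == "C"], 0)
  expect_equal(unname(res$medians["kataegis"]), 1)
})

test_that("planted clonal/subclonal architecture is recovered cohort-wide", {
  co <- defaultCohort()
  snvs <- annotateEpochs(snvTable(co), co@cn)
  timed <- snvs$epoch != "unknown"
  lab <- startsWith(snvs$epoch[timed], "clonal")
  expect_gt(mean(lab == snvs$truth_clonal[timed]), 0.95)
})
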