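test_that("a single VCF row round-trips into one SNV record", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t1000\t.\tC\tT\t.\t.\t."), vcf)
  snvs <- readSnvs(vcf, sampleId = "S1")
  expect_equal(nrow(snvs), 1L)
  expect_equal(snvs$chrom, "chr1")
  expect_equal(snvs$pos, 1000L)
  expect_equal(snvs$ref, "C")
  expect_equal(snvs$alt, "T")
})

test_that("multi-allelic rows split and non-SNV rows are skipped", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t1000\t.\tC\tT,G\t.\t.\t.",
               "chr1\t2000\t.\tCA\tC\t.\t.\t.",
               "chr1\t3000\t.\tA\t<DEL>\t.\t.\t."), vcf)
  expect_message(snvs <- readSnvs(vcf, sampleId = "S1"), "non-SNV")
  expect_equal(nrow(snvs), 2L)
  expect_equal(snvs$pos, c(1000L, 1000L))
  expect_setequal(snvs$alt, c("T", "G"))
})

test_that("writeSnvsVcf / readSnvs round-trip preserves all fields", {
  set.seed(7)
  g <- testGenome()
  n <- 100
  pos <- sort(sample.int(5e5, n))
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  snvs <- data.frame(sample_id = "S1", chrom = "chr1", pos = pos, ref = ref,
                     alt = alt, ccf = round(runif(n), 4),
                     multiplicity = sample(1:2, n, TRUE),
                     epoch = sample(c("clonal_early", "subclonal"), n, TRUE),
                     stringsAsFactors = FALSE)
  vcf <- tempfile(fileext = ".vcf")
  writeSnvsVcf(snvs, vcf, g)
  back <- readSnvs(vcf, sampleId = "S1", genome = g)
  expect_equal(back, snvs, ignore_attr = TRUE)
})

test_that("SNV validation names the offending row and checks bounds", {
  g <- testGenome()
  bad <- snvsAt(c(100, 200))
  bad$alt[2] <- "C"  # ref == alt
  tsv <- tempfile(fileext = ".tsv")
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSnvs(tsv), "row 2")
  outside <- snvsAt(7e5)  # beyond chr1 (600 kb)
  tsv2 <- tempfile(fileext = ".tsv")
  write.table(outside, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSnvs(tsv2, genome = g), "exceeds chromosome length")
  unknown <- snvsAt(100, chrom = "chrZ")
  tsv3 <- tempfile(fileext = ".tsv")
  write.table(unknown, tsv3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSnvs(tsv3, genome = g), "unknown chromosome")
})

test_that("BEDPE coordinates convert 0-based starts to 1-based breakends", {
  bedpe <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t999\t1000\tchr1\t4999\t5000\tsv1\t0\t+\t-\tDEL\tFALSE",
               "chr1\t99\t100\tchr5\t199\t200\tsv2\t0\t+\t-\tTRA\tFALSE"),
             bedpe)
  bk <- readSvBedpe(bedpe, sampleId = "S1")
  expect_equal(nrow(bk), 4L)
  del <- bk[bk$sv_class == "DEL", ]
  expect_setequal(del$pos, c(1000L, 5000L))
  tra <- bk[bk$sv_class == "TRA", ]
  expect_setequal(tra$chrom, c("chr1", "chr5"))
})

test_that("intra-chromosomal TRA rows are rejected", {
  bedpe <- tempfile(fileext = ".bedpe")
  writeLines("chr1\t99\t100\tchr1\t199\t200\tsv1\t0\t+\t-\tTRA\tFALSE",
             bedpe)
  expect_error(readSvBedpe(bedpe), "different chromosomes")
})

test_that("50 BEDPE rows yield 100 breakends with reciprocal mate links", {
  set.seed(11)
  n <- 50
  p1 <- sample.int(1e6, n); p2 <- sample.int(1e6, n)
  pairs <- data.frame(chrom1 = "chr1", start1 = p1 - 1, end1 = p1,
                      chrom2 = "chr2", start2 = p2 - 1, end2 = p2,
                      name = sprintf("sv%02d", 1:n), score = 0,
                      strand1 = "+", strand2 = "-", sv_class = "TRA",
                      chromothripsis = FALSE)
  bedpe <- tempfile(fileext = ".bedpe")
  writeSvBedpe(pairs, bedpe)
  bk <- readSvBedpe(bedpe, sampleId = "S1")
  expect_equal(nrow(bk), 100L)
  # reciprocity: my mate's mate is me
  mate <- bk[match(bk$mate_id, bk$bk_id), ]
  expect_equal(mate$mate_id, bk$bk_id)
  expect_equal(mate$chrom, bk$mate_chrom)
  expect_equal(mate$pos, bk$mate_pos)
})

test_that("event tables round-trip and the BED companion is 0-based", {
  ev <- data.frame(event_id = "S1_chr1_1000", sample_id = "S1",
                   chrom = "chr1", start = 1000L, end = 3667L, n_snv = 5L,
                   span = 2667L, max_adjusted_imd = 700,
                   epoch = "clonal_early", apobec_enriched = TRUE,
                   a3_class = "A3B", sv_distance = 0,
                   sv_class = "SV_associated", stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  writeEvents(ev, tsv, bedPath = bed)
  back <- readEvents(tsv)
  expect_equal(back, ev, ignore_attr = TRUE)
  bedLine <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(bedLine[2:3]), c(999L, 3667L))

  # empty event set -> header-only file
  writeEvents(ev[0, ], tsv)
  expect_equal(length(readLines(tsv)), 1L)
  expect_equal(nrow(readEvents(tsv)), 0L)
})

test_that("clinical and CN readers enforce their invariants", {
  clin <- data.frame(sample_id = "S1", ancestry = "AFR", risk = "LR",
                     isup_gg = 4)
  f <- tempfile(fileext = ".tsv")
  write.table(clin, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readClinical(f), "inconsistent")
  clin$risk <- "HR"
  write.table(clin, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readClinical(f)$risk, "HR")

  cn <- data.frame(sample_id = "S1", chrom = "chr1",
                   start = c(1, 500), end = c(600, 900),
                   major_cn = 2, minor_cn = 1)
  write.table(cn, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCnSegments(f), "overlapping")
  cn$end[1] <- 499
  write.table(cn, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(readCnSegments(f))
})

test_that("FASTA round-trip preserves sequence and bounds are enforced", {
  g <- tinyGenome()
  fa <- tempfile(fileext = ".fa")
  writeFastaRef(g, fa)
  g2 <- readFastaRef(fa)
  expect_equal(chromLengths(g2), chromLengths(g))
  expect_equal(refSequence(g2, "chrA", 5, 9), refSequence(g, "chrA", 5, 9))
  expect_equal(nchar(refSequence(g, "chrA", 3, 12)), 10L)
  expect_error(refSequence(g, "chrA", 0, 5), "outside")
  expect_error(refSequence(g, "chrC", 1, 5), "unknown")
})
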