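test_that("purine-reference substitutions are reported on the other strand", {
  g <- GenomeRef(c(chrD = "CCTGACC"))
  r <- normalizeStrand(g, "chrD", 4, "G", "A", flank = 1)
  expect_equal(r$ref, "C")
  expect_equal(r$alt, "T")
  expect_equal(r$context, "TCA")  # reverse complement of TGA
  # pyrimidine reference: window unchanged
  r2 <- normalizeStrand(g, "chrD", 2, "C", "T", flank = 1)
  expect_equal(r2$context, "CCT")
  expect_false(r2$truncated)
  # off-end windows are truncated and flagged
  r3 <- normalizeStrand(g, "chrD", 1, "C", "A", flank = 3)
  expect_true(r3$truncated)
  expect_equal(nchar(r3$context), 4L)
})

test_that("strand normalization is an involution on the window", {
  g <- testGenome()
  set.seed(31)
  for (i in 1:25) {
    pos <- sample(50:5e5, 1)
    ref <- refSequence(g, "chr1", pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    r <- normalizeStrand(g, "chr1", pos, ref, alt, flank = 10)
    plus <- refSequence(g, "chr1", pos - 10, pos + 10)
    if (ref %in% c("C", "T")) {
      expect_equal(r$context, plus)
    } else {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r$context)))
      expect_equal(rc, plus)   # flipping back recovers the plus strand
    }
    expect_true(r$ref %in% c("C", "T"))
  }
})

test_that("motif counts match a hand count on a literal sequence", {
  g <- GenomeRef(c(chrC = "AATCATT"))
  snv <- snvsAt(4, chrom = "chrC")
  mc <- countMotifs(snv, g, flank = 3)
  expect_equal(mc$mut_c, 1L)
  expect_equal(mc$mut_tcw, 1L)      # T-C-A with the C mutated
  expect_equal(mc$mut_rtcw, 1L)     # preceded by A (purine)
  expect_equal(mc$mut_ytcw, 0L)
  expect_equal(mc$ctx_c, 1L)        # one C, no G in AATCATT
  expect_equal(mc$ctx_tcw, 1L)      # TCA at 3..5; no WGA
  expect_equal(mc$ctx_rtcw, 1L)     # ATCA
  expect_equal(mc$ctx_ytcw, 0L)
  expect_equal(mc$mut_ytcw + mc$mut_rtcw, mc$mut_tcw)
})

test_that("context counts equal a brute-force regex scan of merged windows", {
  g <- testGenome()
  set.seed(41)
  pos <- sort(sample(100:5e5, 50))
  ref <- vapply(pos, function(p) refSequence(g, "chr1", p, p), "")
  snvs <- snvsAt(pos, ref = ref,
                 alt = vapply(ref, function(r)
                   sample(setdiff(c("A", "C", "G", "T"), r), 1), ""))
  mc <- countMotifs(snvs, g, flank = 20)

  # oracle: merge windows by hand, scan with overlapping regex
  ir <- IRanges::reduce(IRanges::IRanges(pmax(1, pos - 20), pos + 20))
  wins <- vapply(seq_along(ir), function(i)
    refSequence(g, "chr1", IRanges::start(ir)[i], IRanges::end(ir)[i]), "")
  expect_equal(mc$ctx_c, regexCount(wins, "[CG]"))
  expect_equal(mc$ctx_tcw, regexCount(wins, "TC[AT]") +
                 regexCount(wins, "[AT]GA"))
  expect_equal(mc$ctx_ytcw, regexCount(wins, "[CT]TC[AT]") +
                 regexCount(wins, "[AT]GA[AG]"))
  expect_equal(mc$ctx_rtcw, regexCount(wins, "[AG]TC[AT]") +
                 regexCount(wins, "[AT]GA[CT]"))

  # mutation-side oracle from per-site context
  isC <- ref %in% c("C", "G")
  tcw <- vapply(seq_along(pos), function(i) {
    tri <- refSequence(g, "chr1", pos[i] - 1, pos[i] + 1)
    grepl("^TC[AT]$", tri) || grepl("^[AT]GA$", tri)
  }, logical(1))
  expect_equal(mc$mut_c, sum(isC))
  expect_equal(mc$mut_tcw, sum(isC & tcw))
  expect_equal(mc$mut_ytcw + mc$mut_rtcw, mc$mut_tcw)
})

test_that("the accessibility-adjusted 2x2 table matches its construction", {
  mkCounts <- function(mut_c, mut_tcw, ctx_c, ctx_tcw) {
    structure(list(mut_c = mut_c, mut_tcw = mut_tcw, mut_ytcw = 0,
                   mut_rtcw = mut_tcw, ctx_c = ctx_c, ctx_tcw = ctx_tcw,
                   ctx_ytcw = ctx_tcw / 2, ctx_rtcw = ctx_tcw / 2,
                   n_dropped = 0), class = "MotifCounts")
  }
  # identical fractions, accessibility 1: no enrichment signal
  r <- apobecEnrichmentTest(mkCounts(10, 5, 1000, 125),
                            mkCounts(100, 50, 10000, 1250))
  expect_equal(r$accessibility, 1)
  expect_gt(r$p, 0.5)

  # constructed [[9,1],[10,90]]: p equals the hypergeometric upper tail
  r <- apobecEnrichmentTest(mkCounts(10, 9, 1000, 125),
                            mkCounts(100, 10, 10000, 1250))
  expect_equal(unname(r$table[1, ]), c(9, 1))
  expect_equal(unname(r$table[2, ]), c(10, 90))
  expect_equal(r$p, fisherOracleGreater(9, 1, 10, 90))

  # degenerate event with no cytosine mutations
  r <- apobecEnrichmentTest(mkCounts(0, 0, 1000, 125),
                            mkCounts(100, 10, 10000, 1250))
  expect_equal(r$p, 1)
  expect_equal(r$note, "no cytosine mutations")

  # background rescaling is clamped into [0, mut_c_bg]
  r <- apobecEnrichmentTest(mkCounts(10, 9, 1000, 500),
                            mkCounts(20, 18, 10000, 500))
  expect_lte(r$table[2, 1], 20)
})

test_that("A3A/A3B one-sided tests behave at the extremes", {
  mk <- function(y, r, cy, cr) {
    structure(list(mut_c = y + r, mut_tcw = y + r, mut_ytcw = y,
                   mut_rtcw = r, ctx_c = 1000, ctx_tcw = cy + cr,
                   ctx_ytcw = cy, ctx_rtcw = cr, n_dropped = 0),
              class = "MotifCounts")
  }
  pA <- classifyA3(mk(9, 0, 50, 50))
  expect_lt(pA["p_a3a"], 0.01)
  expect_gt(pA["p_a3b"], 0.5)
  pB <- classifyA3(mk(0, 9, 50, 50))
  expect_lt(pB["p_a3b"], 0.01)
  # balanced: both one-sided p-values large -> ambiguous downstream
  pAmb <- classifyA3(mk(6, 6, 50, 50))
  expect_gt(pAmb["p_a3a"], 0.5)
  expect_gt(pAmb["p_a3b"], 0.5)
  expect_equal(unname(classifyA3(mk(0, 0, 50, 50))), c(1, 1))
})

test_that("attribution flags a planted TCW event against its background", {
  g <- testGenome()
  set.seed(55)
  # TCW sites (plus strand) inside a 3 kb window of chr1
  m <- Biostrings::matchPattern("TCW", g@seq[["chr1"]], fixed = FALSE)
  sites <- Biostrings::start(m) + 1L
  win <- sites[sites > 2e5 & sites < 2e5 + 3e3]
  memberPos <- sort(sample(win, 8))
  members <- snvsAt(memberPos, ref = "C", alt = "T")
  bgPos <- sort(sample(setdiff(seq(1e3, 5.9e5, by = 97), memberPos), 80))
  bgRef <- vapply(bgPos, function(p) refSequence(g, "chr1", p, p), "")
  bg <- snvsAt(bgPos, ref = bgRef,
               alt = vapply(bgRef, function(r)
                 sample(setdiff(c("A", "C", "G", "T"), r), 1), ""))
  snvs <- rbind(members, bg)
  snvs <- snvs[order(snvs$pos), ]
  tr <- data.frame(sample_id = "S1", chrom = "chr1", start = min(memberPos),
                   end = max(memberPos), n_snv = 8)
  tr$member_pos <- list(memberPos)
  ev <- attributeApobec(eventsFromTruth(tr), snvs, g)
  tb <- eventTable(ev)
  expect_true(tb$apobec_enriched)
  expect_gte(tb$apobec_fdr, tb$apobec_p)
  expect_gt(tb$apobec_or, 1)
  expect_equal(tb$mut_ytcw + tb$mut_rtcw, tb$mut_tcw)
  expect_true(tb$a3_class %in% c("A3A", "A3B", "ambiguous"))
})
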