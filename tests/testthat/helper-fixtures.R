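# session-level fixture cache: expensive synthetic cohorts are built once
# and shared across test files
.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# small literal genome for hand-checkable motif/context tests
tinyGenome <- function() {
  GenomeRef(c(chrA = "ACGTATCATGGCTTAGCATGCCAAGTCCTAGATTCCGGATT",
              chrB = "TTTTGGGGCCCCAAAATTTTGGGGCCCCAAAA"))
}

# a deterministic random genome of modest size (shared; ~1 Mb)
testGenome <- function() {
  fixture("testGenome", function() {
    generateReference(simConfig(chromLengths = c(chr1 = 6e5, chr2 = 4e5),
                                seed = 424242))
  })
}

# build an SNV table quickly from positions
snvsAt <- function(pos, chrom = "chr1", sample_id = "S1", ref = "C",
                   alt = "T", ...) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, ccf = NA_real_,
             multiplicity = NA_integer_, epoch = NA_character_, ...,
             stringsAsFactors = FALSE)
}

# wrap an event table (or truth table) into a KataegisEvents object
eventsFromTruth <- function(truth, params = detectionParams()) {
  ev <- data.frame(event_id = sprintf("%s_%s_%d", truth$sample_id,
                                      truth$chrom, truth$start),
                   sample_id = truth$sample_id, chrom = truth$chrom,
                   start = truth$start, end = truth$end,
                   n_snv = truth$n_snv,
                   span = truth$end - truth$start,
                   max_adjusted_imd = 0, stringsAsFactors = FALSE)
  ev$member_pos <- truth$member_pos
  new("KataegisEvents", events = ev, params = params)
}

# default-scale synthetic cohort shared by detection/timing/pipeline tests
defaultCohort <- function() {
  fixture("defaultCohort", function() {
    generateCohort(simConfig(nSamples = 12, seed = 20260923))
  })
}
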