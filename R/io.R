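#' @include AllClasses.R AllGenerics.R
NULL

.EPOCHS <- c("clonal_early", "clonal_late", "clonal_unspecified",
             "subclonal", "unknown")
.SV_CLASSES <- c("DEL", "DUP", "INV", "TRA", "OTHER")

.emptySnvs <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), ccf = numeric(),
             multiplicity = integer(), epoch = character(),
             stringsAsFactors = FALSE)
}

# Shared invariant checks for an SNV table; errors name the offending row.
.validateSnvs <- function(snvs, genome = NULL) {
  .assertColumns(snvs, c("sample_id", "chrom", "pos", "ref", "alt"), "SNV table")
  bad <- which(!.isSingleBase(snvs$ref) | !.isSingleBase(snvs$alt))
  if (length(bad))
    stop("row ", bad[1], ": ref/alt must be single bases in {A,C,G,T}",
         call. = FALSE)
  bad <- which(snvs$ref == snvs$alt)
  if (length(bad)) stop("row ", bad[1], ": ref equals alt", call. = FALSE)
  if (any(snvs$pos < 1L)) stop("positions must be 1-based positive integers",
                               call. = FALSE)
  if (!is.null(genome)) {
    len <- chromLengths(genome)
    unk <- which(!snvs$chrom %in% names(len))
    if (length(unk))
      stop("row ", unk[1], ": unknown chromosome '", snvs$chrom[unk[1]],
           "' not in reference", call. = FALSE)
    over <- which(snvs$pos > len[snvs$chrom])
    if (length(over))
      stop("row ", over[1], ": position exceeds chromosome length",
           call. = FALSE)
  }
  invisible(snvs)
}

# exact duplicate records (same alleles too); multi-allelic splits at one
# position are kept — the detection stage collapses positions
.collapseDuplicates <- function(snvs) {
  key <- paste(snvs$sample_id, snvs$chrom, snvs$pos, snvs$ref, snvs$alt)
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate SNV record(s) collapsed (first kept)")
    snvs <- snvs[!dup, , drop = FALSE]
  }
  snvs
}

.parseInfoField <- function(info, key) {
  vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]+"), info)),
         function(x) if (length(x)) sub(paste0(".*", key, "="), "", x[1])
         else NA_character_, character(1))
}

#' Read somatic SNVs from VCF or TSV
#'
#' Accepts single-sample VCF 4.2 (plain or gzipped; parsed with
#' \pkg{vcfR}) or a TSV with named columns. Multi-allelic VCF rows are
#' split into one record per alternate allele; rows that are not simple
#' SNVs (indels, MNVs, symbolic alleles) are skipped with a logged count.
#' Records are returned sorted by (sample, chromosome in reference order,
#' position) with duplicate positions collapsed.
#'
#' Optional timing annotations travel in the INFO column under keys
#' `CCF`, `MULT` and `EPOCH` (the convention [writeSnvsVcf()] emits).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param sampleId sample identifier; defaults to the file base name.
#' @param genome optional [GenomeRef-class] used to validate chromosome
#'   names and bounds and to fix the chromosome sort order.
#' @return a data.frame with columns sample_id, chrom, pos, ref, alt, ccf,
#'   multiplicity, epoch.
#' @export
readSnvs <- function(path, format = c("auto", "vcf", "tsv"), sampleId = NULL,
                     genome = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (is.null(sampleId))
    sampleId <- sub("\\.(vcf|tsv)(\\.gz)?$", "", basename(path))

  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) return(.emptySnvs())
    alts <- strsplit(fix$ALT %||% character(nrow(fix)), ",", fixed = TRUE)
    n <- lengths(alts)
    df <- data.frame(
      sample_id = sampleId,
      chrom = rep(fix$CHROM, n),
      pos = as.integer(rep(fix$POS, n)),
      ref = toupper(rep(fix$REF, n)),
      alt = toupper(unlist(alts)),
      ccf = suppressWarnings(as.numeric(rep(.parseInfoField(fix$INFO, "CCF"), n))),
      multiplicity = suppressWarnings(
        as.integer(rep(.parseInfoField(fix$INFO, "MULT"), n))),
      epoch = rep(.parseInfoField(fix$INFO, "EPOCH"), n),
      stringsAsFactors = FALSE)
    keep <- .isSingleBase(df$ref) & .isSingleBase(df$alt)
    if (any(!keep))
      message(sum(!keep), " non-SNV record(s) skipped in ", basename(path))
    df <- df[keep, , drop = FALSE]
  } else {
    # read everything as character first: an alt column of all "T" must
    # not be mistaken for a logical
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    .assertColumns(df, c("chrom", "pos", "ref", "alt"), basename(path))
    if (is.null(df$sample_id)) df$sample_id <- sampleId
    for (col in c("ccf", "multiplicity", "epoch"))
      if (is.null(df[[col]])) df[[col]] <- NA_character_
    df <- df[, c("sample_id", "chrom", "pos", "ref", "alt", "ccf",
                 "multiplicity", "epoch")]
    df$pos <- as.integer(df$pos)
    df$ccf <- suppressWarnings(as.numeric(df$ccf))
    df$multiplicity <- suppressWarnings(as.integer(df$multiplicity))
  }
  .validateSnvs(df, genome)
  df <- .collapseDuplicates(.orderRecords(df, genome))
  rownames(df) <- NULL
  df
}

#' Write SNVs as a minimal single-sample VCF 4.2
#'
#' Timing annotations (ccf, multiplicity, epoch), when present, are encoded
#' in INFO as `CCF=`, `MULT=`, `EPOCH=` so that [readSnvs()] round-trips
#' them losslessly.
#'
#' @param snvs SNV table for a single sample.
#' @param path output path (`.vcf`).
#' @param genome optional [GenomeRef-class]; adds `##contig` header lines.
#' @return invisibly, the path.
#' @export
writeSnvsVcf <- function(snvs, path, genome = NULL) {
  if (length(unique(snvs$sample_id)) > 1L)
    stop("writeSnvsVcf writes one sample per file")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=CCF,Number=1,Type=Float,Description=\"Cancer cell fraction\">",
           "##INFO=<ID=MULT,Number=1,Type=Integer,Description=\"Mutation multiplicity\">",
           "##INFO=<ID=EPOCH,Number=1,Type=String,Description=\"Evolutionary epoch\">")
  if (!is.null(genome)) {
    len <- chromLengths(genome)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(len), len))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(snvs)), function(i) {
    parts <- character(0)
    if (!is.na(snvs$ccf[i]))
      parts <- c(parts, sprintf("CCF=%.6g", snvs$ccf[i]))
    if (!is.na(snvs$multiplicity[i]))
      parts <- c(parts, sprintf("MULT=%d", as.integer(snvs$multiplicity[i])))
    if (!is.na(snvs$epoch[i]) && !is.null(snvs$epoch))
      parts <- c(parts, sprintf("EPOCH=%s", snvs$epoch[i]))
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  snvs$chrom, snvs$pos, snvs$ref, snvs$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.breakendsFromPairs <- function(pairs, sampleId) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), sv_class = character(),
                      chromothripsis_flag = logical(),
                      mate_chrom = character(), mate_pos = integer(),
                      bk_id = character(), mate_id = character(),
                      stringsAsFactors = FALSE))
  }
  pos1 <- as.integer(pairs$start1) + 1L   # BEDPE 0-based start -> 1-based
  pos2 <- as.integer(pairs$start2) + 1L
  id1 <- sprintf("%s_bk%02d_1", sampleId, seq_len(n))
  id2 <- sprintf("%s_bk%02d_2", sampleId, seq_len(n))
  data.frame(
    sample_id = sampleId,
    chrom = c(pairs$chrom1, pairs$chrom2),
    pos = c(pos1, pos2),
    sv_class = rep(pairs$sv_class, 2L),
    chromothripsis_flag = rep(as.logical(pairs$chromothripsis), 2L),
    mate_chrom = c(pairs$chrom2, pairs$chrom1),
    mate_pos = c(pos2, pos1),
    bk_id = c(id1, id2),
    mate_id = c(id2, id1),
    stringsAsFactors = FALSE)
}

#' Read SV breakpoints from a BEDPE file
#'
#' Each BEDPE row yields two mated breakends. BEDPE 0-based starts are
#' converted to 1-based breakend positions (`pos = start + 1`). The
#' optional 11th/12th columns carry the SV class (DEL/DUP/INV/TRA/OTHER)
#' and a chromothripsis flag.
#'
#' @param path BEDPE file (tab separated, no header or `#`-prefixed header).
#' @param sampleId sample identifier; defaults to the file base name.
#' @return a breakend data.frame (two rows per BEDPE row, reciprocal
#'   `bk_id`/`mate_id` links).
#' @export
readSvBedpe <- function(path, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.bedpe(\\.gz)?$", "", basename(path))
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(.breakendsFromPairs(raw, sampleId))
  if (ncol(raw) < 10L)
    stop("BEDPE must have at least 10 columns", call. = FALSE)
  names(raw)[1:10] <- c("chrom1", "start1", "end1", "chrom2", "start2",
                        "end2", "name", "score", "strand1", "strand2")
  raw$sv_class <- if (ncol(raw) >= 11L) toupper(raw[[11L]]) else "OTHER"
  raw$chromothripsis <- if (ncol(raw) >= 12L) as.logical(raw[[12L]]) else FALSE
  bad <- which(!raw$sv_class %in% .SV_CLASSES)
  if (length(bad))
    stop("row ", bad[1], ": unknown SV class '", raw$sv_class[bad[1]], "'",
         call. = FALSE)
  intra <- which(raw$sv_class == "TRA" & raw$chrom1 == raw$chrom2)
  if (length(intra))
    stop("row ", intra[1], ": TRA breakends must lie on different chromosomes",
         call. = FALSE)
  .breakendsFromPairs(raw, sampleId)
}

#' Write an SV pair table as BEDPE
#'
#' @param pairs data.frame with columns chrom1, start1, end1, chrom2,
#'   start2, end2, name, score, strand1, strand2, sv_class, chromothripsis
#'   (starts 0-based per BEDPE).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSvBedpe <- function(pairs, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2", "sv_class",
            "chromothripsis")
  .assertColumns(pairs, cols, "SV pair table")
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.EVENT_COLS <- c("event_id", "sample_id", "chrom", "start", "end", "n_snv",
                 "span", "max_adjusted_imd", "epoch", "apobec_enriched",
                 "a3_class", "sv_distance", "sv_class")

#' Write a kataegis event table
#'
#' Emits one row per event with a stable column order; an optional BED
#' companion file (0-based half-open) can be written alongside.
#'
#' @param events a [KataegisEvents-class] object or event data.frame.
#' @param path output TSV path.
#' @param bedPath optional BED output path.
#' @return invisibly, the path.
#' @export
writeEvents <- function(events, path, bedPath = NULL) {
  ev <- if (is(events, "KataegisEvents")) eventTable(events) else events
  out <- data.frame(row.names = seq_len(nrow(ev)))
  for (col in .EVENT_COLS) out[[col]] <- ev[[col]] %||% rep(NA, nrow(ev))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedPath) ) {
    bed <- data.frame(chrom = out$chrom, start = out$start - 1L,
                      end = out$end, name = out$event_id)
    utils::write.table(bed[seq_len(nrow(out)), , drop = FALSE], bedPath,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a kataegis event table written by [writeEvents()]
#'
#' @param path TSV path.
#' @return event data.frame.
#' @export
readEvents <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assertColumns(df, setdiff(.EVENT_COLS, "event_id"), basename(path))
  df$sv_distance <- as.numeric(df$sv_distance)
  df$apobec_enriched <- as.logical(df$apobec_enriched)
  df
}

#' Read allele-specific copy-number segments
#'
#' @param path TSV with columns sample_id, chrom, start, end, major_cn,
#'   minor_cn (1-based inclusive coordinates).
#' @return validated data.frame.
#' @export
readCnSegments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assertColumns(df, c("sample_id", "chrom", "start", "end", "major_cn",
                       "minor_cn"), basename(path))
  if (any(df$start > df$end)) stop("CN segment with start > end")
  if (any(df$major_cn < df$minor_cn)) stop("major_cn must be >= minor_cn")
  if (any(df$minor_cn < 0)) stop("copy numbers must be non-negative")
  sp <- split(df, paste(df$sample_id, df$chrom))
  for (seg in sp) {
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stop("overlapping CN segments for ", seg$sample_id[1], " ", seg$chrom[1])
  }
  df
}

#' Read a per-sample tumour purity table
#' @param path TSV with columns sample_id, purity.
#' @return data.frame.
#' @export
readPurity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assertColumns(df, c("sample_id", "purity"), basename(path))
  if (any(df$purity <= 0 | df$purity > 1)) stop("purity must be in (0,1]")
  df
}

#' Read a clinical metadata table
#'
#' Validates the risk/grade-group consistency rule: low risk (LR) iff
#' ISUP grade group 1-2, high risk (HR) iff 3-5.
#'
#' @param path TSV with columns sample_id, ancestry, risk, isup_gg and
#'   optional psa, age, followup_days, bcr_flag, metastasis_flag.
#' @return validated data.frame.
#' @export
readClinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assertColumns(df, c("sample_id", "ancestry", "risk", "isup_gg"),
                 basename(path))
  if (any(!df$ancestry %in% c("AFR", "EUR", "ASI")))
    stop("ancestry must be one of AFR, EUR, ASI")
  expected <- ifelse(df$isup_gg %in% 1:2, "LR", "HR")
  bad <- which(df$risk != expected)
  if (length(bad))
    stop("row ", bad[1], ": risk label inconsistent with ISUP grade group")
  for (col in c("bcr_flag", "metastasis_flag"))
    if (!is.null(df[[col]])) df[[col]] <- as.logical(df[[col]])
  df
}

#' Read a reference genome from FASTA
#' @param path FASTA path (optionally faidx-indexed; the index is unused).
#' @return a [GenomeRef-class].
#' @export
readFastaRef <- function(path) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  GenomeRef(seq)
}

#' Write a reference genome to FASTA
#' @param genome a [GenomeRef-class].
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
writeFastaRef <- function(genome, path) {
  Biostrings::writeXStringSet(genome@seq, path)
  invisible(path)
}
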