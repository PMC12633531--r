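#' @include AllClasses.R io.R detect.R timing.R apobec.R svproximity.R cohort.R simulate.R
NULL

.PIPE_STAGES <- c("simulate", "detect", "time", "apobec", "svprox", "report")

.CONFIG_KEYS <- list(
  top = c("seed", "sim", "detect", "report", "stages"),
  report = c("covariates", "logTransform", "survivalModes"))

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML mapping with keys `seed` (integer), `sim`
#' (any [SimConfig-class] slot), `detect` (any [DetectionParams-class]
#' slot), `report` (covariates, logTransform, survivalModes) and `stages`
#' (subset of simulate/detect/time/apobec/svprox/report, in order).
#' Unknown keys raise an error listing the offenders.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @return a validated list with elements seed, simConfig, params,
#'   report, stages.
#' @export
readRunConfig <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- cfg %||% list()
  bad <- setdiff(names(cfg), .CONFIG_KEYS$top)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in c("sim", "detect")) {
    allowed <- methods::slotNames(if (sec == "sim") "SimConfig"
                                  else "DetectionParams")
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown ", sec, " config key(s): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(cfg$report), .CONFIG_KEYS$report)
  if (length(bad))
    stop("unknown report config key(s): ", paste(bad, collapse = ", "))
  stages <- cfg$stages %||% .PIPE_STAGES
  bad <- setdiff(stages, .PIPE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(cfg$seed %||% 1L)
  simArgs <- cfg$sim %||% list()
  if (is.null(simArgs$seed)) simArgs$seed <- saltSeed(seed, "simulate")
  if (!is.null(simArgs$chromLengths))
    simArgs$chromLengths <- unlist(simArgs$chromLengths)
  list(seed = seed,
       simConfig = do.call(simConfig, simArgs),
       params = do.call(detectionParams, cfg$detect %||% list()),
       report = list(
         covariates = cfg$report$covariates %||%
           c("sv_burden", "tmb", "chromothripsis_burden", "age"),
         logTransform = cfg$report$logTransform %||%
           c("sv_burden", "tmb", "chromothripsis_burden")),
       stages = stages)
}

.hashConfig <- function(parsed) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(list(seed = parsed$seed,
                        sim = .slotsAsList(parsed$simConfig),
                        detect = .slotsAsList(parsed$params),
                        report = parsed$report), tmp)
  unname(tools::md5sum(tmp))
}

.slotsAsList <- function(obj) {
  nm <- methods::slotNames(class(obj))
  stats::setNames(lapply(nm, function(s) {
    v <- methods::slot(obj, s)
    if (is.numeric(v)) v[!is.finite(v)] <- 9e99   # YAML-safe Inf/NA
    v
  }), nm)
}

.md5 <- function(paths) unname(tools::md5sum(paths))

# reconstruct a KataegisEvents object (with member positions) from an
# events.tsv and the SNV table it was called on
.eventsFromTable <- function(ev, snvs, params) {
  ev$member_pos <- lapply(seq_len(nrow(ev)), function(i) {
    s <- snvs[snvs$sample_id == ev$sample_id[i] &
                snvs$chrom == ev$chrom[i], , drop = FALSE]
    sort(s$pos[s$pos >= ev$start[i] & s$pos <= ev$end[i]])
  })
  if (is.null(ev$event_id))
    ev$event_id <- sprintf("%s_%s_%d", ev$sample_id, ev$chrom, ev$start)
  new("KataegisEvents", events = ev, params = params)
}

.readCohortSnvs <- function(dir, genome) {
  vcfs <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  do.call(rbind, lapply(vcfs, readSnvs, genome = genome))
}

.genomicCovariates <- function(snvs, svPairsByFile, cn) {
  ids <- sort(unique(c(snvs$sample_id, cn$sample_id)))
  do.call(rbind, lapply(ids, function(sid) {
    sv <- svPairsByFile[[sid]]
    seg <- cn[cn$sample_id == sid, , drop = FALSE]
    segLen <- seg$end - seg$start + 1
    tot <- seg$major_cn + seg$minor_cn
    data.frame(sample_id = sid,
               tmb = sum(snvs$sample_id == sid),
               sv_burden = if (is.null(sv)) 0L else nrow(sv) / 2L,
               chromothripsis_burden = if (is.null(sv)) 0L else
                 sum(sv$chromothripsis_flag[!duplicated(sub("_[12]$", "",
                                                            sv$bk_id))]),
               pga = sum(segLen[tot != 2]) / sum(segLen),
               cn_gain = sum(segLen[tot > 2]) / sum(segLen),
               stringsAsFactors = FALSE)
  }))
}

#' Run the kataegis analysis pipeline
#'
#' Orchestrates simulate, detect, time, apobec, svprox and report over a
#' single output directory with a machine-readable manifest
#' (`manifest.json`). A stage is skipped when its outputs already exist
#' with checksums recorded under an identical configuration hash and no
#' upstream stage was re-run; otherwise it executes and the manifest is
#' refreshed. Two runs with the same config and seed produce
#' byte-identical tables.
#'
#' @param config YAML path or list accepted by [readRunConfig()].
#' @param outDir output directory.
#' @param seed optional override of the config seed.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  parsed <- readRunConfig(config)
  if (!is.null(seed)) {
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    cfg$seed <- as.integer(seed)
    parsed <- readRunConfig(cfg)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohortDir <- file.path(outDir, "cohort")
  hash <- .hashConfig(parsed)
  manifestPath <- file.path(outDir, "manifest.json")
  oldManifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath) else NULL
  sameCfg <- !is.null(oldManifest) &&
    identical(oldManifest$config_hash, hash) &&
    identical(as.integer(oldManifest$seed), parsed$seed)

  outputsOf <- function(stage) switch(stage,
    simulate = c(file.path(cohortDir, "clinical.tsv"),
                 file.path(cohortDir, "cn_segments.tsv"),
                 file.path(cohortDir, "purity.tsv"),
                 file.path(cohortDir, "truth.json"),
                 file.path(cohortDir, "reference.fa")),
    detect = file.path(outDir, c("events.tsv", "rainfall.tsv")),
    time = file.path(outDir, c("epochs.tsv", "evo_events.tsv")),
    apobec = file.path(outDir, "apobec.tsv"),
    svprox = file.path(outDir, c("proximity.tsv", "events_final.tsv")),
    report = file.path(outDir, c("cohort.tsv", "comparisons.tsv",
                                 "nb_regression.tsv", "survival.tsv",
                                 "summary.json")))

  canSkip <- function(stage) {
    if (!sameCfg) return(FALSE)
    rec <- oldManifest$stages[[stage]]
    if (is.null(rec) || !rec$status %in% c("ok", "skipped")) return(FALSE)
    outs <- outputsOf(stage)
    if (!all(file.exists(outs))) return(FALSE)
    identical(unlist(rec$md5), .md5(outs))
  }

  manifest <- list(config_hash = hash, seed = parsed$seed,
                   stages = list())
  env <- new.env(parent = emptyenv())   # cross-stage in-memory cache
  upstreamRan <- FALSE

  loadGenome <- function() {
    if (is.null(env$genome))
      env$genome <- readFastaRef(file.path(cohortDir, "reference.fa"))
    env$genome
  }
  loadSnvs <- function() {
    if (is.null(env$snvs)) env$snvs <- .readCohortSnvs(cohortDir, loadGenome())
    env$snvs
  }
  loadEvents <- function() {
    if (is.null(env$events))
      env$events <- .eventsFromTable(readEvents(file.path(outDir, "events.tsv")),
                                     loadSnvs(), parsed$params)
    env$events
  }
  loadBreakends <- function() {
    if (is.null(env$breakends)) {
      beds <- sort(list.files(cohortDir, pattern = "\\.bedpe$",
                              full.names = TRUE))
      env$breakends <- do.call(rbind, lapply(beds, readSvBedpe))
    }
    env$breakends
  }
  loadClinical <- function() readClinical(file.path(cohortDir, "clinical.tsv"))
  groupsOf <- function(clin)
    stats::setNames(paste(clin$ancestry, clin$risk, sep = "_"),
                    clin$sample_id)

  runStage <- list(
    simulate = function() {
      cohort <- generateCohort(parsed$simConfig)
      emitCohort(cohort, cohortDir)
      env$genome <- cohort@genome
      list(samples = parsed$simConfig@nSamples,
           planted_events = nrow(truthEvents(cohort)))
    },
    detect = function() {
      snvs <- loadSnvs()
      ev <- callKataegis(snvs, parsed$params, loadGenome())
      env$events <- ev
      writeEvents(ev, file.path(outDir, "events.tsv"),
                  bedPath = file.path(outDir, "events.bed"))
      utils::write.table(rainfallData(snvs, ev, loadGenome()),
                         file.path(outDir, "rainfall.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(events_called = nEvents(ev),
           samples_positive = length(unique(eventTable(ev)$sample_id)))
    },
    time = function() {
      snvs <- annotateEpochs(loadSnvs(),
                             readCnSegments(file.path(cohortDir,
                                                      "cn_segments.tsv")),
                             parsed$params@clonalCcfThreshold)
      env$snvsTimed <- snvs
      utils::write.table(
        snvs[, c("sample_id", "chrom", "pos", "major_cn", "minor_cn",
                 "epoch")],
        file.path(outDir, "epochs.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      evo <- refineEvents(loadEvents(), snvs, parsed$params)
      utils::write.table(evo[, setdiff(names(evo), "member_pos")],
                         file.path(outDir, "evo_events.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(evolutionary_events = nrow(evo))
    },
    apobec = function() {
      ev <- attributeApobec(loadEvents(), loadSnvs(), loadGenome(),
                            parsed$params)
      env$events <- ev
      tb <- eventTable(ev)
      utils::write.table(tb[, setdiff(names(tb), "member_pos")],
                         file.path(outDir, "apobec.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(events_tested = nEvents(ev),
           events_enriched = sum(tb$apobec_enriched, na.rm = TRUE))
    },
    svprox = function() {
      ev <- loadEvents()
      apo <- utils::read.delim(file.path(outDir, "apobec.tsv"),
                               stringsAsFactors = FALSE)
      evTab <- eventTable(ev)
      for (col in setdiff(names(apo), names(evTab)))
        evTab[[col]] <- apo[[col]][match(evTab$event_id, apo$event_id)]
      ev <- new("KataegisEvents", events = evTab, params = parsed$params)
      groups <- groupsOf(loadClinical())
      pseudo <- simulatePseudoEvents(ev, loadSnvs(), loadGenome(),
                                     nSim = parsed$params@nSim,
                                     seed = saltSeed(parsed$seed, "svprox"))
      nulls <- proximityTest(ev, pseudo, loadBreakends(), groups,
                             parsed$params)
      prox <- do.call(rbind, lapply(nulls, function(x)
        data.frame(group = x@group, bin = .binLabels(x@edges),
                   observed = x@observed, p_enrich = x@pEnrich,
                   p_sparse = x@pSparse, fdr_enrich = x@fdrEnrich,
                   fdr_sparse = x@fdrSparse, bin_class = x@binClass,
                   stringsAsFactors = FALSE)))
      utils::write.table(prox, file.path(outDir, "proximity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ev <- classifyEventsByBin(ev, nulls, loadBreakends(), groups)
      env$events <- ev
      writeEvents(ev, file.path(outDir, "events_final.tsv"))
      tb <- eventTable(ev)
      list(events_classified = sum(tb$sv_class != "unclassified"),
           sv_associated = sum(tb$sv_class == "SV_associated"))
    },
    report = function() {
      clin <- loadClinical()
      finalEv <- readEvents(file.path(outDir, "events_final.tsv"))
      snvs <- loadSnvs()
      svByS <- split(loadBreakends(), loadBreakends()$sample_id)
      cov <- .genomicCovariates(snvs,
                                svByS,
                                readCnSegments(file.path(cohortDir,
                                                         "cn_segments.tsv")))
      cohortTab <- buildCohortTable(finalEv, clin, cov,
                                    parsed$params@outlierZ)
      utils::write.table(cohortTab, file.path(outDir, "cohort.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      kept <- cohortTab[!cohortTab$excluded_flag, , drop = FALSE]
      cmp <- do.call(rbind, lapply(
        c("tmb", "sv_burden", "chromothripsis_burden"), function(v) {
          if (length(unique(kept$positive)) < 2L)
            return(NULL)
          r <- compareGroups(kept[[v]], kept$positive)
          data.frame(variable = v, comparison = "kataegis_positivity",
                     p = r$p, median_neg = r$medians[1],
                     median_pos = r$medians[2], stringsAsFactors = FALSE)
        }))
      if (!is.null(cmp)) cmp$fdr <- stats::p.adjust(cmp$p, method = "BH")
      else cmp <- data.frame(variable = character(), comparison = character(),
                             p = numeric(), median_neg = numeric(),
                             median_pos = numeric(), fdr = numeric())
      utils::write.table(cmp, file.path(outDir, "comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      nb <- tryCatch(
        nbBurdenRegression(kept, parsed$report$covariates,
                           parsed$report$logTransform),
        error = function(e) NULL)
      nbTab <- if (is.null(nb))
        data.frame(term = "fit_failed", estimate = NA, se = NA, z = NA,
                   p = NA)
      else nb$coefficients
      utils::write.table(nbTab, file.path(outDir, "nb_regression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sv1 <- survivalStrata(cohortTab, "positivity", "bcr_or_met")
      sv2 <- survivalStrata(cohortTab, "burden_gt_1", "met_only",
                            parsed$params@burdenSplit)
      svTab <- data.frame(
        mode = c("positivity", "burden_gt_1"),
        endpoint = c("bcr_or_met", "met_only"),
        n = c(sv1$n, sv2$n), p = c(sv1$p, sv2$p),
        note = c(sv1$note %||% NA, sv2$note %||% NA))
      utils::write.table(svTab, file.path(outDir, "survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      epochs <- utils::read.delim(file.path(outDir, "epochs.tsv"),
                                  stringsAsFactors = FALSE)
      snvsE <- snvs
      snvsE$epoch <- epochs$epoch[match(paste(snvs$sample_id, snvs$chrom,
                                              snvs$pos),
                                        paste(epochs$sample_id, epochs$chrom,
                                              epochs$pos))]
      evObj <- .eventsFromTable(finalEv, snvs, parsed$params)
      props <- epochProportions(snvsE, evObj)
      evo <- utils::read.delim(file.path(outDir, "evo_events.tsv"),
                               stringsAsFactors = FALSE)
      summary <- list(
        n_samples = nrow(cohortTab),
        n_events = nrow(finalEv),
        kataegis_positive_pct =
          round(100 * mean(cohortTab$positive), 1),
        median_events_per_positive =
          stats::median(cohortTab$kataegis_count[cohortTab$positive]),
        median_snvs_per_event = stats::median(finalEv$n_snv),
        median_event_span_kb = round(stats::median(finalEv$span) / 1000, 2),
        apobec_enriched_pct = round(100 * mean(finalEv$apobec_enriched,
                                               na.rm = TRUE), 1),
        clonal_evo_event_pct = if (nrow(evo))
          round(100 * mean(startsWith(evo$epoch, "clonal")), 1) else NA,
        clonal_kataegis_median_pct =
          round(100 * unname(props$medians["kataegis"]), 1),
        clonal_genomewide_median_pct =
          round(100 * unname(props$medians["genomewide"]), 1),
        sv_within_1kb_pct = round(100 * mean(finalEv$sv_distance < 1e3), 1),
        sv_within_10kb_pct = round(100 * mean(finalEv$sv_distance < 1e4), 1),
        sv_spanning_pct = round(100 * mean(finalEv$sv_distance == 0), 1),
        sv_associated_pct =
          round(100 * mean(finalEv$sv_class == "SV_associated"), 1))
      jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(samples = nrow(cohortTab),
           excluded = sum(cohortTab$excluded_flag))
    })

  for (stage in parsed$stages) {
    if (!upstreamRan && canSkip(stage)) {
      manifest$stages[[stage]] <- oldManifest$stages[[stage]]
      manifest$stages[[stage]]$status <- "skipped"
      message("stage ", stage, ": skipped (outputs up to date)")
      next
    }
    message("stage ", stage, ": running")
    counts <- runStage[[stage]]()
    upstreamRan <- TRUE
    manifest$stages[[stage]] <- list(status = "ok", counts = counts,
                                     md5 = .md5(outputsOf(stage)))
  }
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
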